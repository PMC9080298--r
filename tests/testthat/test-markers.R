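test_that("one-way ANOVA follows the classic F and its degenerate policies", {
  set.seed(41)
  # against the standard ANOVA machinery on regular data
  g <- list(rnorm(8), rnorm(10, 0.5), rnorm(6, 1))
  mine <- anova_bonferroni(g)
  df <- data.frame(v = unlist(g), grp = factor(rep(1:3, lengths(g))))
  ref <- summary(aov(v ~ grp, df))[[1]]
  expect_equal(mine$F, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p_raw, ref[1, "Pr(>F)"], tolerance = 1e-10)

  # two groups: F equals the squared pooled-variance t statistic
  g2 <- list(rnorm(7), rnorm(9, 0.8))
  mine2 <- anova_bonferroni(g2)
  tt <- t.test(g2[[1]], g2[[2]], var.equal = TRUE)
  expect_equal(mine2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(mine2$p_raw, tt$p.value, tolerance = 1e-10)

  # identical groups: F = 0, p = 1
  same <- anova_bonferroni(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(same$F, 0)
  expect_equal(same$p_raw, 1)
  # zero within-group variance, unequal means: p floored near zero
  sep <- anova_bonferroni(list(c(1, 1), c(2, 2)))
  expect_lte(sep$p_adj, 1e-300 * 10)
  expect_error(anova_bonferroni(list(1:3)), "2 groups")
  expect_error(anova_bonferroni(list(1, 1:3)), "2 values")
})

test_that("Bonferroni adjustment is monotone and order-invariant", {
  set.seed(42)
  ps <- replicate(20, anova_bonferroni(list(rnorm(5), rnorm(5, 0.5)),
                                       m = 7))
  p_raw <- unlist(ps["p_raw", ]); p_adj <- unlist(ps["p_adj", ])
  expect_true(all(p_adj >= p_raw))
  expect_true(all(p_adj <= 1))
  expect_equal(p_adj, pmin(1, p_raw * 7))
})

test_that("fold change has ratio semantics with a strict up threshold", {
  expect_equal(fold_change(c(6, 6), c(4, 4)), list(fc = 1.5, trend = "up"))
  # equal means: the boundary resolves as down (up requires fc > 1)
  expect_equal(fold_change(c(2, 4), c(3, 3))$trend, "down")
  expect_equal(fold_change(c(2, 4), c(3, 3))$fc, 1)
  out <- fold_change(c(1, 2), c(0, 0))
  expect_true(is.na(out$fc))
  expect_match(attr(out, "reason"), "zero")
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("rank-based AUC equals exhaustive pair counting", {
  set.seed(43)
  for (i in 1:30) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    v <- round(c(rnorm(n1, 1), rnorm(n2)), sample(0:2, 1))  # force some ties
    lab <- c(rep(TRUE, n1), rep(FALSE, n2))
    mine <- roc_auc(v, lab)
    pairs <- outer(v[lab], v[!lab], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(mine$auc, mean(pairs), tolerance = 1e-12)
    # anti-symmetry under label flip
    expect_equal(roc_auc(v, !lab)$auc, 1 - mine$auc, tolerance = 1e-12)
  }
})

test_that("AUC edge cases and cross-check against pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(5, 5, 5, 5), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
  skip_if_not_installed("pROC")
  set.seed(44)
  v <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, v, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(v, lab)$auc, ref, tolerance = 1e-12)
})

test_that("the selection cascade recovers planted markers", {
  fit <- small_fit()
  man <- fit$study$manifest
  for (cl in fit$cfg$classes) {
    sel <- select_markers(fit$model, fit$prep, cl)
    hits <- sel$feature_id[sel$passes]
    truth <- man$feature_id[man$class == cl]
    expect_gte(mean(truth %in% hits), 0.8)
    expect_lte(mean(!hits %in% truth), 0.2)
    # sorted by AUC among the passing rows
    expect_true(!is.unsorted(rev(sel$auc[sel$passes])))
    # the cascade semantics of the passes flag
    expect_identical(sel$passes,
                     !is.na(sel$fc) & sel$p_adj < 0.05 & sel$auc > 0.50)
    expect_true(all(sel$vip > 1))
  }
  # deterministic: a second run gives the identical table
  expect_identical(select_markers(fit$model, fit$prep, "microtubule"),
                   select_markers(fit$model, fit$prep, "microtubule"))
})

test_that("selected markers export in the published-table schema", {
  fit <- small_fit()
  sel <- select_markers(fit$model, fit$prep, "microtubule")
  rec <- marker_records(sel, fit$prep)
  expect_identical(names(rec), names(load_marker_fixtures()))
  expect_equal(nrow(rec), sum(sel$passes))
  expect_true(all(rec$p_flag %in% c("<0.05", "<0.01", "<0.001")))
  expect_identical(rec$trend == "up", rec$fc > 1)
  # rt and m/z are recovered from the feature ids
  expect_false(anyNA(rec$rt))
  expect_false(anyNA(rec$mz))
})

test_that("a no-effect study yields almost no markers", {
  cfg <- small_config(effect_size = 0, seed = 13)
  study <- generate_study(cfg)
  prep <- preprocess_study(study$rp, study$hilic, study$meta)
  tr <- prep$meta$condition == "treated"
  m <- oplsda(subset_scaled_fixture(prep$scaled, tr),
              factor(prep$meta$class[tr]), n_orth = 0, cv_folds = 0)
  sel <- select_markers(m, prep, cfg$classes[1])
  # Bonferroni keeps expected false positives near alpha x families
  expect_lte(sum(sel$passes), max(2, ceiling(0.05 * attr(sel, "m"))))
})

test_that("hierarchical clustering of fold changes behaves canonically", {
  # two identical rows merge at height zero and sit adjacent
  fc <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 9, 9, 9),
              d = c(5, 5, 5, 5))
  hm <- cluster_heatmap(fc, k = 2)
  expect_equal(hm$row_hclust$height[1], 0)
  ia <- match(1, hm$row_order); ib <- match(2, hm$row_order)
  expect_equal(abs(ia - ib), 1)

  # 1-D toy: cut at k = 2 splits the two obvious groups
  toy <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
                dimnames = list(c("w", "x", "y", "z"), NULL))
  cl <- cluster_heatmap(toy, k = 2)$clusters
  expect_equal(cl[["w"]], cl[["x"]])
  expect_equal(cl[["y"]], cl[["z"]])
  expect_false(cl[["w"]] == cl[["y"]])
  # agreement with the standard linkage implementation
  ref <- cutree(hclust(dist(toy), "average"), 2)
  expect_equal(unname(cl), unname(ref))

  # block-structured matrix: the k = 4 cut recovers the planted blocks
  set.seed(45)
  blocks <- rep(1:4, each = 6)
  fc4 <- t(vapply(blocks, function(b) {
    base <- c(0.2, 1, 2.5, 4)[b]
    rnorm(4, mean = ifelse(seq_len(4) == b, base + 3, base), sd = 0.1)
  }, numeric(4)))
  hm4 <- cluster_heatmap(fc4, k = 4)
  expect_equal(adjusted_rand(hm4$clusters, blocks), 1)

  expect_warning(cluster_heatmap(matrix(1, 3, 2)), "single cluster")
  expect_error(cluster_heatmap(matrix(1, 1, 2)), "2 marker rows")
})
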