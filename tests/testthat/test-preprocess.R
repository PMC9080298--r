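test_that("feature alignment follows the greedy windowed rule", {
  # two samples whose peaks differ by 0.3 min / 0.03 Da: one fused feature
  pl <- list(
    A = data.frame(rt = 5.0, mz = 100.00, intensity = 1e5),
    B = data.frame(rt = 5.3, mz = 100.03, intensity = 9e4))
  tab <- align_features(pl, block = "HILIC")
  expect_equal(dim(tab), c(1L, 2L))
  expect_equal(unname(tab$intensities[1, ]), c(1e5, 9e4))
  # the seed (most intense) peak defines the feature's rt and m/z
  expect_equal(tab$features$rt, 5.0)

  # outside either window: two features, zeros where unmatched
  pl$B <- data.frame(rt = 5.3, mz = 100.07, intensity = 9e4)
  tab2 <- align_features(pl, block = "HILIC")
  expect_equal(dim(tab2)[1], 2L)
  expect_equal(sort(unname(as.vector(tab2$intensities))), c(0, 0, 9e4, 1e5))
})

test_that("self-alignment of identical peak lists preserves the peak count", {
  set.seed(4)
  one <- data.frame(rt = runif(20, 1, 30), mz = runif(20, 130, 900),
                    intensity = runif(20, 1e4, 1e6))
  tab <- align_features(list(A = one, B = one, C = one))
  expect_equal(dim(tab), c(20L, 3L))
})

test_that("peaks below 5% of the base peak are discarded", {
  pl <- list(A = data.frame(rt = c(5, 10), mz = c(200, 300),
                            intensity = c(1e6, 4e4)))   # 4% of base peak
  tab <- align_features(pl)
  expect_equal(dim(tab)[1], 1L)
  expect_equal(tab$features$mz, 200)
  # at exactly 5% the peak is kept
  pl$A$intensity[2] <- 5e4
  expect_equal(dim(align_features(pl))[1], 2L)
})

test_that("missing-value filter is strict and idempotent", {
  features <- data.frame(feature_id = c("RP_a", "RP_b", "RP_c"), block = "RP",
                         rt = 1:3, mz = c(200, 300, 400))
  intens <- rbind(c(rep(1, 7), 0, 0, 0),      # 30% zeros: out
                  c(rep(1, 8), 0, 0),         # 20% zeros: kept (strict >)
                  rep(1, 10))
  colnames(intens) <- sprintf("S%02d", 1:10)
  tab <- peak_table(features, intens)
  filt <- filter_missing(tab, 0.20)
  expect_setequal(filt$features$feature_id, c("RP_b", "RP_c"))
  expect_equal(filter_missing(filt, 0.20), filt)          # idempotent
  expect_equal(filter_missing(tab, 0), # threshold 0 drops any zero
               filter_missing(filter_missing(tab, 0), 0))
  expect_equal(filter_missing(tab, 0)$features$feature_id, "RP_c")
  # no zeros anywhere: identity
  clean <- peak_table(features, matrix(1, 3, 10,
                                       dimnames = list(NULL, colnames(intens))))
  expect_equal(filter_missing(clean), clean)
})

test_that("cell-count normalization rescales to the median count", {
  fit <- small_fit()
  tab <- fit$study$rp
  meta <- fit$study$meta
  norm <- normalize_cell_count(tab, meta)
  med <- median(meta$cell_count[meta$condition != "qc"])
  s <- meta$sample_id[meta$condition == "treated"][1]
  fac <- med / meta$cell_count[meta$sample_id == s]
  expect_equal(norm$intensities[, s], tab$intensities[, s] * fac)
  # QC samples pass through untouched
  qc <- meta$sample_id[meta$condition == "qc"][1]
  expect_equal(norm$intensities[, qc], tab$intensities[, qc])
  # equal counts = identity
  meta2 <- meta; meta2$cell_count[meta2$condition != "qc"] <- 1e6
  expect_equal(normalize_cell_count(tab, meta2)$intensities, tab$intensities)
  # a sample at twice the median is halved
  meta3 <- meta2
  meta3$cell_count[meta3$sample_id == s] <- 2e6
  expect_equal(normalize_cell_count(tab, meta3)$intensities[, s],
               tab$intensities[, s] / 2)
})

test_that("log10 transform applies the half-minimum zero rule", {
  m <- matrix(c(1, 10, 100, 0, 10, 20), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  out <- log10_transform(m)
  expect_equal(unname(out[, "f1"]), c(0, 1, 2))
  expect_equal(unname(out[, "f2"]), c(log10(5), 1, log10(20)))
  m[2, ] <- 0
  expect_error(log10_transform(m), "all-zero")
})

test_that("Pareto scaling has the documented algebraic identities", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 14))
  sc <- pareto_scale(x)
  expect_equal(unname(sc$X[, "a"]), c(-1, 0, 1))          # sd 1, sqrt 1
  expect_equal(unname(sc$X[, "b"]), c(0, 0, 0))           # constant column
  # scaled column variance equals the original column sd
  expect_equal(var(sc$X[, "c"]), sd(x[, "c"]))
  expect_equal(var(sc$X[, "a"]), sd(x[, "a"]))
  # stored center/scale invert the transform exactly
  expect_lt(max(abs(back_transform(sc) - x)), 1e-10)
  expect_error(pareto_scale(x[1, , drop = FALSE]), "2 samples")

  big <- small_fit()$prep$scaled
  raw <- back_transform(big)
  expect_lt(max(abs(pareto_scale(raw)$X - big$X)), 1e-10)
})

test_that("block fusion concatenates features and harmonizes sample order", {
  set.seed(8)
  n <- 12
  rp <- pareto_scale(matrix(rnorm(n * 30), n,
                            dimnames = list(sprintf("S%02d", 1:n),
                                            sprintf("RP_%d", 1:30))),
                     block = rep("RP", 30))
  hi_x <- matrix(rnorm(n * 20), n,
                 dimnames = list(sprintf("S%02d", 1:n), sprintf("HI_%d", 1:20)))
  hi <- pareto_scale(hi_x, block = rep("HILIC", 20))
  fused <- fuse_blocks(rp, hi)
  expect_equal(ncol(fused$X), 50)
  expect_equal(fused$block, rep(c("RP", "HILIC"), c(30, 20)))

  # permuting one block's sample order changes nothing
  perm <- sample(n)
  hi_perm <- pareto_scale(hi_x[perm, ], block = rep("HILIC", 20))
  expect_equal(fuse_blocks(rp, hi_perm)$X, fused$X)

  hi_bad <- hi; hi_bad$sample_id[1] <- "S99"
  expect_error(fuse_blocks(rp, hi_bad), "S99")
})

test_that("the pipeline runner enforces the fixed stage order", {
  prep <- small_fit()$prep
  expect_equal(prep$stages,
               c("align (upstream)", "filter", "normalize", "log10",
                 "scale", "fuse"))
  expect_false(any(is.na(prep$scaled$X)))
  expect_false(any(is.na(prep$log)))
})

test_that("fusing both blocks tends to outperform either block alone", {
  # the motivation for combining RP and HILIC: over repeated simulated
  # studies the fused model's cross-validated Q2 matches or beats the best
  # single-block model in a clear majority of runs
  wins <- 0L
  for (s in 1:10) {
    cfg <- synthetic_config(n_cell_lines = 4, n_features_rp = 80,
                            n_features_hilic = 60, markers_per_class = 8,
                            seed = s)
    study <- generate_study(cfg)
    prep <- preprocess_study(study$rp, study$hilic, study$meta)
    tr <- prep$meta$condition == "treated"
    y <- factor(prep$meta$class[tr])
    q2_fused <- cross_validate(subset_scaled_fixture(prep$scaled, tr), y,
                               folds = 7, n_orth = 1, seed = s)$q2
    q2_block <- vapply(c("RP", "HILIC"), function(b) {
      sm <- block_subset_fixture(prep$scaled, b)
      cross_validate(subset_scaled_fixture(sm, tr), y, folds = 7,
                     n_orth = 1, seed = s)$q2
    }, numeric(1))
    wins <- wins + (q2_fused >= max(q2_block))
  }
  expect_gte(wins, 7)
})
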