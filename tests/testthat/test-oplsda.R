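centered_cols <- function(m) sweep(m, 2, colMeans(m))

test_that("NIPALS with a single-column response reduces to PLS1", {
  set.seed(31)
  for (i in 1:5) {
    X <- centered_cols(matrix(rnorm(25 * 10), 25))
    y <- centered_cols(matrix(rnorm(25), 25))
    fit <- fit_pls2_nipals(X, y, 3)
    ora <- pls1_oracle(X, drop(y), 3)
    for (a in 1:3) {
      s <- sign(sum(fit$W[, a] * ora$W[, a]))
      expect_lt(max(abs(fit$W[, a] - s * ora$W[, a])), 1e-8)
      expect_lt(max(abs(fit$T[, a] - s * ora$T[, a])), 1e-8)
      expect_lt(max(abs(fit$P[, a] - s * ora$P[, a])), 1e-8)
    }
  }
})

test_that("NIPALS recovers trivial structure", {
  set.seed(32)
  # orthogonal X columns, y = first column: the weight is e1 and one
  # component explains the response completely
  Q <- qr.Q(qr(matrix(rnorm(20 * 5), 20)))
  fit2 <- fit_pls2_nipals(Q, Q[, 1, drop = FALSE], 1)
  expect_lt(max(abs(abs(fit2$W[, 1]) - c(1, 0, 0, 0, 0))), 1e-8)
  r2y <- 1 - sum(fit2$Y_residual^2) / sum(Q[, 1]^2)
  expect_gt(r2y, 0.999)
  # correlated columns need more components but still converge on an
  # X-column response
  X <- centered_cols(matrix(rnorm(20 * 6), 20))
  full <- fit_pls2_nipals(X, X[, 1, drop = FALSE], 6)
  expect_gt(1 - sum(full$Y_residual^2) / sum(X[, 1]^2), 0.999)
  expect_error(fit_pls2_nipals(matrix(0, 5, 3), Q[1:5, 1, drop = FALSE], 1),
               "variance")
})

test_that("OPLS-DA without orthogonal components is exactly PLS2", {
  set.seed(33)
  for (i in 1:20) {
    X <- centered_cols(matrix(rnorm(30 * 15), 30))
    y <- factor(sample(c("a", "b", "c"), 30, replace = TRUE,
                       prob = c(0.4, 0.3, 0.3)))
    while (min(table(y)) < 4)
      y <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
    m <- oplsda(X, y, n_pred = 2, n_orth = 0, cv_folds = 0)
    Y <- cbind(a = y == "a", b = y == "b", c = y == "c") + 0
    Yc <- centered_cols(Y)
    pls <- fit_pls2_nipals(X, Yc, 2)
    B <- pls$W %*% solve(crossprod(pls$P, pls$W), t(pls$C))
    yhat_oracle <- sweep(X %*% B, 2, colMeans(Y), `+`)
    expect_lt(max(abs(predict(m, X) - yhat_oracle)), 1e-8)
  }
})

test_that("four classes give a 4-column dummy and 3 predictive components", {
  m <- small_fit()$model
  expect_equal(m$y_levels, moa_classes())
  expect_equal(m$n_pred, 3)
  expect_equal(ncol(m$C), 3)
  expect_equal(nrow(m$C), 4)
})

test_that("planted Y-orthogonal variation is removed from predictive scores", {
  set.seed(34)
  n <- 40; p <- 20
  # signal lives in features 1-10; features 11-20 are empty in the base data
  X <- matrix(0, n, p)
  X[, 1:10] <- rnorm(n * 10)
  y <- gl(2, n / 2)
  X[y == 2, 1:4] <- X[y == 2, 1:4] + 1.5
  X <- centered_cols(X)
  # nuisance score: orthogonal (by construction) to the class contrast and
  # to every signal feature, loading only on the empty feature block
  g0 <- rep(c(-1, 1), n / 2)
  g <- residuals(lm(g0 ~ X[, 1:10] + as.integer(y)))
  nuis <- g %o% c(rep(0, 10), rep(2, 10))
  Xa <- centered_cols(X + nuis)
  base <- oplsda(X, y, n_pred = 1, n_orth = 1, cv_folds = 0)
  aug <- oplsda(Xa, y, n_pred = 1, n_orth = 1, cv_folds = 0)
  s <- sign(sum(base$T[, 1] * aug$T[, 1]))
  expect_lt(max(abs(aug$T[, 1] * s - base$T[, 1])), 1e-6)
  # while the unsupervised view does change
  expect_gt(max(abs(abs(fit_pca(Xa, 1)$scores) - abs(fit_pca(X, 1)$scores))),
            0.5)
})

test_that("VIP normalization and limiting behavior", {
  m <- small_fit()$model
  expect_equal(mean(vip(m)^2), 1, tolerance = 1e-12)

  set.seed(35)
  n <- 40; p <- 25
  X <- matrix(rnorm(n * p, sd = 0.05), n)
  y <- gl(2, n / 2)
  X[y == 2, 1] <- X[y == 2, 1] + 5
  X <- centered_cols(X)
  m1 <- oplsda(X, y, n_pred = 1, n_orth = 0, cv_folds = 0)
  expect_equal(unname(vip(m1)[1]), sqrt(p), tolerance = 0.05)
  expect_equal(mean(vip(m1)^2), 1, tolerance = 1e-12)
})

test_that("model invariants hold on every fit", {
  for (m in list(small_fit()$model,
                 oplsda(centered_cols(matrix(rnorm(60 * 12), 60)),
                        gl(3, 20), n_orth = 2, cv_folds = 0))) {
    expect_lt(max(abs(crossprod(m$W) - diag(m$n_pred))), 1e-8)
    if (m$n_orth > 0)
      expect_lt(max(abs(crossprod(m$To, m$T))),
                1e-8 * sqrt(sum(m$T^2) * sum(m$To^2)))
  }
})

test_that("R2Y grows with predictive components; Q2 can fall", {
  fit <- small_fit()
  r2 <- vapply(1:4, function(a)
    oplsda(fit$x, fit$y, n_pred = a, n_orth = 0, cv_folds = 0)$R2Y,
    numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  # overfitting is detectable: on pure noise Q2 sits at or below ~0
  set.seed(36)
  Xn <- centered_cols(matrix(rnorm(40 * 30), 40))
  yn <- gl(4, 10)
  q2 <- cross_validate(Xn, yn, folds = 5, n_pred = 3, n_orth = 0, seed = 1)$q2
  expect_lt(q2, 0.1)
})

test_that("sample order does not matter beyond score row order", {
  fit <- small_fit()
  set.seed(38)
  perm <- sample(seq_along(fit$y))
  x2 <- fit$x
  x2$X <- x2$X[perm, , drop = FALSE]
  x2$sample_id <- x2$sample_id[perm]
  m1 <- small_fit()$model
  m2 <- oplsda(x2, fit$y[perm], n_orth = 1, cv_folds = 0)
  expect_equal(abs(m2$T), abs(m1$T[perm, , drop = FALSE]), tolerance = 1e-6)
  expect_equal(m2$R2Y, m1$R2Y, tolerance = 1e-10)
  expect_equal(m2$vip, m1$vip, tolerance = 1e-8)
})

test_that("two-class assignment agrees with an independent PLS-DA oracle", {
  set.seed(37)
  for (i in 1:20) {
    n <- 24; p <- 10
    Xtr <- matrix(rnorm(n * p), n)
    ytr <- gl(2, n / 2, labels = c("a", "b"))
    Xtr[ytr == "b", 1:3] <- Xtr[ytr == "b", 1:3] + rnorm(1, 1, 0.2)
    Xtr <- centered_cols(Xtr)
    Xte <- Xtr[sample(n, 8), , drop = FALSE]
    m <- oplsda(Xtr, ytr, n_pred = 1, n_orth = 0, cv_folds = 0)
    mine <- predict(m, Xte, type = "class")
    yhat <- plsda2_oracle_predict(Xtr, ytr, Xte, 1)
    oracle <- c("a", "b")[max.col(yhat, ties.method = "first")]
    expect_equal(as.character(mine), oracle)
  }
})

test_that("projection is self-consistent and exact on training data", {
  fit <- small_fit()
  m <- fit$model
  raw <- back_transform(fit$x)
  expect_equal(unname(predict(m, raw)), unname(fitted(m)), tolerance = 1e-10)
  # a duplicated training sample projects to identical scores
  dup <- raw[c(1, 1), , drop = FALSE]
  sc <- predict(m, dup, type = "scores")
  expect_equal(sc$t_pred[1, ], sc$t_pred[2, ])
  # feature mismatch is reported by id
  expect_error(predict(m, raw[, -3]), fit$x$feature_id[3])
})

test_that("held-out samples of a class land in that class's score region", {
  fit <- small_fit()
  nd <- generate_new_drug_set(fit$cfg, "microtubule", 20, seed = 404)
  xn <- apply_preprocess(fit$prep, nd$rp, nd$hilic, nd$meta)
  sc <- predict(fit$model, xn, type = "scores")
  hull_pts <- fit$model$T[fit$model$y == "microtubule", 1:2]
  hull <- hull_pts[grDevices::chull(hull_pts), ]
  inside <- mgcv::in.out(rbind(hull, hull[1, ]),
                         rbind(colMeans(sc$t_pred)[1:2]))
  expect_true(all(inside))
})

test_that("cross-validation separates signal from permuted labels", {
  cfg <- small_config(effect_size = 2, seed = 55)
  study <- generate_study(cfg)
  prep <- preprocess_study(study$rp, study$hilic, study$meta)
  tr <- prep$meta$condition == "treated"
  x <- subset_scaled_fixture(prep$scaled, tr)
  y <- factor(prep$meta$class[tr])
  expect_gt(cross_validate(x, y, folds = 7, n_orth = 1, seed = 1)$q2, 0.9)

  q2_null <- vapply(1:20, function(s) {
    yp <- with_seed(s, sample(y))
    cross_validate(x, yp, folds = 7, n_orth = 0, seed = s)$q2
  }, numeric(1))
  expect_true(all(q2_null <= 0.1))
  expect_lt(median(q2_null), 0)
})

test_that("fold assignment is stratified, deterministic, and guarded", {
  y <- factor(rep(c("a", "b", "c"), times = c(14, 14, 14)))
  f1 <- stratified_folds(y, 7, seed = 3)
  f2 <- stratified_folds(y, 7, seed = 3)
  expect_identical(f1, f2)
  for (k in 1:7) expect_setequal(unique(y[f1 == k]), levels(y))
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(3, 20))), 7),
               "fewer samples")
})
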