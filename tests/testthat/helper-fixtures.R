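# Shared fixtures, built once per test run and memoized so several test
# files can reuse the expensive ones (the default-scale study in
# particular).

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a small study: 3 cell lines, 100 features, same structure as the default
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cell_lines = 3, n_features_rp = 60, n_features_hilic = 40,
                   markers_per_class = 6, seed = 42)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

small_fit <- function() {
  get_fixture("small_fit", function() {
    cfg <- small_config()
    study <- generate_study(cfg)
    prep <- preprocess_study(study$rp, study$hilic, study$meta)
    treated <- prep$meta$condition == "treated"
    x <- subset_scaled_fixture(prep$scaled, treated)
    y <- factor(prep$meta$class[treated])
    model <- oplsda(x, y, n_orth = 1, cv_folds = 0)
    list(cfg = cfg, study = study, prep = prep, x = x, y = y, model = model)
  })
}

# the full default-scale study design (12 cell lines, 500 features): the
# scale on which the headline recovery and Q2 checks run
default_fit <- function() {
  get_fixture("default_fit", function() {
    cfg <- synthetic_config(seed = 101)
    study <- generate_study(cfg)
    prep <- preprocess_study(study$rp, study$hilic, study$meta)
    treated <- prep$meta$condition == "treated"
    x <- subset_scaled_fixture(prep$scaled, treated)
    y <- factor(prep$meta$class[treated])
    model <- oplsda(x, y, n_orth = 1, cv_folds = 7, seed = 101)
    list(cfg = cfg, study = study, prep = prep, x = x, y = y, model = model)
  })
}

# sample subset of a scaled_matrix, keeping the stored center/scale
subset_scaled_fixture <- function(sm, idx) {
  sm$X <- sm$X[idx, , drop = FALSE]
  sm$sample_id <- sm$sample_id[idx]
  sm
}

# restrict a scaled_matrix to one chromatographic block
block_subset_fixture <- function(sm, block) {
  keep <- sm$block == block
  sm$X <- sm$X[, keep, drop = FALSE]
  sm$center <- sm$center[keep]
  sm$scale <- sm$scale[keep]
  sm$feature_id <- sm$feature_id[keep]
  sm$block <- sm$block[keep]
  sm
}

# independent multi-component PLS1 oracle: dominant-direction extraction by
# explicit linear algebra (no NIPALS), for single-column responses
pls1_oracle <- function(X, y, ncomp) {
  W <- matrix(0, ncol(X), ncomp); P <- matrix(0, ncol(X), ncomp)
  T <- matrix(0, nrow(X), ncomp); C <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(X, y)); w <- w / sqrt(sum(w^2))
    tt <- drop(X %*% w)
    cc <- sum(y * tt) / sum(tt^2)
    pp <- drop(crossprod(X, tt)) / sum(tt^2)
    X <- X - tcrossprod(tt, pp)
    y <- y - tt * cc
    W[, a] <- w; P[, a] <- pp; T[, a] <- tt; C[a] <- cc
  }
  list(W = W, P = P, T = T, C = C)
}

# independent two-class PLS-DA oracle: eigen-based weight extraction
# (dominant eigenvector of X'YY'X), then least-squares on scores
plsda2_oracle_predict <- function(Xtr, ytr, Xte, ncomp) {
  Y <- cbind(as.integer(ytr == levels(ytr)[1]),
             as.integer(ytr == levels(ytr)[2]))
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  Ttr <- matrix(0, nrow(Xtr), ncomp); Tte <- matrix(0, nrow(Xte), ncomp)
  for (a in seq_len(ncomp)) {
    e <- eigen(crossprod(Xtr, Yc) %*% t(crossprod(Xtr, Yc)), symmetric = TRUE)
    w <- e$vectors[, 1]
    tt <- drop(Xtr %*% w)
    pp <- drop(crossprod(Xtr, tt)) / sum(tt^2)
    cc <- drop(crossprod(Yc, tt)) / sum(tt^2)
    Tte[, a] <- drop(Xte %*% w)
    Ttr[, a] <- tt
    Xte <- Xte - tcrossprod(Tte[, a], pp)
    Xtr <- Xtr - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, cc)
  }
  # regress class indicators on training scores, predict held-out
  Y0 <- sweep(Y, 2, ym)
  B <- solve(crossprod(Ttr), crossprod(Ttr, Y0))
  sweep(Tte %*% B, 2, ym, `+`)
}

# adjusted Rand index between two partitions (small oracle for clustering)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# mean silhouette width over the first two score dimensions
mean_silhouette <- function(scores, classes) {
  d <- as.matrix(stats::dist(scores))
  cls <- as.character(classes)
  s <- vapply(seq_along(cls), function(i) {
    own <- d[i, cls == cls[i] & seq_along(cls) != i]
    a <- mean(own)
    b <- min(vapply(setdiff(unique(cls), cls[i]), function(cl)
      mean(d[i, cls == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
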