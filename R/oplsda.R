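#' NIPALS PLS2 factorization
#'
#' Reference partial-least-squares backbone: components are extracted one at
#' a time by the alternating NIPALS iteration. Per component, starting from
#' the largest-variance Y column as `u`: `w = X'u / ||X'u||`, `t = Xw`,
#' `c = Y't / t't`, `u = Yc / c'c`, iterated until the relative change in
#' `t` drops below `tol`; then `p = X't / t't` and both blocks are deflated
#' (`X <- X - tp'`, `Y <- Y - tc'`). With a single-column Y the iteration
#' converges in one pass and reduces to PLS1.
#'
#' @param X centered (scaled) predictor matrix, samples x features.
#' @param Yc column-centered response matrix, samples x K.
#' @param n_components number of components to extract.
#' @param tol convergence tolerance on the score vector (default 1e-10).
#' @param max_iter iteration cap per component (default 2000).
#' @param on_nonconvergence what to do when a component has not converged
#'   after `max_iter` iterations: `"error"` (default), `"warn"` (keep the
#'   current direction and warn), or `"continue"` (keep it silently).
#'   Non-convergence arises when the two leading latent directions are
#'   nearly degenerate -- typically on label-free (null) data, where any
#'   direction inside the degenerate subspace is an equally valid
#'   stationary point.
#' @return list with matrices `W` (weights, unit-norm columns), `P`
#'   (X loadings), `T` (X scores), `C` (Y loadings), `U` (Y scores), and
#'   `ssy_explained` (Y sum of squares captured per component, used by VIP).
#' @export
fit_pls2_nipals <- function(X, Yc, n_components, tol = 1e-10, max_iter = 2000,
                            on_nonconvergence = c("error", "warn",
                                                  "continue")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(is.matrix(X))
  Yc <- as.matrix(Yc)
  if (all(abs(X) < .Machine$double.eps))
    stop("X has no variance; nothing to fit")
  n <- nrow(X); p <- ncol(X); k <- ncol(Yc)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  T <- matrix(0, n, n_components); C <- matrix(0, k, n_components)
  U <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps)
        stop("zero weight vector at component ", a,
             " (X carries no Y-related variance)")
      w <- w / nw
      tt <- X %*% w
      cc <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% cc / sum(cc^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
      if (it == max_iter) {
        msg <- paste0("NIPALS did not converge in ", max_iter,
                      " iterations at component ", a)
        switch(on_nonconvergence,
               error = stop(msg),
               warn = warning(msg, "; keeping the current direction"),
               continue = NULL)
      }
    }
    pp <- crossprod(X, tt) / sum(tt^2)
    ssy[a] <- sum(tt^2) * sum(cc^2)
    X <- X - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- pp; T[, a] <- tt; C[, a] <- cc; U[, a] <- u
  }
  list(W = W, P = P, T = T, C = C, U = U, ssy_explained = ssy,
       X_residual = X, Y_residual = Yc)
}

# Orthogonal-variation removal (Trygg-Wold style, multi-Y): per round, take
# the loading p of one PLS pass and strip its projection onto the
# orthonormal basis of X'Y (the Y-predictive weight space); what remains is
# a weight vector orthogonal to Y, whose component is deflated from X.
remove_orthogonal <- function(X, Yc, n_orth, tol = 1e-10, max_iter = 2000) {
  nonconv <- "continue"
  p <- ncol(X)
  Wo <- matrix(0, p, n_orth); Po <- matrix(0, p, n_orth)
  To <- matrix(0, nrow(X), n_orth)
  kept <- 0L
  for (j in seq_len(n_orth)) {
    V <- qr.Q(qr(crossprod(X, Yc)))          # predictive w-basis
    one <- fit_pls2_nipals(X, Yc, 1L, tol, max_iter, nonconv)
    w_o <- one$P[, 1] - V %*% crossprod(V, one$P[, 1])
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break                    # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- X %*% w_o
    p_o <- crossprod(X, t_o) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    kept <- j
    Wo[, j] <- w_o; Po[, j] <- p_o; To[, j] <- t_o
  }
  idx <- seq_len(kept)
  list(X = X, Wo = Wo[, idx, drop = FALSE], Po = Po[, idx, drop = FALSE],
       To = To[, idx, drop = FALSE], n_orth = kept)
}

# Core fit on an already centered/scaled X and a class factor. Returns the
# bare model (no cross-validation fields).
oplsda_core <- function(X, y, n_pred, n_orth, tol = 1e-10, max_iter = 2000,
                        y_levels = NULL) {
  y <- if (is.null(y_levels)) factor(y) else factor(y, levels = y_levels)
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  Y <- dummy_matrix(y)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  X0ss <- sum(X^2)
  orth <- if (n_orth > 0) remove_orthogonal(X, Yc, n_orth, tol, max_iter)
          else list(X = X, Wo = matrix(0, ncol(X), 0),
                    Po = matrix(0, ncol(X), 0),
                    To = matrix(0, nrow(X), 0), n_orth = 0L)
  pls <- fit_pls2_nipals(orth$X, Yc, n_pred, tol, max_iter, "continue")
  B <- pls$W %*% solve(crossprod(pls$P, pls$W), t(pls$C))
  Yhat_c <- tcrossprod(pls$T, pls$C)
  r2y <- 1 - sum((Yc - Yhat_c)^2) / sum(Yc^2)
  r2x <- 1 - sum(pls$X_residual^2) / X0ss
  structure(list(
    W = pls$W, P = pls$P, T = pls$T, C = pls$C,
    Wo = orth$Wo, Po = orth$Po, To = orth$To,
    B = B, n_pred = n_pred, n_orth = orth$n_orth,
    y = y, y_levels = levels(y), y_means = y_means,
    ssy_explained = pls$ssy_explained,
    R2Y = r2y, R2X = r2x,
    fitted_y = sweep(Yhat_c, 2, y_means, `+`)),
    class = "oplsda")
}

#' Fit a multi-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis:
#' predictor variation uncorrelated with the class structure is first
#' removed as `n_orth` orthogonal components, then `n_pred` predictive PLS2
#' components (default K - 1 for K classes) are fitted by NIPALS against
#' the centered class indicator matrix. Class membership predictions come
#' from the regression coefficients `B = W (P'W)^-1 C'`; assignment is
#' argmax of the membership vector, exact ties going to the smallest class
#' index.
#'
#' With `n_orth = "auto"` orthogonal components are added while the
#' sevenfold cross-validated Q2 improves by more than 0.01, up to
#' `max_orth`.
#'
#' @param x a `scaled_matrix` (from [pareto_scale()] / [fuse_blocks()]) or
#'   an already centered/scaled numeric matrix, samples x features. When a
#'   `scaled_matrix` is given its center/scale are stored so that
#'   [predict.oplsda()] accepts new samples on the unscaled (log10) scale.
#' @param y class factor, one label per sample; every class needs at least
#'   2 samples.
#' @param n_pred number of predictive components (default K - 1).
#' @param n_orth number of orthogonal components, or `"auto"`.
#' @param max_orth cap for automatic selection (default 5).
#' @param cv_folds folds used for the automatic selection and the reported
#'   Q2 (default 7).
#' @param tol,max_iter NIPALS convergence controls.
#' @param seed seed for the cross-validation fold assignment.
#' @return object of class `oplsda` with predictive weights/loadings/scores
#'   `W`, `P`, `T`, Y-loadings `C`, orthogonal `Wo`, `Po`, `To`, regression
#'   coefficients `B`, fit statistics `R2X`, `R2Y`, `Q2` (cumulative,
#'   cross-validated; `NA` when `cv_folds = 0`), per-feature `vip`, and the
#'   training centering/scaling state.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 10), 40)
#' y <- gl(2, 20, labels = c("a", "b"))
#' x[y == "b", 1:3] <- x[y == "b", 1:3] + 2
#' m <- oplsda(x, y, n_orth = 1, cv_folds = 5)
#' m$Q2 > 0.5
#' @seealso [predict.oplsda()], [vip()], [cross_validate()],
#'   [permutation_test()]
#' @export
oplsda <- function(x, y, n_pred = NULL, n_orth = "auto", max_orth = 5,
                   cv_folds = 7, tol = 1e-10, max_iter = 2000, seed = 1L) {
  scaled <- inherits(x, "scaled_matrix")
  X <- if (scaled) x$X else x
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- factor(y)
  k <- nlevels(y)
  n_pred <- n_pred %||% max(1L, k - 1L)
  if (n_pred < 1) stop("n_pred must be >= 1")

  if (identical(n_orth, "auto")) {
    if (cv_folds < 2) stop("automatic n_orth selection needs cv_folds >= 2")
    q2_prev <- cross_validate(x, y, folds = cv_folds, n_pred = n_pred,
                              n_orth = 0L, seed = seed)$q2
    n_orth <- 0L
    for (a in seq_len(max_orth)) {
      q2_a <- cross_validate(x, y, folds = cv_folds, n_pred = n_pred,
                             n_orth = a, seed = seed)$q2
      if (q2_a - q2_prev > 0.01) { n_orth <- a; q2_prev <- q2_a } else break
    }
  }

  fit <- oplsda_core(X, y, n_pred, n_orth, tol, max_iter)
  fit$vip <- vip_scores(fit)
  names(fit$vip) <- colnames(X) %||% (if (scaled) x$feature_id else NULL)
  fit$Q2 <- if (cv_folds >= 2)
    cross_validate(x, y, folds = cv_folds, n_pred = n_pred,
                   n_orth = n_orth, seed = seed)$q2 else NA_real_
  fit$cv_folds <- cv_folds
  fit$feature_id <- if (scaled) x$feature_id else colnames(X)
  fit$x_center <- if (scaled) x$center else NULL
  fit$x_scale <- if (scaled) x$scale else NULL
  fit$block <- if (scaled) x$block else NULL
  fit$sample_id <- if (scaled) x$sample_id else rownames(X)
  fit$call <- match.call()
  fit
}

# VIP over the predictive components: per-feature influence weighted by the
# Y sum of squares each component explains. mean(VIP^2) = 1 by construction.
vip_scores <- function(model) {
  W <- model$W
  ssy <- model$ssy_explained
  p <- nrow(W)
  sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` over the
#' predictive components, where `SSY_a` is the Y sum of squares explained by
#' component `a` and the weight columns are unit-norm. The mean of `VIP^2`
#' is exactly 1, so VIP > 1 flags features contributing more than average;
#' that threshold gates marker selection.
#'
#' @param model a fitted [oplsda()] model.
#' @return named numeric vector of per-feature VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "oplsda")) stop("vip() needs a fitted oplsda model")
  model$vip %||% vip_scores(model)
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("oplsda: %d classes (%s), %d predictive + %d orthogonal components\n",
              length(x$y_levels), paste(x$y_levels, collapse = ", "),
              x$n_pred, x$n_orth))
  cat(sprintf("  R2X %.3f  R2Y(cum.) %.3f  Q2(cum.) %s\n", x$R2X, x$R2Y,
              if (is.na(x$Q2)) "not cross-validated" else sprintf("%.3f", x$Q2)))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  out <- list(
    classes = table(object$y),
    components = c(predictive = object$n_pred, orthogonal = object$n_orth),
    R2X = object$R2X, R2Y = object$R2Y, Q2 = object$Q2,
    vip_over_1 = sum(object$vip > 1))
  class(out) <- "summary.oplsda"
  out
}

#' @export
print.summary.oplsda <- function(x, ...) {
  cat("Multi-class OPLS-DA\n\nSamples per class:\n")
  print(x$classes)
  cat(sprintf("\nComponents: %d predictive, %d orthogonal\n",
              x$components["predictive"], x$components["orthogonal"]))
  cat(sprintf("R2X = %.3f, R2 (cum.) = %.3f, Q2 (cum.) = %s\n",
              x$R2X, x$R2Y,
              if (is.na(x$Q2)) "NA" else sprintf("%.3f", x$Q2)))
  cat(sprintf("Features with VIP > 1: %d\n", x$vip_over_1))
  invisible(x)
}

#' @export
coef.oplsda <- function(object, ...) {
  B <- object$B
  dimnames(B) <- list(object$feature_id, object$y_levels)
  B
}

#' @export
fitted.oplsda <- function(object, ...) {
  out <- object$fitted_y
  dimnames(out) <- list(object$sample_id, object$y_levels)
  out
}

#' @export
residuals.oplsda <- function(object, ...) {
  dummy_matrix(object$y) - fitted(object)
}

#' @export
plot.oplsda <- function(x, components = c(1, 2), ...) {
  if (x$n_pred < 2) {
    tp <- cbind(x$T[, 1], if (x$n_orth > 0) x$To[, 1] else
      stats::rnorm(nrow(x$T), 0, 1e-6))
    labs <- c("t[1]", if (x$n_orth > 0) "t[o1]" else "jitter")
  } else {
    tp <- x$T[, components]
    labs <- sprintf("t[%d]", components)
  }
  graphics::plot(tp, col = as.integer(x$y), pch = 19,
                 xlab = labs[1], ylab = labs[2], ...)
  graphics::legend("topright", legend = x$y_levels, col = seq_along(x$y_levels),
                   pch = 19, cex = 0.8)
  invisible(x)
}

#' Predict class membership for new samples
#'
#' New samples are transformed with the training center/scale (when the
#' model was fitted on a `scaled_matrix`; otherwise `newdata` must already
#' be on the training scale), the orthogonal components are stripped with
#' the stored `Wo`/`Po`, and predictive scores and class memberships
#' `Yhat = X B + Ymean` are returned. Projecting the training data
#' reproduces the fitted memberships exactly.
#'
#' @param object fitted [oplsda()] model.
#' @param newdata samples x features matrix on the unscaled (log10) scale if
#'   the model carries scaling state, else pre-scaled. Columns are matched
#'   by feature id when named; a mismatch lists the missing/extra ids.
#' @param type `"response"` (membership matrix), `"class"` (factor of
#'   calls) or `"scores"` (list with predictive `t_pred` and orthogonal
#'   `t_orth` scores).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.oplsda <- function(object, newdata,
                           type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "scaled_matrix")) back_transform(newdata)
       else as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$feature_id)) {
    missing <- setdiff(object$feature_id, colnames(X))
    extra <- setdiff(colnames(X), object$feature_id)
    if (length(missing))
      stop("newdata lacks training feature(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(extra)) paste0("; extra: ",
                                     paste(utils::head(extra, 5), collapse = ", ")))
    X <- X[, object$feature_id, drop = FALSE]
  } else if (ncol(X) != length(object$feature_id %||% numeric(nrow(object$B)))) {
    stop("newdata has ", ncol(X), " features; the model was trained on ",
         nrow(object$B))
  }
  if (!is.null(object$x_center))
    X <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
  for (j in seq_len(object$n_orth)) {
    t_o <- X %*% object$Wo[, j]
    X <- X - tcrossprod(t_o, object$Po[, j])
  }
  Wstar <- object$W %*% solve(crossprod(object$P, object$W))
  t_pred <- X %*% Wstar
  yhat <- sweep(X %*% object$B, 2, object$y_means, `+`)
  colnames(yhat) <- object$y_levels
  rownames(yhat) <- rownames(X)
  switch(type,
         response = yhat,
         class = factor(argmax_class(yhat, object$y_levels),
                        levels = object$y_levels),
         scores = list(t_pred = t_pred,
                       t_orth = orth_scores(object, newdata)))
}

# orthogonal score trajectory of new samples (recomputed from raw newdata)
orth_scores <- function(object, newdata) {
  if (object$n_orth == 0) return(NULL)
  X <- if (inherits(newdata, "scaled_matrix")) back_transform(newdata)
       else as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$feature_id))
    X <- X[, object$feature_id, drop = FALSE]
  if (!is.null(object$x_center))
    X <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
  To <- matrix(0, nrow(X), object$n_orth)
  for (j in seq_len(object$n_orth)) {
    To[, j] <- X %*% object$Wo[, j]
    X <- X - tcrossprod(To[, j], object$Po[, j])
  }
  To
}

#' Cross-validated predictive ability (Q2)
#'
#' Stratified k-fold cross-validation of the OPLS-DA pipeline: folds are
#' assigned per class (deterministically under `seed`); for each fold the
#' Pareto scaling and the model are refitted on the training part only and
#' the held-out samples are predicted. `Q2 = 1 - PRESS / SSY` over the
#' class indicator matrix, with `SSY` taken around the overall class
#' frequencies.
#'
#' @param x `scaled_matrix` (back-transformed internally so scaling can be
#'   refitted per fold, per block) or a plain matrix (refolded scaling is
#'   then fitted on the matrix as given).
#' @param y class factor.
#' @param folds number of folds (default 7).
#' @param n_pred,n_orth model architecture used within each fold.
#' @param seed fold-assignment seed.
#' @param tol,max_iter NIPALS controls.
#' @return object of class `oplsda_cv`: `q2`, `press` (per fold),
#'   `press_total`, `ssy`, `residuals` (element-wise CV residual matrix),
#'   `folds` (assignment), `n`, `k`, `a_total`.
#' @export
cross_validate <- function(x, y, folds = 7, n_pred = NULL, n_orth = 1L,
                           seed = 1L, tol = 1e-10, max_iter = 2000) {
  scaled <- inherits(x, "scaled_matrix")
  R <- if (scaled) back_transform(x) else as.matrix(x)
  block <- if (scaled) x$block else NULL
  y <- factor(y)
  k <- nlevels(y)
  n_pred <- n_pred %||% max(1L, k - 1L)
  fold <- stratified_folds(y, folds, seed)
  Y <- dummy_matrix(y)
  resid <- matrix(NA_real_, nrow(Y), ncol(Y))
  press_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    sc <- pareto_scale_by_block(R[tr, , drop = FALSE], block)
    Xtr <- sc$X
    Xte <- sweep(sweep(R[!tr, , drop = FALSE], 2, sc$center), 2, sc$scale, `/`)
    fit <- oplsda_core(Xtr, y[tr], n_pred, n_orth, tol, max_iter,
                       y_levels = levels(y))
    for (j in seq_len(fit$n_orth)) {
      t_o <- Xte %*% fit$Wo[, j]
      Xte <- Xte - tcrossprod(t_o, fit$Po[, j])
    }
    yhat <- sweep(Xte %*% fit$B, 2, fit$y_means, `+`)
    resid[!tr, ] <- Y[!tr, , drop = FALSE] - yhat
    press_fold[f] <- sum(resid[!tr, ]^2)
  }
  press <- sum(press_fold)
  ssy <- sum(sweep(Y, 2, colMeans(Y))^2)
  structure(list(q2 = 1 - press / ssy, press = press_fold,
                 press_total = press, ssy = ssy, residuals = resid,
                 folds = fold, n = nrow(Y), k = ncol(Y),
                 a_total = n_pred + n_orth),
            class = "oplsda_cv")
}

# per-block pareto scaling of a raw matrix; block NULL = single block
pareto_scale_by_block <- function(R, block) {
  center <- colMeans(R)
  s <- apply(R, 2, stats::sd)
  scale <- sqrt(s)
  scale[s == 0] <- 1
  list(X = sweep(sweep(R, 2, center), 2, scale, `/`),
       center = center, scale = scale)
}

#' @export
print.oplsda_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: Q2 (cum.) = %.3f (PRESS %.1f / SSY %.1f)\n",
              length(x$press), x$q2, x$press_total, x$ssy))
  invisible(x)
}
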