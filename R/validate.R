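#' Permutation test of an OPLS-DA model
#'
#' Chemometric overfit check: the class labels are randomly permuted
#' `n_perm` times; for each permutation the model (fixed architecture:
#' the original predictive and orthogonal component counts) is refitted and
#' its R2Y and cross-validated Q2 recorded, together with the similarity
#' `r` of the permuted labels to the originals (mean absolute column-wise
#' correlation between the permuted and original class indicator matrices).
#' Least-squares lines through all `(r, R2)` and `(r, Q2)` points --
#' including the unpermuted model at `r = 1` -- give the reported
#' intercepts at `r = 0`. A valid model has all permuted values below the
#' originals and a negative Q2 intercept.
#'
#' @param x `scaled_matrix` or matrix, as in [cross_validate()].
#' @param y class factor.
#' @param n_perm number of permutations (default 999). Fewer than 20 gives
#'   an unstable intercept and a warning; 0 is an error.
#' @param folds cross-validation folds (default 7).
#' @param n_pred,n_orth model architecture (defaults: K - 1 predictive,
#'   1 orthogonal).
#' @param seed seed driving both the permutations and the fold assignments.
#' @return object of class `oplsda_permutation`: vectors `r`, `R2`, `Q2`
#'   (first element = original model at r = 1), `r2_intercept`,
#'   `q2_intercept`, and `exceedance` (fraction of permuted R2 / Q2 at or
#'   above the originals).
#' @export
permutation_test <- function(x, y, n_perm = 999, folds = 7, n_pred = NULL,
                             n_orth = 1L, seed = 1L) {
  if (n_perm == 0) stop("n_perm must be positive")
  if (n_perm < 20) warning("fewer than 20 permutations: intercepts unstable")
  y <- factor(y)
  k <- nlevels(y)
  n_pred <- n_pred %||% max(1L, k - 1L)
  scaled <- inherits(x, "scaled_matrix")
  Xs <- if (scaled) x$X else as.matrix(x)
  Y0 <- dummy_matrix(y)

  r2_of <- function(yy) oplsda_core(Xs, yy, n_pred, n_orth,
                                    y_levels = levels(y))$R2Y
  q2_of <- function(yy, s) cross_validate(x, yy, folds = folds,
                                          n_pred = n_pred, n_orth = n_orth,
                                          seed = s)$q2
  r <- numeric(n_perm + 1L); R2 <- numeric(n_perm + 1L); Q2 <- numeric(n_perm + 1L)
  r[1] <- 1
  R2[1] <- r2_of(y)
  Q2[1] <- q2_of(y, seed)
  perms <- with_seed(seed, replicate(n_perm, sample(length(y)),
                                     simplify = FALSE))
  for (i in seq_len(n_perm)) {
    yp <- y[perms[[i]]]
    Yp <- dummy_matrix(yp)
    r[i + 1L] <- mean(abs(vapply(seq_len(k), function(j)
      stats::cor(Yp[, j], Y0[, j]), numeric(1))), na.rm = TRUE)
    R2[i + 1L] <- r2_of(yp)
    Q2[i + 1L] <- q2_of(yp, seed + i)
  }
  intercept <- function(metric) {
    if (stats::sd(r) < 1e-12) return(mean(metric[-1]))
    unname(stats::coef(stats::lm(metric ~ r))[1])
  }
  structure(list(
    n_perm = n_perm, r = r, R2 = R2, Q2 = Q2,
    r2_intercept = intercept(R2), q2_intercept = intercept(Q2),
    exceedance = c(R2 = mean(R2[-1] >= R2[1]), Q2 = mean(Q2[-1] >= Q2[1]))),
    class = "oplsda_permutation")
}

#' @export
print.oplsda_permutation <- function(x, ...) {
  cat(sprintf("permutation test (%d permutations)\n", x$n_perm))
  cat(sprintf("  original: R2 (cum.) = %.4f, Q2 (cum.) = %.4f\n",
              x$R2[1], x$Q2[1]))
  cat(sprintf("  intercepts: R2 = %.4f and Q2 = %.4f\n",
              x$r2_intercept, x$q2_intercept))
  cat(sprintf("  permuted values >= original: R2 %.1f%%, Q2 %.1f%%\n",
              100 * x$exceedance["R2"], 100 * x$exceedance["Q2"]))
  invisible(x)
}

#' @export
plot.oplsda_permutation <- function(x, ...) {
  ylim <- range(c(x$R2, x$Q2))
  graphics::plot(x$r, x$R2, pch = 19, col = "darkgreen", ylim = ylim,
                 xlab = "correlation with original labels (r)",
                 ylab = expression(R^2 ~ "/" ~ Q^2), ...)
  graphics::points(x$r, x$Q2, pch = 17, col = "steelblue")
  graphics::abline(stats::lm(x$R2 ~ x$r), col = "darkgreen", lty = 2)
  graphics::abline(stats::lm(x$Q2 ~ x$r), col = "steelblue", lty = 2)
  graphics::legend("bottomright", legend = c(expression(R^2), expression(Q^2)),
                   col = c("darkgreen", "steelblue"), pch = c(19, 17))
  invisible(x)
}

#' CV-ANOVA model significance
#'
#' F test of the cross-validated residuals against the total class-indicator
#' variation: `SS_reg = SSY - PRESS` on `A` degrees of freedom (the total
#' component count) versus `SS_res = PRESS` on `N*K - K - A` degrees of
#' freedom. A model whose cross-validated predictions explain nothing
#' (PRESS >= SSY) gets `F = 0`, `p = 1`. The degrees-of-freedom bookkeeping
#' follows the published CV-ANOVA formulation as closely as its description
#' allows and is approximate.
#'
#' @param cv an `oplsda_cv` from [cross_validate()].
#' @return object of class `cv_anova`: `F`, `df1`, `df2`, `p`.
#' @export
cv_anova <- function(cv) {
  stopifnot(inherits(cv, "oplsda_cv"))
  ssy <- cv$ssy; press <- cv$press_total
  df1 <- cv$a_total
  df2 <- cv$n * cv$k - cv$k - cv$a_total
  if (df2 <= 0) stop("not enough residual degrees of freedom")
  if (press >= ssy) {
    out <- list(F = 0, df1 = df1, df2 = df2, p = 1)
  } else {
    f <- ((ssy - press) / df1) / (press / df2)
    out <- list(F = f, df1 = df1, df2 = df2,
                p = max(stats::pf(f, df1, df2, lower.tail = FALSE), 1e-300))
  }
  structure(out, class = "cv_anova")
}

#' @export
print.cv_anova <- function(x, ...) {
  cat(sprintf("CV-ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}
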