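#' Principal component analysis of a scaled matrix
#'
#' Unsupervised QC view of the data: singular value decomposition of the
#' (already centered and scaled) matrix. Explained variance fractions are
#' singular values squared over their total. The SVD sign ambiguity is fixed
#' by making the largest-magnitude loading of each component positive.
#'
#' @param x a `scaled_matrix` or a centered numeric matrix (samples x
#'   features).
#' @param n_components number of components; must not exceed
#'   `min(n_samples - 1, n_features)`.
#' @return object of class `pca_result`: `scores` (samples x A), `loadings`
#'   (features x A, orthonormal columns), `explained` (variance fractions,
#'   non-increasing).
#' @export
fit_pca <- function(x, n_components = 2) {
  X <- if (inherits(x, "scaled_matrix")) x$X else x
  stopifnot(is.matrix(X))
  amax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > amax)
    stop("n_components must be in 1..", amax)
  sv <- svd(X, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(a) {
    v <- sv$v[, a]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, loadings = loadings,
                 explained = sv$d^2 / sum(sv$d^2), n_components = n_components),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$explained[seq_len(x$n_components)]
  cat(sprintf("pca_result: %d components; explained variance %s (cum. %.1f%%)\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * ev), collapse = ", "),
              100 * sum(ev)))
  invisible(x)
}

#' @export
plot.pca_result <- function(x, meta = NULL, components = c(1, 2), ...) {
  sc <- x$scores[, components, drop = FALSE]
  col <- 1
  if (!is.null(meta)) {
    grp <- ifelse(meta$condition == "qc", "QC", meta$class)
    col <- as.integer(factor(grp))
  }
  graphics::plot(sc, col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$explained[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$explained[components[2]]), ...)
  invisible(x)
}

#' QC-sample drift check on the PCA score plot
#'
#' Instrument stability check: each pooled QC sample passes when each of its
#' first-two-component scores lies within `k` standard deviations of that
#' component's score distribution over all samples (QC included). The
#' reference population is all samples; QC-only referencing would make the
#' bound trivially tight.
#'
#' @param pca a [fit_pca()] result whose scores include the QC samples.
#' @param meta sample metadata identifying `condition == "qc"` rows.
#' @param k tolerance in standard deviations (default 2).
#' @return data.frame with one row per QC sample (scores, per-component
#'   limits, `pass`), plus an attribute `overall` (all QCs pass).
#' @export
qc_drift_check <- function(pca, meta, k = 2) {
  qc_ids <- meta$sample_id[meta$condition == "qc"]
  if (length(qc_ids) < 2) stop("need at least 2 QC samples")
  sc <- pca$scores[, 1:2, drop = FALSE]
  if (!all(qc_ids %in% rownames(sc)))
    stop("QC samples missing from the PCA scores")
  sds <- apply(sc, 2, stats::sd)
  mus <- colMeans(sc)
  qs <- sc[qc_ids, , drop = FALSE]
  pass <- abs(qs[, 1] - mus[1]) <= k * sds[1] &
    abs(qs[, 2] - mus[2]) <= k * sds[2]
  out <- data.frame(sample_id = qc_ids, pc1 = qs[, 1], pc2 = qs[, 2],
                    limit_pc1 = k * sds[1], limit_pc2 = k * sds[2],
                    pass = pass, row.names = NULL)
  attr(out, "overall") <- all(pass)
  out
}
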