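#' One-way ANOVA with Bonferroni correction
#'
#' Classic one-way ANOVA `F = (SSB/(k-1)) / (SSW/(N-k))` across the given
#' groups, with the Bonferroni-adjusted p value `p_adj = min(1, p * m)`
#' where `m` is the size of the test family (the number of VIP-passing
#' candidates tested alongside this one). Degenerate inputs follow fixed
#' policies: zero within-group variance with equal means gives `F = 0,
#' p = 1`; zero within-group variance with unequal means gives an
#' effectively zero p (floored at 1e-300).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @param m Bonferroni family size (default 1 = no correction).
#' @return list with `F`, `p_raw`, `p_adj`.
#' @export
anova_bonferroni <- function(groups, m = 1) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 values")
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= .Machine$double.eps * (ssb + ssw + 1)) {
    if (ssb <= .Machine$double.eps * (abs(gm) + 1)) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 1e-300
    }
  } else {
    f <- (ssb / (k - 1)) / (ssw / (N - k))
    p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  }
  list(F = f, p_raw = p, p_adj = max(min(1, p * m), 1e-300))
}

#' Fold change between treated and control groups
#'
#' Ratio of group means on the intensity (pre-log) scale:
#' `fc = mean(treated) / mean(control)`. The trend is `"up"` iff `fc > 1`
#' (strict; an exact tie reports `"down"`). A zero control mean makes the
#' ratio undefined: the value is `NA` and the reason is attached.
#'
#' @param treated,control numeric intensity vectors (non-empty).
#' @return list with `fc` and `trend`.
#' @export
fold_change <- function(treated, control) {
  if (!length(treated) || !length(control))
    stop("both groups must be non-empty")
  mc <- mean(control)
  if (mc == 0)
    return(structure(list(fc = NA_real_, trend = NA_character_),
                     reason = "control mean is zero"))
  fc <- mean(treated) / mc
  list(fc = fc, trend = if (fc > 1) "up" else "down")
}

#' Mann-Whitney ROC AUC
#'
#' Area under the ROC curve computed from the rank-based U statistic, ties
#' counted 0.5: the probability a random positive-class value exceeds a
#' random negative-class value. Both the raw AUC (positive class as given)
#' and the oriented AUC (`max(auc, 1 - auc)`, the discriminative power
#' regardless of direction) are returned.
#'
#' @param values numeric vector.
#' @param labels logical or two-level vector; `TRUE` / the second level is
#'   the positive class.
#' @return list with `auc` (raw), `auc_oriented`, `direction` (`"up"` if
#'   the positive class tends higher).
#' @export
roc_auc <- function(values, labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- unique(as.character(labels))
    if (length(lv) != 2) stop("labels must have exactly 2 classes")
    labels <- as.character(labels) == sort(lv)[2]
  }
  labels <- as.logical(labels)
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0 || n2 == 0) stop("both label groups must be non-empty")
  r <- rank(values)                       # midranks handle ties as 0.5
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  list(auc = auc, auc_oriented = max(auc, 1 - auc),
       direction = if (auc >= 0.5) "up" else "down")
}

#' Select differential marker metabolites for one drug class
#'
#' The selection cascade applied per mechanism-of-action class:
#' features with VIP > `vip_threshold` from the fitted model are tested by
#' one-way ANOVA (treated vs control within the class, on log10 values)
#' with Bonferroni correction over the VIP survivors; survivors with
#' `p_adj < alpha` are retained when their oriented ROC AUC (on
#' cell-count-normalized intensities) exceeds `auc_threshold`. Fold changes
#' are computed on the normalized pre-log intensity scale. Results are
#' sorted by AUC, descending.
#'
#' @param model fitted [oplsda()] (supplies VIP per fused feature).
#' @param prep the [preprocess_study()] object (supplies log matrix,
#'   intensity matrix and metadata).
#' @param class the drug class to contrast.
#' @param vip_threshold VIP gate (default 1).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param auc_threshold AUC retention rule (default 0.50, strict).
#' @return data.frame of class `marker_candidates`, one row per VIP
#'   survivor: `feature_id`, `class`, `vip`, `F`, `p_raw`, `p_adj`, `auc`,
#'   `fc`, `trend`, `passes`; passing rows first, by descending AUC. The
#'   Bonferroni family size is attached as attribute `m`.
#' @export
select_markers <- function(model, prep, class, vip_threshold = 1,
                           alpha = 0.05, auc_threshold = 0.50) {
  stopifnot(inherits(model, "oplsda"), inherits(prep, "moa_preprocess"))
  meta <- prep$meta
  if (!class %in% meta$class) stop("class not present in metadata: ", class)
  v <- vip(model)
  cand <- which(v > vip_threshold)
  if (!length(cand)) {
    out <- data.frame(feature_id = character(0), class = character(0),
                      vip = numeric(0), F = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), auc = numeric(0), fc = numeric(0),
                      trend = character(0), passes = logical(0))
    class(out) <- c("marker_candidates", "data.frame")
    return(out)
  }
  m <- length(cand)
  tr_ids <- meta$sample_id[meta$class %in% class & meta$condition == "treated"]
  ct_ids <- meta$sample_id[meta$class %in% class & meta$condition == "control"]
  if (!length(tr_ids) || !length(ct_ids))
    stop("class ", class, " needs both treated and control samples")
  fid <- prep$feature_id[cand]
  logx <- prep$log
  intens <- prep$intensity
  rows <- lapply(seq_along(cand), function(i) {
    f <- fid[i]
    a <- anova_bonferroni(list(logx[tr_ids, f], logx[ct_ids, f]), m = m)
    fcres <- fold_change(intens[f, tr_ids], intens[f, ct_ids])
    roc <- roc_auc(intens[f, c(tr_ids, ct_ids)],
                   c(rep(TRUE, length(tr_ids)), rep(FALSE, length(ct_ids))))
    data.frame(feature_id = f, class = class, vip = v[cand[i]],
               F = a$F, p_raw = a$p_raw, p_adj = a$p_adj,
               auc = roc$auc_oriented, fc = fcres$fc,
               trend = fcres$trend %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dropped <- is.na(out$fc)                  # zero control mean: undefined FC
  out$passes <- !dropped & out$p_adj < alpha & out$auc > auc_threshold
  out <- out[order(-out$passes, -out$auc), ]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "dropped_zero_control") <- sum(dropped)
  class(out) <- c("marker_candidates", "data.frame")
  out
}

#' Convert selected markers to the published-table record schema
#'
#' Reshapes a [select_markers()] result into the same column layout as the
#' packaged marker tables ([load_marker_fixtures()]), so selected and
#' published marker tables are interchangeable downstream: `class`, `no`,
#' `rt`, `name`, `mz`, `p_flag`, `auc`, `fc`, `trend`, `pathway`. Synthetic
#' features have no metabolite identity, so `name` is the feature id and
#' `pathway` is `NA`; the p flag is the strongest printed threshold the
#' adjusted p value clears.
#'
#' @param candidates a `marker_candidates` data.frame.
#' @param prep the [preprocess_study()] object (supplies feature rt / m/z).
#' @param passing_only keep only rows passing the cascade (default TRUE).
#' @return data.frame of class `marker_records`.
#' @export
marker_records <- function(candidates, prep, passing_only = TRUE) {
  stopifnot(inherits(candidates, "marker_candidates"),
            inherits(prep, "moa_preprocess"))
  d <- if (passing_only) candidates[candidates$passes, , drop = FALSE]
       else candidates
  rtmz <- local({
    f <- strsplit(sub("^(RP|HI)_", "", d$feature_id), "_")
    list(rt = as.numeric(vapply(f, `[`, "", 1)),
         mz = as.numeric(vapply(f, `[`, "", 2)))
  })
  out <- data.frame(
    class = d$class,
    no = seq_len(nrow(d)),
    rt = rtmz$rt,
    name = d$feature_id,
    mz = rtmz$mz,
    p_flag = ifelse(d$p_adj < 0.001, "<0.001",
                    ifelse(d$p_adj < 0.01, "<0.01", "<0.05")),
    auc = d$auc, fc = d$fc, trend = d$trend,
    pathway = NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("marker_records", "data.frame")
  out
}

#' Hierarchical clustering of a marker fold-change matrix
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' markers x classes fold-change matrix, as used for the clustered marker
#' heat map: rows (and columns, when more than 2) are ordered by their
#' dendrograms and the row dendrogram is cut into `k` clusters. Ordering is
#' deterministic. A constant matrix cannot be split and yields a single
#' cluster with a warning.
#'
#' @param fc numeric matrix of fold changes, markers x classes (>= 2 rows).
#' @param k number of row clusters to cut (default 4).
#' @return object of class `marker_heatmap`: `row_order`, `col_order`,
#'   `clusters` (named cluster id per row), `row_hclust`, `col_hclust`.
#' @export
cluster_heatmap <- function(fc, k = 4) {
  stopifnot(is.matrix(fc))
  if (nrow(fc) < 2) stop("need at least 2 marker rows to cluster")
  if (max(fc) - min(fc) < .Machine$double.eps) {
    warning("constant fold-change matrix: a single cluster")
    return(structure(list(row_order = seq_len(nrow(fc)),
                          col_order = seq_len(ncol(fc)),
                          clusters = stats::setNames(rep(1L, nrow(fc)),
                                                     rownames(fc)),
                          row_hclust = NULL, col_hclust = NULL),
                     class = "marker_heatmap"))
  }
  rh <- stats::hclust(stats::dist(fc), method = "average")
  ch <- if (ncol(fc) > 2)
    stats::hclust(stats::dist(t(fc)), method = "average") else NULL
  clusters <- stats::cutree(rh, k = min(k, nrow(fc)))
  structure(list(row_order = rh$order,
                 col_order = if (is.null(ch)) seq_len(ncol(fc)) else ch$order,
                 clusters = clusters, row_hclust = rh, col_hclust = ch),
            class = "marker_heatmap")
}

#' @export
print.marker_heatmap <- function(x, ...) {
  cat(sprintf("marker_heatmap: %d markers in %d clusters\n",
              length(x$clusters), length(unique(x$clusters))))
  invisible(x)
}

#' @export
plot.marker_heatmap <- function(x, fc, ...) {
  stopifnot(is.matrix(fc))
  m <- fc[x$row_order, x$col_order, drop = FALSE]
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE, ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.7)
  invisible(x)
}
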