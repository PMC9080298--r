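#' Align per-sample peak lists into a feature table
#'
#' A simple binning aligner in the spirit of the vendor alignment step:
#' peaks from all samples are greedily clustered, in order of descending
#' intensity, into features; a peak joins a feature when its m/z is within
#' `mass_window` and its retention time within `rt_tolerance` of the
#' feature's seed peak. Before clustering, peaks below
#' `min_intensity_frac` of their own sample's base-peak (most intense)
#' intensity are discarded. A peak matched by no other sample still becomes
#' a feature, with zero intensity elsewhere.
#'
#' @param peak_lists named list, one element per sample, each a data.frame
#'   with columns `rt` (minutes), `mz` (Da) and `intensity`.
#' @param block block label for the resulting table (`"RP"` or `"HILIC"`).
#' @param mass_window m/z tolerance in Da (default 0.05).
#' @param rt_tolerance retention-time tolerance in minutes (default 0.5).
#' @param min_intensity_frac per-sample intensity floor as a fraction of the
#'   base-peak intensity (default 0.05). This floor also stands in for the
#'   vendor's proprietary noise-elimination setting.
#' @return a [peak_table()]; feature rt/m/z are those of the seed (most
#'   intense) peak. When several peaks of one sample fall into a feature,
#'   the most intense is kept.
#' @export
align_features <- function(peak_lists, block = "RP", mass_window = 0.05,
                           rt_tolerance = 0.5, min_intensity_frac = 0.05) {
  if (!length(peak_lists)) stop("empty set of peak lists")
  if (is.null(names(peak_lists)))
    names(peak_lists) <- sprintf("S%03d", seq_along(peak_lists))
  peaks <- do.call(rbind, lapply(names(peak_lists), function(s) {
    pl <- peak_lists[[s]]
    stopifnot(all(c("rt", "mz", "intensity") %in% names(pl)))
    if (!nrow(pl)) return(NULL)
    keep <- pl$intensity >= min_intensity_frac * max(pl$intensity)
    cbind(pl[keep, c("rt", "mz", "intensity")], sample = s)
  }))
  if (is.null(peaks) || !nrow(peaks)) stop("no peaks above the intensity floor")
  ord <- order(-peaks$intensity)
  peaks <- peaks[ord, ]
  assigned <- integer(nrow(peaks))          # 0 = unassigned
  seeds <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    if (assigned[i]) next
    hit <- which(!assigned &
                   abs(peaks$mz - peaks$mz[i]) <= mass_window &
                   abs(peaks$rt - peaks$rt[i]) <= rt_tolerance)
    assigned[hit] <- length(seeds) + 1L
    seeds <- c(seeds, i)
  }
  samples <- names(peak_lists)
  intens <- matrix(0, nrow = length(seeds), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (f in seq_along(seeds)) {
    members <- peaks[assigned == f, ]
    # peaks arrive intensity-sorted, so the first per sample is the largest
    first <- !duplicated(members$sample)
    intens[f, members$sample[first]] <- members$intensity[first]
  }
  rt <- peaks$rt[seeds]; mz <- peaks$mz[seeds]
  fid <- paste0(ifelse(block == "RP", "RP_", "HI_"),
                sprintf("%.3f", rt), "_", sprintf("%.4f", mz))
  if (anyDuplicated(fid)) fid <- make.unique(fid, sep = "_")
  features <- data.frame(feature_id = fid, block = block, rt = rt, mz = mz,
                         stringsAsFactors = FALSE)
  ord <- order(features$rt, features$mz)
  peak_table(features[ord, , drop = FALSE], intens[ord, , drop = FALSE])
}

#' Remove features with too many missing values
#'
#' Drops every feature whose fraction of zero intensities (ion not detected)
#' across all samples is strictly greater than `max_missing`; features at
#' exactly the threshold are kept. Idempotent.
#'
#' @param table a [peak_table()].
#' @param max_missing maximum tolerated zero fraction (default 0.20).
#' @return the filtered [peak_table()].
#' @export
filter_missing <- function(table, max_missing = 0.20) {
  stopifnot(inherits(table, "peak_table"))
  zero_frac <- rowMeans(table$intensities == 0)
  keep <- zero_frac <= max_missing
  peak_table(table$features[keep, , drop = FALSE],
             table$intensities[keep, , drop = FALSE])
}

#' Normalize intensities to cell number
#'
#' Rescales each biological sample's intensities to a common cell number:
#' `intensity * reference / cell_count`, where the reference is the median
#' cell count over biological samples. Pooled QC samples are left unchanged
#' (they are mixtures, not single flasks).
#'
#' @param table a [peak_table()].
#' @param meta sample metadata with `cell_count` for every non-QC sample.
#' @return the normalized [peak_table()].
#' @export
normalize_cell_count <- function(table, meta) {
  stopifnot(inherits(table, "peak_table"))
  ids <- colnames(table$intensities)
  m <- meta[match(ids, meta$sample_id), ]
  if (anyNA(m$sample_id))
    stop("metadata missing for sample(s): ",
         paste(utils::head(ids[is.na(m$sample_id)], 5), collapse = ", "))
  bio <- m$condition != "qc"
  if (any(bio & (is.na(m$cell_count) | m$cell_count <= 0)))
    stop("cell_count missing or non-positive for a biological sample")
  ref <- stats::median(m$cell_count[bio])
  fac <- ifelse(bio, ref / m$cell_count, 1)
  out <- table
  out$intensities <- sweep(table$intensities, 2, fac, `*`)
  out
}

#' Log10 transform with half-minimum zero replacement
#'
#' Replaces each remaining zero by half the smallest positive intensity of
#' that feature, then takes log10 elementwise. A feature that is zero in
#' every sample has no detection floor to impute from and is an error (such
#' features should have been removed by [filter_missing()]).
#'
#' @param table a [peak_table()] (or a non-negative features x samples
#'   matrix).
#' @param zero_policy only `"half_min"` is implemented.
#' @return samples x features numeric matrix of log10 intensities (model
#'   orientation), with an attribute `half_min` recording the per-feature
#'   replacement values used.
#' @export
log10_transform <- function(table, zero_policy = "half_min") {
  zero_policy <- match.arg(zero_policy, "half_min")
  x <- if (inherits(table, "peak_table")) table$intensities else table
  stopifnot(is.matrix(x), all(x >= 0))
  all_zero <- rowSums(x > 0) == 0
  if (any(all_zero))
    stop("all-zero feature(s) cannot be log-transformed: ",
         paste(utils::head(rownames(x)[all_zero], 5), collapse = ", "))
  half_min <- apply(x, 1, function(v) min(v[v > 0]) / 2)
  for (i in which(rowSums(x == 0) > 0)) x[i, x[i, ] == 0] <- half_min[i]
  out <- t(log10(x))
  attr(out, "half_min") <- half_min
  out
}

#' Pareto scaling
#'
#' Centers each feature (column) and divides by the square root of its
#' sample standard deviation (n - 1 denominator) -- the metabolomics
#' compromise between no scaling and unit-variance scaling: after it, each
#' column's variance equals the original column's standard deviation, so
#' large-variance features are damped but not flattened. Constant columns
#' are centered and left unscaled.
#'
#' @param x samples x features numeric matrix with no missing values
#'   (from [log10_transform()]).
#' @param block optional per-feature block labels, carried into the result.
#' @return object of class `scaled_matrix`: list with the scaled matrix `X`,
#'   the per-feature `center` and `scale` used (allowing exact
#'   back-projection of new samples), `feature_id`, `sample_id`, `block` and
#'   a `provenance` record.
#' @export
pareto_scale <- function(x, block = NULL) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2) stop("need at least 2 samples to scale")
  if (anyNA(x)) stop("missing values are not allowed at the scaling stage")
  center <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  scale <- sqrt(s)
  scale[s == 0] <- 1
  X <- sweep(sweep(x, 2, center), 2, scale, `/`)
  structure(list(X = X, center = center, scale = scale,
                 feature_id = colnames(x) %||% as.character(seq_len(ncol(x))),
                 sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                 block = block %||% rep(NA_character_, ncol(x)),
                 provenance = list(scaling = "pareto", log_base = 10)),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("scaled_matrix: %d samples x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(unique(stats::na.omit(x$block)), collapse = "+")))
  invisible(x)
}

#' Back-transform a scaled matrix to its input scale
#'
#' Inverts [pareto_scale()] using the stored center and scale.
#'
#' @param scaled a `scaled_matrix`.
#' @return the original samples x features matrix.
#' @export
back_transform <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  out <- sweep(sweep(scaled$X, 2, scaled$scale, `*`), 2, scaled$center, `+`)
  dimnames(out) <- list(scaled$sample_id, scaled$feature_id)
  out
}

#' Fuse the RP and HILIC blocks
#'
#' Feature-wise concatenation of the two per-block scaled matrices into one
#' model matrix ("RP + HI"). Each block is scaled before fusion so neither
#' block's variance dominates; sample order is harmonized by id and block
#' provenance is retained per feature.
#'
#' @param scaled_rp,scaled_hilic `scaled_matrix` objects over the same
#'   sample set.
#' @return a fused `scaled_matrix`.
#' @export
fuse_blocks <- function(scaled_rp, scaled_hilic) {
  stopifnot(inherits(scaled_rp, "scaled_matrix"),
            inherits(scaled_hilic, "scaled_matrix"))
  a <- scaled_rp; b <- scaled_hilic
  only_a <- setdiff(a$sample_id, b$sample_id)
  only_b <- setdiff(b$sample_id, a$sample_id)
  if (length(only_a) || length(only_b))
    stop("sample sets differ between blocks; offending ids: ",
         paste(utils::head(c(only_a, only_b), 10), collapse = ", "))
  idx <- match(a$sample_id, b$sample_id)
  structure(list(
    X = cbind(a$X, b$X[idx, , drop = FALSE]),
    center = c(a$center, b$center),
    scale = c(a$scale, b$scale),
    feature_id = c(a$feature_id, b$feature_id),
    sample_id = a$sample_id,
    block = c(a$block, b$block),
    provenance = list(scaling = "pareto", log_base = 10, fused = TRUE,
                      per_block_scaling = TRUE)),
    class = "scaled_matrix")
}

#' Run the full preprocessing pipeline on a two-block study
#'
#' Applies the fixed stage order filter -> cell-count normalization ->
#' log10 -> per-block Pareto scaling -> fusion to the two aligned peak
#' tables (alignment, when starting from raw peak lists, precedes this via
#' [align_features()]). The order is asserted and recorded in the result's
#' provenance.
#'
#' @param rp,hilic aligned [peak_table()]s for the two blocks.
#' @param meta sample metadata covering all samples in both tables.
#' @param max_missing missing-value filter threshold (default 0.20).
#' @param zero_policy zero handling before log10 (see [log10_transform()]).
#' @return object of class `moa_preprocess`: `scaled` (fused
#'   `scaled_matrix`), `log` (fused unscaled log10 matrix, samples x
#'   features), `intensity` (fused cell-count-normalized intensity matrix on
#'   the pre-log scale, used for fold changes and AUC), `meta`, `block`
#'   (per-feature), `stages` (executed stage names, in order) and
#'   `half_min` / `reference_count` state for applying the identical
#'   transform to new sample sets via [apply_preprocess()].
#' @export
preprocess_study <- function(rp, hilic, meta, max_missing = 0.20,
                             zero_policy = "half_min") {
  stages <- character(0)
  run <- function(name, expr) { stages[length(stages) + 1L] <<- name; expr }
  rp_f <- run("filter", filter_missing(rp, max_missing))
  hi_f <- filter_missing(hilic, max_missing)
  rp_n <- run("normalize", normalize_cell_count(rp_f, meta))
  hi_n <- normalize_cell_count(hi_f, meta)
  rp_l <- run("log10", log10_transform(rp_n, zero_policy))
  hi_l <- log10_transform(hi_n, zero_policy)
  rp_s <- run("scale", pareto_scale(rp_l, rep("RP", ncol(rp_l))))
  hi_s <- pareto_scale(hi_l, rep("HILIC", ncol(hi_l)))
  fused <- run("fuse", fuse_blocks(rp_s, hi_s))
  stopifnot(identical(stages, c("filter", "normalize", "log10", "scale", "fuse")))
  log_fused <- cbind(rp_l, hi_l[match(rownames(rp_l), rownames(hi_l)), ,
                                drop = FALSE])
  intens <- rbind(rp_n$intensities,
                  hi_n$intensities[, colnames(rp_n$intensities), drop = FALSE])
  bio <- meta$condition != "qc"
  structure(list(
    scaled = fused, log = log_fused,
    intensity = intens,
    meta = meta[match(fused$sample_id, meta$sample_id), ],
    block = fused$block,
    stages = c("align (upstream)", stages),
    half_min = c(attr(rp_l, "half_min"), attr(hi_l, "half_min")),
    reference_count = stats::median(meta$cell_count[bio], na.rm = TRUE),
    max_missing = max_missing,
    feature_id = fused$feature_id),
    class = "moa_preprocess")
}

#' @export
print.moa_preprocess <- function(x, ...) {
  cat(sprintf("moa_preprocess: %d samples x %d fused features\n",
              nrow(x$scaled$X), ncol(x$scaled$X)))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' Apply a fitted preprocessing state to new samples
#'
#' Projects a new two-block sample set through the training preprocessing:
#' restrict to the training feature set, normalize by the new samples' cell
#' counts against the training reference count, replace zeros by the
#' training half-minimum values and log10-transform. Scaling is not applied
#' here; [predict.oplsda()] applies the model's stored center/scale.
#'
#' @param prep a `moa_preprocess` from [preprocess_study()].
#' @param rp,hilic new-sample [peak_table()]s containing at least the
#'   training features.
#' @param meta metadata for the new samples.
#' @return samples x features log10 matrix over the training feature set.
#' @export
apply_preprocess <- function(prep, rp, hilic, meta) {
  stopifnot(inherits(prep, "moa_preprocess"))
  intens <- rbind(rp$intensities, hilic$intensities[, colnames(rp$intensities),
                                                    drop = FALSE])
  missing <- setdiff(prep$feature_id, rownames(intens))
  if (length(missing))
    stop("new samples lack training feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  intens <- intens[prep$feature_id, , drop = FALSE]
  ids <- colnames(intens)
  m <- meta[match(ids, meta$sample_id), ]
  bio <- m$condition != "qc"
  fac <- ifelse(bio, prep$reference_count / m$cell_count, 1)
  intens <- sweep(intens, 2, fac, `*`)
  for (i in seq_len(nrow(intens))) {
    z <- intens[i, ] == 0
    if (any(z)) intens[i, z] <- prep$half_min[i]
  }
  t(log10(intens))
}
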