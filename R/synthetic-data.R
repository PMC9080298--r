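#' Configuration of the synthetic profiling study
#'
#' Describes the design emulated by [generate_study()]: a panel of adherent
#' tumor cell lines treated with anticancer drugs from four
#' mechanism-of-action classes (three drugs per class), one treated and one
#' control condition per (cell line, drug), three profiling replicates per
#' condition, two chromatographic blocks (RP and HILIC), pooled QC samples
#' injected periodically, class-specific planted marker metabolites, cell
#' count variation, multiplicative technical noise and zero-inflated
#' missingness.
#'
#' @param n_cell_lines number of tumor cell lines (default 12).
#' @param classes mechanism-of-action class labels (default the four drug
#'   categories: antimetabolite, DNA-acting, microtubule-affecting,
#'   RNA-interfering).
#' @param drugs_per_class drugs per class (default 3).
#' @param replicates profiling replicates per condition (default 3; a fourth
#'   flask is counted, not profiled, and supplies `cell_count`).
#' @param n_features_rp,n_features_hilic features per block (defaults
#'   300 / 200).
#' @param markers_per_class planted marker metabolites per class (default 12).
#' @param effect_size mean log10-scale shift of a planted marker in its
#'   class's treated samples (default 0.5, i.e. about 3.2-fold -- inside the
#'   0.004--6.8 fold-change span of the published marker tables).
#' @param noise_sd log10-scale technical noise s.d. (default 0.1).
#' @param cell_line_sd log10-scale cell-line random effect s.d. (default 0.2).
#' @param missing_rate probability an intensity is recorded as 0 (default
#'   0.05), on top of a detection floor at the 1% quantile of baseline.
#' @param qc_interval one pooled QC injection per this many analytical
#'   samples (default 6).
#' @param cell_count_mean,cell_count_cv cells per flask: mean (default 1e6)
#'   and coefficient of variation (default 0.1).
#' @param seed integer seed; the single source of randomness for all
#'   stochastic generator steps.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_lines = 12, classes = moa_classes(),
                             drugs_per_class = 3, replicates = 3,
                             n_features_rp = 300, n_features_hilic = 200,
                             markers_per_class = 12, effect_size = 0.5,
                             noise_sd = 0.1, cell_line_sd = 0.2,
                             missing_rate = 0.05, qc_interval = 6,
                             cell_count_mean = 1e6, cell_count_cv = 0.1,
                             seed = 1L) {
  if (!length(classes) || anyDuplicated(classes))
    stop("classes must be a non-empty set of distinct labels")
  cfg <- list(
    n_cell_lines = stopifnot_scalar_count(n_cell_lines, "n_cell_lines"),
    classes = as.character(classes),
    drugs_per_class = stopifnot_scalar_count(drugs_per_class, "drugs_per_class"),
    replicates = stopifnot_scalar_count(replicates, "replicates"),
    n_features_rp = stopifnot_scalar_count(n_features_rp, "n_features_rp"),
    n_features_hilic = stopifnot_scalar_count(n_features_hilic, "n_features_hilic"),
    markers_per_class = stopifnot_scalar_count(markers_per_class, "markers_per_class"),
    effect_size = effect_size, noise_sd = noise_sd,
    cell_line_sd = cell_line_sd, missing_rate = missing_rate,
    qc_interval = stopifnot_scalar_count(qc_interval, "qc_interval"),
    cell_count_mean = cell_count_mean, cell_count_cv = cell_count_cv,
    seed = as.integer(seed))
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (noise_sd < 0 || cell_line_sd < 0) stop("noise s.d. must be >= 0")
  if (cfg$markers_per_class > min(cfg$n_features_rp, cfg$n_features_hilic))
    stop("markers_per_class exceeds the smaller block's feature count")
  if (cfg$markers_per_class * length(cfg$classes) >
      cfg$n_features_rp + cfg$n_features_hilic)
    stop("more planted markers than features")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default mechanism-of-action class labels
#' @return character vector of the four drug categories.
#' @export
moa_classes <- function() {
  c("antimetabolite", "dna_acting", "microtubule", "rna_interference")
}

# Deterministic study design: feature chemistry (rt, m/z, baseline), marker
# placement, cell-line effects and per-drug idiosyncratic shifts. Drawn from
# cfg$seed only, so generate_study() and generate_new_drug_set() share one
# feature space.
study_design <- function(cfg) {
  with_seed(cfg$seed, {
    n_rp <- cfg$n_features_rp; n_hi <- cfg$n_features_hilic
    p <- n_rp + n_hi
    block <- rep(c("RP", "HILIC"), c(n_rp, n_hi))
    rt <- c(stats::runif(n_rp, 0.5, 45), stats::runif(n_hi, 0.5, 35))
    mz <- c(stats::runif(n_rp, 124, 1000), stats::runif(n_hi, 8, 1000))
    feature_id <- paste0(ifelse(block == "RP", "RP_", "HI_"),
                         sprintf("%.3f", rt), "_", sprintf("%.4f", mz))
    if (anyDuplicated(feature_id))
      feature_id <- make.unique(feature_id, sep = "_")
    mu <- stats::runif(p, 3, 6)              # log10 baseline abundance
    k <- length(cfg$classes)
    # markers emulate identified metabolites: quantifiable compounds, so
    # they live in the upper half of baseline abundance -- a down-shifted
    # marker sitting at the detection floor would be censored, not measured
    eligible <- which(mu >= stats::median(mu))
    if (length(eligible) < cfg$markers_per_class * k)
      stop("not enough quantifiable features to plant all markers")
    marker_idx <- matrix(sample(eligible, cfg$markers_per_class * k),
                         nrow = cfg$markers_per_class)
    direction <- matrix(sample(c(-1, 1), cfg$markers_per_class * k,
                               replace = TRUE), nrow = cfg$markers_per_class)
    shift <- matrix(0, nrow = p, ncol = k,
                    dimnames = list(feature_id, cfg$classes))
    for (j in seq_len(k))
      shift[marker_idx[, j], j] <- direction[, j] * cfg$effect_size
    cell_lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
    cl_effect <- matrix(stats::rnorm(cfg$n_cell_lines * p, 0, cfg$cell_line_sd),
                        nrow = cfg$n_cell_lines,
                        dimnames = list(cell_lines, feature_id))
    drugs <- paste0(rep(cfg$classes, each = cfg$drugs_per_class), "_drug",
                    rep(seq_len(cfg$drugs_per_class), length(cfg$classes)))
    drug_class <- rep(cfg$classes, each = cfg$drugs_per_class)
    # drugs of a class share the class markers but get a small private shift
    drug_idio <- matrix(0, nrow = length(drugs), ncol = p,
                        dimnames = list(drugs, feature_id))
    for (d in seq_along(drugs)) {
      j <- match(drug_class[d], cfg$classes)
      drug_idio[d, marker_idx[, j]] <-
        stats::rnorm(cfg$markers_per_class, 0, cfg$effect_size / 5)
    }
    manifest <- data.frame(
      feature_id = feature_id[as.vector(marker_idx)],
      block = block[as.vector(marker_idx)],
      class = rep(cfg$classes, each = cfg$markers_per_class),
      direction = ifelse(as.vector(direction) > 0, "up", "down"),
      shift = as.vector(direction) * cfg$effect_size,
      stringsAsFactors = FALSE)
    list(feature_id = feature_id, block = block, rt = rt, mz = mz, mu = mu,
         shift = shift, cell_lines = cell_lines, cl_effect = cl_effect,
         drugs = drugs, drug_class = drug_class, drug_idio = drug_idio,
         floor_log = stats::quantile(mu, 0.01), manifest = manifest)
  })
}

# log10 expectation for one biological sample
sample_log_mean <- function(design, cfg, cell_line, drug, treated) {
  m <- design$mu + design$cl_effect[cell_line, ]
  if (treated) {
    cl <- design$drug_class[match(drug, design$drugs)]
    m <- m + design$shift[, cl] + design$drug_idio[drug, ]
  }
  m
}

# intensity-scale post-processing shared by study and new-set generation:
# cell-count scaling, detection floor, random dropouts
finish_intensities <- function(log_mat, counts, cfg, design, dropout = TRUE) {
  intens <- 10^log_mat
  intens <- sweep(intens, 2, counts / cfg$cell_count_mean, `*`)
  intens[log_mat < design$floor_log] <- 0
  if (dropout && cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(intens)) < cfg$missing_rate,
                   nrow = nrow(intens))
    intens[drop] <- 0
  }
  intens
}

split_blocks <- function(design, intens) {
  features <- data.frame(feature_id = design$feature_id, block = design$block,
                         rt = design$rt, mz = design$mz,
                         stringsAsFactors = FALSE)
  rp <- design$block == "RP"
  list(rp = peak_table(features[rp, , drop = FALSE],
                       intens[rp, , drop = FALSE]),
       hilic = peak_table(features[!rp, , drop = FALSE],
                          intens[!rp, , drop = FALSE]))
}

#' Generate a synthetic two-block profiling study
#'
#' Simulates the full study design described in [synthetic_config()]: for
#' every (cell line, drug) pair one treated and one control condition with
#' `replicates` profiling replicates each, plus pooled QC samples inserted
#' after every `qc_interval` analytical injections. Feature baselines are
#' log10-normal (means uniform on 3--6), with an additive cell-line random
#' effect; planted markers are shifted by +/- `effect_size` (log10) in their
#' class's treated samples only; intensities are scaled by each flask's cell
#' count relative to the nominal seeding density; values under the detection
#' floor and random dropouts are recorded as 0. QC samples are the
#' feature-wise mean of all biological samples (a pooled mixture of equal
#' aliquots) with halved technical noise. Deterministic under a fixed
#' `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `rp` and `hilic` ([peak_table()]s), `meta`
#'   (sample metadata) and `manifest` (ground-truth marker table:
#'   `feature_id`, `block`, `class`, `direction`, `shift`).
#' @examples
#' cfg <- synthetic_config(n_cell_lines = 2, n_features_rp = 40,
#'                         n_features_hilic = 20, markers_per_class = 4,
#'                         seed = 7)
#' study <- generate_study(cfg)
#' dim(study$rp)
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  design <- study_design(cfg)
  with_seed(cfg$seed + 1L, {
    grid <- expand.grid(replicate = seq_len(cfg$replicates),
                        condition = c("treated", "control"),
                        drug = design$drugs,
                        cell_line = design$cell_lines,
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    sample_id <- sprintf("S%04d", seq_len(n))
    # one counted flask per (cell line, drug, condition); its count applies
    # to the condition's profiling replicates
    flask <- interaction(grid$cell_line, grid$drug, grid$condition, drop = TRUE)
    flask_count <- stats::rlnorm(nlevels(flask),
                                 meanlog = log(cfg$cell_count_mean) -
                                   0.5 * log(1 + cfg$cell_count_cv^2),
                                 sdlog = sqrt(log(1 + cfg$cell_count_cv^2)))
    counts <- flask_count[as.integer(flask)]
    p <- length(design$feature_id)
    log_mu <- vapply(seq_len(n), function(i)
      sample_log_mean(design, cfg, grid$cell_line[i], grid$drug[i],
                      grid$condition[i] == "treated"), numeric(p))
    log_mat <- log_mu + stats::rnorm(n * p, 0, cfg$noise_sd)
    dimnames(log_mat) <- list(design$feature_id, sample_id)
    intens <- finish_intensities(log_mat, counts, cfg, design)

    # pooled QC: feature-wise mean of all biological samples, halved noise
    n_qc <- 1L + n %/% cfg$qc_interval
    qc_id <- sprintf("QC%03d", seq_len(n_qc))
    pooled <- rowMeans(intens)
    qc <- vapply(seq_len(n_qc), function(i)
      pooled * 10^stats::rnorm(p, 0, cfg$noise_sd / 2), numeric(p))
    qc[log10(pmax(qc, .Machine$double.xmin)) < design$floor_log] <- 0
    dimnames(qc) <- list(design$feature_id, qc_id)

    # injection order: QC first, then one QC after every qc_interval samples
    all_id <- character(0); qi <- 1L
    for (i in seq_len(n)) {
      if ((i - 1L) %% cfg$qc_interval == 0L) {
        all_id <- c(all_id, qc_id[qi]); qi <- qi + 1L
      }
      all_id <- c(all_id, sample_id[i])
    }
    all_id <- c(all_id, qc_id[qi:n_qc][qi <= n_qc])
    intens_all <- cbind(intens, qc)[, all_id, drop = FALSE]

    meta <- data.frame(
      sample_id = c(sample_id, qc_id),
      cell_line = c(grid$cell_line, rep(NA, n_qc)),
      drug = c(grid$drug, rep(NA, n_qc)),
      class = c(design$drug_class[match(grid$drug, design$drugs)],
                rep(NA, n_qc)),
      condition = c(grid$condition, rep("qc", n_qc)),
      cell_count = c(counts, rep(NA, n_qc)),
      stringsAsFactors = FALSE)
    meta <- meta[match(all_id, meta$sample_id), ]
    meta$injection_order <- seq_len(nrow(meta))
    rownames(meta) <- NULL
    meta <- validate_sample_meta(meta)

    c(split_blocks(design, intens_all),
      list(meta = meta, manifest = design$manifest))
  })
}

#' Generate an evaluation sample set for a new compound
#'
#' Draws treated samples for a compound whose mechanism matches one of the
#' configured classes (emulating the study's independent evaluation drugs),
#' or -- with `model_class = "mixed"` -- a compound acting through two
#' mechanisms at once: the two named classes' marker shifts are applied
#' simultaneously at half magnitude, the situation in which projected points
#' fall between two class regions.
#'
#' @param cfg the [synthetic_config()] that generated the training study
#'   (same seed = same feature space).
#' @param model_class one of `cfg$classes`, or `"mixed"`.
#' @param n_samples number of samples to draw (0 gives empty, valid tables).
#' @param mixed_classes length-2 character vector naming the two classes a
#'   `"mixed"` compound acts through.
#' @param drug label recorded in the metadata (default `"NEW"`).
#' @param seed randomness for this draw; defaults to `cfg$seed + 10000`.
#' @return list with `rp`, `hilic` and `meta` as in [generate_study()].
#' @export
generate_new_drug_set <- function(cfg, model_class, n_samples,
                                  mixed_classes = NULL, drug = "NEW",
                                  seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mixed <- identical(model_class, "mixed")
  if (!mixed && !model_class %in% cfg$classes)
    stop("unknown class label: ", model_class)
  if (mixed) {
    if (is.null(mixed_classes) || length(mixed_classes) != 2 ||
        !all(mixed_classes %in% cfg$classes))
      stop("'mixed' needs mixed_classes naming two of cfg$classes")
  }
  n_samples <- stopifnot_scalar_count(n_samples, "n_samples", min = 0)
  design <- study_design(cfg)
  with_seed(seed %||% (cfg$seed + 10000L), {
    p <- length(design$feature_id)
    shift <- if (mixed) {
      0.5 * (design$shift[, mixed_classes[1]] + design$shift[, mixed_classes[2]])
    } else design$shift[, model_class]
    cl <- rep_len(design$cell_lines, n_samples)
    sample_id <- sprintf("N%04d", seq_len(n_samples))
    counts <- stats::rlnorm(n_samples,
                            meanlog = log(cfg$cell_count_mean) -
                              0.5 * log(1 + cfg$cell_count_cv^2),
                            sdlog = sqrt(log(1 + cfg$cell_count_cv^2)))
    log_mat <- vapply(seq_len(n_samples), function(i)
      design$mu + design$cl_effect[cl[i], ] + shift +
        stats::rnorm(p, 0, cfg$noise_sd), numeric(p))
    if (n_samples == 0L)
      log_mat <- matrix(numeric(0), nrow = p, ncol = 0L)
    dimnames(log_mat) <- list(design$feature_id, sample_id)
    intens <- finish_intensities(log_mat, counts, cfg, design)
    meta <- data.frame(
      sample_id = sample_id, cell_line = cl,
      drug = rep_len(drug, n_samples),
      class = rep_len(if (mixed) "mixed" else model_class, n_samples),
      condition = rep_len("treated", n_samples),
      cell_count = counts, injection_order = seq_len(n_samples),
      stringsAsFactors = FALSE)
    meta <- validate_sample_meta(meta)
    c(split_blocks(design, intens), list(meta = meta))
  })
}
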