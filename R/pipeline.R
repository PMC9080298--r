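#' Assemble a run configuration
#'
#' Validates a pipeline configuration (a named list, or a YAML file path).
#' Recognized top-level keys: `seed`, `out_dir`, `stages` (character subset
#' of the fixed stage order), `synthetic` (arguments for
#' [synthetic_config()]), `preprocess` (`max_missing`), `model` (`n_pred`,
#' `n_orth`, `cv_folds`), `validate` (`n_perm`, `folds`), `markers`
#' (`vip_threshold`, `alpha`, `auc_threshold`), `predict`
#' (`n_samples_per_set`, `margin_threshold`). Unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("seed", "out_dir", "stages", "synthetic", "preprocess", "model",
             "validate", "markers", "predict")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  all_stages <- c("simulate", "preprocess", "qa", "fit", "validate",
                  "markers", "predict")
  cfg <- list(
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir %||% NULL,
    stages = config$stages %||% all_stages,
    synthetic = config$synthetic %||% list(),
    preprocess = config$preprocess %||% list(),
    model = config$model %||% list(),
    validate = config$validate %||% list(),
    markers = config$markers %||% list(),
    predict = config$predict %||% list())
  bad <- setdiff(cfg$stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$stages <- all_stages[all_stages %in% cfg$stages]   # fixed order
  class(cfg) <- "run_config"
  cfg
}

#' Run the end-to-end study pipeline
#'
#' Executes the enabled stages in the fixed order simulate -> preprocess ->
#' qa -> fit -> validate -> markers -> predict, from a single configuration
#' and a single seed. A stage whose upstream requirement was toggled off
#' fails fast naming the missing stage. When `out_dir` is set, artifacts
#' (peak tables, metadata, marker tables, reports) and a JSON manifest
#' (seed, per-stage sample/feature counts, file hashes) are written there.
#'
#' @param config a [run_config()], a named list, or a YAML path.
#' @return invisible list with the per-stage results (`study`, `prep`,
#'   `qa`, `model`, `validation`, `markers`, `predictions`, `manifest`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  res <- list()
  manifest <- list(seed = cfg$seed, stages = cfg$stages, counts = list())
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs the output of a disabled stage",
           call. = FALSE)
  }

  if ("simulate" %in% cfg$stages) {
    scfg <- do.call(synthetic_config, c(cfg$synthetic, list(seed = cfg$seed)))
    res$study <- generate_study(scfg)
    res$synthetic_config <- scfg
    manifest$counts$simulate <- c(samples = nrow(res$study$meta),
                                  features = nrow(res$study$rp) +
                                    nrow(res$study$hilic))
  }
  if ("preprocess" %in% cfg$stages) {
    need("study", "preprocess")
    res$prep <- do.call(preprocess_study,
                        c(list(res$study$rp, res$study$hilic, res$study$meta),
                          cfg$preprocess))
    manifest$counts$preprocess <- c(samples = nrow(res$prep$scaled$X),
                                    features = ncol(res$prep$scaled$X))
  }
  if ("qa" %in% cfg$stages) {
    need("prep", "qa")
    pca <- fit_pca(res$prep$scaled, n_components = 2)
    res$qa <- list(pca = pca,
                   qc = qc_drift_check(pca, res$prep$meta),
                   explained_pc12 = sum(pca$explained[1:2]))
    manifest$counts$qa <- c(qc_pass = sum(res$qa$qc$pass),
                            qc_total = nrow(res$qa$qc))
  }
  if ("fit" %in% cfg$stages) {
    need("prep", "fit")
    tr <- res$prep$meta$condition == "treated"
    xs <- subset_scaled(res$prep$scaled, tr)
    res$train_x <- xs
    res$train_y <- factor(res$prep$meta$class[tr])
    res$model <- do.call(oplsda, c(list(xs, res$train_y, seed = cfg$seed),
                                   cfg$model))
    manifest$counts$fit <- c(R2Y = res$model$R2Y, Q2 = res$model$Q2)
  }
  if ("validate" %in% cfg$stages) {
    need("model", "validate")
    n_perm <- cfg$validate$n_perm %||% 99
    folds <- cfg$validate$folds %||% 7
    perm <- permutation_test(res$train_x, res$train_y, n_perm = n_perm,
                             folds = folds, n_pred = res$model$n_pred,
                             n_orth = res$model$n_orth, seed = cfg$seed)
    cv <- cross_validate(res$train_x, res$train_y, folds = folds,
                         n_pred = res$model$n_pred,
                         n_orth = res$model$n_orth, seed = cfg$seed)
    res$validation <- list(permutation = perm, cv = cv, cv_anova = cv_anova(cv))
    manifest$counts$validate <- c(q2_intercept = perm$q2_intercept,
                                  cv_anova_p = res$validation$cv_anova$p)
  }
  if ("markers" %in% cfg$stages) {
    need("model", "markers")
    classes <- res$model$y_levels
    res$markers <- lapply(classes, function(cl)
      do.call(select_markers, c(list(res$model, res$prep, cl), cfg$markers)))
    names(res$markers) <- classes
    manifest$counts$markers <- vapply(res$markers, function(m) sum(m$passes),
                                      numeric(1))
  }
  if ("predict" %in% cfg$stages) {
    need("model", "predict")
    scfg <- res$synthetic_config
    n_new <- cfg$predict$n_samples_per_set %||% 24
    res$predictions <- lapply(scfg$classes, function(cl) {
      nd <- generate_new_drug_set(scfg, cl, n_new,
                                  seed = cfg$seed + 20000L + match(cl, scfg$classes))
      xn <- apply_preprocess(res$prep, nd$rp, nd$hilic, nd$meta)
      classify_set(res$model, xn, set_label = cl,
                   margin_threshold = cfg$predict$margin_threshold %||% 0.2)
    })
    names(res$predictions) <- scfg$classes
    manifest$counts$predict <-
      vapply(res$predictions, `[[`, numeric(1), "concordance")
  }

  res$manifest <- manifest
  if (!is.null(cfg$out_dir)) write_run_dir(cfg, res)
  invisible(res)
}

# restrict a scaled_matrix to a sample subset (keeps center/scale: they
# remain the training-state projection for new samples)
subset_scaled <- function(sm, idx) {
  out <- sm
  out$X <- sm$X[idx, , drop = FALSE]
  out$sample_id <- sm$sample_id[idx]
  out
}

write_run_dir <- function(cfg, res) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(res$study)) {
    paths <- c(paths,
               write_peak_table(res$study$rp, file.path(cfg$out_dir, "rp.tsv")),
               write_peak_table(res$study$hilic, file.path(cfg$out_dir, "hilic.tsv")),
               write_sample_meta(res$study$meta, file.path(cfg$out_dir, "meta.tsv")))
    utils::write.table(res$study$manifest,
                       file.path(cfg$out_dir, "marker_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, file.path(cfg$out_dir, "marker_manifest.tsv"))
  }
  if (!is.null(res$markers)) {
    mk <- do.call(rbind, res$markers)
    utils::write.table(mk, file.path(cfg$out_dir, "markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, file.path(cfg$out_dir, "markers.tsv"))
  }
  manifest <- res$manifest
  hashes <- tools::md5sum(paths)
  manifest$files <- as.list(stats::setNames(unname(hashes), basename(paths)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}
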