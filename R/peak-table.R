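#' Aligned LC-MS peak table
#'
#' A `peak_table` holds one chromatographic block (reversed-phase `"RP"` or
#' hydrophilic-interaction `"HILIC"`) of an aligned feature matrix: one row
#' per feature (retention time, m/z) and one intensity column per sample.
#' An intensity of 0 encodes a missing (undetected) ion.
#'
#' @param features data.frame with columns `feature_id`, `block`, `rt`
#'   (minutes) and `mz` (Da).
#' @param intensities numeric matrix, features x samples, non-negative, with
#'   column names giving sample ids and rows matching `features`.
#' @return object of class `peak_table` with elements `features` and
#'   `intensities`.
#' @details Feature ids must be unique within a table. m/z values must lie in
#'   the block's acquired mass range: 124--1000 Da for RP and 8--1000 Da for
#'   HILIC.
#' @seealso [read_peak_table()], [write_peak_table()]
#' @export
peak_table <- function(features, intensities) {
  stopifnot(is.data.frame(features), is.matrix(intensities))
  required <- c("feature_id", "block", "rt", "mz")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols))
    stop("features is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(features) != nrow(intensities))
    stop("features (", nrow(features), " rows) and intensities (",
         nrow(intensities), " rows) disagree")
  x <- structure(list(features = features, intensities = intensities),
                 class = "peak_table")
  validate_peak_table(x)
}

validate_peak_table <- function(x) {
  f <- x$features
  dup <- f$feature_id[duplicated(f$feature_id)]
  if (length(dup))
    stop("duplicated feature_id: ", paste(unique(dup), collapse = ", "))
  if (!all(f$block %in% c("RP", "HILIC")))
    stop("block must be 'RP' or 'HILIC'")
  if (any(f$rt <= 0)) stop("retention times must be > 0 minutes")
  lo <- ifelse(f$block == "RP", 124, 8)
  bad <- f$mz < lo | f$mz > 1000
  if (any(bad))
    stop("m/z outside the block's acquired range for feature(s): ",
         paste(utils::head(f$feature_id[bad], 5), collapse = ", "))
  if (any(x$intensities < 0))
    stop("negative intensity found; intensities must be >= 0 (0 = missing)")
  rownames(x$intensities) <- f$feature_id
  x
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d features (%s) x %d samples\n",
              nrow(x$features), paste(unique(x$features$block), collapse = "+"),
              ncol(x$intensities)))
  zf <- mean(x$intensities == 0)
  cat(sprintf("  rt %.2f-%.2f min, m/z %.4f-%.4f, %.1f%% zero entries\n",
              min(x$features$rt), max(x$features$rt),
              min(x$features$mz), max(x$features$mz), 100 * zf))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Read / write an aligned peak table
#'
#' The on-disk format is a wide, UTF-8, tab-separated table with a mandatory
#' header: columns `feature_id`, `block`, `rt_min`, `mz`, then one intensity
#' column per sample id. Writing then reading a valid table reproduces it
#' exactly (round-trip identity).
#'
#' @param path file path of the TSV.
#' @return `read_peak_table` returns a [peak_table()]; `write_peak_table`
#'   returns `path` invisibly.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  fixed <- c("feature_id", "block", "rt_min", "mz")
  if (!all(fixed %in% names(df)))
    stop("peak table header must contain: ", paste(fixed, collapse = ", "))
  sample_ids <- setdiff(names(df), fixed)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad))
      stop("malformed numeric in column '", what, "' at data row ", bad[1],
           ": '", df[[col]][bad[1]], "'")
    v
  }
  features <- data.frame(feature_id = df$feature_id, block = df$block,
                         rt = num("rt_min", "rt_min"), mz = num("mz", "mz"),
                         stringsAsFactors = FALSE)
  intens <- vapply(sample_ids, function(s) num(s, s), numeric(nrow(df)))
  if (nrow(df) == 1L) intens <- matrix(intens, nrow = 1L,
                                       dimnames = list(NULL, sample_ids))
  if (nrow(df) == 0L) intens <- matrix(numeric(0), nrow = 0L, ncol = length(sample_ids),
                                       dimnames = list(NULL, sample_ids))
  peak_table(features, intens)
}

#' @rdname read_peak_table
#' @param table a [peak_table()].
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  f <- table$features
  out <- data.frame(feature_id = f$feature_id, block = f$block,
                    rt_min = f$rt, mz = f$mz, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(table$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Sample annotations: `sample_id`, `cell_line`, `drug`, `class` (one of the
#' mechanism-of-action labels, or empty), `condition`
#' (`treated`/`control`/`qc`), `cell_count` (cells per flask; the
#' normalization denominator) and `injection_order`. Pooled QC samples carry
#' no drug, class or cell count.
#'
#' @param path TSV path.
#' @return data.frame of class `sample_meta`.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_sample_meta(df)
}

#' @rdname read_sample_meta
#' @param meta sample metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

validate_sample_meta <- function(df) {
  required <- c("sample_id", "cell_line", "drug", "class", "condition",
                "cell_count", "injection_order")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  if (!all(df$condition %in% c("treated", "control", "qc")))
    stop("condition must be treated, control or qc")
  qc <- df$condition == "qc"
  if (any(!is.na(df$drug[qc])) || any(!is.na(df$class[qc])))
    stop("QC samples must have no drug or class label")
  if (any(!qc & (is.na(df$cell_count) | df$cell_count <= 0)))
    stop("every biological sample needs cell_count > 0")
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Load the packaged marker-metabolite tables
#'
#' Returns the package's transcription of the four published marker tables
#' (one per mechanism-of-action class: microtubule-affecting, DNA-acting,
#' antimetabolite, RNA-interfering), 52 records in total. Each record carries
#' the printed retention time, metabolite name, m/z, significance flag
#' (`<0.05` / `<0.01` / `<0.001` -- the tables print significance stars, not
#' exact p values), ROC AUC, fold change, trend and pathway annotation.
#'
#' On load the records are integrity-checked against the published row
#' counts and the table semantics (AUC > 0.5 retention rule; trend arrow
#' consistent with fold change as a treated/control ratio).
#'
#' @param path directory holding the fixture TSVs; defaults to the copies
#'   installed with the package.
#' @return data.frame of class `marker_records` (one row per printed marker).
#' @examples
#' m <- load_marker_fixtures()
#' table(m$class)
#' @export
load_marker_fixtures <- function(path = NULL) {
  path <- path %||% system.file("extdata", package = "moaprofile")
  files <- file.path(path, paste0("table", 2:5, ".tsv"))
  if (!all(file.exists(files)))
    stop("marker fixture files not found under ", path)
  recs <- do.call(rbind, lapply(files, function(f)
    utils::read.delim(f, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                      quote = "")))
  expected <- c(antimetabolite = 11L, dna_acting = 17L,
                microtubule = 12L, rna_interference = 12L)
  counts <- table(recs$class)
  for (cl in names(expected)) {
    n <- if (cl %in% names(counts)) counts[[cl]] else 0L
    if (n != expected[[cl]])
      stop("fixture integrity check failed: class ", cl, " has ", n,
           " records, expected ", expected[[cl]])
  }
  if (!all(recs$p_flag %in% c("<0.05", "<0.01", "<0.001")))
    stop("fixture integrity check failed: bad p_flag value")
  if (any(recs$auc <= 0.50 | recs$auc > 1))
    stop("fixture integrity check failed: AUC outside (0.50, 1]")
  if (any(recs$fc <= 0))
    stop("fixture integrity check failed: fold change must be > 0")
  if (!identical(recs$trend == "up", recs$fc > 1))
    stop("fixture integrity check failed: trend arrow inconsistent with FC")
  class(recs) <- c("marker_records", "data.frame")
  recs
}

#' Deduplicate marker records by metabolite identity
#'
#' Several metabolites recur across the four per-class tables (the same
#' compound responds to more than one drug class), and one compound appears
#' as two distinct ions. The published per-class tables therefore hold more
#' rows than unique metabolites. The deduplication key is configurable
#' because name-level and ion-level counting give different answers.
#'
#' @param records data.frame from [load_marker_fixtures()].
#' @param key `"name"` (case-insensitive metabolite name) or `"name_mz"`
#'   (name plus m/z rounded to `digits`, distinguishing distinct ions of the
#'   same compound).
#' @param digits m/z rounding used by the `"name_mz"` key.
#' @return the records with one row per unique key (first occurrence kept).
#' @export
dedup_markers <- function(records, key = c("name", "name_mz"), digits = 1) {
  key <- match.arg(key)
  id <- tolower(trimws(records$name))
  if (key == "name_mz") id <- paste(id, round(records$mz, digits))
  records[!duplicated(id), , drop = FALSE]
}
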