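# Internal helpers shared across modules.

#' Class indicator (dummy) matrix
#'
#' Expands a class factor into an n x K indicator matrix with one 1 per row,
#' the coding used by the discriminant models. Column order follows the factor
#' levels.
#'
#' @param y factor (or coercible) of class labels.
#' @param levels optional explicit level ordering.
#' @return numeric matrix, n rows, one column per class level.
#' @keywords internal
#' @noRd
dummy_matrix <- function(y, levels = NULL) {
  y <- if (is.null(levels)) factor(y) else factor(y, levels = levels)
  if (anyNA(y)) stop("class labels contain values outside the given levels")
  k <- nlevels(y)
  if (k < 2L) stop("need at least 2 class levels, got ", k)
  Y <- matrix(0, nrow = length(y), ncol = k,
              dimnames = list(names(y), levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so every fold sees every class when class sizes allow it.
stratified_folds <- function(y, folds, seed = NULL) {
  y <- factor(y)
  if (folds < 2L) stop("folds must be >= 2")
  if (min(table(y)) < folds)
    stop("smallest class has fewer samples (", min(table(y)),
         ") than folds (", folds, "); every fold must see every class")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# argmax over a membership vector; exact ties broken by smallest class index.
argmax_class <- function(yhat, levels) {
  levels[max.col(yhat, ties.method = "first")]
}

# Run an expression with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(name, " must be a single integer >= ", min)
  as.integer(x)
}
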