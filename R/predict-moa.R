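#' Classify a new compound sample set by projection
#'
#' Projects a set of samples from one (candidate) compound onto the trained
#' OPLS-DA model and summarizes the set: per-sample class membership
#' vectors (raw, un-renormalized `Yhat`), per-sample calls (argmax), the
#' set-level majority call, the concordance (fraction of samples agreeing
#' with the majority), a projection fit `R2_pred` and a sevenfold
#' re-blocked external `Q2_ext` under the called class, and a
#' mixed-mechanism flag raised when the two largest mean memberships differ
#' by less than `margin_threshold` -- the situation where the points fall
#' between two class regions. A set whose top mean membership stays below
#' `no_signal_threshold` (e.g. untreated controls) is called `"none"` with
#' a warning.
#'
#' With the default frozen-model projection the re-blocked `Q2_ext` equals
#' `R2_pred` (the predictions do not depend on the blocking); `refit = TRUE`
#' instead refits the model per block on the training data plus the
#' remaining new samples.
#'
#' @param model fitted [oplsda()].
#' @param x_new new samples on the scale [predict.oplsda()] expects
#'   (log10 matrix from [apply_preprocess()] when the model carries scaling
#'   state).
#' @param set_label label for reporting (e.g. the compound code).
#' @param margin_threshold mixed-mechanism margin on mean memberships
#'   (default 0.2).
#' @param no_signal_threshold minimum top mean membership for a confident
#'   call (default 0.4).
#' @param folds re-blocking folds for `Q2_ext` (default 7).
#' @param refit refit the model per re-block instead of freezing it.
#' @param x_train,y_train training data, required only when `refit = TRUE`.
#' @return object of class `moa_prediction`: `set_label`, `yhat`,
#'   `t_pred`, `t_orth`, `sample_class` (per-sample calls), `call`
#'   (majority class, `"none"`, or `"unresolved"` on an exact vote tie),
#'   `concordance`, `mean_membership`, `top2`, `margin`, `mixed_flag`,
#'   `r2_pred`, `q2_ext`.
#' @export
classify_set <- function(model, x_new, set_label = "set",
                         margin_threshold = 0.2, no_signal_threshold = 0.4,
                         folds = 7, refit = FALSE, x_train = NULL,
                         y_train = NULL) {
  stopifnot(inherits(model, "oplsda"))
  if (is.null(dim(x_new)) || nrow(x_new) == 0) stop("empty sample set")
  yhat <- predict(model, x_new, type = "response")
  scores <- predict(model, x_new, type = "scores")
  cls <- argmax_class(yhat, model$y_levels)
  votes <- table(factor(cls, levels = model$y_levels))
  top_votes <- which(votes == max(votes))
  mean_mem <- colMeans(yhat)
  ord <- order(mean_mem, decreasing = TRUE)
  top2 <- model$y_levels[ord[1:2]]
  margin <- unname(mean_mem[ord[1]] - mean_mem[ord[2]])
  mixed_flag <- margin < margin_threshold
  call_cls <- if (length(top_votes) > 1) "unresolved"
              else model$y_levels[top_votes]
  if (mean_mem[ord[1]] < no_signal_threshold) {
    warning("set '", set_label, "': low membership for every class (max ",
            sprintf("%.2f", mean_mem[ord[1]]), "); calling 'none'")
    call_cls <- "none"
  }
  concordance <- max(votes) / length(cls)

  # fit of the set under its called class
  eff_cls <- if (call_cls %in% model$y_levels) call_cls else top2[1]
  Ycall <- matrix(0, nrow(yhat), length(model$y_levels),
                  dimnames = list(NULL, model$y_levels))
  Ycall[, eff_cls] <- 1
  ss_res <- sum((yhat - Ycall)^2)
  ss_tot <- sum(sweep(Ycall, 2, model$y_means)^2)
  r2_pred <- 1 - ss_res / ss_tot

  q2_ext <- if (!refit) {
    r2_pred        # frozen model: predictions are blocking-independent
  } else {
    if (is.null(x_train) || is.null(y_train))
      stop("refit = TRUE needs x_train and y_train")
    fold <- rep_len(seq_len(min(folds, nrow(yhat))), nrow(yhat))
    press <- 0
    Xtr0 <- if (inherits(x_train, "scaled_matrix")) back_transform(x_train)
            else as.matrix(x_train)
    Xnw <- as.matrix(x_new)[, model$feature_id, drop = FALSE]
    for (f in unique(fold)) {
      hold <- fold == f
      Xf <- rbind(Xtr0, Xnw[!hold, , drop = FALSE])
      yf <- factor(c(as.character(y_train), rep(eff_cls, sum(!hold))),
                   levels = model$y_levels)
      sc <- pareto_scale(Xf)
      mf <- oplsda_core(sc$X, yf, model$n_pred, model$n_orth,
                        y_levels = model$y_levels)
      Xh <- sweep(sweep(Xnw[hold, , drop = FALSE], 2, sc$center),
                  2, sc$scale, `/`)
      for (j in seq_len(mf$n_orth)) {
        t_o <- Xh %*% mf$Wo[, j]
        Xh <- Xh - tcrossprod(t_o, mf$Po[, j])
      }
      yh <- sweep(Xh %*% mf$B, 2, mf$y_means, `+`)
      press <- press + sum((Ycall[hold, , drop = FALSE] - yh)^2)
    }
    1 - press / ss_tot
  }

  structure(list(set_label = set_label, yhat = yhat,
                 t_pred = scores$t_pred, t_orth = scores$t_orth,
                 sample_class = cls, call = call_cls,
                 concordance = unname(concordance),
                 mean_membership = mean_mem, top2 = top2, margin = margin,
                 mixed_flag = mixed_flag, r2_pred = r2_pred, q2_ext = q2_ext),
            class = "moa_prediction")
}

#' @export
print.moa_prediction <- function(x, ...) {
  cat(sprintf("set '%s': called %s (concordance %.2f)\n",
              x$set_label, x$call, x$concordance))
  cat(sprintf("  R2 = %.3f and Q2 = %.3f\n", x$r2_pred, x$q2_ext))
  cat(sprintf("  mean memberships: %s\n",
              paste(sprintf("%s %.2f", names(x$mean_membership),
                            x$mean_membership), collapse = ", ")))
  if (x$mixed_flag)
    cat(sprintf("  mixed mechanism flag: between %s and %s (margin %.2f)\n",
                x$top2[1], x$top2[2], x$margin))
  invisible(x)
}

#' Score-space region report for new sample sets
#'
#' Summarizes where new sets land relative to the training classes in the
#' first two predictive score dimensions: the convex hull of each training
#' class is computed, and for every prediction set the fraction of its
#' points falling inside each hull is reported. A mixed-mechanism set shows
#' nonzero fractions in two hulls.
#'
#' @param model fitted [oplsda()] with >= 2 predictive components.
#' @param results list of `moa_prediction` objects (at least one).
#' @return object of class `moa_regions`: `hulls` (per-class score
#'   polygons) and `inside` (sets x classes matrix of fractions).
#' @export
region_report <- function(model, results) {
  stopifnot(inherits(model, "oplsda"), length(results) >= 1)
  if (inherits(results, "moa_prediction")) results <- list(results)
  if (model$n_pred < 2) stop("need >= 2 predictive components for regions")
  tr <- model$T[, 1:2, drop = FALSE]
  hulls <- lapply(model$y_levels, function(cl) {
    pts <- tr[model$y == cl, , drop = FALSE]
    if (nrow(pts) < 3) stop("class ", cl, " has fewer than 3 training samples")
    pts[grDevices::chull(pts), , drop = FALSE]
  })
  names(hulls) <- model$y_levels
  inside <- t(vapply(results, function(res) {
    pts <- res$t_pred[, 1:2, drop = FALSE]
    vapply(hulls, function(h)
      mean(mgcv::in.out(rbind(h, h[1, ]), pts)), numeric(1))
  }, numeric(length(hulls))))
  rownames(inside) <- vapply(results, `[[`, character(1), "set_label")
  structure(list(hulls = hulls, inside = inside,
                 scores = lapply(results, `[[`, "t_pred"),
                 labels = rownames(inside), training_scores = tr,
                 training_class = model$y),
            class = "moa_regions")
}

#' @export
print.moa_regions <- function(x, ...) {
  cat("fraction of new points inside each training-class hull:\n")
  print(round(x$inside, 3))
  invisible(x)
}

#' @export
plot.moa_regions <- function(x, ...) {
  n <- length(x$labels)
  old <- graphics::par(mfrow = grDevices::n2mfrow(n), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  classes <- levels(x$training_class)
  for (i in seq_len(n)) {
    graphics::plot(x$training_scores, col = as.integer(x$training_class),
                   pch = 1, cex = 0.6, xlab = "t[1]", ylab = "t[2]",
                   main = x$labels[i], ...)
    for (j in seq_along(x$hulls)) {
      h <- x$hulls[[j]]
      graphics::polygon(h, border = j, lty = 2)
    }
    graphics::points(x$scores[[i]][, 1:2, drop = FALSE], pch = 19, col = 1,
                     cex = 0.8)
  }
  invisible(x)
}
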