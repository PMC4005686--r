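#' Fit the L1-regularized logistic filter model
#'
#' Fits a sparse logistic regression of the potential-false-positive label on
#' the overhang-deviation feature vectors, over the whole set of detectable
#' junctions (semi-supervised: the labelled class is a strict subset of the
#' true false positives, and the presumed-OK class tolerates label noise).
#' The L1 penalty promotes a sparse representation — counts at distant
#' overhang positions are inherently noisier and the penalty selects the
#' informative positions agnostically.
#'
#' The penalty is parameterised sklearn-style by an inverse strength `C`
#' (objective `C * sum(logloss) + ||w||_1`), translated internally to the
#' glmnet scale `lambda = 1 / (C * n)`. The intercept is unpenalized.
#'
#' @param x Numeric feature matrix (junctions x positions), from
#'   [junction_features()].
#' @param labels Character vector (`"POTENTIAL_FP"` / `"PRESUMED_OK"`) or
#'   logical vector (`TRUE` = potential FP), length `nrow(x)`.
#' @param l1_c Inverse regularization strength `C` (default 1.0).
#' @param seed Optional integer seed (the fit itself is deterministic; the
#'   seed is set for strict end-to-end reproducibility).
#' @return A `filter_model`: list with `weights` (named numeric vector),
#'   `intercept`, `l1_c`, `lambda`, `n_train`, `n_labeled_fp`.
#' @examples
#' x <- rbind(matrix(-3, 10, 4), matrix(0, 100, 4))
#' y <- rep(c(TRUE, FALSE), c(10, 100))
#' m <- fit_filter_model(x, y)
#' mean((posterior_fp(m, x) > 0.5) == y)  # 1
#' @export
fit_filter_model <- function(x, labels, l1_c = 1.0, seed = NULL) {
  x <- as.matrix(x)
  y <- as_fp_indicator(labels)
  stopifnot(nrow(x) == length(y), l1_c > 0)
  if (!all(is.finite(x))) stop("non-finite feature value")
  n_fp <- sum(y)
  if (n_fp == 0L || n_fp == length(y))
    stop(structure(class = c("NoLabeledClassError", "error", "condition"),
                   list(message = "both label classes are required to fit the filter model",
                        call = sys.call())))
  if (!is.null(seed)) set.seed(as.integer(seed))
  lambda <- 1 / (l1_c * length(y))
  # fit along a decreasing lambda path (warm starts); a lone small lambda
  # does not converge reliably in coordinate descent
  lmax <- max(max(abs(crossprod(x, y - mean(y)))) / length(y), lambda * 10)
  lam_seq <- exp(seq(log(lmax), log(lambda), length.out = 50L))
  fit <- glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 1, lambda = lam_seq,
                        standardize = FALSE, thresh = 1e-6, maxit = 1e4)
  k <- which.min(abs(fit$lambda - lambda))
  if (abs(fit$lambda[k] - lambda) > 1e-8 * lambda)
    warning("solver did not reach the requested penalty; ",
            "using the closest converged solution on the path")
  w <- as.numeric(fit$beta[, k])
  names(w) <- colnames(x)
  structure(list(weights = w, intercept = as.numeric(fit$a0[k]),
                 l1_c = l1_c, lambda = lambda,
                 n_train = length(y), n_labeled_fp = n_fp),
            class = "filter_model")
}

as_fp_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("POTENTIAL_FP", "PRESUMED_OK")))
      stop("labels must be POTENTIAL_FP or PRESUMED_OK")
    return(labels == "POTENTIAL_FP")
  }
  stop("labels must be logical or character")
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf(paste0("filter_model: %d features (%d nonzero), intercept %.4f, ",
                     "C = %g, trained on %d junctions (%d labelled FP)\n"),
              length(x$weights), sum(x$weights != 0), x$intercept,
              x$l1_c, x$n_train, x$n_labeled_fp))
  invisible(x)
}

#' Posterior probability of the false-positive class
#'
#' `plogis(intercept + weights . x)` for each feature vector.
#'
#' @param model A `filter_model`.
#' @param x Feature matrix (or single vector) with columns matching the
#'   model's weights.
#' @return Numeric vector of posteriors in (0, 1).
#' @export
posterior_fp <- function(model, x) {
  stopifnot(inherits(model, "filter_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$weights))
    stop("feature length does not match model weights")
  if (!all(is.finite(x))) stop("non-finite feature value")
  as.numeric(plogis(model$intercept + x %*% model$weights))
}

#' Export a fitted model as a tidy weight table
#'
#' @param model A `filter_model`.
#' @param path Optional path; when given a TSV of (position, weight) rows
#'   plus an intercept row is written.
#' @return Invisibly, a `data.table` with columns `term`, `weight`.
#' @export
dump_filter_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "filter_model"))
  tab <- data.table(term = c("(intercept)", names(model$weights)),
                    weight = c(model$intercept, unname(model$weights)))
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Score junctions and apply the posterior filter
#'
#' Every junction — including those labelled as potential false positives —
#' is scored by the fitted model; a junction is discarded iff its posterior
#' probability of belonging to the false-positive class strictly exceeds the
#' threshold. With `hard_labels = TRUE`, labelled potential false positives
#' are discarded unconditionally (`AUTO_DISCARDED`) instead of being given
#' the chance of rescue by a low posterior.
#'
#' @param labelled A labelled `junction_evidence` table (from
#'   [label_junctions()]).
#' @param features Feature matrix aligned row-wise with `labelled`.
#' @param model A `filter_model`, or `NULL` for the degenerate fallback in
#'   which every junction is accepted with posterior 0.
#' @param threshold Posterior cut in (0, 1), default 0.5; strict inequality.
#' @param hard_labels Discard labelled potential FPs unconditionally.
#' @return `data.table` of junction decisions: key columns, `label`,
#'   `posterior_fp`, `status` (`ACCEPTED`, `DISCARDED` or `AUTO_DISCARDED`).
#' @export
apply_filter <- function(labelled, features, model, threshold = 0.5,
                         hard_labels = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  keyc <- c("reference", "intron_start", "intron_end", "strand")
  out <- as.data.table(labelled)[, c(keyc, "label", "n_unique"), with = FALSE]
  if (nrow(out) == 0L) {
    out[, `:=`(posterior_fp = numeric(0), status = character(0))]
    return(out[])
  }
  if (is.null(model)) {
    out[, posterior_fp := 0]
    out[, status := "ACCEPTED"]
  } else {
    out[, posterior_fp := posterior_fp(model, features)]
    out[, status := fifelse(posterior_fp > threshold, "DISCARDED", "ACCEPTED")]
  }
  if (hard_labels)
    out[label == "POTENTIAL_FP", status := "AUTO_DISCARDED"]
  out[]
}
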