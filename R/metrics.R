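junction_key_str <- function(dt) {
  paste(dt$reference, dt$intron_start, dt$intron_end, dt$strand, sep = ":")
}

as_call_keys <- function(calls) {
  if (inherits(calls, "junction_filter_result")) calls <- calls$calls
  dt <- as.data.table(calls)
  if ("status" %in% names(dt)) dt <- dt[status == "ACCEPTED"]
  unique(junction_key_str(dt))
}

#' Build a detection report from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, positive predictive value `tp/(tp+fp)` and
#' their harmonic mean (F1). Zero-denominator ratios are reported as `NA`,
#' never as 0.
#'
#' @param tp,fp,fn Confusion counts.
#' @return A `detection_report` list: `tp`, `fp`, `fn`, `sensitivity`,
#'   `ppv`, `f1`.
#' @export
detection_report <- function(tp, fp, fn) {
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(ppv) && sens + ppv > 0)
    2 * sens * ppv / (sens + ppv) else NA_real_
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 sensitivity = sens, ppv = ppv, f1 = f1),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: tp=%d fp=%d fn=%d  sens=%.4f ppv=%.4f f1=%.4f\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$ppv, x$f1))
  invisible(x)
}

#' Junction detection metrics against a truth table
#'
#' True positives are called junctions present in the expressed truth set;
#' false positives are called junctions absent from it; false negatives are
#' expressed junctions that were not called — all expressed junctions by
#' default (an expressed junction with no unique hit counts as a false
#' negative), or only those inside a supplied detectable `universe`.
#'
#' @param calls Accepted junction calls: a `junction_filter_result`, or a
#'   table with the junction key columns (rows with a `status` column are
#'   filtered to `ACCEPTED`).
#' @param truth Truth table (see [simulate_spliced_dataset()]); rows with
#'   `class == "expressed"` define the positive set.
#' @param universe Optional table of detectable junction keys restricting
#'   the false-negative count.
#' @return A [detection_report()].
#' @export
detection_metrics <- function(calls, truth, universe = NULL) {
  truth <- as.data.table(truth)
  stopifnot(nrow(truth) > 0L)
  expressed <- unique(junction_key_str(truth[class == "expressed"]))
  called <- as_call_keys(calls)
  tp <- sum(called %chin% expressed)
  fp <- length(called) - tp
  missed <- setdiff(expressed, called)
  if (!is.null(universe)) {
    uni <- unique(junction_key_str(as.data.table(universe)))
    missed <- intersect(missed, uni)
  }
  detection_report(tp, fp, length(missed))
}

#' Junction quantification error against a truth table
#'
#' Per-junction absolute error `|called - true|` over the union of called
#' and expressed junctions: an expressed junction absent from the calls
#' contributes its full true count (false negative), a called junction
#' absent from the expressed truth contributes its full called count (false
#' positive). The relative error `absolute/true` is defined only where
#' `true_count > 0`.
#'
#' @param calls Either a `junction_filter_result` (accepted calls with
#'   `total_count`) or a table with the junction key columns and a `count`
#'   column (`total_count`, `count` or `n_unique`).
#' @param truth Truth table.
#' @return A `quant_report` list: `per_junction` (`data.table` with `key`,
#'   `called`, `true`, `absolute_error`, `relative_error`),
#'   `total_absolute_error`, and `summary` (percentiles of the absolute
#'   error).
#' @export
quantification_error <- function(calls, truth) {
  if (inherits(calls, "junction_filter_result")) calls <- calls$calls
  dt <- as.data.table(calls)
  if ("status" %in% names(dt)) dt <- dt[status == "ACCEPTED"]
  cnt_col <- intersect(c("total_count", "count", "n_unique"), names(dt))[1L]
  if (is.na(cnt_col)) stop("no count column found in calls")
  cl <- data.table(jkey = junction_key_str(dt), called = dt[[cnt_col]])
  truth <- as.data.table(truth)
  tr <- truth[class == "expressed",
              .(jkey = junction_key_str(.SD), true = true_count)]
  per <- merge(cl, tr, by = "jkey", all = TRUE)
  per[is.na(called), called := 0L]
  per[is.na(true), true := 0L]
  per[, absolute_error := abs(called - true)]
  per[, relative_error := fifelse(true > 0L, absolute_error / true, NA_real_)]
  qs <- quantile(per$absolute_error, c(0, .25, .5, .75, .9, 1), names = TRUE)
  structure(list(per_junction = per[],
                 total_absolute_error = sum(per$absolute_error),
                 summary = qs),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("quant_report: %d junctions, total absolute error %d\n",
              nrow(x$per_junction), x$total_absolute_error))
  print(x$summary)
  invisible(x)
}

#' Pseudo detection metrics without ground truth
#'
#' In real data the expression status of a junction is unknown; a junction
#' is designated pseudo-true when its median read count across all methods
#' is greater than zero, and each method's called set (count > 0) is scored
#' against that consensus set.
#'
#' @param counts Numeric matrix of read counts, junctions in rows, methods
#'   (>= 2) in columns.
#' @return `data.table`, one row per method: `method`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv`, `f1`.
#' @export
pseudo_metrics <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("pseudo metrics require counts from at least two methods")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("method%d", seq_len(ncol(counts)))
  med <- apply(counts, 1L, median)
  pseudo_true <- med > 0
  rbindlist(lapply(colnames(counts), function(m) {
    called <- counts[, m] > 0
    rep_ <- detection_report(tp = sum(called & pseudo_true),
                             fp = sum(called & !pseudo_true),
                             fn = sum(!called & pseudo_true))
    data.table(method = m, tp = rep_$tp, fp = rep_$fp, fn = rep_$fn,
               sensitivity = rep_$sensitivity, ppv = rep_$ppv, f1 = rep_$f1)
  }))
}
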