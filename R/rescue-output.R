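#' Rescue multimapped reads with a unique surviving location
#'
#' After filtering, a multimapped read whose candidate alignment locations
#' have all but one been eliminated is allocated to the surviving location:
#' it contributes +1 to every junction spanned by that alignment. An
#' alignment location "survives" iff it spans at least one junction and all
#' of its junctions are ACCEPTED. A gapless (contiguous) alignment of a
#' multiread blocks rescue altogether — the read's location remains
#' ambiguous. Reads with zero or two or more surviving locations contribute
#' nothing; each rescued read is allocated exactly once.
#'
#' @param x A `spliced_alignments` object (its multiread alignment index is
#'   used).
#' @param decisions Junction decision table from [apply_filter()].
#' @param allow_unknown If `FALSE` (default), a multiread junction absent
#'   from `decisions` is a contract violation; `TRUE` treats such junctions
#'   as not accepted (used by the pipeline driver, where junctions with no
#'   unique evidence are undetectable and carry no decision).
#' @return A `data.table` with the junction key columns and `rescued_count`
#'   increments; attribute `rescued_reads` holds the rescued read ids.
#' @export
rescue_multireads <- function(x, decisions, allow_unknown = FALSE) {
  stopifnot(inherits(x, "spliced_alignments"))
  keyc <- c("reference", "intron_start", "intron_end", "strand")
  empty <- data.table(reference = character(0), intron_start = integer(0),
                      intron_end = integer(0), strand = character(0),
                      rescued_count = integer(0))
  setattr(empty, "rescued_reads", character(0))
  rec <- x$records[uniq == FALSE]
  if (nrow(rec) == 0L) return(empty)

  acc <- as.data.table(decisions)
  rec <- copy(rec)
  rec[, accepted := FALSE]
  known <- acc[rec, on = keyc, which = TRUE]
  if (!allow_unknown && anyNA(known))
    stop("multiread junction without a decision")
  has_dec <- !is.na(known)
  rec[has_dec, accepted := acc$status[known[has_dec]] == "ACCEPTED"]

  per_aln <- rec[, .(read_id = read_id[1L], n_j = .N,
                     all_acc = all(accepted)), by = aln_id]
  per_aln[, survives := n_j >= 1L & all_acc]
  gapless <- x$alignments[n_junctions == 0L, .(read_id)]
  blocked <- unique(gapless$read_id)
  per_read <- per_aln[, .(n_surv = sum(survives)), by = read_id]
  rescued <- per_read[n_surv == 1L & !read_id %chin% blocked, read_id]
  if (length(rescued) == 0L) return(empty)

  surv_aln <- per_aln[survives == TRUE & read_id %chin% rescued, aln_id]
  inc <- rec[aln_id %in% surv_aln,
             .(rescued_count = .N), by = keyc]
  setattr(inc, "rescued_reads", sort(rescued))
  inc[]
}

#' Write junction calls to TSV or BED
#'
#' TSV columns: `reference`, `intron_start` (0-based), `intron_end`
#' (half-open), `strand`, `unique_count`, `rescued_count`, `total_count`,
#' `posterior_fp`, `status`, sorted by (reference, intron_start,
#' intron_end). BED6: the intron interval with `name = JUNC%08d` and
#' `score = min(total_count, 1000)`.
#'
#' @param calls Junction call table (e.g. `$calls` of a
#'   [filter_junctions()] result).
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @param include_discarded Write discarded junctions too (default `FALSE`:
#'   accepted junctions only).
#' @return Invisibly, the path.
#' @export
write_junction_calls <- function(calls, path, format = c("tsv", "bed"),
                                 include_discarded = FALSE) {
  format <- match.arg(format)
  dt <- as.data.table(calls)
  if (!include_discarded) dt <- dt[status == "ACCEPTED"]
  setorder(dt, reference, intron_start, intron_end)
  if (format == "tsv") {
    cols <- c("reference", "intron_start", "intron_end", "strand",
              "unique_count", "rescued_count", "total_count",
              "posterior_fp", "status")
    write.table(dt[, cols, with = FALSE], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  } else {
    bed <- dt[, .(chrom = reference, chromStart = intron_start,
                  chromEnd = intron_end,
                  name = sprintf("JUNC%08d", seq_len(.N)),
                  score = pmin(total_count, 1000L),
                  strand = fifelse(strand %chin% c("+", "-"), strand, "."))]
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Filter splice junctions from a spliced alignment file
#'
#' End-to-end driver: parse spliced alignments, aggregate per-junction
#' overhang evidence, label patent anomalies as potential false positives,
#' fit the L1-logistic filter model, discard junctions by posterior, and
#' rescue multimapped reads left with a unique surviving location.
#'
#' Degenerate inputs: when no junction is labelled as a potential false
#' positive, no model can be fitted and every junction is accepted with
#' posterior 0 (with a prominent warning); when no junction is presumed OK,
#' the run aborts — the semi-supervised scheme is undefined with a single
#' class.
#'
#' @param file Path to a SAM/BAM file, or a pre-parsed
#'   `spliced_alignments` object.
#' @param min_mapq MAPQ fallback threshold for uniqueness (default 50).
#' @param o_min,o_max Overhang support bounds; `o_max = NULL` (auto) uses
#'   `floor(L/2)` with `L` the modal read length of unique gapped records.
#' @param alpha Labelling probability threshold (default 0.99).
#' @param pseudocount Feature pseudocount (default 0.5).
#' @param l1_c Inverse L1 regularization strength (default 1.0).
#' @param threshold Posterior cut for discarding (default 0.5, strict).
#' @param seed Integer seed (default 17).
#' @param hard_labels Discard labelled potential FPs unconditionally.
#' @param max_indel_distance See [read_spliced_alignments()].
#' @return A `junction_filter_result` list: `calls` (per-junction table with
#'   `unique_count`, `rescued_count`, `total_count`, `posterior_fp`,
#'   `status`, `label`), `decisions`, `model`, `evidence`, `support`,
#'   `params`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_true_junctions = 40, n_fp_junctions = 8,
#'                          mean_reads_per_junction = 10, seed = 7)
#' sam <- tempfile(fileext = ".sam")
#' sim <- simulate_spliced_dataset(cfg, sam)
#' res <- filter_junctions(sam)
#' res$calls[status == "ACCEPTED", .N]
#' }
#' @export
filter_junctions <- function(file, min_mapq = 50L, o_min = 1L, o_max = NULL,
                             alpha = 0.99, pseudocount = 0.5, l1_c = 1.0,
                             threshold = 0.5, seed = 17L,
                             hard_labels = FALSE, max_indel_distance = 3L) {
  aln <- if (inherits(file, "spliced_alignments")) file
         else read_spliced_alignments(file, min_mapq = min_mapq,
                                      max_indel_distance = max_indel_distance)
  ev <- aggregate_evidence(aln)
  keyc <- c("reference", "intron_start", "intron_end", "strand")
  if (nrow(ev) == 0L) {
    calls <- data.table(reference = character(0), intron_start = integer(0),
                        intron_end = integer(0), strand = character(0),
                        unique_count = integer(0), rescued_count = integer(0),
                        total_count = integer(0), posterior_fp = numeric(0),
                        status = character(0), label = character(0))
    return(structure(list(calls = calls, decisions = calls, model = NULL,
                          evidence = ev, support = NULL, params = list()),
                     class = "junction_filter_result"))
  }
  if (is.null(o_max)) {
    rl <- aln$records[uniq == TRUE, read_length]
    tab <- table(rl)
    modal <- max(as.integer(names(tab)[tab == max(tab)]))
    o_max <- modal %/% 2L
  }
  support <- overhang_support(o_max = o_max, o_min = o_min)

  labelled <- label_junctions(ev, support, alpha = alpha)
  X <- junction_features(ev, support, pseudocount = pseudocount)
  n_fp <- sum(labelled$label == "POTENTIAL_FP")
  if (n_fp == nrow(labelled))
    stop("no junction is PRESUMED_OK: data quality too low to fit the filter")
  model <- NULL
  if (n_fp == 0L) {
    warning("no junction labelled POTENTIAL_FP: no model fitted, ",
            "all junctions accepted with posterior 0")
  } else {
    model <- fit_filter_model(X, labelled$label, l1_c = l1_c, seed = seed)
  }
  decisions <- apply_filter(labelled, X, model, threshold = threshold,
                            hard_labels = hard_labels)
  resc <- rescue_multireads(aln, decisions, allow_unknown = TRUE)

  calls <- copy(decisions)
  setnames(calls, "n_unique", "unique_count")
  calls <- merge(calls, resc, by = keyc, all.x = TRUE)
  calls[is.na(rescued_count), rescued_count := 0L]
  calls[status != "ACCEPTED", rescued_count := 0L]
  calls[, total_count := unique_count + rescued_count]
  setorder(calls, reference, intron_start, intron_end, strand)
  setcolorder(calls, c(keyc, "unique_count", "rescued_count", "total_count",
                       "posterior_fp", "status", "label"))

  structure(list(calls = calls, decisions = decisions, model = model,
                 evidence = ev, support = support,
                 params = list(min_mapq = min_mapq, alpha = alpha,
                               pseudocount = pseudocount, l1_c = l1_c,
                               threshold = threshold, seed = seed,
                               hard_labels = hard_labels),
                 rescued_reads = attr(resc, "rescued_reads")),
            class = "junction_filter_result")
}

#' @export
print.junction_filter_result <- function(x, ...) {
  n <- nrow(x$calls)
  n_acc <- sum(x$calls$status == "ACCEPTED")
  n_fp <- sum(x$calls$label == "POTENTIAL_FP")
  cat(sprintf(paste0(
    "junction_filter_result: %d detectable junctions, %d labelled potential FP\n",
    "  accepted: %d   discarded: %d   rescued reads: %d\n"),
    n, n_fp, n_acc, n - n_acc, length(x$rescued_reads)))
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}
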