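#' Discrete-uniform overhang support
#'
#' Under random cDNA fragmentation, the overhang of a read across a junction
#' (the shorter of its two aligned arms) is equally likely to take any
#' admissible length, i.e. follows a discrete uniform distribution on
#' `{o_min, ..., o_max}`. `o_max` defaults to `floor(read_length/2)`, the
#' largest value the shorter arm can take; `o_min` defaults to 1 (some
#' aligners enforce a larger minimum anchor, in which case raise it).
#'
#' @param o_max Maximum admissible overhang (bp).
#' @param o_min Minimum admissible overhang (bp), default 1.
#' @return An `overhang_support` list with elements `o_min`, `o_max`.
#' @examples
#' overhang_support(o_max = 25)
#' @export
overhang_support <- function(o_max, o_min = 1L) {
  o_max <- as.integer(o_max); o_min <- as.integer(o_min)
  if (!(o_min >= 1L && o_min <= o_max))
    stop("invalid overhang support: need 1 <= o_min <= o_max")
  structure(list(o_min = o_min, o_max = o_max), class = "overhang_support")
}

#' Trim an overhang at the first mismatch position
#'
#' Systematic mismatches close to the splice site are the hallmark of an
#' artefactual gapped alignment; they are penalised by truncating the
#' overhang at the first mismatching base (counted from the splice site) and
#' ignoring any matches beyond it. A mismatch at position 1 leaves no
#' matching overhang (trimmed length 0).
#'
#' @param raw_overhang Integer vector of raw overhang lengths (bp).
#' @param mismatch_positions For a single overhang, an integer vector of
#'   sorted 1-based mismatch distances from the splice site within the
#'   overhang arm; or a list of such vectors parallel to `raw_overhang`.
#' @return Integer vector of trimmed overhang lengths: `raw_overhang` where
#'   no mismatch is present, `min(mismatch_positions) - 1` otherwise.
#' @examples
#' trim_overhang(20, integer(0))  # 20
#' trim_overhang(20, c(5, 12))    # 4
#' trim_overhang(20, 1)           # 0
#' @export
trim_overhang <- function(raw_overhang, mismatch_positions) {
  if (!is.list(mismatch_positions)) {
    stopifnot(length(raw_overhang) == 1L)
    mismatch_positions <- list(as.integer(mismatch_positions))
  }
  stopifnot(length(raw_overhang) == length(mismatch_positions))
  firstmm <- vapply(mismatch_positions,
                    function(p) if (length(p)) min(p) else NA_integer_,
                    integer(1))
  bad <- !is.na(firstmm) & (firstmm < 1L | firstmm > raw_overhang)
  if (any(bad))
    stop("mismatch position outside the overhang arm")
  as.integer(fifelse(is.na(firstmm), as.integer(raw_overhang), firstmm - 1L))
}

#' Probability of exceeding an overhang position under uniformity
#'
#' For a junction spanned by `n` uniquely mapping reads whose overhangs are
#' discrete-uniform on the support, the probability that at least one read
#' shows an overhang greater than `p_star` is `1 - F(p_star)^n`, with
#' `F(p) = (p - o_min + 1) / (o_max - o_min + 1)` the uniform CDF. When no
#' read exceeds the first mismatching position `p_star` despite this
#' probability being very high, the uniformity assumption is patently
#' violated and the junction is a candidate false positive.
#'
#' @param p_star Position(s) within the support (bp); vectorised.
#' @param n Number of spanning unique reads (>= 1); vectorised.
#' @param support An [overhang_support()].
#' @return Numeric vector of probabilities in `[0, 1]`; monotone increasing
#'   in `n`, decreasing in `p_star`, and exactly 0 at `p_star = o_max`.
#' @examples
#' prob_exceed(24, 1, overhang_support(25))  # 1/25
#' @export
prob_exceed <- function(p_star, n, support) {
  stopifnot(inherits(support, "overhang_support"))
  if (any(p_star < support$o_min | p_star > support$o_max))
    stop("p_star outside the overhang support")
  if (any(n < 1L)) stop("n must be >= 1")
  Fp <- (p_star - support$o_min + 1) / (support$o_max - support$o_min + 1)
  1 - Fp^n
}

#' Label junctions as potential false positives
#'
#' Implements the semi-supervised labelling rule. A junction is labelled
#' `POTENTIAL_FP` with reason `single-mismatch-rule` iff (i) its unique reads
#' carry mismatches at exactly one distinct position `p*` within the overhang
#' arm, (ii) no raw overhang is greater than `p*`, and (iii)
#' `prob_exceed(p*, n_unique, support) > alpha`; or with reason
#' `no-matching-overhang` iff every trimmed overhang is 0. All remaining
#' junctions are `PRESUMED_OK` — the detectable majority, assumed to be
#' mostly proper mappings.
#'
#' @param evidence A `junction_evidence` table from [aggregate_evidence()].
#' @param support An [overhang_support()]; per-junction supports are capped
#'   at `floor(max_read_length/2)` when a junction is spanned only by reads
#'   shorter than the modal length.
#' @param alpha Probability threshold for the labelling rule (default 0.99).
#' @return The evidence table with columns `label`
#'   (`"POTENTIAL_FP"`/`"PRESUMED_OK"`) and `reason`
#'   (`"single-mismatch-rule"`, `"no-matching-overhang"` or `"default"`)
#'   appended.
#' @export
label_junctions <- function(evidence, support, alpha = 0.99) {
  stopifnot(inherits(evidence, "junction_evidence"),
            inherits(support, "overhang_support"),
            alpha > 0, alpha < 1)
  ev <- copy(evidence)
  if (nrow(ev) == 0L) {
    ev[, `:=`(label = character(0), reason = character(0))]
    return(ev[])
  }
  distinct_mm <- vapply(ev$mismatch_positions,
                        function(p) length(unique(p)), integer(1))
  p_star <- vapply(ev$mismatch_positions,
                   function(p) if (length(p)) unique(p)[1L] else NA_integer_,
                   integer(1))
  max_raw <- vapply(ev$raw_overhangs, max, integer(1))
  all_trim0 <- vapply(ev$trimmed_overhangs, function(tr) all(tr == 0L),
                      logical(1))
  # per-junction support: junctions seen only in shorter reads get their own
  # floor(L/2) cap
  o_max_j <- pmin(support$o_max, ev$max_read_length %/% 2L)
  pe <- rep(NA_real_, nrow(ev))
  cand <- which(distinct_mm == 1L & !is.na(p_star) & max_raw <= p_star &
                  p_star >= support$o_min & p_star <= o_max_j)
  if (length(cand)) {
    pe[cand] <- vapply(cand, function(i)
      prob_exceed(p_star[i], ev$n_unique[i],
                  overhang_support(o_max_j[i], support$o_min)),
      numeric(1))
  }
  single_rule <- !is.na(pe) & pe > alpha
  ev[, reason := "default"]
  ev[single_rule, reason := "single-mismatch-rule"]
  ev[all_trim0 & !single_rule, reason := "no-matching-overhang"]
  ev[, label := fifelse(reason == "default", "PRESUMED_OK", "POTENTIAL_FP")]
  ev[]
}

#' Observed exceedance counts
#'
#' `C_p` is the number of reads whose trimmed overhang is strictly greater
#' than position `p`, for `p = o_min, ..., o_max - 1`. It is non-increasing
#' in `p`.
#'
#' @param trimmed_overhangs Integer vector (multiset) of trimmed overhangs.
#' @param support An [overhang_support()].
#' @return Named integer vector `C_p` indexed by `p = o_min ... o_max - 1`.
#' @export
exceedance_counts <- function(trimmed_overhangs, support) {
  stopifnot(inherits(support, "overhang_support"))
  if (length(trimmed_overhangs) &&
      any(trimmed_overhangs < 0L | trimmed_overhangs > support$o_max))
    stop("trimmed overhang outside [0, o_max]")
  p <- seq.int(support$o_min, support$o_max - 1L)
  cp <- vapply(p, function(pp) sum(trimmed_overhangs > pp), integer(1))
  names(cp) <- p
  cp
}

#' Expected exceedance counts under the uniform model
#'
#' `E_p = n * (o_max - p) / (o_max - o_min + 1)` — the expected number of
#' reads, among `n` uniform draws, with overhang greater than `p`.
#'
#' @param n Number of reads.
#' @param p Position(s), must lie in `[o_min, o_max - 1]`.
#' @param support An [overhang_support()].
#' @return Numeric vector of expected counts (strictly positive).
#' @export
expected_exceedance <- function(n, p, support) {
  stopifnot(inherits(support, "overhang_support"))
  if (any(p < support$o_min | p > support$o_max - 1L))
    stop("p outside [o_min, o_max - 1]")
  n * (support$o_max - p) / (support$o_max - support$o_min + 1)
}

#' Per-junction overhang-deviation feature vectors
#'
#' For each junction, the feature at position `p` is the log2 deviation of
#' the observed exceedance count from its uniform expectation,
#' `x_p = log2((C_p + pc) / (E_p + pc))`, for `p = o_min ... o_max - 1`
#' (`p = o_max` is excluded: `E_p` vanishes there). The symmetric pseudocount
#' `pc` keeps every feature finite and leaves `x_p = 0` whenever
#' `C_p = E_p`. Junctions conforming to the uniform model have features near
#' 0; artefactual junctions with systematically short, mismatch-trimmed
#' overhangs show strongly negative features at most positions.
#'
#' @param evidence A `junction_evidence` table.
#' @param support An [overhang_support()]; the feature grid is common to all
#'   junctions.
#' @param pseudocount Positive pseudocount (default 0.5).
#' @return Numeric matrix, one row per junction (same order as `evidence`),
#'   columns named by position `o_min ... o_max - 1`.
#' @export
junction_features <- function(evidence, support, pseudocount = 0.5) {
  stopifnot(inherits(evidence, "junction_evidence"),
            inherits(support, "overhang_support"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  p <- seq.int(support$o_min, support$o_max - 1L)
  span <- support$o_max - support$o_min + 1L
  nj <- nrow(evidence)
  X <- matrix(0, nrow = nj, ncol = length(p),
              dimnames = list(NULL, as.character(p)))
  if (nj == 0L) return(X)
  # tabulate trimmed overhangs once, then reverse-cumulate for C_p
  for (i in seq_len(nj)) {
    tr <- evidence$trimmed_overhangs[[i]]
    tab <- tabulate(tr[tr >= 1L], nbins = support$o_max)
    cp <- rev(cumsum(rev(tab)))            # cp[k] = #overhangs >= k
    Cp <- c(cp[-1L], 0L)[p]                # #overhangs > p
    Ep <- evidence$n_unique[i] * (support$o_max - p) / span
    X[i, ] <- log2((Cp + pseudocount) / (Ep + pseudocount))
  }
  if (!all(is.finite(X))) stop("non-finite feature value")
  X
}
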