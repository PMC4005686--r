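#' Read spliced (N-gapped) alignments from a SAM or BAM file
#'
#' Parses a SAM/BAM file and extracts every alignment whose CIGAR contains an
#' N (skipped reference) operation, i.e. a spliced mapping across one or more
#' introns. Each spanned junction yields one record with the read-consuming
#' arm lengths flanking the gap, the overhang (shorter arm), and the 1-based
#' distances from the splice site of any reference mismatches falling in the
#' overhang arm (recovered from the MD tag).
#'
#' A read is considered uniquely mapping iff its NH tag equals 1; when NH is
#' absent, MAPQ >= `min_mapq` is used as a fallback (TopHat2 reports unique
#' hits with MAPQ 50). Secondary/supplementary alignments never contribute to
#' unique evidence; they are retained, like all alignments of multimapped
#' reads, for multiread rescue bookkeeping. Junction strand is taken from the
#' XS tag when present, `"*"` (unknown) otherwise. Intron coordinates are
#' 0-based half-open.
#'
#' @param file Path to a SAM or BAM file. SAM input is converted on the fly
#'   with [Rsamtools::asBam()].
#' @param min_mapq MAPQ threshold standing in for NH = 1 when the NH tag is
#'   missing (default 50).
#' @param max_indel_distance Alignments carrying an insertion or deletion
#'   within this many aligned bases of a splice site are flagged and excluded
#'   from junction evidence (default 3); 0 disables the exclusion.
#' @return An object of class `spliced_alignments`: a list with
#'   \describe{
#'     \item{records}{`data.table`, one row per (alignment, junction): read
#'       and junction identity, arm lengths, `overhang`, `mm_dist` (list
#'       column of 1-based mismatch distances from the splice site within the
#'       overhang arm), multiplicity and flags.}
#'     \item{alignments}{`data.table`, one row per alignment line of a
#'       multimapped read (gapped or not), used for rescue.}
#'     \item{n_skipped}{number of malformed records skipped.}
#'   }
#' @seealso [aggregate_evidence()], [filter_junctions()]
#' @export
read_spliced_alignments <- function(file, min_mapq = 50L, max_indel_distance = 3L) {
  stopifnot(length(file) == 1L, file.exists(file))
  bam <- if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    Rsamtools::asBam(file, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else file

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("NH", "NM", "MD", "XS"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]

  n <- length(res$qname)
  tagv <- function(tg, fill) {
    v <- res$tag[[tg]]
    if (is.null(v)) rep(fill, n) else v
  }
  dt <- data.table(
    aln_id = seq_len(n),
    read_id = res$qname,
    flag = res$flag,
    reference = as.character(res$rname),
    pos = res$pos,
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    NH = as.integer(tagv("NH", NA_integer_)),
    NM = as.integer(tagv("NM", NA_integer_)),
    MD = as.character(tagv("MD", NA_character_)),
    XS = as.character(tagv("XS", NA_character_)))
  if (n == 0L) return(empty_spliced_alignments())

  dt[, secondary := bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L]
  dt[, n_hits := fifelse(!is.na(NH), NH,
                         fifelse(!is.na(mapq) & mapq >= min_mapq, 1L, 2L))]
  dt[, uniq := n_hits == 1L & !secondary]
  dt[, strand := fifelse(!is.na(XS) & XS %chin% c("+", "-"), XS, "*")]
  dt[, is_gapped := grepl("N", cigar, fixed = TRUE)]

  # malformed CIGAR / MD: per-record skip, counted
  ok_cigar <- grepl("^([0-9]+[MIDNSHP=X])+$", dt$cigar)
  ok_md <- is.na(dt$MD) |
    grepl("^[0-9]+((\\^[A-Za-z]+|[A-Za-z])[0-9]+)*$", dt$MD)
  bad <- !(ok_cigar & ok_md)
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d malformed record(s), e.g. read '%s'",
                    n_skipped, dt$read_id[which(bad)[1L]]))
    dt <- dt[!bad]
  }
  if (nrow(dt) == 0L) return(empty_spliced_alignments(n_skipped))

  dt[, read_length := GenomicAlignments::cigarWidthAlongQuerySpace(
        cigar, after.soft.clipping = FALSE)]

  g <- dt[is_gapped == TRUE]
  records <- if (nrow(g)) parse_gapped(g, max_indel_distance) else empty_records()

  multi_reads <- unique(dt[uniq == FALSE, read_id])
  alignments <- dt[read_id %chin% multi_reads,
                   .(read_id, aln_id, is_gapped, secondary, n_hits)]
  if (nrow(alignments)) {
    nj <- records[, .(n_junctions = .N), by = aln_id]
    alignments <- nj[alignments, on = "aln_id"]
    set(alignments, which(is.na(alignments$n_junctions)), "n_junctions", 0L)
  } else {
    alignments[, n_junctions := integer(0)]
  }

  structure(list(records = records, alignments = alignments,
                 n_skipped = n_skipped),
            class = "spliced_alignments")
}

empty_records <- function() {
  data.table(aln_id = integer(0), read_id = character(0),
             reference = character(0), strand = character(0),
             intron_start = integer(0), intron_end = integer(0),
             junc_idx = integer(0), left_arm = integer(0),
             right_arm = integer(0), overhang = integer(0),
             mm_dist = list(), n_hits = integer(0), uniq = logical(0),
             secondary = logical(0), read_length = integer(0),
             mm_unknown = logical(0), indel_near_ss = logical(0))
}

empty_spliced_alignments <- function(n_skipped = 0L) {
  structure(list(records = empty_records(),
                 alignments = data.table(read_id = character(0),
                                         aln_id = integer(0),
                                         is_gapped = logical(0),
                                         secondary = logical(0),
                                         n_hits = integer(0),
                                         n_junctions = integer(0)),
                 n_skipped = n_skipped),
            class = "spliced_alignments")
}

#' @export
print.spliced_alignments <- function(x, ...) {
  nj <- if (nrow(x$records))
    nrow(unique(x$records[, .(reference, intron_start, intron_end, strand)]))
  else 0L
  cat(sprintf(paste0("spliced_alignments: %d junction-spanning records ",
                     "(%d unique), %d junctions, %d multiread alignment(s)\n"),
              nrow(x$records), sum(x$records$uniq), nj, nrow(x$alignments)))
  invisible(x)
}

# CIGAR/MD arithmetic over gapped records. One row per CIGAR op keeps the
# computation vectorised; mismatches (sparse) are the only per-base quantity
# ever materialised. Segment s = stretch of the read between gaps s and s+1
# (0-based); junction j separates segments j-1 and j.
parse_gapped <- function(g, max_indel_distance = 3L) {
  ops <- GenomicAlignments::explodeCigarOps(g$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(g$cigar)
  n_op <- lengths(ops)
  L <- data.table(aln_id = rep(g$aln_id, n_op),
                  op = unlist(ops), len = unlist(lens))
  L[op %chin% c("=", "X"), op := "M"]
  L[, seg := cumsum(op == "N"), by = aln_id]
  L[, ref_c := len * (op %chin% c("M", "D", "N"))]
  L[, md_c := len * (op %chin% c("M", "D"))]
  L[, arm_c := len * (op %chin% c("M", "I"))]
  L[, ref_before := cumsum(ref_c) - ref_c, by = aln_id]
  L[, md_before := cumsum(md_c) - md_c, by = aln_id]
  L[, arm_before := cumsum(arm_c) - arm_c, by = .(aln_id, seg)]

  arms <- L[op %chin% c("M", "I"), .(arm = sum(len)), by = .(aln_id, seg)]
  ngap <- L[op == "N", .(n_gaps = .N), by = aln_id]

  meta <- g[, .(aln_id, read_id, reference, pos, strand, n_hits, uniq,
                secondary, read_length, NM, MD)]
  J <- L[op == "N", .(aln_id, junc_idx = seg, gap_len = len, ref_before)]
  J <- meta[J, on = "aln_id"]
  J[, intron_start := (pos - 1L) + ref_before]
  J[, intron_end := intron_start + gap_len]
  J <- merge(J, arms[, .(aln_id, junc_idx = seg + 1L, left_arm = arm)],
             by = c("aln_id", "junc_idx"), all.x = TRUE)
  J <- merge(J, arms[, .(aln_id, junc_idx = seg, right_arm = arm)],
             by = c("aln_id", "junc_idx"), all.x = TRUE)

  bad_aln <- unique(J[is.na(left_arm) | is.na(right_arm) |
                        left_arm < 1L | right_arm < 1L, aln_id])
  if (length(bad_aln)) {
    warning(sprintf("skipped %d gapped record(s) with an empty junction flank",
                    length(bad_aln)))
    J <- J[!aln_id %in% bad_aln]
  }
  if (nrow(J) == 0L) return(empty_records())

  J[, overhang := pmin(left_arm, right_arm)]
  J[, ovh_side := fifelse(left_arm <= right_arm, "L", "R")]  # tie -> left arm
  J[, ovh_seg := fifelse(ovh_side == "L", junc_idx - 1L, junc_idx)]

  # alignments with an indel within max_indel_distance aligned bases of a
  # splice site are excluded from evidence downstream
  indel_aln <- integer(0)
  if (max_indel_distance > 0L && L[op %chin% c("I", "D"), .N] > 0L) {
    idl <- L[op %chin% c("I", "D")]
    idl <- merge(idl, arms, by = c("aln_id", "seg"), all.x = TRUE)
    idl <- merge(idl, ngap, by = "aln_id", all.x = TRUE)
    idl[is.na(arm), arm := 0L]
    idl[, arm_after := arm - arm_before - arm_c]
    near <- idl[(seg > 0L & arm_before < max_indel_distance) |
                  (seg < n_gaps & arm_after < max_indel_distance)]
    indel_aln <- unique(near$aln_id)
  }
  J[, indel_near_ss := aln_id %in% indel_aln]
  J[, mm_unknown := is.na(MD) & !is.na(NM) & NM > 0L]
  if (any(J$mm_unknown)) {
    warning(sprintf(
      "%d gapped record(s) have NM>0 but no MD tag: mismatch positions unknown",
      length(unique(J[mm_unknown == TRUE, aln_id]))))
  }

  # mismatch distances from the splice site within the overhang arm
  mm <- md_mismatch_table(meta)
  J[, mm_dist := rep(list(integer(0)), .N)]
  if (nrow(mm)) {
    Lm <- L[op == "M",
            .(aln_id, seg, md_lo = md_before, md_hi = md_before + len,
              op_md_start = md_before, op_arm_before = arm_before)]
    hit <- Lm[mm, on = .(aln_id, md_lo < mdpos, md_hi >= mdpos), nomatch = NULL]
    # after the join md_lo/md_hi hold the i-side mdpos value
    hit <- hit[, .(aln_id, seg,
                   arm_pos = op_arm_before + (md_lo - op_md_start))]
    jk <- J[, .(aln_id, junc_idx, ovh_seg, ovh_side, overhang)]
    pair <- hit[jk, on = c(aln_id = "aln_id", seg = "ovh_seg"),
                allow.cartesian = TRUE, nomatch = NULL]
    pair[, dist := fifelse(ovh_side == "L", overhang - arm_pos + 1L, arm_pos)]
    mm_by_j <- pair[, .(mm = list(sort(dist))), by = .(aln_id, junc_idx)]
    idx <- J[mm_by_j, on = c("aln_id", "junc_idx"), which = TRUE]
    set(J, idx, "mm_dist", mm_by_j$mm)
  }

  setorder(J, reference, intron_start, intron_end, aln_id)
  J[, .(aln_id, read_id, reference, strand, intron_start, intron_end,
        junc_idx, left_arm, right_arm, overhang, mm_dist, n_hits, uniq,
        secondary, read_length, mm_unknown, indel_near_ss)]
}

# one row per mismatch: aln_id, mdpos (1-based position along the M/D
# reference walk of the MD tag)
md_mismatch_table <- function(meta) {
  cand <- meta[!is.na(MD) & grepl("[0-9][A-Za-z]", MD)]
  if (nrow(cand) == 0L)
    return(data.table(aln_id = integer(0), mdpos = integer(0)))
  walks <- md_mismatch_walk(cand$MD)
  data.table(aln_id = rep(cand$aln_id, lengths(walks)),
             mdpos = as.integer(unlist(walks)))
}

# positions (1-based) of substitution mismatches along the M/D reference
# walk of each MD tag; deletions (^) advance the walk but are not mismatches
md_mismatch_walk <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))
  lapply(toks, function(tk) {
    pos <- 0L
    out <- integer(0)
    for (t in tk) {
      c1 <- substr(t, 1L, 1L)
      if (c1 == "^") {
        pos <- pos + nchar(t) - 1L
      } else if (c1 >= "0" && c1 <= "9") {
        pos <- pos + as.integer(t)
      } else {
        pos <- pos + 1L
        out <- c(out, pos)
      }
    }
    out
  })
}

#' Aggregate junction-spanning records into per-junction evidence
#'
#' Collapses the per-(alignment, junction) records of
#' [read_spliced_alignments()] into one row per junction: the multiset of
#' unique-read overhangs (raw and trimmed at the first mismatch position),
#' the tally of mismatch distances from the splice site, and the identities
#' of multimapped reads spanning the junction. Only uniquely mapping reads
#' (NH = 1, primary) contribute overhang evidence and `n_unique`; alignments
#' flagged for an indel near the splice site are excluded from evidence.
#'
#' @param x A `spliced_alignments` object.
#' @return A `data.table` of class `junction_evidence`, one row per junction
#'   with at least one unique spanning read, sorted by coordinate: columns
#'   `reference`, `intron_start`, `intron_end`, `strand`, `n_unique`,
#'   `raw_overhangs` (list), `trimmed_overhangs` (list),
#'   `mismatch_positions` (list), `multiread_ids` (list),
#'   `max_read_length`.
#' @export
aggregate_evidence <- function(x) {
  stopifnot(inherits(x, "spliced_alignments"))
  rec <- x$records
  keyc <- c("reference", "intron_start", "intron_end", "strand")
  u <- rec[uniq == TRUE & indel_near_ss == FALSE]
  if (nrow(u)) {
    u[, trimmed := trim_overhang(overhang, mm_dist)]
    ev <- u[, .(n_unique = .N,
                raw_overhangs = list(overhang),
                trimmed_overhangs = list(trimmed),
                mismatch_positions = list(sort(as.integer(unlist(mm_dist)))),
                max_read_length = max(read_length)),
            by = keyc]
  } else {
    ev <- data.table(reference = character(0), intron_start = integer(0),
                     intron_end = integer(0), strand = character(0),
                     n_unique = integer(0), raw_overhangs = list(),
                     trimmed_overhangs = list(), mismatch_positions = list(),
                     max_read_length = integer(0))
  }
  m <- rec[uniq == FALSE]
  if (nrow(m)) {
    mi <- m[, .(multiread_ids = list(sort(unique(read_id)))), by = keyc]
    ev <- merge(ev, mi, by = keyc, all.x = TRUE)
    null_idx <- which(vapply(ev$multiread_ids, is.null, logical(1)))
    if (length(null_idx))
      set(ev, null_idx, "multiread_ids", rep(list(character(0)), length(null_idx)))
  } else {
    ev[, multiread_ids := rep(list(character(0)), .N)]
  }
  setorderv(ev, keyc)
  setattr(ev, "class", c("junction_evidence", class(ev)))
  ev[]
}
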