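#' Configuration for the synthetic spliced-alignment simulator
#'
#' The generator emulates the statistical structure the filtering algorithm
#' assumes: true junctions receive reads whose overhangs are discrete-uniform
#' over all admissible lengths `{1..floor(L/2)}` with a low i.i.d. background
#' mismatch rate per base; artefactual junctions receive reads with
#' systematically short overhangs (uniform on `{1..fp_max_overhang}`) and a
#' recurrent mismatch at a fixed distance from the splice site. A configured
#' fraction of true-junction reads is additionally emitted as multireads
#' (NH = 2) with a decoy secondary alignment across an artefactual junction,
#' exercising the rescue step.
#'
#' Defaults are the package's reference evaluation scenario: 2000 true and
#' 200 artefactual junctions, 50 bp reads, 20 reads/junction on average,
#' artefactual overhangs capped at 4 bp with the recurrent mismatch at
#' position 4, 10\% multireads, background mismatch rate 0.001/base.
#'
#' @param n_true_junctions,n_fp_junctions Numbers of true and artefactual
#'   junctions.
#' @param read_length Read length L (bp); all reads equal length.
#' @param mean_reads_per_junction Mean of the per-junction read count,
#'   drawn as `1 + Poisson(mean - 1)` so every junction is detectable.
#' @param background_mismatch_rate Per-base substitution probability.
#' @param fp_max_overhang Maximum overhang of artefactual reads (bp); must
#'   be `< floor(read_length/2)`.
#' @param fp_mismatch_position 1-based distance from the splice site of the
#'   recurrent mismatch on artefactual reads (placed whenever the overhang
#'   reaches it), or `"random-per-junction"` to draw one position per
#'   junction in `1..fp_max_overhang`.
#' @param fraction_multireads Fraction of true-junction reads emitted as
#'   NH = 2 multireads with an artefactual decoy location.
#' @param seed Integer seed; the emitted SAM is byte-identical given the
#'   same configuration and seed.
#' @param n_references,reference_length Fictitious reference layout (no
#'   sequence is emitted; MD tags are synthesized directly).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_true_junctions = 2000L,
                              n_fp_junctions = 200L,
                              read_length = 50L,
                              mean_reads_per_junction = 20,
                              background_mismatch_rate = 0.001,
                              fp_max_overhang = 4L,
                              fp_mismatch_position = fp_max_overhang,
                              fraction_multireads = 0.10,
                              seed = 1L,
                              n_references = 5L,
                              reference_length = 1e6L) {
  cfg <- list(n_true_junctions = as.integer(n_true_junctions),
              n_fp_junctions = as.integer(n_fp_junctions),
              read_length = as.integer(read_length),
              mean_reads_per_junction = mean_reads_per_junction,
              background_mismatch_rate = background_mismatch_rate,
              fp_max_overhang = as.integer(fp_max_overhang),
              fp_mismatch_position = fp_mismatch_position,
              fraction_multireads = fraction_multireads,
              seed = as.integer(seed),
              n_references = as.integer(n_references),
              reference_length = as.integer(reference_length))
  with(cfg, {
    if (read_length < 4L) stop("read_length too small")
    if (fp_max_overhang >= read_length %/% 2L)
      stop("fp_max_overhang must be < floor(read_length/2)")
    if (background_mismatch_rate < 0 || background_mismatch_rate > 1 ||
        fraction_multireads < 0 || fraction_multireads > 1)
      stop("probabilities must lie in [0, 1]")
    if (mean_reads_per_junction < 1)
      stop("mean_reads_per_junction must be >= 1")
    if (!identical(fp_mismatch_position, "random-per-junction")) {
      p <- as.integer(fp_mismatch_position)
      if (is.na(p) || p < 1L || p > fp_max_overhang + 1L)
        stop("infeasible fp_mismatch_position (must be in 1..fp_max_overhang+1)")
    }
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a spliced-alignment dataset with known truth
#'
#' Emits a valid coordinate-sorted SAM file (header with fictitious
#' references; consistent CIGAR/MD/NM/NH/XS tags) and the matching truth
#' table. See [simulation_config()] for the generative model. Fully
#' reproducible: the same configuration yields a byte-identical SAM.
#'
#' @param config A [simulation_config()].
#' @param sam_path Output SAM path.
#' @param truth_path Optional path for a TSV truth table (columns
#'   `reference`, `intron_start`, `intron_end`, `strand`, `class`,
#'   `true_count`).
#' @return Invisibly, a list with `sam` (path), `truth` (`data.table`) and
#'   `config`.
#' @export
simulate_spliced_dataset <- function(config, sam_path, truth_path = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$read_length
  o_max <- L %/% 2L
  n_all <- cfg$n_true_junctions + cfg$n_fp_junctions
  if (n_all == 0L) stop("no junctions to simulate")

  # junction layout on fictitious contigs; dedupe improbable key collisions
  repeat {
    junc <- data.table(
      jid = seq_len(n_all),
      class = rep(c("expressed", "artefactual"),
                  c(cfg$n_true_junctions, cfg$n_fp_junctions)),
      reference = sprintf("contig%d", 1L + (seq_len(n_all) - 1L) %% cfg$n_references),
      intron_start = sample.int(cfg$reference_length - 40000L, n_all,
                                replace = TRUE) + 20000L,
      intron_len = sample(100:5000, n_all, replace = TRUE),
      strand = sample(c("+", "-"), n_all, replace = TRUE))
    if (!anyDuplicated(junc[, .(reference, intron_start)])) break
  }
  junc[, intron_end := intron_start + intron_len]
  junc[, n_reads := 1L + rpois(n_all, cfg$mean_reads_per_junction - 1)]
  junc[, fp_pos := NA_integer_]
  if (cfg$n_fp_junctions > 0L) {
    if (identical(cfg$fp_mismatch_position, "random-per-junction")) {
      junc[class == "artefactual",
           fp_pos := sample.int(cfg$fp_max_overhang, .N, replace = TRUE)]
    } else {
      junc[class == "artefactual", fp_pos := as.integer(cfg$fp_mismatch_position)]
    }
  }

  # one row per primary alignment
  reads <- junc[rep(seq_len(nrow(junc)), junc$n_reads),
                .(jid, class, reference, intron_start, intron_end,
                  intron_len, strand, fp_pos)]
  nr <- nrow(reads)
  reads[, qname := sprintf("read%06d", seq_len(nr))]
  reads[, o := fifelse(class == "expressed",
                       sample.int(o_max, nr, replace = TRUE),
                       sample.int(cfg$fp_max_overhang, nr, replace = TRUE))]
  reads[, short_left := runif(nr) < 0.5]
  reads[, left_arm := fifelse(short_left, o, L - o)]
  reads[, planted := fifelse(class == "artefactual" & !is.na(fp_pos) &
                               o >= fp_pos,
                             fifelse(short_left, left_arm - fp_pos + 1L,
                                     left_arm + fp_pos),
                             NA_integer_)]
  reads[, multi := FALSE]
  if (cfg$n_fp_junctions > 0L && cfg$fraction_multireads > 0 &&
      cfg$n_true_junctions > 0L) {
    reads[class == "expressed", multi := runif(.N) < cfg$fraction_multireads]
  }

  # decoy secondary alignments for multireads, across artefactual junctions
  sec <- reads[multi == TRUE]
  if (nrow(sec)) {
    fpj <- junc[class == "artefactual"]
    pick <- fpj[sample.int(nrow(fpj), nrow(sec), replace = TRUE)]
    sec <- data.table(jid = pick$jid, class = "decoy",
                      reference = pick$reference,
                      intron_start = pick$intron_start,
                      intron_end = pick$intron_end,
                      intron_len = pick$intron_len,
                      strand = pick$strand, fp_pos = pick$fp_pos,
                      qname = sec$qname,
                      o = sample.int(cfg$fp_max_overhang, nrow(sec),
                                     replace = TRUE),
                      short_left = runif(nrow(sec)) < 0.5)
    sec[, left_arm := fifelse(short_left, o, L - o)]
    sec[, planted := fifelse(!is.na(fp_pos) & o >= fp_pos,
                             fifelse(short_left, left_arm - fp_pos + 1L,
                                     left_arm + fp_pos),
                             NA_integer_)]
    sec[, multi := TRUE]
  }

  aln <- rbind(reads[, .(jid, reference, intron_start, intron_len, strand,
                         qname, left_arm, planted, multi,
                         secondary = FALSE)],
               if (nrow(sec)) sec[, .(jid, reference, intron_start,
                                      intron_len, strand, qname, left_arm,
                                      planted, multi, secondary = TRUE)])
  na <- nrow(aln)

  # i.i.d. background mismatches plus the planted one
  nbg <- rbinom(na, L, cfg$background_mismatch_rate)
  mm_list <- vector("list", na)
  idx_bg <- which(nbg > 0L)
  for (i in idx_bg) mm_list[[i]] <- sample.int(L, nbg[i])
  has_planted <- which(!is.na(aln$planted))
  for (i in has_planted)
    mm_list[[i]] <- unique(c(aln$planted[i], mm_list[[i]]))
  nm_v <- lengths(mm_list)

  md_v <- rep(as.character(L), na)
  need_md <- which(nm_v > 0L)
  if (length(need_md)) {
    md_v[need_md] <- vapply(need_md, function(i) {
      pos <- sort(mm_list[[i]])
      refb <- sample(c("C", "G", "T"), length(pos), replace = TRUE)
      paste0(paste0(diff(c(0L, pos)) - 1L, refb, collapse = ""),
             L - pos[length(pos)])
    }, character(1))
  }

  aln[, `:=`(nm = nm_v, md = md_v)]
  aln[, pos := intron_start - left_arm + 1L]
  aln[, cigar := sprintf("%dM%dN%dM", left_arm, intron_len, L - left_arm)]
  aln[, flag := fifelse(secondary, 256L, 0L)]
  aln[, nh := fifelse(multi, 2L, 1L)]
  aln[, mapq := fifelse(multi, 3L, 50L)]

  setorder(aln, reference, pos, qname, flag)
  seq_str <- strrep("A", L)
  qual_str <- strrep("I", L)
  lines <- aln[, sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d\tNM:i:%d\tMD:Z:%s\tXS:A:%s",
    qname, flag, reference, pos, mapq, cigar, seq_str, qual_str,
    nh, nm, md, strand)]
  refs <- sprintf("contig%d", seq_len(cfg$n_references))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", refs, cfg$reference_length))
  writeLines(c(header, lines), sam_path)

  truth <- junc[, .(reference, intron_start, intron_end, strand, class,
                    true_count = fifelse(class == "expressed", n_reads, 0L))]
  setorder(truth, reference, intron_start, intron_end)
  if (!is.null(truth_path))
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(sam = sam_path, truth = truth, config = cfg))
}

#' Read a truth table written by [simulate_spliced_dataset()]
#'
#' @param path TSV truth-table path.
#' @return `data.table` with columns `reference`, `intron_start`,
#'   `intron_end`, `strand`, `class`, `true_count`.
#' @export
read_truth_table <- function(path) {
  fread(path, colClasses = list(character = c("reference", "strand", "class")))
}
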