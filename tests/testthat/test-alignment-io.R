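test_that("CIGAR arithmetic recovers junctions, arms and introns", {
  sam <- write_sam(c(
    # one junction at 0-based reference pos 1000: intron [1030,1130), arms 30/20
    sam_line("r1", "30M100N20M", pos = 1001L, tags = c("NH:i:1", "NM:i:0", "MD:Z:50")),
    # two junctions from one read: arms (20,30) and (30,26)
    sam_line("r2", "20M50N30M100N26M", pos = 2001L,
             tags = c("NH:i:1", "NM:i:0", "MD:Z:76", "XS:A:+"))))
  aln <- read_spliced_alignments(sam)
  rec <- aln$records

  r1 <- rec[read_id == "r1"]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$intron_start, 1030L)
  expect_equal(r1$intron_end, 1130L)
  expect_equal(c(r1$left_arm, r1$right_arm), c(30L, 20L))
  expect_equal(r1$overhang, 20L)
  expect_equal(r1$mm_dist[[1]], integer(0))
  expect_equal(r1$strand, "*")

  r2 <- rec[read_id == "r2"][order(junc_idx)]
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$left_arm, c(20L, 30L))
  expect_equal(r2$right_arm, c(30L, 26L))
  expect_equal(r2$intron_start, c(2020L, 2100L))
  expect_equal(r2$intron_end, c(2070L, 2200L))
  expect_equal(r2$strand, c("+", "+"))
})

test_that("MD mismatch positions agree with an independent per-base walker", {
  cases <- list(
    list(cigar = "30M100N20M", md = "45A4"),
    list(cigar = "30M100N20M", md = "10C19A19"),
    list(cigar = "5S25M100N20M", md = "20G24"),          # soft clip shifts read offsets
    list(cigar = "10M2D20M100N20M", md = "10^AC18T21"),  # deletion advances MD walk
    list(cigar = "10M2I18M100N22M", md = "25A24"),       # insertion advances read only
    list(cigar = "20M50N30M100N26M", md = "0A50T24"))
  for (cs in cases) {
    oracle <- md_offsets_oracle(cs$cigar, cs$md)
    walk <- juncfilter:::md_mismatch_walk(cs$md)[[1]]
    expect_equal(walk, oracle$mdpos, info = cs$md)
  }

  # spec-style worked case: MD 45A4 on 30M100N20M -> read offset 45,
  # i.e. 16 bases into the (shorter) right arm
  expect_equal(md_offsets_oracle("30M100N20M", "45A4")$read_off, 45L)
  sam <- write_sam(sam_line("m1", "30M100N20M", pos = 1001L,
                            tags = c("NH:i:1", "NM:i:1", "MD:Z:45A4")))
  rec <- read_spliced_alignments(sam)$records
  expect_equal(rec$mm_dist[[1]], 16L)

  # mismatch in the longer arm must not appear among overhang-arm distances
  sam2 <- write_sam(sam_line("m2", "30M100N20M", pos = 1001L,
                             tags = c("NH:i:1", "NM:i:1", "MD:Z:5A44")))
  rec2 <- read_spliced_alignments(sam2)$records
  expect_equal(rec2$mm_dist[[1]], integer(0))

  # mismatch in the left arm of an equal-arm read: left arm is the overhang
  # arm by convention; read offset 24 -> 1-based distance 25 - 24 = 1
  sam3 <- write_sam(sam_line("m3", "25M100N25M", pos = 1001L,
                             tags = c("NH:i:1", "NM:i:1", "MD:Z:24A25")))
  rec3 <- read_spliced_alignments(sam3)$records
  expect_equal(rec3$overhang, 25L)
  expect_equal(rec3$mm_dist[[1]], 1L)
})

test_that("aggregation pools unique reads and tracks multireads separately", {
  sam <- write_sam(c(
    sam_line("u1", "40M100N10M", pos = 1001L, tags = c("NH:i:1", "NM:i:0", "MD:Z:50")),
    sam_line("u2", "8M100N42M", pos = 1033L, tags = c("NH:i:1", "NM:i:0", "MD:Z:50")),
    sam_line("mm", "35M100N15M", pos = 1006L, mapq = 3L,
             tags = c("NH:i:2", "NM:i:0", "MD:Z:50")),
    sam_line("mm", "35M100N15M", pos = 2001L, flag = 256L, mapq = 3L,
             tags = c("NH:i:2", "NM:i:0", "MD:Z:50"))))
  ev <- aggregate_evidence(read_spliced_alignments(sam))
  j <- ev[intron_start == 1040L]
  expect_equal(j$n_unique, 2L)
  expect_setequal(j$raw_overhangs[[1]], c(10L, 8L))
  expect_equal(j$trimmed_overhangs[[1]], j$raw_overhangs[[1]])
  expect_equal(j$multiread_ids[[1]], "mm")
  # the multiread's decoy junction has no unique evidence -> absent
  expect_false(any(ev$intron_start == 2035L))
  # invariant: |raw| = |trimmed| = n_unique
  expect_true(all(lengths(ev$raw_overhangs) == ev$n_unique))
  expect_true(all(lengths(ev$trimmed_overhangs) == ev$n_unique))
})

test_that("NM>0 without MD flags mismatch positions unknown", {
  sam <- write_sam(sam_line("x1", "30M100N20M", pos = 1001L,
                            tags = c("NH:i:1", "NM:i:1")))
  expect_warning(aln <- read_spliced_alignments(sam), "mismatch positions unknown")
  expect_true(aln$records$mm_unknown)
  expect_equal(aln$records$mm_dist[[1]], integer(0))
})

test_that("indels near the splice site exclude a read from evidence", {
  sam <- write_sam(c(
    sam_line("d1", "28M2D2M100N20M", pos = 1001L,  # deletion 2 bp from the gap
             tags = c("NH:i:1", "NM:i:2", "MD:Z:28^AC22")),
    sam_line("d2", "10M2D20M100N20M", pos = 1001L, # deletion far from the gap
             tags = c("NH:i:1", "NM:i:2", "MD:Z:10^AC40"))))
  aln <- read_spliced_alignments(sam)
  expect_true(aln$records[read_id == "d1", indel_near_ss])
  expect_false(aln$records[read_id == "d2", indel_near_ss])
  ev <- aggregate_evidence(aln)
  expect_equal(ev$n_unique, 1L)
})

test_that("evidence is order-independent and round-trips the simulator", {
  cfg <- simulation_config(n_true_junctions = 30L, n_fp_junctions = 6L,
                           mean_reads_per_junction = 8, seed = 11L)
  sam <- tempfile(fileext = ".sam")
  sim <- simulate_spliced_dataset(cfg, sam)
  ev1 <- aggregate_evidence(read_spliced_alignments(sam))

  # shuffle the record lines and re-parse
  lines <- readLines(sam)
  hdr <- grepl("^@", lines)
  set.seed(99)
  shuffled <- c(lines[hdr], sample(lines[!hdr]))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(shuffled, sam2)
  ev2 <- aggregate_evidence(read_spliced_alignments(sam2))
  expect_equal(ev1$reference, ev2$reference)
  expect_equal(ev1$intron_start, ev2$intron_start)
  expect_equal(ev1$n_unique, ev2$n_unique)
  expect_equal(lapply(ev1$raw_overhangs, sort), lapply(ev2$raw_overhangs, sort))
  expect_equal(lapply(ev1$trimmed_overhangs, sort),
               lapply(ev2$trimmed_overhangs, sort))
  expect_equal(ev1$mismatch_positions, ev2$mismatch_positions)

  # sum of n_unique equals the number of unique gapped alignment lines
  # (each simulated alignment spans exactly one junction)
  body <- lines[!hdr]
  n_unique_lines <- sum(grepl("NH:i:1", body))
  expect_equal(sum(ev1$n_unique), n_unique_lines)

  # every raw overhang within the admissible support
  expect_true(all(unlist(ev1$raw_overhangs) >= 1L))
  expect_true(all(unlist(ev1$raw_overhangs) <= cfg$read_length %/% 2L))
})
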