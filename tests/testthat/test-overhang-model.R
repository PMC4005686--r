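test_that("overhang trimming truncates at the first mismatch", {
  expect_equal(trim_overhang(20, integer(0)), 20L)
  expect_equal(trim_overhang(20, c(5L, 12L)), 4L)
  expect_equal(trim_overhang(20, 1L), 0L)
  expect_equal(trim_overhang(c(20L, 10L), list(c(5L, 12L), integer(0))),
               c(4L, 10L))
  expect_error(trim_overhang(20, 21L), "outside the overhang arm")
  expect_error(trim_overhang(20, 0L), "outside the overhang arm")
})

test_that("exceedance probability matches closed-form expectations", {
  sup <- overhang_support(25)
  expect_equal(prob_exceed(25, 7, sup), 0)          # nothing exceeds o_max
  expect_equal(prob_exceed(24, 1, sup), 1 / 25)     # exhaustive: 1 of 25 outcomes
  expect_equal(prob_exceed(3, 10, sup), 1 - (3 / 25)^10)
  expect_error(prob_exceed(26, 1, sup), "outside")
  expect_error(prob_exceed(0, 1, sup), "outside")
  # monotone: increasing in n, decreasing in p_star
  ps <- prob_exceed(rep(10, 5), 1:5, sup)
  expect_true(all(diff(ps) > 0))
  pp <- prob_exceed(1:24, 5, sup)
  expect_true(all(diff(pp) < 0))
  # o_min > 1 support
  sup2 <- overhang_support(25, o_min = 5)
  expect_equal(prob_exceed(5, 1, sup2), 1 - 1 / 21)
})

test_that("labelling flags patently anomalous junctions only", {
  sup <- overhang_support(25)
  # 10 reads, all overhangs <= 3, every mismatch at position 3
  ev1 <- make_evidence(raw = rep(3L, 10), mm = replicate(10, 3L, simplify = FALSE))
  lab1 <- label_junctions(ev1, sup)
  expect_equal(lab1$label, "POTENTIAL_FP")
  expect_equal(lab1$reason, "single-mismatch-rule")

  # a single long read with a mismatch at its tip: too plausible to flag
  ev2 <- make_evidence(raw = 24L, mm = list(24L))
  expect_equal(label_junctions(ev2, sup)$label, "PRESUMED_OK")

  # clean reads: rule (i) requires a mismatch
  ev3 <- make_evidence(raw = c(3L, 2L, 5L, 8L, 1L))
  expect_equal(label_junctions(ev3, sup)$label, "PRESUMED_OK")

  # every read mismatching at the splice-adjacent base: no matching overhang
  ev4 <- make_evidence(raw = c(5L, 9L), mm = list(1L, 1L))
  lab4 <- label_junctions(ev4, sup)
  expect_equal(lab4$label, "POTENTIAL_FP")
  expect_equal(lab4$reason, "no-matching-overhang")

  # two distinct mismatch positions break rule (i)
  ev5 <- make_evidence(raw = rep(3L, 10),
                       mm = c(replicate(5, 3L, simplify = FALSE),
                              replicate(5, 2L, simplify = FALSE)))
  expect_equal(label_junctions(ev5, sup)$label, "PRESUMED_OK")

  # an overhang beyond p* breaks rule (ii)
  ev6 <- make_evidence(raw = c(rep(3L, 9), 10L),
                       mm = c(replicate(9, 3L, simplify = FALSE),
                              list(integer(0))))
  expect_equal(label_junctions(ev6, sup)$label, "PRESUMED_OK")
})

test_that("labelling is monotone in supporting read count", {
  sup <- overhang_support(25)
  # adding reads with overhang <= p* can only raise prob_exceed
  for (n in 4:12) {
    ev <- make_evidence(raw = rep(3L, n),
                        mm = c(list(3L), replicate(n - 1, integer(0),
                                                   simplify = FALSE)))
    lab <- label_junctions(ev, sup)
    if (n >= 5) expect_equal(lab$label, "POTENTIAL_FP", info = n)
  }
  # invariant to read order and duplication of the evidence map
  ev <- make_evidence(raw = c(3L, 2L, 3L), mm = list(3L, integer(0), 3L))
  evr <- make_evidence(raw = c(3L, 3L, 2L), mm = list(3L, 3L, integer(0)))
  expect_equal(label_junctions(ev, sup)$label, label_junctions(evr, sup)$label)
  ev2 <- rbind(ev, ev)
  data.table::setattr(ev2, "class", class(ev))
  expect_equal(label_junctions(ev2, sup)$label,
               rep(label_junctions(ev, sup)$label, 2))
})

test_that("exceedance counts and expectations follow the uniform model", {
  sup <- overhang_support(25)
  cp <- exceedance_counts(c(10L, 8L), sup)
  expect_equal(unname(cp["7"]), 2L)
  expect_equal(unname(cp["9"]), 1L)
  expect_equal(unname(cp["10"]), 0L)
  expect_true(all(diff(cp) <= 0))
  expect_equal(unname(exceedance_counts(integer(0), sup)), rep(0L, 24))
  expect_equal(unname(exceedance_counts(rep(25L, 6), sup)), rep(6L, 24))

  sup50 <- overhang_support(50)
  expect_equal(expected_exceedance(100, 10, sup50), 80)
  expect_equal(expected_exceedance(100, 49, sup50), 2)
  expect_equal(expected_exceedance(7, 49, sup50), 7 / 50)
  expect_error(expected_exceedance(10, 50, sup50), "outside")
})

test_that("feature vectors measure log2 deviation from uniform expectation", {
  sup <- overhang_support(25)
  # one read at every admissible overhang: C_p = 25 - p = E_p exactly
  ev <- make_evidence(raw = 1:25)
  expect_equal(unname(junction_features(ev, sup)[1, ]), rep(0, 24))

  # all trimmed overhangs zero: strictly negative features everywhere
  ev0 <- make_evidence(raw = rep(5L, 10), mm = replicate(10, 1L, simplify = FALSE))
  x0 <- junction_features(ev0, sup)
  expect_true(all(x0 < 0))
  p <- 1:24
  expected <- log2(0.5 / (10 * (25 - p) / 25 + 0.5))
  expect_equal(unname(x0[1, ]), expected)

  # doubling the counts with a vanishing pseudocount approaches +1:
  # two reads at every overhang value but n taken as 25 gives C_p = 2 E_p
  ev2 <- make_evidence(raw = rep(1:25, 2))
  ev2$n_unique <- 25L
  x2 <- junction_features(ev2, sup, pseudocount = 1e-9)
  expect_equal(unname(x2[1, ]), rep(1, 24), tolerance = 1e-6)

  expect_error(junction_features(ev, sup, pseudocount = 0), "pseudocount")
})

test_that("mean features over uniform-model junctions concentrate near zero", {
  # pseudocount bias at sparse tail positions does not vanish with more
  # junctions, only with more reads; at n = 200 reads it is < 0.1
  set.seed(31)
  sup <- overhang_support(25)
  nj <- 250L
  build <- function(nreads) {
    ev <- data.table(reference = "c", intron_start = seq_len(nj),
                     intron_end = seq_len(nj) + 100L, strand = "+",
                     n_unique = nreads,
                     raw_overhangs = replicate(nj, sample(25L, nreads, TRUE),
                                               simplify = FALSE),
                     max_read_length = 50L)
    ev[, trimmed_overhangs := raw_overhangs]
    ev[, mismatch_positions := replicate(nj, integer(0), simplify = FALSE)]
    ev[, multiread_ids := replicate(nj, character(0), simplify = FALSE)]
    setattr(ev, "class", c("junction_evidence", class(ev)))
    ev
  }
  m200 <- colMeans(junction_features(build(200L), sup))
  expect_lt(max(abs(m200)), 0.15)
  m20 <- colMeans(junction_features(build(20L), sup))
  expect_lt(max(abs(m20)), 0.5)
  # bias shrinks with read depth
  expect_lt(max(abs(m200)), max(abs(m20)))
})
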