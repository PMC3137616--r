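test_that("single-topology alignments yield an unpartitioned fit", {
  tr <- fixture_tree(8, seed = 81, min_bl = 0.05, max_bl = 0.25)
  reg <- selection_regime("M0", kappa = 2, omegas = 0.5)
  sim <- simulate_codon_alignment(tr, reg, 150, seed = 82)
  part <- scan_breakpoints(sim$alignment, max_breakpoints = 3)
  expect_length(part$breakpoints, 0)
  # with no breakpoints the partitioned c-AIC equals the single-model c-AIC
  expect_equal(part$caic_total, part$caic_single, tolerance = 1e-9)
  expect_equal(part$delta_caic, 0, tolerance = 1e-9)
  expect_equal(part$segments$start, 1)
  expect_equal(part$segments$end, 150)
})

test_that("a mid-alignment topology switch is recovered on the grid", {
  trees <- trimevol:::.discordant_trees()
  reg <- selection_regime("M0", kappa = 2, omegas = 0.5)
  rec <- simulate_recombinant_alignment(trees, reg, c(100, 100), seed = 5)
  part <- scan_breakpoints(rec$alignment, max_breakpoints = 4)
  expect_gte(length(part$breakpoints), 1)
  expect_true(any(abs(part$breakpoints - 100) <= 10))
  expect_gt(part$delta_caic, 0)
  # accepted breakpoints strictly improved the criterion
  expect_lt(part$caic_total, part$caic_single)
  # nucleotide coordinates are 3x codon coordinates
  expect_equal(part$breakpoints_nuc, 3L * part$breakpoints)
})

test_that("segments tile the alignment and map coordinates bijectively", {
  trees <- trimevol:::.discordant_trees()
  reg <- selection_regime("M0", kappa = 2, omegas = 0.5)
  rec <- simulate_recombinant_alignment(trees, reg, c(60, 80), seed = 9)
  part <- scan_breakpoints(rec$alignment, max_breakpoints = 4)
  segs <- part$segments
  expect_equal(segs$start[1], 1)
  expect_equal(segs$end[nrow(segs)], 140)
  if (nrow(segs) > 1) {
    expect_equal(segs$start[-1], utils::head(segs$end, -1) + 1)
  }
  # round trip: every whole-alignment codon belongs to exactly one segment
  covered <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    segs$start[i]:segs$end[i]
  }))
  expect_identical(sort(covered), 1:140)
  # segment-local -> whole-alignment index map is a bijection per segment
  for (i in seq_len(nrow(segs))) {
    loc <- seq_len(segs$end[i] - segs$start[i] + 1)
    glob <- loc + segs$start[i] - 1L
    expect_identical(glob, segs$start[i]:segs$end[i])
  }
})

test_that("segments too short for the minimum length are never created", {
  tr <- fixture_tree(8, seed = 91)
  reg <- selection_regime("M0", kappa = 2, omegas = 0.5)
  sim <- simulate_codon_alignment(tr, reg, 60, seed = 92)
  part <- scan_breakpoints(sim$alignment, max_breakpoints = 6,
                           grid_step = 3, min_segment = 25)
  lens <- part$segments$end - part$segments$start + 1
  expect_true(all(lens >= 25))
  expect_error(scan_breakpoints(subset_codons(sim$alignment, 1, 4)),
               "too short")
})

test_that("per-segment selection tests isolate the selected fragment", {
  # codons 1-60 evolve neutrally/purifying, codons 61-140 contain positive
  # selection; a forced split at 60 should localize the signal
  tr <- fixture_tree(10, seed = 95, min_bl = 0.15, max_bl = 0.4)
  null_reg <- selection_regime("M1a", kappa = 2, omegas = c(0.2, 1),
                               proportions = c(0.7, 0.3))
  pos_reg <- selection_regime("M2a", kappa = 2, omegas = c(0.2, 1, 8),
                              proportions = c(0.55, 0.2, 0.25))
  s1 <- simulate_codon_alignment(tr, null_reg, 60, seed = 96)
  s2 <- simulate_codon_alignment(tr, pos_reg, 80, seed = 97)
  states <- cbind(s1$alignment$states, s2$alignment$states[s1$alignment$ids, ])
  aln <- codon_alignment(matrix(SENSE_CODONS[states], nrow = nrow(states),
                                dimnames = list(s1$alignment$ids, NULL)))
  partition <- list(segments = data.frame(start = c(1, 61), end = c(60, 140)))
  res <- segment_selection_tests(aln, partition, model_pairs = "M1a-M2a")
  expect_length(res, 2)
  p1 <- res[[1]]$lrts[["M1a-M2a"]]$p_value
  p2 <- res[[2]]$lrts[["M1a-M2a"]]$p_value
  expect_gt(p1, 0.001)
  expect_lt(p2, 0.001)
  # positive sites are reported in whole-alignment coordinates
  if (nrow(res[[2]]$positive_sites) > 0) {
    expect_true(all(res[[2]]$positive_sites$site >= 61))
    expect_equal(res[[2]]$positive_sites$site,
                 res[[2]]$positive_sites$segment_site + 60L)
  }
  # true positive sites in segment 2 overlap the reported ones
  truepos <- which(s2$site_classes == 3) + 60L
  expect_gt(length(intersect(res[[2]]$positive_sites$site, truepos)), 0)
})

test_that("a failing segment does not abort the others", {
  tr <- fixture_tree(6, seed = 98)
  reg <- selection_regime("M0", kappa = 2, omegas = 0.5)
  sim <- simulate_codon_alignment(tr, reg, 80, seed = 99)
  # second segment extends beyond the alignment: fails in subsetting
  partition <- list(segments = data.frame(start = c(1, 79), end = c(78, 90)))
  res <- segment_selection_tests(sim$alignment, partition,
                                 model_pairs = "M1a-M2a")
  expect_null(res[[1]]$error)
  expect_false(is.null(res[[1]]$lrts[["M1a-M2a"]]))
  expect_false(is.null(res[[2]]$error))
})
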