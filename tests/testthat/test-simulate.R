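test_that("simulation is byte-identical under a fixed seed", {
  tr <- fixture_tree(6, seed = 4)
  reg <- fixture_m2a_regime()
  a <- simulate_codon_alignment(tr, reg, 50, seed = 99)
  b <- simulate_codon_alignment(tr, reg, 50, seed = 99)
  expect_identical(as.character(a$alignment), as.character(b$alignment))
  expect_identical(a$site_classes, b$site_classes)
  c <- simulate_codon_alignment(tr, reg, 50, seed = 100)
  expect_false(identical(as.character(a$alignment), as.character(c$alignment)))
})

test_that("omega = 0 evolution is purely synonymous", {
  tr <- fixture_tree(6, seed = 2, min_bl = 0.2, max_bl = 0.6)
  reg <- selection_regime("M0", kappa = 2, omegas = 0)
  sim <- simulate_codon_alignment(tr, reg, 100, seed = 5)
  aa <- matrix(CODON_AA[sim$alignment$states], nrow = sim$alignment$n)
  # every column is a single amino acid across sequences
  expect_true(all(apply(aa, 2, function(x) length(unique(x)) == 1)))
  # but nucleotide differences do occur
  expect_gt(sum(sim$alignment$states[1, ] != sim$alignment$states[2, ]), 0)
})

test_that("site classes are drawn i.i.d. from the regime proportions", {
  tr <- fixture_tree(4, seed = 6)
  reg <- selection_regime("M2a",
    kappa = 2, omegas = c(0.2, 1, 4),
    proportions = c(0.6, 0.3, 0.1)
  )
  sim <- simulate_codon_alignment(tr, reg, 10000, seed = 21)
  frac_pos <- mean(sim$site_classes == 3)
  expect_lt(abs(frac_pos - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("simulated codon frequencies converge to equilibrium", {
  # long-branch pair accumulates many substitutions towards stationarity
  tr <- ape::read.tree(text = "(a:10,b:10);")
  pi <- f3x4_frequencies(c(0.3, 0.25, 0.25, 0.2))
  reg <- selection_regime("M0", kappa = 2, omegas = 0.8)
  sim <- simulate_codon_alignment(tr, reg, 10000, seed = 13,
                                  codon_frequencies = pi)
  obs <- tabulate(as.integer(sim$alignment$states), nbins = 61)
  gof <- stats::chisq.test(obs, p = pi)
  expect_gt(gof$p.value, 0.01)
})

test_that("counting-method dN/dS recovers the generating omega under M0", {
  # modest divergence keeps the counting method in its consistent regime
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  for (om in c(0.2, 1, 2)) {
    reg <- selection_regime("M0", kappa = 1, omegas = om)
    sim <- simulate_codon_alignment(tr, reg, 20000, seed = 31 + round(10 * om))
    seqs <- as.character(sim$alignment)
    est <- ng86_omega(seqs[[1]], seqs[[2]])
    expect_lt(abs(est - om) / om, 0.15)
  }
})

test_that("recombinant simulation reports construction breakpoints", {
  trees <- trimevol:::.discordant_trees()
  reg <- selection_regime("M0", kappa = 2, omegas = 0.5)
  # degenerate single segment: no breakpoints
  one <- simulate_recombinant_alignment(trees[1], reg, 120, seed = 1)
  expect_length(one$breakpoints, 0)
  expect_equal(one$alignment$c, 120)
  # two segments: breakpoint at codon 100, invariant to seed
  r1 <- simulate_recombinant_alignment(trees, reg, c(100, 100), seed = 1)
  r2 <- simulate_recombinant_alignment(trees, reg, c(100, 100), seed = 2)
  expect_equal(r1$breakpoints, 100)
  expect_identical(r1$breakpoints, r2$breakpoints)
  expect_identical(r1$segments, r2$segments)
  expect_false(identical(as.character(r1$alignment), as.character(r2$alignment)))
  # mismatched leaf sets are rejected
  bad <- trees
  bad[[2]]$tip.label[1] <- "zz"
  expect_error(
    simulate_recombinant_alignment(bad, reg, c(50, 50), seed = 1),
    "leaf label set"
  )
})

test_that("regime invariants are enforced", {
  expect_error(
    selection_regime("M2a", omegas = c(0.2, 1, 4), proportions = c(0.6, 0.3, 0.2)),
    "sum to 1"
  )
  expect_error(selection_regime("M1a", omegas = c(1.2, 1), proportions = c(0.5, 0.5)))
  expect_error(selection_regime("M2a", omegas = c(0.2, 1, 0.5),
                                proportions = c(0.6, 0.3, 0.1)))
  expect_error(selection_regime("M8", beta_p = 1, beta_q = 2, omega_pos = 0.5,
                                p_pos = 0.1), "omega_pos")
  r8 <- selection_regime("M8", beta_p = 1, beta_q = 2, omega_pos = 3, p_pos = 0.1)
  expect_equal(sum(r8$class_proportions), 1, tolerance = 1e-12)
  expect_length(r8$class_omegas, 11)
})

test_that("domain-table simulator realizes architecture mixes", {
  dt <- simulate_domain_table(10, c("RING,BBOX,CC,B30.2" = 1), seed = 3)
  calls <- classify_domain_table(dt)
  expect_equal(nrow(calls), 10)
  expect_true(all(calls$trim_class == "IV"))
  # intervals ordered and non-overlapping within protein
  for (g in split(dt, dt$protein_id)) {
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # novel architecture flagged
  dt2 <- simulate_domain_table(
    6, c("RING,TM,B30.2" = 0.5, "RING,BBOX,CC,B30.2" = 0.5), seed = 5
  )
  calls2 <- classify_domain_table(dt2)
  novel <- calls2[calls2$architecture == "RING,TM,B30.2", ]
  expect_true(all(grepl("novel_combination", novel$flags)))
  # empty mix and unknown tokens
  expect_equal(nrow(simulate_domain_table(5, numeric(0), seed = 1)), 0)
  expect_error(simulate_domain_table(5, c("RING,XYZ" = 1), seed = 1), "unknown domain")
})
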