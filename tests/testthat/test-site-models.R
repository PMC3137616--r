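test_that("beta discretization returns equal-probability category medians", {
  # beta(1,1) is uniform: medians are (k - 0.5)/10
  expect_equal(discretize_beta(1, 1, 10), ((1:10) - 0.5) / 10, tolerance = 1e-12)
  om <- discretize_beta(0.8, 2.3, 10)
  expect_length(om, 10)
  expect_true(all(om > 0 & om < 1))
  expect_true(all(diff(om) > 0))
})

test_that("LRT follows the chi-square reference distribution", {
  mkfit <- function(model, lnl, np) {
    structure(list(model_id = model, lnL = lnl, np = np),
              class = "site_model_fit")
  }
  r <- lrt(mkfit("M1a", -1000, 4), mkfit("M2a", -1000, 6))
  expect_equal(r$two_delta_lnl, 0)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 1)
  # closed form at df = 2: p = exp(-x/2)
  r2 <- lrt(mkfit("M7", -1000, 4), mkfit("M8", -1000 + 9.21034 / 2, 6))
  expect_equal(r2$p_value, 0.0100, tolerance = 1e-4)
  expect_equal(r2$p_value, exp(-9.21034 / 2), tolerance = 1e-9)
  # non-nested pairs are rejected; tiny negatives are clipped with a warning
  expect_error(lrt(mkfit("M2a", -1000, 6), mkfit("M7", -999, 4)), "not nested")
  expect_warning(r3 <- lrt(mkfit("M1a", -1000, 4), mkfit("M2a", -1000.00001, 6)),
                 "clipped")
  expect_equal(r3$two_delta_lnl, 0)
})

test_that("nesting holds: the alternative never fits worse", {
  tr <- fixture_tree(8, seed = 15)
  reg <- selection_regime("M1a", kappa = 2, omegas = c(0.3, 1),
                          proportions = c(0.6, 0.4))
  sim <- simulate_codon_alignment(tr, reg, 120, seed = 51)
  f1 <- fit_site_model(sim$alignment, tr, "M1a")
  f2 <- fit_site_model(sim$alignment, tr, "M2a",
    options = list(init = trimevol:::.warm_start(f1, "M2a"))
  )
  expect_gte(f2$lnL, f1$lnL - 1e-4)
  f7 <- fit_site_model(sim$alignment, tr, "M7")
  f8 <- fit_site_model(sim$alignment, tr, "M8",
    options = list(init = trimevol:::.warm_start(f7, "M8"))
  )
  expect_gte(f8$lnL, f7$lnL - 1e-4)
  # class structures respect the model constraints
  expect_equal(f2$class_omegas[2], 1)
  expect_gte(f2$omega_pos, 1)
  expect_equal(sum(f2$class_proportions), 1, tolerance = 1e-9)
  expect_equal(sum(f8$class_proportions), 1, tolerance = 1e-9)
})

test_that("M2a collapses onto M1a truth on null data", {
  # median over 10 seeds of the M1a-M2a 2*delta-lnL stays near 0
  reg <- selection_regime("M1a", kappa = 2, omegas = c(0.2, 1),
                          proportions = c(0.7, 0.3))
  two_d <- vapply(1:10, function(s) {
    tr <- fixture_tree(6, seed = 100 + s)
    sim <- simulate_codon_alignment(tr, reg, 100, seed = 200 + s)
    f1 <- fit_site_model(sim$alignment, tr, "M1a")
    f2 <- fit_site_model(sim$alignment, tr, "M2a",
      options = list(init = trimevol:::.warm_start(f1, "M2a"))
    )
    suppressWarnings(lrt(f1, f2)$two_delta_lnl)
  }, numeric(1))
  expect_lt(median(two_d), 0.5)
})

test_that("M0 recovers kappa and omega from its own simulations", {
  tr <- fixture_tree(10, seed = 23, min_bl = 0.1, max_bl = 0.3)
  reg <- selection_regime("M0", kappa = 3, omegas = 0.5)
  sim <- simulate_codon_alignment(tr, reg, 400, seed = 99)
  f0 <- fit_site_model(sim$alignment, tr, "M0")
  expect_lt(abs(f0$kappa - 3) / 3, 0.2)
  expect_lt(abs(f0$class_omegas[1] - 0.5) / 0.5, 0.2)
  expect_lt(abs(f0$tree_scale - 1), 0.15) # branch lengths were in true units
})

test_that("an internal NJ tree supports fitting when no tree is given", {
  tr <- fixture_tree(8, seed = 40, min_bl = 0.1, max_bl = 0.25)
  reg <- selection_regime("M0", kappa = 2, omegas = 0.4)
  sim <- simulate_codon_alignment(tr, reg, 150, seed = 41)
  f <- fit_site_model(sim$alignment, NULL, "M0")
  expect_true(is.finite(f$lnL))
  expect_lt(abs(f$class_omegas[1] - 0.4), 0.15)
})

test_that("posterior site identification flags simulated positive sites", {
  # strongly selected sites (omega = 8) on a long tree are recovered;
  # aggregate over 10 seeds, expecting >= 80% detection among true positives
  reg <- selection_regime("M2a", kappa = 2, omegas = c(0.2, 1, 8),
                          proportions = c(0.65, 0.2, 0.15))
  hit <- 0
  tot <- 0
  extra <- 0
  for (s in 1:10) {
    tr <- fixture_tree(12, seed = 300 + s, min_bl = 0.15, max_bl = 0.4)
    sim <- simulate_codon_alignment(tr, reg, 150, seed = 400 + s)
    f2 <- fit_site_model(sim$alignment, tr, "M2a")
    sp <- site_posteriors(f2, sim$alignment, tr, method = "NEB")
    pos <- sim$site_classes == 3
    hit <- hit + sum(sp$significant & pos)
    tot <- tot + sum(pos)
    extra <- extra + sum(sp$significant & !pos)
  }
  expect_gte(hit / tot, 0.8)
  # false calls stay rare relative to true calls
  expect_lt(extra / max(hit, 1), 0.25)
})

test_that("posteriors of the positive class vanish when p_pos = 0", {
  tr <- fixture_tree(6, seed = 52)
  reg <- selection_regime("M0", kappa = 2, omegas = 0.3)
  sim <- simulate_codon_alignment(tr, reg, 60, seed = 53)
  f <- fit_site_model(sim$alignment, tr, "M2a")
  # force the fitted mixture to put zero weight on the positive class
  f$class_proportions <- c(f$class_proportions[1] + f$class_proportions[3],
                           f$class_proportions[2], 0)
  sp <- site_posteriors(f, sim$alignment, tr, method = "NEB")
  expect_true(all(sp$posterior == 0))
  expect_false(any(sp$significant))
})

test_that("posterior methods are restricted to M2a/M8", {
  tr <- fixture_tree(5, seed = 61)
  reg <- selection_regime("M0", kappa = 2, omegas = 0.3)
  sim <- simulate_codon_alignment(tr, reg, 40, seed = 62)
  f1 <- fit_site_model(sim$alignment, tr, "M1a")
  expect_error(site_posteriors(f1, sim$alignment, tr), "M2a or M8")
})

test_that("BEB and NEB agree on clear-cut sites", {
  reg <- selection_regime("M2a", kappa = 2, omegas = c(0.2, 1, 8),
                          proportions = c(0.65, 0.2, 0.15))
  tr <- fixture_tree(12, seed = 71, min_bl = 0.15, max_bl = 0.4)
  sim <- simulate_codon_alignment(tr, reg, 150, seed = 72)
  f2 <- fit_site_model(sim$alignment, tr, "M2a")
  neb <- site_posteriors(f2, sim$alignment, tr, method = "NEB")
  beb <- site_posteriors(f2, sim$alignment, tr, method = "BEB")
  expect_equal(beb$method[1], "BEB")
  # high-confidence NEB sites remain high under BEB
  strong <- neb$posterior > 0.99
  expect_true(all(beb$posterior[strong] > 0.9))
  expect_true(all(beb$posterior >= 0 & beb$posterior <= 1))
})
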