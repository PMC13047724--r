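test_that("the hypergeometric ratio law matches direct enumeration", {
  pmf <- hypergeometric_ratio_pmf(2, 3, 2)
  expect_equal(pmf$prob[pmf$k == 1], 0.6)          # C(2,1)C(3,1)/C(5,2)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)

  # exhaustive draw -> point mass at pool_b / pool_a
  full <- hypergeometric_ratio_pmf(4, 12, 16)
  expect_equal(full$prob[full$k == 4], 1)
  expect_equal(full$ratio[full$k == 4], 3)

  # independent combinatorial oracle
  a <- 40; b <- 360; d <- 120
  pmf <- hypergeometric_ratio_pmf(a, b, d)
  oracle <- choose(a, pmf$k) * choose(b, d - pmf$k) / choose(a + b, d)
  expect_equal(pmf$prob, oracle, tolerance = 1e-12)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
})

test_that("a mixture run partitions its test spectra and is deterministic", {
  gen <- generator_config(separation = 2.2)
  pot <- generate_event_spectra(150, gen, composition = c(OT = 1), seed = 41)
  pvp <- generate_event_spectra(150, gen, composition = c(VP = 1), seed = 42)
  mix <- generate_event_spectra(150, gen, composition = c(OT = 0.5, VP = 0.5),
                                label = "MIX", seed = 43)
  cfg <- protocol_config(num_trees = 60)
  r1 <- run_mixture_protocol(pot, pvp, mix, cfg, seed = 5)
  expect_identical(r1$m_ot + r1$m_vp + r1$m_mix, r1$n_mix_test)
  expect_identical(r1$n_mix_test, 45L)             # 30% of 150
  r2 <- run_mixture_protocol(pot, pvp, mix, cfg, seed = 5)
  expect_identical(r1, r2)
})

test_that("a mixture that copies one pure class redistributes to that class", {
  gen <- generator_config(separation = 2.2)
  pot <- generate_event_spectra(150, gen, composition = c(OT = 1), seed = 41)
  pvp <- generate_event_spectra(150, gen, composition = c(VP = 1), seed = 42)
  vp_copy <- generate_event_spectra(150, gen, composition = c(VP = 1),
                                    label = "MIX", seed = 44)
  r <- run_mixture_protocol(pot, pvp, vp_copy, protocol_config(num_trees = 60),
                            seed = 6)
  expect_gt(r$m_vp, 5 * max(1, r$m_ot))
})

test_that("ratio histograms bin, pick modes, and validate input", {
  h <- ratio_histogram(rep(1.4, 60))
  expect_equal(h$mode, 1.4)
  expect_identical(sum(h$bins$count), 60L)
  expect_identical(h$n_included, 60L)

  # large ratios fall into logarithmic bins with geometric centers
  h9 <- ratio_histogram(rep(9, 60))
  bin <- h9$bins[h9$bins$count > 0, ]
  expect_gt(bin$lower, 3)
  expect_equal(bin$center, sqrt(bin$lower * bin$upper))
  expect_lt(abs(h9$mode - 9), (exp(0.2) - 1) * 9)  # within one log bin

  # excluded runs are counted, not binned
  runs <- tibble::tibble(ratio = c(rep(1, 35), NA, NA), excluded = FALSE)
  h2 <- ratio_histogram(runs)
  expect_identical(h2$n_excluded, 2L)
  expect_identical(h2$n_included, 35L)

  expect_error(ratio_histogram(rep(1, 10)), "at least 30")
  expect_error(ratio_histogram(c(NA_real_, NA_real_)), "all runs")

  # mode ties break toward the median ratio
  tied <- c(rep(0.6, 20), rep(1.0, 20), rep(0.95, 5))
  ht <- ratio_histogram(tied, min_runs = 30)
  expect_equal(ht$mode, 1.0)
})

test_that("composition estimates follow the mode", {
  est1 <- estimate_composition(ratio_histogram(rep(1, 40)))
  expect_equal(est1$fraction, c(0.5, 0.5))
  # synthetic histogram object with an exact mode of 9
  h9 <- structure(list(mode = 9, n_included = 40L, n_excluded = 0L,
                       ratios = rep(9, 40)), class = "ratio_histogram")
  est9 <- estimate_composition(h9, spike_concentration = 1)
  expect_equal(est9$fraction, c(0.1, 0.9))
  expect_equal(est9$concentration, c(1, 9))
})

test_that("equal compositions are recovered and the estimator is
           swap-equivariant", {
  gen <- generator_config(separation = 2.2)
  pot <- generate_event_spectra(150, gen, composition = c(OT = 1), seed = 41)
  pvp <- generate_event_spectra(150, gen, composition = c(VP = 1), seed = 42)
  cfg <- protocol_config(num_trees = 60)

  mix11 <- generate_event_spectra(150, gen, composition = c(OT = 0.5, VP = 0.5),
                                  label = "MIX", seed = 45)
  runs <- mixture_ratio_runs(pot, pvp, mix11, cfg, seeds = 1:40)
  h <- ratio_histogram(runs)
  expect_lt(abs(h$mode - 1), 0.2 + 1e-9)           # within one bin of 1:1

  # class swap: VP:OT ratio inverts (within one bin on the log scale)
  mix13 <- generate_event_spectra(200, gen, composition = c(OT = 0.25, VP = 0.75),
                                  label = "MIX", seed = 46)
  fwd <- ratio_histogram(mixture_ratio_runs(pot, pvp, mix13, cfg, seeds = 1:40))
  swp <- ratio_histogram(mixture_ratio_runs(pvp, pot, mix13, cfg, seeds = 1:40))
  expect_lt(abs(log(fwd$mode) + log(swp$mode)), 0.45)

  # run-to-run spread is at least the sampling-only hypergeometric spread
  n_true_ot <- sum(mix11$true_label == "OT")
  pmf <- hypergeometric_ratio_pmf(n_true_ot, 150 - n_true_ot, 45)
  fin <- is.finite(pmf$ratio)
  mu <- sum(pmf$ratio[fin] * pmf$prob[fin]) / sum(pmf$prob[fin])
  hyper_sd <- sqrt(sum((pmf$ratio[fin] - mu)^2 * pmf$prob[fin]) /
                     sum(pmf$prob[fin]))
  expect_gte(sd(h$ratios), hyper_sd)
})
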