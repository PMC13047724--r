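test_that("the time trace is the per-frame channel sum", {
  ones <- make_clean_stream(matrix(1, nrow = 9, ncol = 61))
  tr <- build_time_trace(ones)
  expect_true(all(tr$photons == 61))
  sim <- sim_fixture()
  clean <- remove_bad_pixels(sim$stream)
  tr <- build_time_trace(clean)
  expect_equal(sum(tr$photons), sum(clean$counts))  # conservation
})

test_that("segmented median baseline flattens constants and tracks slow drift", {
  const <- make_trace(rep(5, 3000), corrected = FALSE)
  out <- subtract_segmented_baseline(const, 500)
  expect_true(all(out$corrected == 0))

  # slow sinusoid, no events: residual bounded by the within-segment
  # drift range around the median, computed directly per segment
  n <- 6000; L <- 500
  x <- 50 + 10 * sin(2 * pi * seq_len(n) / 20000)
  tr <- subtract_segmented_baseline(make_trace(x, corrected = FALSE), L)
  seg <- (seq_len(n) - 1) %/% L
  bound <- max(sapply(split(x, seg), function(s) max(abs(s - median(s)))))
  expect_lte(max(abs(tr$corrected)), bound + 1e-12)
  expect_lt(bound, 10)  # far below the sinusoid's full swing

  # median robustness: a lone spike is reduced only by the background median
  y <- rep(3, 1000); y[400] <- 250
  tr2 <- subtract_segmented_baseline(make_trace(y, corrected = FALSE), 1000)
  expect_equal(tr2$corrected[400], 250 - 3)
})

test_that("thresholding finds runs and merges across small gaps", {
  x <- c(rep(0, 10), 5, 6, 0, 7, rep(0, 10))
  ev0 <- detect_events(make_trace(x), detection_config(min_gap = 0),
                      threshold = 2)
  expect_identical(nrow(ev0), 2L)
  ev1 <- detect_events(make_trace(x), detection_config(min_gap = 1),
                      threshold = 2)
  expect_identical(nrow(ev1), 1L)
  expect_identical(c(ev1$start_frame, ev1$end_frame), c(11L, 14L))
  none <- detect_events(make_trace(rep(0:1, 20)), threshold = 5)
  expect_identical(nrow(none), 0L)
  expect_warning(detect_events(make_trace(rep(2, 50))), "robust scale")
})

test_that("detection on the synthetic stream matches ground truth", {
  sim <- sim_fixture()
  det <- detection_fixture()
  m <- match_events(det$intervals, sim$events)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
  # detected intervals disjoint and sorted after merging
  iv <- det$intervals
  expect_true(all(diff(iv$start_frame) > 0))
  expect_true(all(utils::head(iv$end_frame, -1) <
                    utils::tail(iv$start_frame, -1)))
  # photon conservation across extraction
  expect_lte(sum(det$spectra$total_photons), sum(sim$stream$counts))
})

test_that("event spectra are raw-count sums over the interval", {
  sim <- sim_fixture()
  kept <- setdiff(1:64, c(7, 31, 50))
  one <- extract_events(sim$stream,
                        tibble::tibble(start_frame = 101L, end_frame = 101L))
  expect_equal(unlist(one[1, spectrum_channels(one)], use.names = FALSE),
               as.vector(sim$stream$counts[101, kept]))
  iv <- tibble::tibble(start_frame = 201L, end_frame = 210L)
  ten <- extract_events(sim$stream, iv)
  expect_identical(ten$total_photons,
                   as.integer(sum(sim$stream$counts[201:210, kept])))
  expect_error(extract_events(sim$stream,
                              tibble::tibble(start_frame = 1L,
                                             end_frame = 10^6L)),
               "bounds")
})

test_that("detected events carry the experiment's photon budget", {
  det <- detection_fixture()
  ps <- photon_statistics(det$spectra)
  expect_gt(ps$mean, 112)
  expect_lt(ps$mean, 130)
  expect_identical(sum(ps$histogram$count), ps$n)
  single <- photon_statistics(tibble::tibble(total_photons = 120L))
  expect_equal(single$mean, 120)
  expect_equal(single$median, 120)
  expect_error(photon_statistics(tibble::tibble(total_photons = integer())),
               "at least one")
})

test_that("cumulative spectra average correctly and converge to the template", {
  # identical events -> the mean is any one of them
  sp <- tibble::tibble(event_id = c("a", "b"), label = "OT",
                       start_frame = NA_integer_, end_frame = NA_integer_,
                       total_photons = 6L, c0 = 1L, c1 = 2L, c2 = 3L)
  cum <- cumulative_spectrum(sp)
  expect_equal(unname(cum$mean_photons), c(1, 2, 3))

  # linearity: mean of equal-size partition means equals the grand mean
  d <- dataset_fixture()
  feat <- spectrum_channels(d)
  g1 <- colMeans(as.matrix(d[1:200, feat]))
  g2 <- colMeans(as.matrix(d[201:400, feat]))
  expect_equal((g1 + g2) / 2, colMeans(as.matrix(d[1:400, feat])))

  # law of large numbers: pure-OT events without fluctuation line up with
  # the emission template on the kept channels
  cfg <- generator_config(fluctuation = 0)
  pure <- generate_event_spectra(3000, cfg, composition = c(OT = 1), seed = 13)
  cum <- cumulative_spectrum(pure)
  kept <- setdiff(1:64, cfg$bad_pixels)
  tpl <- peptide_templates()$OT$emission[kept]
  v <- cum$mean_photons
  cosine <- sum(v * tpl) / sqrt(sum(v^2) * sum(tpl^2))
  expect_gte(cosine, 0.99)
})
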