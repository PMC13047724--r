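test_that("confusion-derived metrics match hand-computed values", {
  m <- metrics_from_confusion(50, 40, 10, 20)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 0.8333, tolerance = 1e-4)
  expect_equal(m$recall, 0.7143, tolerance = 1e-4)
  expect_equal(m$f1, 0.7692, tolerance = 1e-4)
  expect_false(m$degenerate)

  perfect <- metrics_from_confusion(60, 60, 0, 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  degen <- metrics_from_confusion(0, 90, 0, 10)
  expect_equal(degen$precision, 0)
  expect_true(degen$degenerate)
  expect_error(metrics_from_confusion(0, 0, 0, 0), "> 0")

  # F1 is the harmonic mean: never above either component
  set.seed(1)
  mm <- metrics_from_confusion(sample(1:50, 20), sample(1:50, 20),
                               sample(1:50, 20), sample(1:50, 20))
  expect_true(all(mm$f1 <= pmax(mm$precision, mm$recall) + 1e-12))
  expect_true(all(mm$f1 >= pmin(mm$precision, mm$recall) - 1e-12))
})

test_that("the power transform standardises, stays monotone, and agrees with
           an independent implementation", {
  set.seed(7)
  x <- cbind(rpois(300, 3), rexp(300, 0.2), rnorm(300), rep(2, 300))
  fit <- fit_power_transform(x)
  y <- apply_power_transform(fit, x)
  expect_true(all(abs(colMeans(y[, 1:3])) < 1e-8))
  expect_true(all(abs(apply(y[, 1:3], 2, sd) - 1) < 1e-6))
  expect_true(all(y[, 4] == 0))                    # constant feature -> 0
  for (j in 1:3) expect_identical(order(y[, j]), order(x[, j]))  # monotone
  # an (almost) normal feature is left essentially affine
  expect_gt(cor(y[, 3], x[, 3]), 0.999)

  skip_if_not_installed("caret")
  pp <- caret::preProcess(as.data.frame(x[, 1:3]),
                          method = c("YeoJohnson", "center", "scale"))
  yc <- as.matrix(predict(pp, as.data.frame(x[, 1:3])))
  for (j in 1:3) expect_gt(cor(y[, j], yc[, j]), 0.9999)
})

test_that("PCA projection is orthonormal with ordered variance", {
  set.seed(8)
  x <- matrix(rnorm(200 * 12), 200)
  fit <- fit_pca(x, k = 5)
  rot <- fit$rotation
  expect_equal(crossprod(rot), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  expect_error(fit_pca(x, k = 50), "exceeds")

  # data on an exact 2-plane reconstructs perfectly with k = 2
  basis <- qr.Q(qr(matrix(rnorm(12 * 2), 12)))
  planar <- matrix(rnorm(100 * 2), 100) %*% t(basis)
  f2 <- fit_pca(planar, k = 2)
  sc <- project_pca(f2, planar)
  recon <- sc %*% t(f2$rotation) + matrix(f2$center, 100, 12, byrow = TRUE)
  expect_lt(max(abs(recon - planar)), 1e-10)
})

test_that("centroid diagnostics report separations and degeneracies", {
  pts <- rbind(matrix(0, 10, 2), matrix(3, 10, 2))
  colnames(pts) <- c("PC1", "PC2")
  cd <- centroid_diagnostics(pts, rep(c("A", "B"), each = 10))
  expect_equal(cd$separation$distance, 3 * sqrt(2))
  expect_equal(cd$centroids$var_pc1, c(0, 0))
  same <- centroid_diagnostics(rbind(pts[1:10, ], pts[1:10, ]),
                               rep(c("A", "B"), each = 10))
  expect_equal(same$separation$distance, 0)
  single <- centroid_diagnostics(pts, rep("A", 20))
  expect_true(single$degenerate)

  # calibrated synthetic classes: separable centroids, overlapping clouds
  d <- dataset_fixture()
  feat <- spectrum_channels(d)
  pt <- fit_power_transform(as.matrix(d[feat]))
  sc <- project_pca(fit_pca(apply_power_transform(pt, as.matrix(d[feat])), 10),
                    apply_power_transform(pt, as.matrix(d[feat])))
  cd <- centroid_diagnostics(sc, d$label)
  spread <- mean(sqrt(cd$centroids$var_pc1 + cd$centroids$var_pc2))
  expect_gt(cd$separation$distance, 0)
  expect_lt(cd$separation$distance, 2 * spread)   # substantial overlap
})

test_that("the forest separates separable data and is seed-deterministic", {
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2))
  colnames(x) <- c("PC1", "PC2")
  y <- rep(c("A", "B"), each = 50)
  rf <- train_forest(x, y, seed = 1)
  expect_equal(mean(sersflow:::.predict_forest(rf, x) == y), 1.0)
  rf2 <- train_forest(x, y, seed = 1)
  expect_identical(sersflow:::.predict_forest(rf, x),
                   sersflow:::.predict_forest(rf2, x))
  expect_error(train_forest(x, rep("A", 100)), "two classes")

  # permuted labels give chance-level held-out accuracy
  d <- dataset_fixture()
  perm <- d
  perm$label <- withr::with_seed(99, sample(perm$label))
  ev <- evaluate_multirun(perm, protocol_config(n_runs = 4, num_trees = 100))
  expect_gt(ev$mean_accuracy, 0.35)
  expect_lt(ev$mean_accuracy, 0.65)
})

test_that("repeated evaluation splits exactly 280/120 per class and scores
           the calibrated dataset near its operating point", {
  d <- dataset_fixture(400, seed = 211)
  ev <- evaluate_multirun(d, protocol_config(n_runs = 2))
  expect_true(all(ev$runs$n_train == 560))
  expect_true(all(ev$runs$n_test == 240))
  expect_identical(sum(ev$confusion), 480L)       # 2 runs x 240 test rows
  g <- glance(ev)
  expect_gt(g$mean_accuracy, 0.55)
  expect_lt(g$mean_accuracy, 0.85)
  expect_identical(nrow(tidy(ev)), 2L)
})

test_that("indistinguishable classes score at chance", {
  d0 <- generate_event_spectra(300, generator_config(separation = 0, seed = 17),
                               composition = c(OT = 0.5, VP = 0.5),
                               exact = TRUE)
  ev <- evaluate_multirun(d0, protocol_config(n_runs = 4, num_trees = 100))
  se <- ev$sd_accuracy / sqrt(4)
  expect_lt(abs(ev$mean_accuracy - 0.5), max(3 * se, 0.1))
})

test_that("accuracy rises monotonically with class separation", {
  accs <- vapply(c(0, 0.9, 2.4), function(delta) {
    d <- generate_event_spectra(
      240, generator_config(separation = delta, seed = 19),
      composition = c(OT = 0.5, VP = 0.5), exact = TRUE)
    evaluate_multirun(d, protocol_config(n_runs = 3,
                                         num_trees = 100))$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))  # non-decreasing within MC noise
  expect_gt(accs[3], 0.95)              # saturates at large separation
})

test_that("fits depend on the training fold only", {
  d <- dataset_fixture()
  feat <- spectrum_channels(d)
  x <- as.matrix(d[feat]); y <- d$label
  tr <- withr::with_seed(1, sersflow:::.stratified_split(y, 0.7))
  te <- setdiff(seq_along(y), tr)
  probe <- x[te[1:20], ]
  fit1 <- sersflow:::.fit_pipeline(x[tr, ], y[tr], protocol_config(), seed = 1)
  x2 <- x
  x2[te, ] <- x2[rev(te), ]    # scramble held-out rows
  fit2 <- sersflow:::.fit_pipeline(x2[tr, ], y[tr], protocol_config(), seed = 1)
  expect_identical(fit1$transform, fit2$transform)
  expect_identical(fit1$pca$rotation, fit2$pca$rotation)
  expect_identical(sersflow:::.predict_pipeline(fit1, probe),
                   sersflow:::.predict_pipeline(fit2, probe))
})

test_that("averaging groups same-class spectra and shrinks variance as 1/N", {
  d <- dataset_fixture()
  feat <- spectrum_channels(d)
  a1 <- average_event_spectra(d, 1, seed = 2)
  expect_identical(nrow(a1), nrow(d))
  expect_equal(sort(a1$total_photons), sort(as.numeric(d$total_photons)))

  # one group per class = the class mean, exactly (linearity)
  aN <- average_event_spectra(d, 200, seed = 2)
  ot <- aN[aN$label == "OT", ]
  expect_equal(unlist(ot[1, feat], use.names = FALSE),
               unname(colMeans(as.matrix(d[d$label == "OT", feat]))))
  expect_equal(ot$total_photons[1],
               mean(d$total_photons[d$label == "OT"]))

  pure <- generate_event_spectra(800, generator_config(), seed = 23,
                                 composition = c(OT = 1))
  a4 <- average_event_spectra(pure, 4, seed = 3)
  v1 <- apply(as.matrix(pure[feat]), 2, var)
  v4 <- apply(as.matrix(a4[feat]), 2, var)
  ratio <- mean(v4 / v1)
  expect_gt(ratio, 0.15)
  expect_lt(ratio, 0.40)                  # ~ 1/4 within sampling noise
  expect_error(average_event_spectra(d, 1000), "class size")
})

test_that("the accuracy curve is consistent with single-event evaluation", {
  d <- dataset_fixture()
  cfg <- protocol_config(n_runs = 2, num_trees = 100)
  curve <- accuracy_vs_n(d, cfg, n_grid = c(1, 8), threshold = 0.99)
  ev <- evaluate_multirun(d, cfg)
  expect_equal(curve$curve$mean_accuracy[curve$curve$n_events == 1],
               ev$mean_accuracy)
  acc <- curve$curve$mean_accuracy
  expect_gt(acc[2], acc[1] - 0.05)        # averaging does not hurt
  expect_error(accuracy_vs_n(d, cfg, n_grid = 1000), "infeasible")
})

test_that("the exact majority-vote tail matches its analytic properties", {
  expect_equal(majority_vote_tail(0.705, 1), 0.705)
  for (n in c(2, 5, 8, 41)) expect_equal(majority_vote_tail(0.5, n), 0.5)
  # frozen value, cross-checked against the binomial distribution function
  v <- majority_vote_tail(0.705, 40)
  expect_equal(v, 0.9964975115, tolerance = 1e-9)
  alt <- 1 - pbinom(20, 40, 0.705) + 0.5 * dbinom(20, 40, 0.705)
  expect_equal(v, alt, tolerance = 1e-12)
  expect_gte(v, 0.99)
})
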