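# Supervised discrimination protocol: Yeo-Johnson power transform fitted on
# the training fold, PCA projection to 10 components, random forest, repeated
# stratified 70/30 evaluation, confusion-derived metrics, N-event averaging,
# and the exact majority-vote oracle for the averaging claim.

#' Protocol configuration
#'
#' @param n_components Number of principal components kept (default 10).
#' @param train_fraction Training fraction of each class (default 0.7).
#' @param n_runs Number of repeated random splits (default 10).
#' @param num_trees Random-forest size (default 200 trees).
#' @param mtry Features tried per split; default `floor(sqrt(n_components))`.
#' @param seed Base seed; run `r` uses `seed + r - 1`.
#' @return A validated list of class `protocol_config`.
#' @export
protocol_config <- function(n_components = 10, train_fraction = 0.7,
                            n_runs = 10, num_trees = 200, mtry = NULL,
                            seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_components >= 1,
            n_runs >= 1, num_trees >= 1)
  structure(list(n_components = as.integer(n_components),
                 train_fraction = train_fraction, n_runs = as.integer(n_runs),
                 num_trees = as.integer(num_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

## ---- Yeo-Johnson power transform ------------------------------------------

.yj <- function(x, lambda) {
  pos <- x >= 0
  out <- numeric(length(x))
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (any(!pos)) {
    l2 <- 2 - lambda
    if (abs(l2) > 1e-10) {
      out[!pos] <- -((-x[!pos] + 1)^l2 - 1) / l2
    } else {
      out[!pos] <- -log1p(-x[!pos])
    }
  }
  out
}

.yj_loglik <- function(x, lambda) {
  y <- .yj(x, lambda)
  v <- stats::var(y) * (length(y) - 1) / length(y)
  if (!is.finite(v) || v <= 0) return(-Inf)
  -length(x) / 2 * log(v) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit a Yeo-Johnson power transform on training features
#'
#' Per feature: the Yeo-Johnson transform parameter lambda is fitted by
#' profile maximum likelihood (valid at zero and for negative values), and
#' the transformed training column's mean/SD are stored for standardisation.
#' Constant features are passed through and standardised to zero.
#'
#' @param x Numeric training matrix (rows = spectra, columns = features).
#' @return An object of class `power_transform` (per-feature `lambda`,
#'   `mean`, `sd`).
#' @seealso [apply_power_transform()]
#' @export
fit_power_transform <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  lambda <- numeric(p); mu <- numeric(p); sd_ <- numeric(p)
  for (j in seq_len(p)) {
    xj <- x[, j]
    if (max(xj) == min(xj)) {            # constant feature: skip transform
      lambda[j] <- 1; mu[j] <- xj[1]; sd_[j] <- 1
      next
    }
    opt <- stats::optimize(function(l) .yj_loglik(xj, l),
                           interval = c(-5, 5), maximum = TRUE)
    lambda[j] <- opt$maximum
    yj <- .yj(xj, lambda[j])
    mu[j] <- mean(yj)
    sd_[j] <- stats::sd(yj)
    if (sd_[j] == 0) sd_[j] <- 1
  }
  structure(list(lambda = lambda, mean = mu, sd = sd_), class = "power_transform")
}

#' Apply a fitted power transform
#'
#' Applies the training-fitted Yeo-Johnson parameters and train-mean/SD
#' standardisation to new data (the transform never refits on held-out data).
#'
#' @param fit A `power_transform` from [fit_power_transform()].
#' @param x Numeric matrix with the same columns as the training matrix.
#' @return Transformed, standardised numeric matrix.
#' @export
apply_power_transform <- function(fit, x) {
  stopifnot(inherits(fit, "power_transform"))
  x <- as.matrix(x)
  if (ncol(x) != length(fit$lambda))
    stop("column count differs from the fitted transform", call. = FALSE)
  out <- matrix(0, nrow = nrow(x), ncol = ncol(x))
  for (j in seq_len(ncol(x)))
    out[, j] <- (.yj(x[, j], fit$lambda[j]) - fit$mean[j]) / fit$sd[j]
  out
}

## ---- PCA -------------------------------------------------------------------

#' Fit a PCA projection on training features
#'
#' @param x Transformed training matrix.
#' @param k Number of components (<= min(n_train, n_features)).
#' @return List of class `pca_projection`: `rotation`, `center`,
#'   `explained_variance` (per-component fractions, all components).
#' @export
fit_pca <- function(x, k = 10) {
  x <- as.matrix(x)
  if (k > min(nrow(x), ncol(x)))
    stop("`k` exceeds min(n samples, n features)", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center,
                 explained_variance = pc$sdev^2 / sum(pc$sdev^2),
                 k = as.integer(k)),
            class = "pca_projection")
}

#' Project data onto a fitted PCA basis
#'
#' @param fit A `pca_projection` from [fit_pca()].
#' @param x Matrix with the same columns as the training matrix.
#' @return Score matrix (`n x k`), columns `PC1..PCk`.
#' @export
project_pca <- function(fit, x) {
  stopifnot(inherits(fit, "pca_projection"))
  scores <- sweep(as.matrix(x), 2, fit$center) %*% fit$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Per-class centroid diagnostics in PC space
#'
#' Centroid positions and per-axis variances of each class in the first two
#' principal components, plus pairwise centroid separation distances.
#'
#' @param scores Score matrix or data frame with at least `PC1`, `PC2`.
#' @param labels Class label per row.
#' @return List of class `centroid_diagnostics`: `centroids` tibble (`label`,
#'   `pc1`, `pc2`, `var_pc1`, `var_pc2`, `n`), `separation` tibble of
#'   pairwise distances, and `degenerate` flag (single class).
#' @export
centroid_diagnostics <- function(scores, labels) {
  scores <- as.data.frame(scores)
  stopifnot(all(c("PC1", "PC2") %in% names(scores)),
            nrow(scores) == length(labels))
  cent <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(label = labels,
                                   PC1 = scores$PC1, PC2 = scores$PC2),
                    .data$label),
    pc1 = mean(.data$PC1), pc2 = mean(.data$PC2),
    var_pc1 = stats::var(.data$PC1), var_pc2 = stats::var(.data$PC2),
    n = dplyr::n(), .groups = "drop")
  degenerate <- nrow(cent) < 2
  sep <- if (degenerate) {
    tibble::tibble(label_a = character(), label_b = character(),
                   distance = numeric())
  } else {
    pairs <- utils::combn(seq_len(nrow(cent)), 2)
    tibble::tibble(
      label_a = cent$label[pairs[1, ]], label_b = cent$label[pairs[2, ]],
      distance = sqrt((cent$pc1[pairs[1, ]] - cent$pc1[pairs[2, ]])^2 +
                        (cent$pc2[pairs[1, ]] - cent$pc2[pairs[2, ]])^2))
  }
  structure(list(centroids = cent, separation = sep, degenerate = degenerate),
            class = "centroid_diagnostics")
}

## ---- Random forest ---------------------------------------------------------

#' Train the random-forest classifier
#'
#' Bagged ensemble of randomised decision trees (via \pkg{ranger}) on the PC
#' scores, grown as a probability forest: prediction averages the per-tree
#' class probabilities and takes the arg-max (soft voting, with a fixed
#' first-class tie-break), which keeps prediction deterministic given `seed`
#' even when hard per-tree votes would tie.
#'
#' @param features Numeric matrix of input features (PC scores).
#' @param labels Class label per row (>= 2 distinct classes).
#' @param cfg A [protocol_config()] (forest size, mtry).
#' @param seed Integer seed for the forest.
#' @return A fitted `ranger` object.
#' @export
train_forest <- function(features, labels, cfg = protocol_config(), seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("training labels must contain at least two classes", call. = FALSE)
  df <- as.data.frame(features)
  df$.class <- droplevels(labels)
  mtry <- cfg$mtry %||% max(1L, floor(sqrt(ncol(features))))
  ranger::ranger(dependent.variable.name = ".class", data = df,
                 num.trees = cfg$num_trees, mtry = mtry,
                 probability = TRUE, seed = seed, num.threads = 1,
                 respect.unordered.factors = TRUE)
}

.predict_forest <- function(model, features) {
  prob <- stats::predict(model, data = as.data.frame(features),
                         num.threads = 1)$predictions
  colnames(prob)[max.col(prob, ties.method = "first")]
}

# Fit transform + PCA + forest on a training fold. Everything is fitted on
# the training rows only; held-out data never touch the fit.
.fit_pipeline <- function(x_train, y_train, cfg, seed) {
  pt <- fit_power_transform(x_train)
  xt <- apply_power_transform(pt, x_train)
  pca <- fit_pca(xt, k = min(cfg$n_components, nrow(xt), ncol(xt)))
  sc <- project_pca(pca, xt)
  rf <- train_forest(sc, y_train, cfg, seed = seed)
  list(transform = pt, pca = pca, forest = rf)
}

.predict_pipeline <- function(fit, x) {
  xt <- apply_power_transform(fit$transform, x)
  sc <- project_pca(fit$pca, xt)
  .predict_forest(fit$forest, sc)
}

# Stratified split: per class, floor(train_fraction * n) training rows.
.stratified_split <- function(labels, train_fraction) {
  train <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- floor(train_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop("split leaves an empty train or test class", call. = FALSE)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

## ---- Metrics ---------------------------------------------------------------

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 from TP/TN/FP/FN:
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2*precision*recall/(precision+recall)`.
#' Degenerate denominators (e.g. `TP+FP = 0`) yield 0 with `degenerate =
#' TRUE`. Vectorised over counts.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Tibble with `tp`, `tn`, `fp`, `fn`, `accuracy`, `precision`,
#'   `recall`, `f1`, `degenerate`.
#' @export
#' @examples
#' metrics_from_confusion(50, 40, 10, 20)
metrics_from_confusion <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- tp + tn + fp + fn
  if (any(total == 0)) stop("TP+TN+FP+FN must be > 0", call. = FALSE)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / total, precision = precision, recall = recall,
    f1 = f1,
    degenerate = (tp + fp == 0) | (tp + fn == 0) | (precision + recall == 0))
}

.confusion_onevsrest <- function(truth, pred, classes) {
  res <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    dplyr::mutate(metrics_from_confusion(tp, tn, fp, fn), class = cl,
                  .before = 1)
  })
  dplyr::bind_rows(res)
}

## ---- Repeated evaluation ---------------------------------------------------

#' Repeated stratified 70/30 evaluation of the discrimination protocol
#'
#' For each run: a stratified random train/test split, then power transform,
#' PCA and random forest are fitted on the training fold only and evaluated
#' on the held-out fold. Reports per-run and mean metrics, per-class
#' one-vs-rest confusion counts, and the aggregated confusion matrix.
#'
#' @param data Spectrum table with a `label` column and `c<j>` channel
#'   columns (see [generate_event_spectra()] / [extract_events()]).
#' @param cfg A [protocol_config()].
#' @return Object of class `sers_eval` with elements `runs` (per-run
#'   metrics), `per_class` (aggregated one-vs-rest counts and metrics),
#'   `confusion` (summed truth x prediction matrix), `mean_accuracy`,
#'   `sd_accuracy`, `cfg`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' d <- generate_event_spectra(120, generator_config(separation = 1.5), seed = 1)
#' ev <- evaluate_multirun(d, protocol_config(n_runs = 2))
#' glance(ev)
evaluate_multirun <- function(data, cfg = protocol_config()) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  feat <- spectrum_channels(data)
  if (length(feat) == 0) stop("no channel columns found", call. = FALSE)
  labels <- as.character(data$label)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("`data` must contain at least two classes", call. = FALSE)
  x <- as.matrix(data[feat])

  runs <- vector("list", cfg$n_runs)
  per_class_runs <- vector("list", cfg$n_runs)
  confusion <- matrix(0L, nrow = length(classes), ncol = length(classes),
                      dimnames = list(truth = classes, prediction = classes))
  for (r in seq_len(cfg$n_runs)) {
    seed_r <- cfg$seed + r - 1L
    tr <- withr::with_seed(seed_r,
                           .stratified_split(labels, cfg$train_fraction))
    fit <- .fit_pipeline(x[tr, , drop = FALSE], labels[tr], cfg, seed = seed_r)
    te <- setdiff(seq_along(labels), tr)
    pred <- .predict_pipeline(fit, x[te, , drop = FALSE])
    truth <- labels[te]
    confusion <- confusion + table(factor(truth, classes),
                                   factor(pred, classes))
    pc <- .confusion_onevsrest(truth, pred, classes)
    per_class_runs[[r]] <- dplyr::mutate(pc, run = r, .before = 1)
    runs[[r]] <- tibble::tibble(
      run = r, seed = seed_r, n_train = length(tr), n_test = length(te),
      accuracy = mean(truth == pred),
      macro_precision = mean(pc$precision), macro_recall = mean(pc$recall),
      macro_f1 = mean(pc$f1))
  }
  runs <- dplyr::bind_rows(runs)
  per_class <- dplyr::bind_rows(per_class_runs) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(c("tp", "tn", "fp", "fn"), sum),
                     .groups = "drop")
  per_class <- dplyr::bind_cols(
    per_class["class"],
    metrics_from_confusion(per_class$tp, per_class$tn, per_class$fp,
                           per_class$fn))
  structure(
    list(runs = runs, per_class = per_class, confusion = confusion,
         mean_accuracy = mean(runs$accuracy),
         sd_accuracy = stats::sd(runs$accuracy), cfg = cfg),
    class = "sers_eval")
}

#' @export
print.sers_eval <- function(x, ...) {
  cat(sprintf("<sers_eval> %d runs: mean accuracy %.3f (sd %.3f)\n",
              nrow(x$runs), x$mean_accuracy, x$sd_accuracy))
  print(x$confusion)
  invisible(x)
}

## ---- Averaging -------------------------------------------------------------

#' Average groups of same-class event spectra
#'
#' Forms disjoint groups of `n_events` same-class spectra (sampled without
#' replacement) and replaces each group by its channel-wise arithmetic mean,
#' preserving labels. Averaging raises the effective signal-to-noise ratio of
#' each classified item.
#'
#' @param data Spectrum table with `label` and channel columns.
#' @param n_events Events averaged per output spectrum (>= 1).
#' @param n_groups Output spectra per class; default as many disjoint groups
#'   as the class size allows.
#' @param seed Optional seed for the grouping.
#' @return Spectrum table of averaged (real-valued) spectra.
#' @export
average_event_spectra <- function(data, n_events, n_groups = NULL,
                                  seed = NULL) {
  stopifnot(is.data.frame(data), "label" %in% names(data), n_events >= 1)
  feat <- spectrum_channels(data)
  min_class <- min(table(data$label))
  if (n_events > min_class)
    stop("`n_events` exceeds the smallest class size", call. = FALSE)
  run <- function() {
    out <- lapply(split(seq_len(nrow(data)), data$label), function(idx) {
      g_max <- length(idx) %/% n_events
      g <- min(n_groups %||% g_max, g_max)
      pick <- sample(idx, g * n_events)
      grp <- rep(seq_len(g), each = n_events)
      m <- unname(rowsum(as.matrix(data[pick, feat]), grp)) / n_events
      colnames(m) <- feat
      lab <- data$label[idx[1]]
      res <- tibble::tibble(
        event_id = sprintf("avg_%s_%03d", lab, seq_len(g)),
        label = lab, true_label = lab,
        start_frame = NA_integer_, end_frame = NA_integer_,
        total_photons = rowSums(m))  # mean of member totals, by linearity
      dplyr::bind_cols(res, tibble::as_tibble(as.data.frame(m)))
    })
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Accuracy as a function of the number of averaged events
#'
#' For each value of `n_events`: repeated stratified splits of the raw
#' spectra, then averaging applied *within the train and test folds
#' separately* (after the split, so no group ever mixes folds), then the
#' standard transform/PCA/forest pipeline. Returns the accuracy curve and the
#' smallest `n_events` whose mean accuracy reaches `threshold`.
#'
#' @param data Spectrum table with `label` and channel columns.
#' @param cfg A [protocol_config()].
#' @param n_grid Integer grid of events-per-average values.
#' @param threshold Target accuracy for the crossing point (default 0.99).
#' @return Object of class `accuracy_curve`: `curve` (per-`n_events` mean/sd
#'   accuracy), `runs`, `n_at_threshold` (NA if never reached), `threshold`.
#' @export
accuracy_vs_n <- function(data, cfg = protocol_config(),
                          n_grid = c(1, 5, 10, 20, 40), threshold = 0.99) {
  stopifnot(all(n_grid >= 1))
  labels <- as.character(data$label)
  feat <- spectrum_channels(data)
  x <- as.matrix(data[feat])
  min_class <- min(table(labels))
  if (max(n_grid) > floor(cfg$train_fraction * min_class))
    stop("`n_grid` infeasible for the class sizes at this split", call. = FALSE)

  all_runs <- list()
  for (n_ev in sort(unique(as.integer(n_grid)))) {
    for (r in seq_len(cfg$n_runs)) {
      seed_r <- cfg$seed + r - 1L
      tr <- withr::with_seed(seed_r,
                             .stratified_split(labels, cfg$train_fraction))
      te <- setdiff(seq_along(labels), tr)
      if (n_ev == 1) {
        xtr <- x[tr, , drop = FALSE]; ytr <- labels[tr]
        xte <- x[te, , drop = FALSE]; yte <- labels[te]
      } else {
        dtr <- average_event_spectra(data[tr, ], n_ev, seed = seed_r)
        dte <- average_event_spectra(data[te, ], n_ev, seed = seed_r + 5000L)
        xtr <- as.matrix(dtr[feat]); ytr <- dtr$label
        xte <- as.matrix(dte[feat]); yte <- dte$label
      }
      fit <- .fit_pipeline(xtr, ytr, cfg, seed = seed_r)
      pred <- .predict_pipeline(fit, xte)
      all_runs[[length(all_runs) + 1L]] <- tibble::tibble(
        n_events = n_ev, run = r, n_test = length(yte),
        accuracy = mean(pred == yte))
    }
  }
  runs <- dplyr::bind_rows(all_runs)
  curve <- runs |>
    dplyr::group_by(.data$n_events) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     n_test_total = sum(.data$n_test), .groups = "drop")
  crossed <- curve$n_events[curve$mean_accuracy >= threshold]
  structure(
    list(curve = curve, runs = runs,
         n_at_threshold = if (length(crossed)) min(crossed) else NA_integer_,
         threshold = threshold),
    class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat("<accuracy_curve>\n")
  print(x$curve)
  cat(sprintf("  first n_events with mean accuracy >= %.2f: %s\n",
              x$threshold, x$n_at_threshold))
  invisible(x)
}

#' Exact majority-vote accuracy over N events
#'
#' Probability that a majority vote over `n` independent single-event
#' classifications, each correct with probability `p`, returns the correct
#' class; an even-split tie is broken at random (half weight). Exact binomial
#' tail summation.
#'
#' @param p Per-event accuracy in `[0, 1]`.
#' @param n Number of events (>= 1).
#' @return Probability of a correct majority decision.
#' @export
#' @examples
#' majority_vote_tail(0.705, 40)
majority_vote_tail <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 1, n == round(n))
  k <- seq(floor(n / 2) + 1, n)
  tail <- sum(stats::dbinom(k, n, p))
  if (n %% 2 == 0) tail <- tail + 0.5 * stats::dbinom(n / 2, n, p)
  tail
}
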