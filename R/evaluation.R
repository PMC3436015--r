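#' Multiclass accuracy
#'
#' @param predictions,truth equal-length class id vectors.
#' @return fraction of exact matches.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  if (length(truth) == 0) stop("empty inputs")
  mean(predictions == truth)
}

#' Robustness experiment configuration
#'
#' @param kind noise kind, `"rotational"` (levels in degrees) or
#'   `"additive"` (levels in mG).
#' @param levels noise level grid; must contain 0 (the clean baseline).
#' @param S disturbed-sensor count (fusion experiments) or the sensor id
#'   under test (single-sensor experiments).
#' @param repetitions number of repeated random train/test splits.
#' @param train_frac fraction of windows used for training (the rest is the
#'   disturbed test partition).
#' @param seed master seed; repetition r uses seed `seed + r`.
#' @param granularity rotational angle resampling: `"window"` or `"run"`.
#' @param swnc a [swnc_config()].
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("rotational", "additive"),
                              levels, S = 1L, repetitions = 100L,
                              train_frac = 0.7, seed = 1L,
                              granularity = c("window", "run"),
                              swnc = swnc_config()) {
  kind <- match.arg(kind)
  granularity <- match.arg(granularity)
  if (!0 %in% levels) stop("the level grid must contain 0 (clean baseline)")
  if (any(levels < 0)) stop("levels must be >= 0")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  structure(list(kind = kind, levels = sort(unique(as.numeric(levels))),
                 S = as.integer(S), repetitions = as.integer(repetitions),
                 train_frac = as.numeric(train_frac), seed = as.integer(seed),
                 granularity = granularity, swnc = swnc),
            class = "experiment_config")
}

#' Stratified train/test split
#'
#' Splits window indices into a training and a test partition, sampling the
#' training fraction independently within every class so the class
#' distribution is preserved (each class keeps at least one window on each
#' side). Uses the current RNG state.
#'
#' @param labels integer class label per window.
#' @param train_frac training fraction in (0, 1).
#' @return list with sorted integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac) {
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    ntr <- round(train_frac * length(idx))
    ntr <- max(1L, min(length(idx) - 1L, ntr))
    train <- c(train, idx[seq_len(ntr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

make_curve <- function(samples, levels, kind, target) {
  # samples: repetitions x levels accuracy matrix
  curve <- data.frame(level = levels,
                      mean = colMeans(samples),
                      sd = apply(samples, 2, stats::sd),
                      reps = nrow(samples))
  if (nrow(samples) == 1) curve$sd <- 0
  structure(curve, class = c("robustness_curve", "data.frame"),
            kind = kind, target = target, samples = samples)
}

# Shared evaluation engine. Per repetition: one stratified split, one model
# fit on clean training windows, then for every noise level the test windows
# of each sensor are disturbed once and reused by both the single-sensor
# curves (node-level decisions) and every fusion configuration (weighted
# network decisions with the disturbed sensors' scores substituted in).
robustness_engine <- function(dataset, kind, levels, repetitions, train_frac,
                              seed, granularity, swnc_cfg,
                              singles = integer(0), S_values = integer(0)) {
  M <- n_sensors(dataset)
  nlev <- length(levels)
  acc_single <- lapply(singles, function(m) matrix(0, repetitions, nlev))
  names(acc_single) <- as.character(singles)
  acc_fusion <- lapply(S_values, function(s) matrix(0, repetitions, nlev))
  names(acc_fusion) <- as.character(S_values)
  train_disturbed <- 0L
  need_disturb <- sort(unique(c(singles,
                                if (length(S_values) && max(S_values) > 0) seq_len(M))))

  for (r in seq_len(repetitions)) {
    set.seed(seed + r)
    sp <- stratified_split(dataset$label, train_frac)
    train_set <- subset_windows(dataset, sp$train)
    test_set <- subset_windows(dataset, sp$test)
    train_disturbed <- train_disturbed + sum(train_set$disturbed)
    model <- swnc_fit(train_set, swnc_cfg)
    clean_feats <- lapply(seq_len(M), function(m)
      feature_matrix(test_set, m, swnc_cfg$bank)$features)
    truth <- test_set$label

    for (li in seq_len(nlev)) {
      lev <- levels[li]
      feats <- clean_feats
      if (lev > 0) {
        for (m in need_disturb) {
          spec <- disturbance_spec(kind, lev, m, granularity)
          dset <- disturb(test_set, spec)
          feats[[m]] <- feature_matrix(dset, m, swnc_cfg$bank)$features
        }
      }
      clean_scores <- NULL
      dist_scores <- vector("list", M)
      get_scores <- function(m, disturbed) {
        if (disturbed) {
          if (is.null(dist_scores[[m]]))
            dist_scores[[m]] <<- node_scores(model$nodes[[m]], feats[[m]],
                                             swnc_cfg$encoding)
          dist_scores[[m]]
        } else {
          if (is.null(clean_scores)) clean_scores <<- vector("list", M)
          if (is.null(clean_scores[[m]]))
            clean_scores[[m]] <<- node_scores(model$nodes[[m]], clean_feats[[m]],
                                              swnc_cfg$encoding)
          clean_scores[[m]]
        }
      }
      for (m in singles) {
        sc <- get_scores(m, disturbed = TRUE)
        acc_single[[as.character(m)]][r, li] <-
          accuracy(max.col(sc, ties.method = "first"), truth)
      }
      for (s in S_values) {
        D <- if (s > 0) sort(sample.int(M, s)) else integer(0)
        net <- 0
        for (m in seq_len(M))
          net <- net + model$mu[m] * get_scores(m, disturbed = m %in% D && lev > 0)
        acc_fusion[[as.character(s)]][r, li] <-
          accuracy(max.col(net, ties.method = "first"), truth)
      }
    }
  }

  singles_curves <- lapply(singles, function(m)
    make_curve(acc_single[[as.character(m)]], levels, kind,
               paste0("sensor ", m)))
  names(singles_curves) <- as.character(singles)
  fusion_curves <- lapply(S_values, function(s)
    make_curve(acc_fusion[[as.character(s)]], levels, kind,
               paste0("fusion S=", s)))
  names(fusion_curves) <- as.character(S_values)
  list(single = singles_curves, fusion = fusion_curves,
       train_windows_disturbed = train_disturbed)
}

#' Single-sensor robustness curve
#'
#' For each repetition: a fresh stratified train/test split, a one-node
#' recognition pipeline fitted on clean training windows of sensor
#' `config$S`, and test windows of that sensor disturbed at every grid
#' level. Reports mean accuracy and its standard deviation per level.
#'
#' @param dataset a [signal_set()].
#' @param sensor sensor id under test (overrides `config$S` if given).
#' @param config an [experiment_config()].
#' @return a `robustness_curve` data frame (columns `level`, `mean`, `sd`,
#'   `reps`) with the per-repetition accuracy matrix in `attr(, "samples")`.
#' @export
run_single_sensor <- function(dataset, sensor = NULL, config) {
  stopifnot(inherits(dataset, "signal_set"), inherits(config, "experiment_config"))
  m <- if (is.null(sensor)) config$S else as.integer(sensor)
  if (!m %in% seq_len(n_sensors(dataset))) stop("unknown sensor id ", m)
  one <- subset_sensors(dataset, m)
  res <- robustness_engine(one, config$kind, config$levels, config$repetitions,
                           config$train_frac, config$seed, config$granularity,
                           config$swnc, singles = 1L)
  curve <- res$single[[1]]
  attr(curve, "target") <- paste0("sensor ", m)
  attr(curve, "train_windows_disturbed") <- res$train_windows_disturbed
  curve
}

#' Fused-network robustness curve
#'
#' As [run_single_sensor()], but fitting the full M-sensor network and, per
#' repetition and level, disturbing a freshly drawn random subset of
#' `config$S` sensors in the test partition only.
#'
#' @inheritParams run_single_sensor
#' @return a `robustness_curve` data frame.
#' @export
run_fusion <- function(dataset, config) {
  stopifnot(inherits(dataset, "signal_set"), inherits(config, "experiment_config"))
  if (config$S > n_sensors(dataset))
    stop("S cannot exceed the sensor count ", n_sensors(dataset))
  res <- robustness_engine(dataset, config$kind, config$levels,
                           config$repetitions, config$train_frac, config$seed,
                           config$granularity, config$swnc,
                           S_values = config$S)
  curve <- res$fusion[[1]]
  attr(curve, "train_windows_disturbed") <- res$train_windows_disturbed
  curve
}

#' Compare a fusion curve against single-sensor curves
#'
#' @param fused a fusion `robustness_curve`.
#' @param singles list of single-sensor `robustness_curve`s on the same
#'   level grid.
#' @return data frame, one row per level: fused mean, best / mean / worst
#'   single-sensor means, their differences from the fused mean, and a flag
#'   marking levels where fusion underperforms the best single sensor.
#' @export
compare_curves <- function(fused, singles) {
  if (!length(singles)) stop("need at least one single-sensor curve")
  for (s in singles)
    if (!isTRUE(all.equal(s$level, fused$level)))
      stop("level grids do not match")
  sm <- vapply(singles, function(s) s$mean, numeric(nrow(fused)))
  if (is.null(dim(sm))) sm <- matrix(sm, nrow = 1)
  data.frame(
    level = fused$level,
    fused = fused$mean,
    best_single = apply(sm, 1, max),
    mean_single = rowMeans(sm),
    worst_single = apply(sm, 1, min),
    fused_minus_best = fused$mean - apply(sm, 1, max),
    fused_minus_mean = fused$mean - rowMeans(sm),
    underperforms_best = fused$mean < apply(sm, 1, max)
  )
}

#' Full robustness sweep
#'
#' Runs the complete factorial study: for each noise kind, single-sensor
#' curves for every sensor and fusion curves for every requested S, all
#' sharing one model fit and one disturbance realization per repetition so
#' the comparisons are paired. Results are reproducible from the master
#' seed (repetition r uses seed `seed + r`).
#'
#' @param dataset a [signal_set()].
#' @param rotational rotational level grid in degrees (must contain 0); the
#'   defaults embed the commonly discussed 15 / 30 / 90 degree levels.
#' @param additive additive level grid in mG (must contain 0).
#' @param S_values fusion disturbed-sensor counts (default 1..M).
#' @param repetitions repeated random splits per configuration.
#' @param train_frac training fraction per split.
#' @param seed master seed.
#' @param granularity rotational angle resampling granularity.
#' @param swnc a [swnc_config()].
#' @return list of class `swnc_sweep`: per kind, the single-sensor and
#'   fusion curves plus fusion-vs-single comparison tables, and provenance
#'   counters.
#' @export
run_sweep <- function(dataset,
                      rotational = c(0, 15, 30, 45, 90, 180),
                      additive = c(0, 50, 100, 200, 500),
                      S_values = NULL, repetitions = 100L, train_frac = 0.7,
                      seed = 1L, granularity = c("window", "run"),
                      swnc = swnc_config()) {
  stopifnot(inherits(dataset, "signal_set"))
  granularity <- match.arg(granularity)
  M <- n_sensors(dataset)
  if (is.null(S_values)) S_values <- seq_len(M)
  grids <- list(rotational = sort(unique(as.numeric(rotational))),
                additive = sort(unique(as.numeric(additive))))
  out <- list()
  for (kind in names(grids)) {
    res <- robustness_engine(dataset, kind, grids[[kind]], repetitions,
                             train_frac, seed, granularity, swnc,
                             singles = seq_len(M), S_values = S_values)
    comparisons <- lapply(res$fusion, compare_curves, singles = res$single)
    out[[kind]] <- list(single = res$single, fusion = res$fusion,
                        comparison = comparisons,
                        train_windows_disturbed = res$train_windows_disturbed)
  }
  structure(c(out, list(seed = seed, repetitions = repetitions,
                        S_values = S_values, granularity = granularity)),
            class = "swnc_sweep")
}

#' Plot robustness curves
#'
#' Accuracy versus noise level with error bars of one standard deviation,
#' one line per curve.
#'
#' @param curves named list of `robustness_curve` objects on a common kind.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_robustness <- function(curves, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_robustness requires ggplot2")
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    d <- as.data.frame(curves[[nm]])
    d$curve <- if (nzchar(nm)) attr(curves[[nm]], "target") %||% nm else nm
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$mean,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.02 * max(df$level)) +
    ggplot2::labs(x = "noise level", y = "accuracy", title = title) +
    ggplot2::ylim(0, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
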