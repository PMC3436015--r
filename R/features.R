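#' Default feature bank
#'
#' A representative time/frequency-domain feature catalogue for biaxial
#' acceleration windows. Per axis: mean, standard deviation, variance,
#' median, min, max, range, RMS, mean absolute deviation, zero-crossing
#' count about the mean, signal magnitude area contribution (mean absolute
#' value), spectral energy, normalized spectral entropy, dominant frequency,
#' and the first five non-DC FFT magnitude coefficients; cross-axis: Pearson
#' correlation and covariance. 40 features in total.
#'
#' Every function is total on finite windows of length >= 2: correlation of
#' a constant axis is defined as 0, and spectral features of an all-zero
#' spectrum return 0 (entropy) or the first bin frequency (dominant
#' frequency).
#'
#' @return Named list of functions `f(x, y, rate) -> numeric(1)`, the
#'   calling convention every [extract_features()] bank must follow.
#' @export
default_feature_bank <- function() {
  spec_mag <- function(v) {
    n <- length(v)
    Mod(stats::fft(v))[seq(2L, floor(n / 2) + 1L)] / n
  }
  axis_feats <- function(get) {
    list(
      mean   = function(x, y, rate) mean(get(x, y)),
      sd     = function(x, y, rate) stats::sd(get(x, y)),
      var    = function(x, y, rate) stats::var(get(x, y)),
      median = function(x, y, rate) stats::median(get(x, y)),
      min    = function(x, y, rate) min(get(x, y)),
      max    = function(x, y, rate) max(get(x, y)),
      range  = function(x, y, rate) diff(range(get(x, y))),
      rms    = function(x, y, rate) sqrt(mean(get(x, y)^2)),
      mad    = function(x, y, rate) { v <- get(x, y); mean(abs(v - mean(v))) },
      zcr    = function(x, y, rate) {
        v <- get(x, y) - mean(get(x, y))
        sum(v[-1] * v[-length(v)] < 0)
      },
      sma    = function(x, y, rate) mean(abs(get(x, y))),
      energy = function(x, y, rate) sum(spec_mag(get(x, y))^2),
      sentropy = function(x, y, rate) {
        p <- spec_mag(get(x, y))^2
        s <- sum(p)
        if (s <= 0) return(0)
        p <- p / s
        p <- p[p > 0]
        -sum(p * log(p)) / log(max(length(spec_mag(get(x, y))), 2))
      },
      domfreq = function(x, y, rate) {
        m <- spec_mag(get(x, y))
        which.max(m) * rate / length(get(x, y))
      },
      fft1 = function(x, y, rate) spec_mag(get(x, y))[1],
      fft2 = function(x, y, rate) spec_mag(get(x, y))[2],
      fft3 = function(x, y, rate) spec_mag(get(x, y))[3],
      fft4 = function(x, y, rate) spec_mag(get(x, y))[4],
      fft5 = function(x, y, rate) spec_mag(get(x, y))[5]
    )
  }
  fx <- axis_feats(function(x, y) x)
  fy <- axis_feats(function(x, y) y)
  names(fx) <- paste0("x_", names(fx))
  names(fy) <- paste0("y_", names(fy))
  c(fx, fy, list(
    xy_cor = function(x, y, rate) {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
      stats::cor(x, y)
    },
    xy_cov = function(x, y, rate) stats::cov(x, y)
  ))
}

#' Segment a continuous stream into fixed-length windows
#'
#' Windows have exactly `floor(duration * rate)` samples; consecutive start
#' offsets are spaced by `floor(len * (1 - overlap))` samples and a trailing
#' partial window is discarded. A stream shorter than one window yields an
#' empty list.
#'
#' @param x,y numeric sample vectors of equal length.
#' @param rate sampling rate in Hz.
#' @param duration window duration in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return list of windows, each a list with elements `x` and `y`.
#' @export
sliding_window <- function(x, y, rate, duration, overlap = 0) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  len <- floor(duration * rate)
  if (len < 2) stop("duration * rate must be >= 2")
  step <- floor(len * (1 - overlap))
  if (step < 1) stop("overlap too large for this window length")
  if (length(x) < len) return(list())
  starts <- seq(1L, length(x) - len + 1L, by = step)
  lapply(starts, function(s) {
    idx <- s:(s + len - 1L)
    list(x = x[idx], y = y[idx])
  })
}

#' Extract a feature vector from one window
#'
#' Applies every bank function to the window, in bank order. Any non-finite
#' result aborts with an error naming the offending feature, so downstream
#' matrices are guaranteed finite.
#'
#' @param x,y numeric sample vectors (length >= 2).
#' @param rate sampling rate in Hz.
#' @param bank named list of feature functions, e.g. [default_feature_bank()].
#' @return named numeric vector, one entry per bank feature.
#' @export
extract_features <- function(x, y, rate, bank = default_feature_bank()) {
  if (length(x) < 2) stop("window must have at least 2 samples")
  out <- vapply(bank, function(f) f(x, y, rate), numeric(1))
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value for: ",
         paste(names(bank)[bad], collapse = ", "))
  out
}

#' Feature matrix for one sensor of a signal set
#'
#' @param set a [signal_set()].
#' @param sensor sensor id.
#' @param bank feature bank (named list of functions).
#' @return object of class `feature_matrix`: list with `features`
#'   (windows x features numeric matrix, named columns), `label` (integer
#'   class per row) and `sensor` (provenance).
#' @export
feature_matrix <- function(set, sensor, bank = default_feature_bank()) {
  stopifnot(inherits(set, "signal_set"))
  if (!sensor %in% seq_len(n_sensors(set))) stop("unknown sensor id ", sensor)
  nw <- n_windows(set)
  X <- matrix(0, nw, length(bank), dimnames = list(NULL, names(bank)))
  xs <- set$x[[sensor]]; ys <- set$y[[sensor]]
  for (w in seq_len(nw))
    X[w, ] <- extract_features(xs[w, ], ys[w, ], set$rate, bank)
  structure(list(features = X, label = set$label, sensor = as.integer(sensor)),
            class = "feature_matrix")
}

#' Rank-statistic ROC AUC
#'
#' AUC of a single feature for a binary split, computed by the Mann-Whitney
#' rank formulation with ties sharing mid-ranks: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param values numeric feature values.
#' @param positive logical vector, `TRUE` for the target class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(values, positive) {
  stopifnot(length(values) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank features by one-vs-rest ROC separability
#'
#' Scores every feature by `|AUC - 0.5|` for the problem "class n vs the
#' rest", so both positively and negatively associated features rank as
#' informative. Features are ordered by score descending, ties broken by
#' bank (column) order.
#'
#' @param fm a [feature_matrix()].
#' @param class_n target class id.
#' @return data frame with columns `feature`, `auc`, `score`, ordered by
#'   decreasing score.
#' @export
roc_rank <- function(fm, class_n) {
  stopifnot(inherits(fm, "feature_matrix"))
  pos <- fm$label == class_n
  if (all(pos) || !any(pos))
    stop("both the target class and its complement must be present")
  auc <- apply(fm$features, 2, auc_rank, positive = pos)
  score <- abs(auc - 0.5)
  ord <- order(-score, seq_along(score))  # ties keep bank order
  data.frame(feature = colnames(fm$features)[ord], auc = auc[ord],
             score = score[ord], row.names = NULL)
}

#' Truncate a feature ranking to the top L entries
#'
#' @param ranking a ranking data frame from [roc_rank()].
#' @param L number of features to keep (>= 1); clamped to the bank size.
#' @return the first `min(L, nrow(ranking))` rows.
#' @export
select_top <- function(ranking, L) {
  if (L < 1) stop("L must be >= 1")
  utils::head(ranking, min(L, nrow(ranking)))
}
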