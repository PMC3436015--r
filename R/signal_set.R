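#' Labeled multi-sensor biaxial signal set
#'
#' The universal container for windowed accelerometer data: for each of M
#' sensors it holds two `windows x samples` matrices (X and Y axis, in G),
#' plus one activity label and one subject id per window. Window rows are
#' aligned across sensors: row `i` of every sensor matrix was recorded
#' simultaneously, so a classifier fusing sensors sees consistent instances.
#'
#' @param x,y lists of M numeric matrices, `n_windows x n_samples`, in G.
#' @param label integer vector of per-window activity class ids (1..N).
#' @param subject integer vector of per-window subject ids.
#' @param sensors data frame with columns `sensor` (1..M), `name`,
#'   `mobility` (see [sensor_placements()]).
#' @param rate sampling rate in Hz.
#' @param disturbed optional `n_windows x M` logical matrix flagging windows
#'   that have passed through [disturb()]; used as a provenance guard so that
#'   evaluation code can prove training data was never disturbed.
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(x, y, label, subject, sensors, rate, disturbed = NULL) {
  stopifnot(is.list(x), is.list(y), length(x) == length(y))
  M <- length(x)
  if (M < 1) stop("at least one sensor is required")
  nw <- nrow(x[[1]])
  ns <- ncol(x[[1]])
  for (m in seq_len(M)) {
    if (!is.matrix(x[[m]]) || !is.matrix(y[[m]]))
      stop("sensor ", m, ": x and y must be matrices (windows x samples)")
    if (nrow(x[[m]]) != nw || nrow(y[[m]]) != nw)
      stop("sensor ", m, ": window count differs across sensors")
    if (ncol(x[[m]]) != ns || ncol(y[[m]]) != ns)
      stop("sensor ", m, ": all windows must have equal sample count")
  }
  label <- as.integer(label)
  subject <- as.integer(subject)
  if (length(label) != nw || length(subject) != nw)
    stop("label and subject must have one entry per window")
  if (nw > 0 && any(is.na(label) | label < 1L))
    stop("labels must be positive integers")
  if (!is.data.frame(sensors) || nrow(sensors) != M)
    stop("sensors must be a data frame with one row per sensor")
  if (!identical(as.integer(sensors$sensor), seq_len(M)))
    stop("sensor ids must be unique and contiguous 1..M")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (is.null(disturbed)) disturbed <- matrix(FALSE, nw, M)
  stopifnot(is.logical(disturbed), nrow(disturbed) == nw, ncol(disturbed) == M)
  structure(
    list(x = x, y = y, label = label, subject = subject,
         sensors = sensors, rate = rate, disturbed = disturbed),
    class = "signal_set"
  )
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf(
    "<signal_set> %d sensors, %d windows of %d samples @ %g Hz, %d classes, %d subjects\n",
    n_sensors(x), n_windows(x), ncol(x$x[[1]]), x$rate,
    length(unique(x$label)), length(unique(x$subject))))
  if (any(x$disturbed))
    cat(sprintf("  %d disturbed (window, sensor) cells\n", sum(x$disturbed)))
  invisible(x)
}

#' Number of windows / sensors in a signal set
#' @param set a [signal_set()].
#' @return integer count.
#' @export
n_windows <- function(set) nrow(set$x[[1]])

#' @rdname n_windows
#' @export
n_sensors <- function(set) length(set$x)

#' Subset a signal set by sensor id
#'
#' Keeps all windows; selects sensors and renumbers them contiguously.
#'
#' @param set a [signal_set()].
#' @param ids sensor ids to keep.
#' @return A `signal_set` with `length(ids)` sensors.
#' @export
subset_sensors <- function(set, ids) {
  stopifnot(inherits(set, "signal_set"))
  ids <- as.integer(ids)
  if (any(!ids %in% seq_len(n_sensors(set)))) stop("unknown sensor id")
  sensors <- set$sensors[ids, , drop = FALSE]
  sensors$sensor <- seq_along(ids)
  rownames(sensors) <- NULL
  signal_set(set$x[ids], set$y[ids], set$label, set$subject, sensors,
             set$rate, set$disturbed[, ids, drop = FALSE])
}

#' Subset a signal set by window index
#'
#' Keeps all sensors; selects window rows. Used by the evaluation protocol to
#' form train/test partitions without copying sample data out of the object.
#'
#' @param set a [signal_set()].
#' @param idx integer vector of window row indices.
#' @return A `signal_set` with `length(idx)` windows.
#' @export
subset_windows <- function(set, idx) {
  stopifnot(inherits(set, "signal_set"))
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_windows(set)))
    stop("window index out of range")
  signal_set(
    x = lapply(set$x, function(m) m[idx, , drop = FALSE]),
    y = lapply(set$y, function(m) m[idx, , drop = FALSE]),
    label = set$label[idx], subject = set$subject[idx],
    sensors = set$sensors, rate = set$rate,
    disturbed = set$disturbed[idx, , drop = FALSE]
  )
}
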