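#' Write a signal set to the columnar CSV format
#'
#' Schema: `subject,sensor,window,sample,ax,ay,label`, acceleration in G,
#' label as integer class id; one row per (sensor, window, sample). The
#' round trip through [read_signals()] is lossless to at least 9
#' significant digits.
#'
#' @param set a [signal_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(set, path) {
  stopifnot(inherits(set, "signal_set"))
  nw <- n_windows(set)
  ns <- ncol(set$x[[1]])
  parts <- lapply(seq_len(n_sensors(set)), function(m)
    data.table::data.table(
      subject = rep(set$subject, each = ns),
      sensor = m,
      window = rep(seq_len(nw), each = ns),
      sample = rep(seq_len(ns), nw),
      ax = as.vector(t(set$x[[m]])),
      ay = as.vector(t(set$y[[m]])),
      label = rep(set$label, each = ns)
    ))
  data.table::fwrite(data.table::rbindlist(parts), path)
  invisible(path)
}

#' Read a signal set from the columnar CSV format
#'
#' Validates the schema and rejects malformed rows with the offending
#' column and line number. An empty file with a valid header yields an
#' empty set (zero windows). The sampling rate is not part of the schema
#' and must be supplied.
#'
#' @param path input file path.
#' @param rate sampling rate in Hz of the stored signals.
#' @param sensors optional [sensor_placements()] table; defaults to generic
#'   placements with mobility 1.
#' @return a [signal_set()].
#' @export
read_signals <- function(path, rate = 50, sensors = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- c("subject", "sensor", "window", "sample", "ax", "ay", "label")
  dt <- data.table::fread(path, fill = TRUE, colClasses = "character")
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
  int_cols <- c("subject", "sensor", "window", "sample", "label")
  for (col in required) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("parse error in column '", col, "' at line ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
    data.table::set(dt, j = col,
                    value = if (col %in% int_cols) as.integer(v) else v)
  }
  M <- if (nrow(dt)) max(dt$sensor) else 1L
  if (is.null(sensors))
    sensors <- sensor_placements(paste0("sensor", seq_len(M)), rep(1, M))
  if (nrow(dt) == 0)
    return(signal_set(rep(list(matrix(0, 0, 0)), M),
                      rep(list(matrix(0, 0, 0)), M),
                      integer(0), integer(0), sensors, rate))
  if (!all(sort(unique(dt$sensor)) == seq_len(M)))
    stop("parse error: sensor ids must be contiguous 1..M")
  data.table::setorderv(dt, c("sensor", "window", "sample"))
  wins <- sort(unique(dt$window))
  nw <- length(wins)
  ns <- nrow(dt) / (M * nw)
  if (ns != floor(ns))
    stop("parse error: unequal sample counts across (sensor, window) blocks")
  xs <- vector("list", M); ys <- vector("list", M)
  for (m in seq_len(M)) {
    sub <- dt[dt$sensor == m, ]
    if (nrow(sub) != nw * ns)
      stop("parse error: sensor ", m, " has an incomplete window grid")
    xs[[m]] <- matrix(sub$ax, nw, ns, byrow = TRUE)
    ys[[m]] <- matrix(sub$ay, nw, ns, byrow = TRUE)
  }
  first <- dt[dt$sensor == 1L & dt$sample == dt$sample[1L], ]
  signal_set(xs, ys, first$label, first$subject, sensors, rate)
}

#' Read / write a run configuration
#'
#' A run configuration is a JSON object holding any of the sections
#' `scenario` (overrides for [synth_config()]), `disturbance`
#' (a [disturbance_spec()]), `swnc` ([swnc_config()] scalars), `experiment`
#' (level grids, repetitions, train fraction), plus `seed` and `out_dir`.
#' Configurations round-trip losslessly, and every CLI run directory
#' records the exact configuration used.
#'
#' @param path JSON file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("scenario", "disturbance", "swnc", "experiment", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @param config named list to serialize.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Persist / restore a fitted SWNC
#'
#' The model is stored as an RDS companion holding the trained predictors,
#' next to a JSON metadata sidecar (`<path>.json`) with the weights, chosen
#' k values, selected features and accuracy rates for inspection.
#'
#' @param model a fitted [swnc_fit()] object.
#' @param path output path for the model file.
#' @return `path`, invisibly.
#' @export
save_swnc <- function(model, path) {
  stopifnot(inherits(model, "swnc"))
  saveRDS(model, path)
  meta <- list(
    M = model$M, N = model$N, mu = model$mu, R_node = model$R_node,
    encoding = model$config$encoding, L = model$config$L,
    nodes = lapply(model$nodes, function(nd) list(
      sensor = nd$sensor, lambda = nd$lambda,
      k = vapply(nd$classifiers, function(c) c$k, integer(1)),
      features = lapply(nd$classifiers, function(c) c$features)))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_swnc
#' @export
load_swnc <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "swnc")) stop("not a saved swnc model: ", path)
  model
}

#' Write sweep results to a directory
#'
#' Emits, per noise kind: a long CSV with one row per (curve, level,
#' repetition) accuracy sample, and a JSON summary with the per-level means,
#' standard deviations and fusion-vs-single comparison tables.
#'
#' @param sweep a [run_sweep()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "swnc_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in c("rotational", "additive")) {
    res <- sweep[[kind]]
    long <- data.table::rbindlist(lapply(c(res$single, res$fusion), function(cv) {
      s <- attr(cv, "samples")
      data.table::data.table(
        kind = kind, target = attr(cv, "target"),
        level = rep(cv$level, each = nrow(s)),
        rep = rep(seq_len(nrow(s)), length(cv$level)),
        accuracy = as.vector(s))
    }))
    data.table::fwrite(long, file.path(dir, paste0(kind, "_samples.csv")))
    summary <- list(
      curves = lapply(c(res$single, res$fusion), function(cv)
        c(list(target = attr(cv, "target")), as.list(as.data.frame(cv)))),
      comparison = res$comparison,
      train_windows_disturbed = res$train_windows_disturbed)
    jsonlite::write_json(summary, file.path(dir, paste0(kind, "_summary.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  write_run_config(list(seed = sweep$seed,
                        experiment = list(repetitions = sweep$repetitions,
                                          S_values = sweep$S_values,
                                          granularity = sweep$granularity)),
                   file.path(dir, "run_config.json"))
  invisible(dir)
}
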