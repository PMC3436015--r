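#' Activity signal profile
#'
#' Describes the acceleration signature of one activity class across all
#' sensor placements. Each biaxial accelerometer senses a static (gravity
#' projection) component plus an activity-dependent oscillatory component;
#' postures such as sitting or lying are dominated by the static part
#' (frequency 0), ambulatory activities by a fundamental oscillation with a
#' few harmonics.
#'
#' @param activity integer class id (1..N).
#' @param name character label.
#' @param gravity `M x 2` numeric matrix: gravity projection (g_x, g_y) per
#'   placement, in G. Row norms must not exceed 1 (projection of unit gravity
#'   onto two sensed axes).
#' @param amplitude length-M numeric vector: dynamic amplitude per placement,
#'   in G, before the placement mobility factor is applied. Must be >= 0.
#' @param frequency fundamental oscillation frequency in Hz (>= 0; 0 for
#'   purely static postures).
#' @param harmonics number of harmonics of the fundamental to superpose.
#' @param jitter intra-class amplitude jitter as a fraction: each window's
#'   amplitude is scaled by a factor drawn uniformly from `1 +/- jitter`.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(activity, name, gravity, amplitude, frequency,
                             harmonics = 1L, jitter = 0.1) {
  gravity <- as.matrix(gravity)
  stopifnot(ncol(gravity) == 2, nrow(gravity) == length(amplitude))
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  if (frequency < 0) stop("frequency must be >= 0")
  if (any(sqrt(rowSums(gravity^2)) > 1 + 1e-9))
    stop("|(g_x, g_y)| must not exceed 1 G")
  if (jitter < 0 || jitter >= 1) stop("jitter must be in [0, 1)")
  structure(
    list(activity = as.integer(activity), name = as.character(name),
         gravity = gravity, amplitude = as.numeric(amplitude),
         frequency = as.numeric(frequency), harmonics = as.integer(harmonics),
         jitter = as.numeric(jitter)),
    class = "activity_profile"
  )
}

#' Sensor placement table
#'
#' @param names character vector of placement labels.
#' @param mobility unitless multipliers scaling the dynamic amplitude at each
#'   placement; trunk-proximal sites (hip, thigh) move less than distal ones
#'   (wrist, ankle) and get factors below 1.
#' @return data frame with columns `sensor` (1..M), `name`, `mobility`.
#' @export
sensor_placements <- function(names, mobility) {
  stopifnot(length(names) == length(mobility), all(mobility >= 0))
  data.frame(sensor = seq_along(names), name = as.character(names),
             mobility = as.numeric(mobility))
}

#' Synthetic dataset configuration
#'
#' @param M sensor count (>= 1).
#' @param N activity class count (>= 2).
#' @param subjects number of subjects.
#' @param rate sampling rate in Hz.
#' @param windows_per windows generated per (subject, activity) pair; the
#'   class distribution is therefore exactly balanced.
#' @param window_s window duration in seconds.
#' @param noise_floor standard deviation of the per-sample Gaussian sensor
#'   noise floor, in G.
#' @param subject_sd standard deviation (log scale) of the per-(subject,
#'   placement) log-normal amplitude multiplier emulating individual
#'   execution styles.
#' @param seed integer seed controlling generation.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(M = 5L, N = 9L, subjects = 20L, rate = 50,
                         windows_per = 4L, window_s = 6, noise_floor = 0.02,
                         subject_sd = 0.15, seed = 1L) {
  if (M < 1) stop("M must be >= 1")
  if (N < 2) stop("N must be >= 2")
  if (rate <= 0) stop("rate must be > 0")
  if (window_s <= 0) stop("window_s must be > 0")
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  structure(
    list(M = as.integer(M), N = as.integer(N), subjects = as.integer(subjects),
         rate = as.numeric(rate), windows_per = as.integer(windows_per),
         window_s = as.numeric(window_s), noise_floor = as.numeric(noise_floor),
         subject_sd = as.numeric(subject_sd), seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate one biaxial window for an (activity, placement) pair
#'
#' Signal model per axis: gravity projection + jittered
#' sinusoid-plus-harmonics (amplitude scaled by the placement mobility factor
#' and any per-subject multiplier) + zero-mean Gaussian floor noise. Harmonic
#' `h` contributes amplitude `A/h` with an independent uniform random phase
#' per axis. At frequency 0 the oscillatory term reduces to a small random
#' constant offset, emulating posture-to-posture variation in quasi-static
#' activities. Deterministic given the R random number generator state.
#'
#' @param profile an [activity_profile()].
#' @param placement a single row of a [sensor_placements()] table.
#' @param duration window duration in seconds.
#' @param rate sampling rate in Hz.
#' @param noise_floor Gaussian noise standard deviation in G.
#' @param subject_scale per-subject amplitude multiplier (default 1).
#' @return list with numeric vectors `x` and `y` of length
#'   `floor(duration * rate)`.
#' @export
generate_window <- function(profile, placement, duration, rate,
                            noise_floor = 0, subject_scale = 1) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  n <- floor(duration * rate)
  if (n < 1) stop("duration * rate must be >= 1")
  m <- placement$sensor
  g <- profile$gravity[m, ]
  amp <- profile$amplitude[m] * placement$mobility * subject_scale
  amp <- amp * stats::runif(1, 1 - profile$jitter, 1 + profile$jitter)
  t <- (seq_len(n) - 1) / rate
  f <- profile$frequency
  H <- profile$harmonics
  ax <- rep(g[1], n)
  ay <- rep(g[2], n)
  for (h in seq_len(H)) {
    ax <- ax + (amp / h) * sin(2 * pi * h * f * t + stats::runif(1, 0, 2 * pi))
    ay <- ay + (amp / h) * sin(2 * pi * h * f * t + stats::runif(1, 0, 2 * pi))
  }
  if (noise_floor > 0) {
    ax <- ax + stats::rnorm(n, 0, noise_floor)
    ay <- ay + stats::rnorm(n, 0, noise_floor)
  }
  list(x = ax, y = ay)
}

#' Generate a labeled multi-sensor dataset
#'
#' Produces a balanced [signal_set()]: `windows_per` windows for every
#' (subject, activity) pair, recorded simultaneously by all M sensors.
#' A log-normal amplitude multiplier per (subject, placement) is applied
#' consistently across all of that subject's windows. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [synth_config()].
#' @param profiles list of N [activity_profile()] objects (class ids 1..N).
#' @param placements a [sensor_placements()] table with M rows.
#' @return A [signal_set()] with `subjects * N * windows_per` windows.
#' @export
generate_dataset <- function(config, profiles, placements) {
  stopifnot(inherits(config, "synth_config"))
  if (length(profiles) != config$N)
    stop("need exactly N = ", config$N, " activity profiles, got ",
         length(profiles))
  if (nrow(placements) != config$M)
    stop("need exactly M = ", config$M, " placements, got ", nrow(placements))
  M <- config$M; N <- config$N
  nper <- config$windows_per
  nwin <- config$subjects * N * nper
  nsamp <- floor(config$window_s * config$rate)
  withr::with_seed(config$seed, {
    xs <- lapply(seq_len(M), function(m) matrix(0, nwin, nsamp))
    ys <- lapply(seq_len(M), function(m) matrix(0, nwin, nsamp))
    label <- integer(nwin)
    subject <- integer(nwin)
    row <- 0L
    for (s in seq_len(config$subjects)) {
      scale_sm <- exp(stats::rnorm(M, 0, config$subject_sd))
      for (a in seq_len(N)) {
        for (w in seq_len(nper)) {
          row <- row + 1L
          for (m in seq_len(M)) {
            win <- generate_window(profiles[[a]], placements[m, ],
                                   config$window_s, config$rate,
                                   noise_floor = config$noise_floor,
                                   subject_scale = scale_sm[m])
            xs[[m]][row, ] <- win$x
            ys[[m]][row, ] <- win$y
          }
          label[row] <- a
          subject[row] <- s
        }
      }
    }
    signal_set(xs, ys, label, subject, placements, config$rate)
  })
}

#' Default nine-activity, five-sensor scenario
#'
#' A ready-made study design emulating a classic wearable setup: five biaxial
#' accelerometers (right hip, dominant wrist, non-dominant arm, dominant
#' ankle, non-dominant thigh) worn by 20 subjects performing nine daily
#' activities: walking, running, cycling, sitting, standing still, lying
#' down, stretching, strength-training and climbing stairs. Sedentary
#' postures differ mainly in static gravity orientation (so rotational
#' disturbance visibly confuses e.g. standing with lying); ambulatory
#' activities differ in fundamental frequency and amplitude pattern.
#' Hip and thigh get lower mobility factors than wrist and ankle, reflecting
#' the weaker accelerations measured at motion-limited sites.
#'
#' @param ... overrides passed to [synth_config()] (e.g. `subjects`,
#'   `windows_per`, `seed`).
#' @return list with elements `config`, `profiles`, `placements`.
#' @export
default_scenario <- function(...) {
  placements <- sensor_placements(
    names = c("hip", "wrist", "arm", "ankle", "thigh"),
    mobility = c(0.6, 1.2, 1.0, 1.3, 0.7)
  )
  g <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  # rows: hip, wrist, arm, ankle, thigh; columns: (g_x, g_y) in G
  spec <- list(
    list("walking", g(0, .95, .4, .55, .3, .7, .1, .9, .15, .9),
         c(.20, .25, .20, .45, .30), 2.0, 3L, 0.2),
    list("running", g(0, .9, .5, .4, .4, .6, .15, .85, .2, .85),
         c(.45, .50, .40, .90, .60), 2.8, 3L, 0.2),
    list("cycling", g(.3, .85, .6, .5, .5, .6, .5, .7, .6, .6),
         c(.15, .20, .15, .50, .45), 1.5, 2L, 0.2),
    list("sitting", g(.7, .6, .5, .7, .2, .9, .15, .95, .9, .3),
         c(.01, .03, .02, .01, .01), 0, 1L, 0.1),
    list("standing", g(0, 1, .25, .9, .1, .95, 0, 1, .05, .95),
         c(.01, .02, .02, .01, .01), 0, 1L, 0.1),
    list("lying", g(.95, .1, .8, .4, .9, .2, .9, .15, .95, .05),
         c(.01, .01, .01, .01, .01), 0, 1L, 0.1),
    list("stretching", g(.1, .9, .7, .3, .6, .5, .1, .9, .2, .85),
         c(.08, .30, .28, .10, .08), 0.5, 2L, 0.2),
    list("strength", g(.4, .8, .6, .6, .7, .5, .3, .9, .5, .8),
         c(.20, .40, .40, .25, .25), 1.0, 2L, 0.2),
    list("stairs", g(.1, .9, .45, .5, .35, .65, .25, .8, .3, .8),
         c(.25, .25, .20, .55, .40), 1.8, 3L, 0.2)
  )
  profiles <- lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    activity_profile(i, s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]])
  })
  list(config = synth_config(M = 5L, N = 9L, ...),
       profiles = profiles, placements = placements)
}
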