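#' Euler rotation angles
#'
#' Angles (degrees) of rotation about the X, Y and Z axes of the sensor's
#' local frame. Stored canonically in (-180, 180].
#'
#' @param phi,theta,psi rotation about X, Y, Z in degrees.
#' @return object of class `rotation_angles`.
#' @export
rotation_angles <- function(phi = 0, theta = 0, psi = 0) {
  a <- c(phi = phi, theta = theta, psi = psi)
  if (any(!is.finite(a))) stop("rotation angles must be finite")
  # wrap into (-180, 180]
  a <- a - 360 * ceiling((a - 180) / 360)
  structure(as.list(a), class = "rotation_angles")
}

#' Full 3D rotation matrix from Euler angles
#'
#' Builds the 3x3 rotation matrix that maps raw accelerations into the frame
#' of a rotated sensor, with c() and s() denoting cosine and sine of the
#' rotations phi (about X), theta (about Y) and psi (about Z):
#' row 1 is (c(theta)c(psi), -c(phi)s(psi)+s(phi)s(theta)c(psi),
#' s(phi)s(psi)+c(phi)s(theta)c(psi)), and so on. The result is orthonormal
#' with determinant +1.
#'
#' @param angles a [rotation_angles()] object (degrees).
#' @return 3x3 numeric matrix.
#' @export
rotation_matrix <- function(angles) {
  stopifnot(inherits(angles, "rotation_angles"))
  r <- pi / 180
  cf <- cos(angles$phi * r);   sf <- sin(angles$phi * r)
  ct <- cos(angles$theta * r); st <- sin(angles$theta * r)
  cp <- cos(angles$psi * r);   sp <- sin(angles$psi * r)
  matrix(c(
    ct * cp, -cf * sp + sf * st * cp,  sf * sp + cf * st * cp,
    ct * sp,  cf * cp + sf * st * sp, -sf * cp + cf * st * sp,
    -st,      sf * ct,                 cf * ct
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a biaxial signal pair
#'
#' Specialization of the full 3D mapping to two-axis accelerometers, whose
#' third raw channel is identically zero:
#' `x_rot = c(theta)c(psi) x - (c(phi)s(psi) - s(phi)s(theta)c(psi)) y` and
#' `y_rot = c(theta)s(psi) x + (c(phi)c(psi) + s(phi)s(theta)s(psi)) y`.
#' Identical to taking the first two components of
#' `rotation_matrix(angles) %*% c(x, y, 0)` samplewise, so the map inherits
#' the rotation group's properties (in particular it can never inflate the
#' biaxial signal energy).
#'
#' @param x,y numeric sample vectors of equal length, in G.
#' @param angles a [rotation_angles()] object.
#' @return list with rotated vectors `x` and `y`.
#' @export
apply_rotation_biaxial <- function(x, y, angles) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  R <- rotation_matrix(angles)
  list(x = R[1, 1] * x + R[1, 2] * y,
       y = R[2, 1] * x + R[2, 2] * y)
}

#' Add white Gaussian sensor noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma_mg`
#' (quoted in mG, thousandths of standard gravity) to a signal in G,
#' emulating displacement, uncalibration, battery faults and similar
#' anomalies. `sigma_mg = 0` returns the input unchanged. Uses the current R
#' random number generator state.
#'
#' @param signal numeric vector in G.
#' @param sigma_mg noise standard deviation in mG (>= 0).
#' @return numeric vector of the same length.
#' @export
apply_additive_noise <- function(signal, sigma_mg) {
  if (!is.numeric(sigma_mg) || length(sigma_mg) != 1L || sigma_mg < 0)
    stop("sigma_mg must be a non-negative scalar")
  if (sigma_mg == 0) return(signal)
  signal + stats::rnorm(length(signal), 0, sigma_mg / 1000)
}

#' Draw random rotation angles up to a bound
#'
#' Each of phi, theta, psi is drawn independently and uniformly from
#' `[0, max_deg]`, modelling an arbitrary re-orientation whose severity is
#' capped by a single scalar level.
#'
#' @param max_deg maximum rotation angle in degrees (>= 0).
#' @return a [rotation_angles()] object.
#' @export
sample_rotation <- function(max_deg) {
  if (!is.numeric(max_deg) || length(max_deg) != 1L || max_deg < 0)
    stop("max_deg must be a non-negative scalar")
  a <- stats::runif(3, 0, max_deg)
  rotation_angles(a[1], a[2], a[3])
}

#' Disturbance specification
#'
#' Describes which sensors of a signal set are disturbed and how: either
#' rotational noise (arbitrary re-orientation, level = maximum Euler angle in
#' degrees) or additive white Gaussian noise (level = standard deviation in
#' mG). Rotational angles can be redrawn for every window (`"window"`,
#' emulating a loosely attached, shifting sensor) or drawn once and applied
#' to all windows (`"run"`, emulating a fixed misplacement).
#'
#' @param kind `"rotational"` or `"additive"`.
#' @param level maximum angle in degrees (rotational) or sigma in mG
#'   (additive); >= 0.
#' @param sensors integer ids of the disturbed sensors (may be empty).
#' @param granularity `"window"` (default) or `"run"`; rotational only.
#' @param seed optional integer seed; if `NULL`, [disturb()] uses the current
#'   RNG state.
#' @return object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(kind = c("rotational", "additive"), level,
                             sensors = integer(), granularity = c("window", "run"),
                             seed = NULL) {
  kind <- match.arg(kind)
  granularity <- match.arg(granularity)
  if (!is.numeric(level) || length(level) != 1L || level < 0)
    stop("level must be a non-negative scalar")
  sensors <- sort(unique(as.integer(sensors)))
  if (length(sensors) && any(sensors < 1L))
    stop("sensor ids must be positive")
  structure(
    list(kind = kind, level = as.numeric(level), sensors = sensors,
         granularity = granularity,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "disturbance_spec"
  )
}

#' Apply a disturbance to selected sensors of a signal set
#'
#' Transforms every window of the sensors named in `spec`: rotational noise
#' draws fresh Euler angles per window (or one triple per sensor in `"run"`
#' granularity) from `[0, level]` degrees; additive noise draws fresh
#' Gaussian noise per sample, independently on both axes. Undisturbed
#' sensors, labels and subjects are returned bit-identical; the input object
#' is not modified. Disturbed (window, sensor) cells are flagged in the
#' returned object's `disturbed` matrix.
#'
#' @param set a [signal_set()].
#' @param spec a [disturbance_spec()].
#' @return a new [signal_set()].
#' @export
disturb <- function(set, spec) {
  stopifnot(inherits(set, "signal_set"), inherits(spec, "disturbance_spec"))
  M <- n_sensors(set)
  if (length(spec$sensors) && any(!spec$sensors %in% seq_len(M)))
    stop("unknown sensor id in disturbance spec: ",
         paste(setdiff(spec$sensors, seq_len(M)), collapse = ", "))
  # zero-level or empty disturbance is a bit-exact no-op
  if (length(spec$sensors) == 0 || spec$level == 0) return(set)
  run <- function() {
    out <- set
    nw <- n_windows(set)
    for (m in spec$sensors) {
      if (spec$kind == "rotational") {
        if (spec$granularity == "run") {
          ang <- sample_rotation(spec$level)
          rot <- apply_rotation_biaxial(c(t(set$x[[m]])), c(t(set$y[[m]])), ang)
          out$x[[m]] <- matrix(rot$x, nw, byrow = TRUE)
          out$y[[m]] <- matrix(rot$y, nw, byrow = TRUE)
        } else {
          for (w in seq_len(nw)) {
            ang <- sample_rotation(spec$level)
            rot <- apply_rotation_biaxial(set$x[[m]][w, ], set$y[[m]][w, ], ang)
            out$x[[m]][w, ] <- rot$x
            out$y[[m]][w, ] <- rot$y
          }
        }
      } else {
        out$x[[m]] <- matrix(apply_additive_noise(c(set$x[[m]]), spec$level),
                             nrow = nw)
        out$y[[m]] <- matrix(apply_additive_noise(c(set$y[[m]]), spec$level),
                             nrow = nw)
      }
      out$disturbed[, m] <- TRUE
    }
    out
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}
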