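# Shared fixtures: small scenarios that keep unit tests fast.

tiny_scenario <- function(subjects = 4L, windows_per = 3L, seed = 42L, ...) {
  default_scenario(subjects = subjects, windows_per = windows_per,
                   seed = seed, ...)
}

tiny_dataset <- function(...) {
  sc <- tiny_scenario(...)
  generate_dataset(sc$config, sc$profiles, sc$placements)
}

# A minimal 2-sensor / 3-class scenario with well-separated classes.
micro_scenario <- function(seed = 11L, noise_floor = 0.02, subjects = 3L,
                           windows_per = 4L) {
  placements <- sensor_placements(c("hip", "wrist"), c(0.7, 1.2))
  g <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  profiles <- list(
    activity_profile(1, "walk", g(0, .9, .4, .6), c(.3, .4), 2.0, 2L, 0.2),
    activity_profile(2, "stand", g(0, 1, .2, .9), c(.01, .02), 0, 1L, 0.1),
    activity_profile(3, "lie", g(.95, .1, .8, .3), c(.01, .01), 0, 1L, 0.1)
  )
  list(config = synth_config(M = 2L, N = 3L, subjects = subjects, rate = 25,
                             windows_per = windows_per, window_s = 2,
                             noise_floor = noise_floor, seed = seed),
       profiles = profiles, placements = placements)
}

micro_dataset <- function(...) {
  sc <- micro_scenario(...)
  generate_dataset(sc$config, sc$profiles, sc$placements)
}

# Random feature_matrix with guaranteed class presence.
random_feature_matrix <- function(nrow, nfeat, N, sensor = 1L) {
  X <- matrix(stats::rnorm(nrow * nfeat), nrow,
              dimnames = list(NULL, paste0("f", seq_len(nfeat))))
  label <- c(seq_len(N), sample.int(N, nrow - N, replace = TRUE))
  structure(list(features = X, label = as.integer(label),
                 sensor = as.integer(sensor)),
            class = "feature_matrix")
}
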