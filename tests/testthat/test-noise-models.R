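test_that("zero angles give the identity rotation", {
  expect_equal(rotation_matrix(rotation_angles(0, 0, 0)), diag(3))
})

test_that("a pure 90-degree yaw matches the hand-evaluated matrix", {
  R <- rotation_matrix(rotation_angles(0, 0, 90))
  expect_equal(R, matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("rotation matrices lie in SO(3) for random angle triples", {
  set.seed(1)
  for (i in 1:50) {
    ang <- rotation_angles(runif(1, -180, 180), runif(1, -180, 180),
                           runif(1, -180, 180))
    R <- rotation_matrix(ang)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("non-finite angles are rejected and storage is canonical", {
  expect_error(rotation_angles(NaN, 0, 0), "finite")
  expect_error(rotation_angles(0, Inf, 0), "finite")
  a <- rotation_angles(270, -190, 540)
  expect_equal(unlist(a), c(phi = -90, theta = 170, psi = 180))
})

test_that("biaxial rotation reduces to the full 3D mapping with z = 0", {
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    ang <- rotation_angles(runif(1, -180, 180), runif(1, -180, 180),
                           runif(1, -180, 180))
    got <- apply_rotation_biaxial(x, y, ang)
    want <- oracle_rotate_via_3d(x, y, ang)
    expect_equal(got$x, want$x, tolerance = 1e-12)
    expect_equal(got$y, want$y, tolerance = 1e-12)
  }
})

test_that("identity rotation leaves the signals untouched", {
  x <- sin(1:20); y <- cos(1:20)
  got <- apply_rotation_biaxial(x, y, rotation_angles(0, 0, 0))
  expect_identical(got$x, x)
  expect_identical(got$y, y)
})

test_that("rotation cannot inflate the biaxial signal energy", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    ang <- rotation_angles(runif(1, 0, 180), runif(1, 0, 180),
                           runif(1, 0, 180))
    got <- apply_rotation_biaxial(x, y, ang)
    expect_true(all(got$x^2 + got$y^2 <= x^2 + y^2 + 1e-12))
  }
  # pure yaw (phi = theta = 0) preserves energy exactly
  x <- rnorm(50); y <- rnorm(50)
  got <- apply_rotation_biaxial(x, y, rotation_angles(0, 0, 37))
  expect_equal(got$x^2 + got$y^2, x^2 + y^2, tolerance = 1e-12)
})

test_that("mismatched signal lengths are rejected", {
  expect_error(apply_rotation_biaxial(1:3, 1:4, rotation_angles()), "length")
})

test_that("additive noise honours its degenerate and error cases", {
  sig <- sin(1:100)
  expect_identical(apply_additive_noise(sig, 0), sig)
  expect_error(apply_additive_noise(sig, -1), "non-negative")
  set.seed(4); a <- apply_additive_noise(sig, 100)
  set.seed(4); b <- apply_additive_noise(sig, 100)
  expect_identical(a, b)
  expect_false(identical(a, sig))
})

test_that("rotation sampling is bounded and uniform on [0, max]", {
  set.seed(5)
  z <- sample_rotation(0)
  expect_equal(unlist(z), c(phi = 0, theta = 0, psi = 0))
  draws <- t(replicate(1e4, unlist(sample_rotation(90))))
  expect_true(all(draws >= 0 & draws <= 90))
  expect_true(all(abs(colMeans(draws) - 45) < 2))
  expect_error(sample_rotation(-5), "non-negative")
})

test_that("disturb transforms only the requested sensors", {
  set <- tiny_dataset()
  spec <- disturbance_spec("rotational", 45, c(1, 3), seed = 9L)
  out <- disturb(set, spec)
  for (m in c(2, 4, 5)) {
    expect_identical(out$x[[m]], set$x[[m]])
    expect_identical(out$y[[m]], set$y[[m]])
  }
  for (m in c(1, 3)) expect_false(identical(out$x[[m]], set$x[[m]]))
  expect_identical(out$label, set$label)
  expect_identical(dim(out$x[[1]]), dim(set$x[[1]]))
  expect_true(all(out$disturbed[, c(1, 3)]))
  expect_false(any(out$disturbed[, c(2, 4, 5)]))
  expect_false(any(set$disturbed))  # input untouched
})

test_that("empty or zero-level disturbances are bit-exact no-ops", {
  set <- micro_dataset()
  expect_identical(disturb(set, disturbance_spec("additive", 100, integer())),
                   set)
  expect_identical(disturb(set, disturbance_spec("rotational", 0, 1:2)), set)
})

test_that("run granularity applies one rotation to all windows of a sensor", {
  set <- micro_dataset()
  spec <- disturbance_spec("rotational", 60, 1, granularity = "run", seed = 3L)
  out <- disturb(set, spec)
  # one shared rotation: the samplewise map is the same linear transform for
  # every window, so solving for the 2x2 coefficients per window must agree
  coef_for <- function(w) {
    A <- cbind(set$x[[1]][w, ], set$y[[1]][w, ])
    qr.solve(A, cbind(out$x[[1]][w, ], out$y[[1]][w, ]))
  }
  expect_equal(coef_for(1), coef_for(10), tolerance = 1e-8)
  # per-window granularity draws fresh angles instead
  out2 <- disturb(set, disturbance_spec("rotational", 60, 1, seed = 3L))
  c1 <- qr.solve(cbind(set$x[[1]][1, ], set$y[[1]][1, ]),
                 cbind(out2$x[[1]][1, ], out2$y[[1]][1, ]))
  c2 <- qr.solve(cbind(set$x[[1]][10, ], set$y[[1]][10, ]),
                 cbind(out2$x[[1]][10, ], out2$y[[1]][10, ]))
  expect_gt(max(abs(c1 - c2)), 1e-6)
})

test_that("disturb validates its sensor ids and is seed-reproducible", {
  set <- micro_dataset()
  expect_error(disturb(set, disturbance_spec("additive", 100, 7)),
               "unknown sensor")
  s <- disturbance_spec("additive", 200, 1:2, seed = 8L)
  expect_identical(disturb(set, s), disturb(set, s))
})
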