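test_that("1-NN on separated data reproduces its training labels", {
  fm <- structure(list(
    features = matrix(c(1:10, 101:110), ncol = 1,
                      dimnames = list(NULL, "f1")),
    label = rep(c(1L, 2L), each = 10), sensor = 1L), class = "feature_matrix")
  clf <- train_base(fm, 1, k_grid = 1)
  expect_true(all(predict(clf, fm$features) == (fm$label == 1)))
})

test_that("grid-selected k matches a brute-force leave-one-out oracle", {
  set.seed(30)
  for (i in 1:5) {
    X <- matrix(c(rnorm(30, 0, 1.5), rnorm(30, 2, 1.5)), ncol = 2)
    colnames(X) <- c("f1", "f2")
    fm <- structure(list(features = X, label = rep(c(1L, 2L), each = 15),
                         sensor = 1L), class = "feature_matrix")
    grid <- c(1L, 3L, 5L)
    clf <- train_base(fm, 1, k_grid = grid)
    Xs <- sweep(sweep(X, 2, clf$center), 2, clf$scale, "/")
    acc <- vapply(grid, function(k)
      oracle_loo_accuracy(Xs, fm$label == 1, k), numeric(1))
    expect_identical(clf$k, grid[which.max(acc)])  # smallest k on ties
  }
})

test_that("the internal kNN agrees with class::knn away from ties", {
  skip_if_not_installed("class")
  set.seed(31)
  Xtr <- matrix(rnorm(60), ncol = 2)
  ytr <- Xtr[, 1] + 0.3 * rnorm(30) > 0
  Xte <- matrix(rnorm(40), ncol = 2)
  for (k in c(1L, 3L, 5L)) {
    got <- swnc:::knn_vote(swnc:::squared_dists(Xte, Xtr), ytr, k)
    ref <- class::knn(Xtr, Xte, factor(ytr), k = k) == "TRUE"
    expect_equal(unname(got), unname(ref))
  }
})

test_that("base training validates its inputs", {
  set.seed(32)
  fm <- random_feature_matrix(20, 3, 2)
  expect_error(train_base(fm, 1, k_grid = c(2, 4)), "odd")
  expect_error(train_base(fm, 1, k_grid = integer()), "non-empty")
  expect_error(train_base(fm, 1, k_grid = 21), "fewer")
  one <- fm; one$label <- rep(1L, 20)
  expect_error(train_base(one, 1), "complement")
})

test_that("class weights normalize accuracy rates", {
  expect_equal(class_weights(c(0.5, 0.3, 0.2)), c(0.5, 0.3, 0.2))
  expect_equal(class_weights(c(0.8, 0.6, 0.6)), c(0.4, 0.3, 0.3))
  expect_equal(class_weights(rep(0.7, 4)), rep(0.25, 4))
  expect_error(class_weights(c(0, 0, 0)), "degenerate")
  expect_error(class_weights(c(0.5, 1.2)), "rates")
})

test_that("node weights follow the same normalization", {
  expect_equal(node_weights(c(0.9, 0.6)), c(0.6, 0.4))
  expect_equal(node_weights(c(0.5, 0.5, 0.5)), rep(1, 3) / 3)
  expect_equal(node_weights(0.4), 1)
})

test_that("vote encoding follows acceptance and complement rules", {
  expect_equal(vote(TRUE, 1, 3), c(1, 0, 0))
  expect_equal(vote(FALSE, 2, 3), c(1, 0, 1))
  # at N = 2 an acceptance of class 1 and a rejection by the class-2
  # classifier encode identically
  expect_equal(vote(TRUE, 1, 2), vote(FALSE, 2, 2))
  expect_equal(vote(FALSE, 2, 3, encoding = "abstain"), c(0, 0, 0))
  expect_error(vote(TRUE, 4, 3), "1..N")
})

test_that("node outputs combine votes with the class weights", {
  votes <- rbind(vote(TRUE, 1, 2), vote(FALSE, 2, 2))
  O <- node_output(votes, c(0.6, 0.4))
  expect_equal(O, c(1, 0))
  expect_equal(node_predict(O), 1L)
  # all classifiers accepting returns the weights themselves
  lam <- c(0.2, 0.3, 0.5)
  votes3 <- t(vapply(1:3, function(n) vote(TRUE, n, 3), numeric(3)))
  expect_equal(node_output(votes3, lam), lam)
  # uniform weights reduce to the vote share
  acc <- c(TRUE, FALSE, TRUE)
  votesm <- t(vapply(1:3, function(n) vote(acc[n], n, 3), numeric(3)))
  expect_equal(node_output(votesm, rep(1, 3) / 3),
               colSums(votesm) / 3)
  expect_true(all(node_output(votesm, rep(1, 3) / 3) >= 0 &
                  node_output(votesm, rep(1, 3) / 3) <= 1))
})

test_that("argmax decisions break ties by the lowest class index", {
  expect_equal(node_predict(c(0.2, 0.7, 0.1)), 2L)
  expect_equal(node_predict(c(0.5, 0.5, 0.0)), 1L)
  expect_equal(network_predict(c(0.4, 0.4, 0.4)), 1L)
})

test_that("network outputs fuse node outputs with node weights", {
  expect_equal(network_output(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5)),
               c(0.5, 0.5))
  O <- c(0.3, 0.7)
  expect_equal(network_output(rbind(O), 1), O)
  # three one-hot nodes under uniform weights recover majority voting
  nodes <- rbind(c(1, 0), c(1, 0), c(0, 1))
  net <- network_output(nodes, rep(1, 3) / 3)
  expect_equal(net, c(2 / 3, 1 / 3))
  expect_equal(network_predict(net), 1L)
})

test_that("the vectorized node scores equal the scalar vote chain", {
  set.seed(33)
  for (encoding in c("complement", "abstain")) {
    for (i in 1:20) {
      N <- sample(2:5, 1)
      A <- matrix(sample(c(TRUE, FALSE), 4 * N, replace = TRUE), 4, N)
      lam <- class_weights(runif(N, 0.1, 1))
      fast <- swnc:::node_scores_from_accept(A, lam, encoding)
      for (w in 1:4) {
        votes <- t(vapply(seq_len(N), function(n)
          vote(A[w, n], n, N, encoding), numeric(N)))
        expect_equal(fast[w, ], node_output(votes, lam), tolerance = 1e-12)
      }
    }
  }
})

test_that("fitted weights are normalized and reproducible", {
  set <- micro_dataset()
  set.seed(34)
  model <- swnc_fit(set, swnc_config(k_grid = c(1, 3), L = 5))
  for (nd in model$nodes)
    expect_equal(sum(nd$lambda), 1, tolerance = 1e-12)
  expect_equal(sum(model$mu), 1, tolerance = 1e-12)
  set.seed(34)
  model2 <- swnc_fit(set, swnc_config(k_grid = c(1, 3), L = 5))
  expect_identical(model$mu, model2$mu)
  expect_identical(model$R_bin, model2$R_bin)
})

test_that("a pure-noise sensor receives the smallest node weight", {
  set <- tiny_dataset()
  set.seed(35)
  nw <- n_windows(set); ns <- ncol(set$x[[1]])
  set$x[[2]] <- matrix(rnorm(nw * ns), nw, ns)
  set$y[[2]] <- matrix(rnorm(nw * ns), nw, ns)
  model <- swnc_fit(set, swnc_config(k_grid = c(1, 3), L = 5))
  expect_equal(which.min(model$mu), 2L)
})

test_that("cross-validated weight estimation also yields a valid model", {
  set <- micro_dataset(subjects = 4L)
  set.seed(36)
  model <- swnc_fit(set, swnc_config(k_grid = c(1, 3), L = 5,
                                     weight_mode = "cv", p = 4L))
  for (nd in model$nodes)
    expect_equal(sum(nd$lambda), 1, tolerance = 1e-12)
  expect_equal(sum(model$mu), 1, tolerance = 1e-12)
  pred <- predict(model, set)
  expect_gt(accuracy(pred$class, set$label), 1 / 3)
})

test_that("prediction follows the full weighted-vote pipeline by hand", {
  # hand-built 2-node, 2-class model with forced base outcomes
  set.seed(37)
  mk_fm <- function() {
    X <- matrix(c(rnorm(8, -2), rnorm(8, 2)), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
    structure(list(features = X, label = rep(c(1L, 2L), 4), sensor = 1L),
              class = "feature_matrix")
  }
  fm1 <- mk_fm(); fm2 <- mk_fm()
  nodes <- list(
    list(sensor = 1L, classifiers = list(train_base(fm1, 1, 1), train_base(fm1, 2, 1)),
         lambda = c(0.7, 0.3)),
    list(sensor = 2L, classifiers = list(train_base(fm2, 1, 1), train_base(fm2, 2, 1)),
         lambda = c(0.4, 0.6)))
  model <- structure(list(nodes = nodes, mu = c(0.55, 0.45), classes = 1:2,
                          M = 2L, N = 2L, config = swnc_config(k_grid = 1)),
                     class = "swnc")
  newdata <- list(fm1$features[1:3, ], fm2$features[1:3, ])
  pred <- predict(model, newdata)
  # oracle: recover each classifier's outcomes and evaluate the vote algebra
  for (w in 1:3) {
    accepts <- rbind(
      vapply(nodes[[1]]$classifiers, function(c)
        predict(c, newdata[[1]][w, , drop = FALSE]), logical(1)),
      vapply(nodes[[2]]$classifiers, function(c)
        predict(c, newdata[[2]][w, , drop = FALSE]), logical(1)))
    want <- oracle_swnc_decision(accepts, rbind(c(0.7, 0.3), c(0.4, 0.6)),
                                 c(0.55, 0.45))
    expect_equal(pred$class[w], want$class)
    expect_equal(pred$network_scores[w, ], want$net, tolerance = 1e-12)
  }
})

test_that("a one-node network reduces to that node's decisions", {
  set <- subset_sensors(micro_dataset(), 2)
  set.seed(38)
  model <- swnc_fit(set, swnc_config(k_grid = c(1, 3), L = 5))
  expect_equal(model$mu, 1)
  pred <- predict(model, set)
  expect_equal(pred$class, as.integer(pred$node_class[, 1]))
  expect_true(all(pred$network_scores >= 0 & pred$network_scores <= 1))
})

test_that("unanimous node decisions survive fusion for any valid weights", {
  set.seed(39)
  for (i in 1:10) {
    N <- 4; M <- 3
    winner <- sample.int(N, 1)
    # every node accepts only the winner
    A <- matrix(FALSE, M, N); A[, winner] <- TRUE
    mu <- class_weights(runif(M, 0.2, 1))
    net <- 0
    for (m in seq_len(M)) {
      lam <- class_weights(runif(N, 0.2, 1))
      sc <- swnc:::node_scores_from_accept(A[m, , drop = FALSE], lam,
                                           "complement")
      expect_equal(which.max(sc), winner)
      net <- net + mu[m] * sc
    }
    expect_equal(which.max(net), winner)
  }
})

test_that("fit rejects degenerate inputs", {
  set <- micro_dataset()
  one_class <- subset_windows(set, which(set$label == 1))
  expect_error(swnc_fit(one_class, swnc_config()), "two classes")
})
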