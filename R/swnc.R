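#' SWNC training configuration
#'
#' Hyperparameters of the sensor-weighted network classifier: the ensemble
#' of M x N one-vs-rest base classifiers (kNN by default), class-level
#' weights derived from base-classifier accuracies, and node-level weights
#' derived from per-sensor multiclass accuracies.
#'
#' @param k_grid odd candidate neighbour counts; the k of each base
#'   classifier is chosen independently by leave-one-out accuracy on its
#'   training subset (highest accuracy, smallest k on ties).
#' @param L number of top-ranked features per base classifier.
#' @param encoding vote encoding for a rejecting base classifier:
#'   `"complement"` (votes 1 for every class except its specialization, the
#'   default) or `"abstain"` (votes 0 everywhere).
#' @param weight_mode `"holdout"` splits the training data into three equal
#'   stratified subsets (base training / class-weight assessment /
#'   node-weight assessment); `"cv"` instead trains on all data and
#'   estimates both accuracy sets by p-fold cross-validation.
#' @param p fold count for `weight_mode = "cv"`.
#' @param bank feature bank, see [default_feature_bank()].
#' @return list of class `swnc_config`.
#' @export
swnc_config <- function(k_grid = c(1L, 3L, 5L, 7L, 9L), L = 10L,
                        encoding = c("complement", "abstain"),
                        weight_mode = c("holdout", "cv"), p = 10L,
                        bank = default_feature_bank()) {
  encoding <- match.arg(encoding)
  weight_mode <- match.arg(weight_mode)
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0) stop("k grid must be non-empty")
  if (any(k_grid %% 2L == 0L)) stop("k grid values must be odd")
  if (L < 1) stop("L must be >= 1")
  structure(list(k_grid = sort(k_grid), L = as.integer(L),
                 encoding = encoding, weight_mode = weight_mode,
                 p = as.integer(p), bank = bank),
            class = "swnc_config")
}

#' Train one one-vs-rest base classifier
#'
#' Binarizes the labels to (class n, rest), standardizes the selected
#' features with training statistics (kNN is distance based), and picks k
#' from the grid by leave-one-out binary accuracy — highest accuracy,
#' smallest k on ties. The returned classifier is frozen.
#'
#' @param fm a [feature_matrix()].
#' @param class_n specialization class id.
#' @param k_grid odd candidate neighbour counts.
#' @param selection character vector of feature names to use (default: all).
#' @return object of class `base_classifier`.
#' @export
train_base <- function(fm, class_n, k_grid = c(1L, 3L, 5L, 7L, 9L),
                       selection = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  k_grid <- sort(as.integer(k_grid))
  if (length(k_grid) == 0) stop("k grid must be non-empty")
  if (any(k_grid %% 2L == 0L)) stop("k grid values must be odd")
  accept <- fm$label == class_n
  if (all(accept) || !any(accept))
    stop("training data must contain class ", class_n, " and its complement")
  if (nrow(fm$features) <= max(k_grid))
    stop("fewer training samples than the largest k in the grid")
  if (is.null(selection)) selection <- colnames(fm$features)
  X <- fm$features[, selection, drop = FALSE]
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  acc <- knn_loo_accuracy(Xs, accept, k_grid)
  k <- k_grid[which.max(acc)]  # first max -> smallest k on ties
  structure(list(sensor = fm$sensor, class_n = as.integer(class_n),
                 features = selection, center = center, scale = scale,
                 X = Xs, accept = accept, k = k, cv_accuracy = max(acc)),
            class = "base_classifier")
}

#' Predict accept/reject with a base classifier
#'
#' @param object a `base_classifier` from [train_base()].
#' @param newdata numeric matrix with (at least) the classifier's feature
#'   columns, unstandardized.
#' @param ... unused.
#' @return logical vector: `TRUE` = the window is accepted as the
#'   specialization class.
#' @export
predict.base_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss))
    stop("newdata is missing feature(s): ", paste(miss, collapse = ", "))
  X <- newdata[, object$features, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  knn_vote(squared_dists(Xs, object$X), object$accept, object$k)
}

#' Accuracy-proportional class weights
#'
#' Normalizes the held-out accuracy rates of a node's N base classifiers so
#' they sum to one: `lambda_n = R_n / sum(R)`.
#'
#' @param accuracies numeric vector of rates in `[0, 1]`.
#' @return numeric weight vector summing to 1.
#' @export
class_weights <- function(accuracies) {
  if (any(!is.finite(accuracies)) || any(accuracies < 0 | accuracies > 1))
    stop("accuracies must be rates in [0, 1]")
  s <- sum(accuracies)
  if (s <= 0) stop("degenerate weights: all accuracy rates are zero")
  accuracies / s
}

#' Accuracy-proportional node weights
#'
#' As [class_weights()], over the M node classifiers: `mu_m = R_m / sum(R)`.
#'
#' @inheritParams class_weights
#' @return numeric weight vector summing to 1.
#' @export
node_weights <- function(accuracies) class_weights(accuracies)

#' Binary vote vector of one base classifier
#'
#' Encodes the accept/reject decision of the classifier specialized in class
#' `n` over all N classes. Acceptance votes 1 for class n and 0 elsewhere.
#' Under the default `"complement"` encoding a rejection votes 1 for every
#' class except n (the rejecting classifier supports the rest of the
#' ensemble); under `"abstain"` it votes 0 everywhere.
#'
#' @param accept logical scalar: did the classifier accept its class?
#' @param n specialization class id.
#' @param N total class count.
#' @param encoding `"complement"` or `"abstain"`.
#' @return 0/1 vector of length N.
#' @export
vote <- function(accept, n, N, encoding = c("complement", "abstain")) {
  encoding <- match.arg(encoding)
  if (n < 1 || n > N) stop("n must be in 1..N")
  ind <- as.numeric(seq_len(N) == n)
  if (accept) ind else if (encoding == "complement") 1 - ind else 0 * ind
}

#' Weighted node output over classes
#'
#' Combines the N vote vectors of one sensor's base classifiers with the
#' class weights: `O_q = sum_n lambda_n y_nq`. All outputs lie in `[0, 1]`.
#'
#' @param votes `N x N` matrix, row n = [vote()] vector of classifier n.
#' @param lambda class weights summing to 1.
#' @return numeric vector of length N.
#' @export
node_output <- function(votes, lambda) {
  stopifnot(nrow(votes) == length(lambda))
  if (abs(sum(lambda) - 1) > 1e-9) stop("lambda must be normalized")
  as.numeric(lambda %*% votes)
}

#' Class decision of a node
#'
#' Argmax of the node output; ties broken deterministically by lowest class
#' index.
#'
#' @param output numeric score vector over classes.
#' @return integer class id.
#' @export
node_predict <- function(output) which.max(output)

#' Weighted network output over classes
#'
#' Fuses the M node outputs with the node weights:
#' `O_q = sum_p mu_p O_pq`.
#'
#' @param node_outputs `M x N` matrix, row m = output of node m.
#' @param mu node weights summing to 1.
#' @return numeric vector of length N.
#' @export
network_output <- function(node_outputs, mu) {
  stopifnot(nrow(node_outputs) == length(mu))
  if (abs(sum(mu) - 1) > 1e-9) stop("mu must be normalized")
  as.numeric(mu %*% node_outputs)
}

#' Class decision of the network
#'
#' @inheritParams node_predict
#' @return integer class id.
#' @export
network_predict <- function(output) which.max(output)

# Vectorized node score matrix: ntest x N, from the ntest x N acceptance
# matrix A of the node's classifiers. Algebraically identical to applying
# vote()/node_output() per window; the equivalence is enforced by tests.
node_scores_from_accept <- function(A, lambda, encoding) {
  ntest <- nrow(A); N <- ncol(A)
  lam <- matrix(lambda, ntest, N, byrow = TRUE)
  if (encoding == "abstain") return(A * lam)
  s <- as.numeric(A %*% lambda)
  out <- 2 * A * lam + matrix(1 - lambda, ntest, N, byrow = TRUE) - s
  pmin(pmax(out, 0), 1)  # exact bounds despite float round-off
}

node_accept_matrix <- function(node, X) {
  vapply(node$classifiers, function(clf) predict(clf, X), logical(nrow(X)))
}

node_scores <- function(node, X, encoding) {
  A <- node_accept_matrix(node, X)
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  node_scores_from_accept(A, node$lambda, encoding)
}

# Train the N base classifiers of one sensor on the given training rows,
# with per-class ROC feature selection performed on those same rows.
build_node <- function(fm, train_idx, classes, config) {
  fm_train <- structure(list(features = fm$features[train_idx, , drop = FALSE],
                             label = fm$label[train_idx], sensor = fm$sensor),
                        class = "feature_matrix")
  classifiers <- lapply(classes, function(n) {
    sel <- select_top(roc_rank(fm_train, n), config$L)$feature
    train_base(fm_train, n, config$k_grid, selection = sel)
  })
  list(sensor = fm$sensor, classifiers = classifiers)
}

# Stratified assignment of indices into ngroup equal groups (round-robin
# within each shuffled class); uses the current RNG state.
stratified_groups <- function(labels, ngroup) {
  g <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    g[idx] <- rep_len(seq_len(ngroup), length(idx))
  }
  g
}

#' Fit a sensor-weighted network classifier
#'
#' Implements the full training protocol. In the default holdout mode the
#' training windows are split into three equal stratified subsets: subset A
#' trains the M x N base classifiers (with per-(sensor, class) top-L ROC
#' feature selection on A); subset B measures each base classifier's binary
#' accuracy, normalized into the class weights lambda; subset C measures
#' each node's multiclass accuracy, normalized into the node weights mu. In
#' `"cv"` mode both accuracy sets are instead p-fold cross-validated
#' averages over all training windows and the final classifiers are trained
#' on everything. Uses the current RNG state for the stratified splits;
#' seed the generator for reproducible fits.
#'
#' @param train_set a [signal_set()] of training windows.
#' @param config a [swnc_config()].
#' @param featmats optional precomputed list of [feature_matrix()] objects
#'   (one per sensor) for `train_set`; extracted from the signals if `NULL`.
#' @return object of class `swnc`: per-node classifiers and `lambda`
#'   weights, network `mu` weights, accuracy rates and the configuration.
#' @export
swnc_fit <- function(train_set, config = swnc_config(), featmats = NULL) {
  stopifnot(inherits(train_set, "signal_set"), inherits(config, "swnc_config"))
  M <- n_sensors(train_set)
  labels <- train_set$label
  classes <- seq_len(max(labels))
  N <- length(classes)
  if (length(unique(labels)) < 2) stop("need at least two classes to fit")
  if (is.null(featmats))
    featmats <- lapply(seq_len(M), feature_matrix, set = train_set,
                       bank = config$bank)

  if (config$weight_mode == "holdout") {
    grp <- stratified_groups(labels, 3L)
    for (g in 1:3)
      if (!all(classes %in% labels[grp == g]))
        stop("stratification error: a class is missing from training subset ", g)
    idxA <- which(grp == 1L); idxB <- which(grp == 2L); idxC <- which(grp == 3L)
    nodes <- lapply(featmats, build_node, train_idx = idxA,
                    classes = classes, config = config)
    R_bin <- matrix(0, M, N)
    for (m in seq_len(M)) {
      XB <- featmats[[m]]$features[idxB, , drop = FALSE]
      for (n in classes) {
        pred <- predict(nodes[[m]]$classifiers[[n]], XB)
        R_bin[m, n] <- mean(pred == (labels[idxB] == n))
      }
      nodes[[m]]$lambda <- class_weights(R_bin[m, ])
    }
    R_node <- numeric(M)
    for (m in seq_len(M)) {
      XC <- featmats[[m]]$features[idxC, , drop = FALSE]
      sc <- node_scores(nodes[[m]], XC, config$encoding)
      R_node[m] <- mean(max.col(sc, ties.method = "first") == labels[idxC])
    }
    subset_sizes <- vapply(1:3, function(g) sum(grp == g), integer(1))
  } else {
    folds <- stratified_groups(labels, config$p)
    R_bin_acc <- matrix(0, M, N); R_node_acc <- numeric(M)
    for (f in seq_len(config$p)) {
      tr <- which(folds != f); te <- which(folds == f)
      if (!all(classes %in% labels[tr]) || !all(classes %in% labels[te]))
        stop("stratification error: a class is missing from fold ", f)
      for (m in seq_len(M)) {
        nf <- build_node(featmats[[m]], tr, classes, config)
        Xte <- featmats[[m]]$features[te, , drop = FALSE]
        A <- node_accept_matrix(nf, Xte)
        racc <- vapply(classes, function(n) mean(A[, n] == (labels[te] == n)),
                       numeric(1))
        R_bin_acc[m, ] <- R_bin_acc[m, ] + racc
        nf$lambda <- class_weights(racc)
        sc <- node_scores_from_accept(A, nf$lambda, config$encoding)
        R_node_acc[m] <- R_node_acc[m] +
          mean(max.col(sc, ties.method = "first") == labels[te])
      }
    }
    R_bin <- R_bin_acc / config$p
    R_node <- R_node_acc / config$p
    nodes <- lapply(featmats, build_node, train_idx = seq_along(labels),
                    classes = classes, config = config)
    for (m in seq_len(M)) nodes[[m]]$lambda <- class_weights(R_bin[m, ])
    subset_sizes <- rep(length(labels), 3L)
  }

  structure(
    list(nodes = nodes, mu = node_weights(R_node), R_bin = R_bin,
         R_node = R_node, classes = classes, M = M, N = N,
         config = config, subset_sizes = subset_sizes,
         sensors = train_set$sensors, rate = train_set$rate),
    class = "swnc"
  )
}

#' @export
print.swnc <- function(x, ...) {
  cat(sprintf("<swnc> %d nodes x %d classes; encoding '%s'\n",
              x$M, x$N, x$config$encoding))
  cat("  node weights mu:",
      paste(sprintf("%.3f", x$mu), collapse = " "), "\n")
  invisible(x)
}

#' Predict activity classes with a fitted SWNC
#'
#' Runs the full decision pipeline for every window: each base classifier
#' votes, votes are fused per node with the lambda weights, node outputs are
#' fused across sensors with the mu weights, and the network argmax gives
#' the class (ties to the lowest class index).
#'
#' @param object a fitted [swnc_fit()] model.
#' @param newdata either a [signal_set()] or a list of M numeric feature
#'   matrices (full bank columns, one matrix per sensor, equal row counts).
#' @param ... unused.
#' @return list with `class` (integer vector), `node_class`
#'   (windows x M matrix of per-node decisions), `network_scores`
#'   (windows x N), and `node_scores` (list of M windows x N matrices).
#' @export
predict.swnc <- function(object, newdata, ...) {
  if (inherits(newdata, "signal_set")) {
    if (n_sensors(newdata) != object$M)
      stop("newdata has ", n_sensors(newdata), " sensors; model expects ", object$M)
    newdata <- lapply(seq_len(object$M), function(m)
      feature_matrix(newdata, m, object$config$bank)$features)
  }
  if (!is.list(newdata) || length(newdata) != object$M)
    stop("newdata must be a signal_set or a list of ", object$M, " feature matrices")
  sc <- lapply(seq_len(object$M), function(m)
    node_scores(object$nodes[[m]], newdata[[m]], object$config$encoding))
  nw <- nrow(sc[[1]])
  net <- Reduce(`+`, Map(function(s, mu) mu * s, sc, object$mu))
  list(class = max.col(net, ties.method = "first"),
       node_class = vapply(sc, function(s) max.col(s, ties.method = "first"),
                           integer(nw)),
       network_scores = net,
       node_scores = sc)
}
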