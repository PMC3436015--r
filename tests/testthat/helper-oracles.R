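# Independent brute-force oracles, deliberately written as plain loops over
# the defining formulas so they share no code with the package internals.

# AUC by exhaustive concordant-pair counting (1/2 credit per tie).
oracle_auc_pairs <- function(values, positive) {
  pos <- values[positive]
  neg <- values[!positive]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Full 3D rotation applied samplewise with z_raw = 0; returns first two
# components (the definitional route the biaxial shortcut must match).
oracle_rotate_via_3d <- function(x, y, angles) {
  R <- rotation_matrix(angles)
  out_x <- numeric(length(x)); out_y <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- R %*% c(x[i], y[i], 0)
    out_x[i] <- v[1]; out_y[i] <- v[2]
  }
  list(x = out_x, y = out_y)
}

# Window count by explicit offset enumeration.
oracle_window_count <- function(len, wlen, overlap) {
  step <- floor(wlen * (1 - overlap))
  count <- 0L; start <- 1L
  while (start + wlen - 1L <= len) {
    count <- count + 1L
    start <- start + step
  }
  count
}

# Deterministic kNN leave-one-out accuracy for one k, by explicit loops
# (ties in distance broken by index, majority vote).
oracle_loo_accuracy <- function(X, accept, k) {
  n <- nrow(X)
  correct <- 0L
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
    d[i] <- Inf
    nn <- order(d, seq_len(n))[seq_len(k)]
    pred <- sum(accept[nn]) > k / 2
    if (pred == accept[i]) correct <- correct + 1L
  }
  correct / n
}

# Exhaustive evaluation of the two-level weighted voting scheme from the
# accept/reject outcomes: vote encoding, class-weighted node outputs,
# node-weighted network output, argmax with lowest-index ties.
oracle_swnc_decision <- function(accepts, lambdas, mu,
                                 encoding = "complement") {
  M <- nrow(accepts); N <- ncol(accepts)
  node_out <- matrix(0, M, N)
  for (m in seq_len(M)) {
    for (q in seq_len(N)) {
      o <- 0
      for (n in seq_len(N)) {
        y <- if (accepts[m, n]) {
          if (q == n) 1 else 0
        } else if (encoding == "complement") {
          if (q == n) 0 else 1
        } else 0
        o <- o + lambdas[m, n] * y
      }
      node_out[m, q] <- o
    }
  }
  net <- numeric(N)
  for (q in seq_len(N)) for (m in seq_len(M))
    net[q] <- net[q] + mu[m] * node_out[m, q]
  best <- 1L
  for (q in seq_len(N)) if (net[q] > net[best]) best <- q
  list(class = best, net = net, node_out = node_out)
}

# Plurality vote over base acceptances, ties to the lowest class index.
oracle_plurality <- function(accepts) {
  counts <- colSums(accepts)
  best <- 1L
  for (q in seq_along(counts)) if (counts[q] > counts[best]) best <- q
  best
}
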