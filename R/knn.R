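# Deterministic k-nearest-neighbour primitives used by the base classifiers.
# Ties in distance are broken by training-row index; with odd k a binary
# majority vote can never tie, so prediction is fully deterministic.

squared_dists <- function(test, train) {
  # ntest x ntrain matrix of squared Euclidean distances
  d2 <- outer(rowSums(test^2), rowSums(train^2), "+") - 2 * tcrossprod(test, train)
  d2[d2 < 0] <- 0
  d2
}

knn_vote <- function(d2, accept, k) {
  # d2: ntest x ntrain; accept: logical per training row
  apply(d2, 1, function(d) {
    nn <- order(d, seq_along(d))[seq_len(k)]
    sum(accept[nn]) * 2 > k
  })
}

# Leave-one-out binary accuracy over a grid of k values, from one distance
# matrix. Returns the accuracy per grid entry.
knn_loo_accuracy <- function(X, accept, k_grid) {
  n <- nrow(X)
  d2 <- squared_dists(X, X)
  diag(d2) <- Inf
  ord <- apply(d2, 1, function(d) order(d, seq_along(d)))  # ntrain x ntest
  vapply(k_grid, function(k) {
    pred <- vapply(seq_len(n),
                   function(i) sum(accept[ord[seq_len(k), i]]) * 2 > k,
                   logical(1))
    mean(pred == accept)
  }, numeric(1))
}
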