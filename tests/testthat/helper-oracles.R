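# Independent brute-force oracles used against the package implementations.

# Exhaustive posterior marginals and summed two-slice counts for an HMM with
# (possibly unnormalized) start/transition/emission weights, by enumerating
# all K^T state sequences.
enum_posterior <- function(log_pi, log_A, log_B) {
  T_ <- nrow(log_B); K <- ncol(log_B)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logw <- apply(seqs, 1L, function(s) {
    w <- log_pi[s[1]] + log_B[1, s[1]]
    if (T_ > 1L) for (t in 2:T_)
      w <- w + log_A[s[t - 1], s[t]] + log_B[t, s[t]]
    w
  })
  m <- max(logw)
  w <- exp(logw - m)
  Z <- sum(w)
  gamma <- matrix(0, T_, K)
  xi <- matrix(0, K, K)
  for (i in seq_len(nrow(seqs))) {
    s <- seqs[i, ]
    for (t in seq_len(T_)) gamma[t, s[t]] <- gamma[t, s[t]] + w[i]
    if (T_ > 1L) for (t in seq_len(T_ - 1L))
      xi[s[t], s[t + 1]] <- xi[s[t], s[t + 1]] + w[i]
  }
  list(gamma = gamma / Z, xi = xi / Z, loglik = m + log(Z))
}

# Exhaustive Viterbi: lexicographically smallest argmax sequence.
enum_viterbi <- function(log_pi, log_A, log_B) {
  T_ <- nrow(log_B); K <- ncol(log_B)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  # expand.grid varies the first column fastest; reorder rows so that
  # sequences are in lexicographic order of (s1, s2, ..., sT)
  seqs <- seqs[do.call(order, as.data.frame(seqs)), , drop = FALSE]
  best <- -Inf; best_s <- NULL
  for (i in seq_len(nrow(seqs))) {
    s <- seqs[i, ]
    w <- log_pi[s[1]] + log_B[1, s[1]]
    if (T_ > 1L) for (t in 2:T_)
      w <- w + log_A[s[t - 1], s[t]] + log_B[t, s[t]]
    if (w > best + 1e-12) { best <- w; best_s <- s }
  }
  as.integer(best_s)
}

# Master-equation occupancy for a rate matrix via dense series expansion of
# the matrix exponential (independent of the sampling code).
occupancy_at <- function(rate_matrix, p0, t, n_terms = 60L) {
  K <- nrow(rate_matrix)
  Q <- rate_matrix
  diag(Q) <- -rowSums(Q)
  M <- diag(K)
  out <- diag(K)
  for (n in seq_len(n_terms)) {
    M <- M %*% (Q * t) / n
    out <- out + M
  }
  as.numeric(p0 %*% out)
}

make_record <- function(efret, frame_interval = 2.67, mask = NULL,
                        id = "r1", end_cause = "bleach_or_loss") {
  efret_record(id, t0 = 0,
               time = (seq_along(efret) - 1) * frame_interval,
               efret = efret, end_cause = end_cause,
               frame_interval = frame_interval, mask = mask)
}

# random (log-space) HMM weights for oracle comparisons
random_hmm <- function(T_, K, seed) {
  set.seed(seed)
  pi0 <- rgamma(K, 1) + 0.05; pi0 <- pi0 / sum(pi0)
  A <- matrix(rgamma(K * K, 1) + 0.05, K, K); A <- A / rowSums(A)
  B <- matrix(rnorm(T_ * K), T_, K)
  list(log_pi = log(pi0), log_A = log(A), log_B = B)
}
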