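# Shared fixture builders; everything is generated in code under fixed seeds.

# Random valid HMM spec over hidden graphs.
random_hmm_spec <- function(H, T_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pi <- stats::runif(H)
  pi <- pi / sum(pi)
  A <- matrix(stats::runif(H * H), H, H)
  A <- A / rowSums(A)
  B <- matrix(stats::runif(H * T_, 0.05, 1), H, T_)
  node_hmm_spec(pi, A, B)
}

# Exhaustive-path oracle: joint enumeration over all H^T hidden paths.
enumerate_posteriors <- function(spec) {
  H <- spec$H
  T_ <- spec$T
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), T_)))
  pr <- apply(paths, 1L, function(q) {
    p <- spec$pi[q[1L]] * spec$B[q[1L], 1L]
    if (T_ > 1L)
      for (t in 2:T_)
        p <- p * spec$A[q[t - 1L], q[t]] * spec$B[q[t], t]
    p
  })
  Z <- sum(pr)
  gamma <- matrix(0, H, T_)
  for (t in seq_len(T_))
    for (h in seq_len(H))
      gamma[h, t] <- sum(pr[paths[, t] == h]) / Z
  xi <- if (T_ > 1L) {
    x <- array(0, c(H, H, T_ - 1L))
    for (t in seq_len(T_ - 1L))
      for (h in seq_len(H))
        for (g in seq_len(H))
          x[h, g, t] <- sum(pr[paths[, t] == h & paths[, t + 1L] == g]) / Z
    x
  } else NULL
  best <- which.max(pr)   # ties: expand.grid varies the first column fastest,
                          # so the lowest-index path comes first
  list(gamma = gamma, xi = xi, loglik = log(Z), map_path = paths[best, ],
       map_prob = pr[best])
}

# Simulate a child that copies one parent (or a designated regime of
# parents) with given fidelity; returns a discrete_ts.
simulate_switching_child <- function(T_, regimes, fidelity = 0.95,
                                     n_extra = 0L, seed = 1L) {
  # regimes: list of list(from = t0, parent = j or NA for none)
  set.seed(seed)
  regimes <- lapply(regimes, function(r) {
    r$parent <- as.integer(r$parent)
    r
  })
  n_par <- max(vapply(regimes, function(r) ifelse(is.na(r$parent), 0L,
                                                  r$parent), 0L))
  N <- max(2L, n_par, 1L + n_extra + 1L)
  x <- matrix(sample(0:1, N * (T_ + 1L), replace = TRUE), N, T_ + 1L)
  starts <- vapply(regimes, function(r) r$from, numeric(1L))
  for (t in seq_len(T_)) {
    k <- max(which(starts <= t))
    j <- regimes[[k]]$parent
    if (!is.na(j))
      x[1L, t + 1L] <- ifelse(stats::runif(1) < fidelity, x[j, t],
                              sample(0:1, 1L))
  }
  discrete_timeseries(x, arities = rep(2L, N))
}

# Minimal stand-in node model for decode/assemble tests.
fake_node <- function(node, graphs, path, T_) {
  H <- length(graphs)
  gamma <- matrix(0, H, T_)
  gamma[cbind(path, seq_len(T_))] <- 1
  structure(list(node = node,
                 hgs = hidden_graph_set(node, graphs),
                 spec = node_hmm_spec(rep(1 / H, H),
                                      matrix(1 / H, H, H),
                                      pmax(gamma, 1e-6)),
                 post = structure(list(gamma = gamma, loglik = 0,
                                       H = H, T = T_),
                                  class = "hmm_posteriors"),
                 score = 0, converged = TRUE),
            class = "node_hmdbn")
}
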