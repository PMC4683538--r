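#' Per-node HMM specification over hidden graphs
#'
#' An HMM whose hidden states are a node's candidate parent-set
#' configurations ("hidden graphs"). The emission likelihoods are
#' precomputed per time point: `B[h, t] = P(x_i(t) | hidden graph h, x(t-1))`
#' from the multinomial CPD of graph h (see [emission_matrix()]).
#'
#' @param pi initial distribution over the H hidden graphs (sums to 1).
#' @param A H x H transition matrix, rows summing to 1.
#' @param B H x T emission-likelihood matrix, entries in `[0, 1]`.
#' @return An object of class `node_hmm_spec`.
#' @export
node_hmm_spec <- function(pi, A, B) {
  pi <- as.numeric(pi)
  A <- as.matrix(A)
  B <- as.matrix(B)
  H <- length(pi)
  if (!all(dim(A) == c(H, H)) || nrow(B) != H)
    stop("dimension mismatch between pi, A and B")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("rows of A must sum to 1")
  if (any(pi < 0) || any(A < 0) || any(B < 0))
    stop("probabilities must be non-negative")
  if (any(B > 1 + 1e-12)) stop("emission likelihoods must be <= 1")
  if (any(!is.finite(B))) stop("non-finite emission likelihoods")
  structure(list(pi = pi, A = A, B = B, H = H, T = ncol(B)),
            class = "node_hmm_spec")
}

#' @export
print.node_hmm_spec <- function(x, ...) {
  cat(sprintf("node_hmm_spec: H = %d hidden graphs, T = %d\n", x$H, x$T))
  invisible(x)
}

#' Scaled forward-backward posteriors
#'
#' Computes the exact smoothing posteriors of a discrete HMM with
#' Rabiner-style per-step scaling, so series of at least 10^4 points run
#' without underflow. `gamma[h, t]` is the posterior probability that time
#' point t was generated by hidden graph h; `xi[h, g, t]` is the pairwise
#' posterior of (h at t, g at t+1). The log-likelihood is the sum of the
#' log scaling constants.
#'
#' @param spec a [node_hmm_spec()].
#' @param full_xi return the full pairwise-posterior array (default) or,
#'   when `FALSE`, only its sum over t (`xi_sum`) as used by EM updates.
#' @return An object of class `hmm_posteriors`: `gamma` (H x T), `xi`
#'   (H x H x (T-1)) or `xi_sum` (H x H), `loglik`.
#' @export
forward_backward <- function(spec, full_xi = TRUE) {
  stopifnot(inherits(spec, "node_hmm_spec"))
  zero <- which(colSums(spec$B) == 0)
  if (length(zero))
    stop("emission column identically zero at t = ", zero[1L])
  out <- .fb_kernel(spec$pi, spec$A, spec$B, full_xi)
  out$H <- spec$H
  out$T <- spec$T
  structure(out, class = "hmm_posteriors")
}

#' Viterbi decoding of the hidden-graph path
#'
#' Maximum a posteriori joint state path, computed in log space. Ties are
#' broken toward the lower state index, deterministically across platforms.
#'
#' @param spec a [node_hmm_spec()].
#' @return Integer vector of length T with 1-based hidden-graph indices.
#' @export
viterbi <- function(spec) {
  stopifnot(inherits(spec, "node_hmm_spec"))
  zero <- which(colSums(spec$B) == 0)
  if (length(zero))
    stop("emission column identically zero at t = ", zero[1L])
  .viterbi_kernel(spec$pi, spec$A, spec$B)
}

#' Re-estimate the initial hidden-graph distribution
#'
#' Baum-Welch M-step for the prior: the posterior over hidden graphs at the
#' first time point.
#'
#' @param post an [forward_backward()] result.
#' @return Numeric vector of length H summing to 1.
#' @export
reestimate_pi <- function(post) {
  stopifnot(inherits(post, "hmm_posteriors"))
  p <- post$gamma[, 1L]
  p / sum(p)
}

#' Re-estimate the hidden-graph transition matrix
#'
#' Baum-Welch M-step for A: expected transition counts divided by expected
#' occupancy, `a[h, g] = sum_t xi[h, g, t] / sum_t gamma[h, t]` over
#' t = 1..T-1. A row whose expected occupancy is (numerically) zero carries
#' no information and falls back to the corresponding row of `prev` when
#' supplied, else to uniform.
#'
#' @param post an [forward_backward()] result (needs T >= 2).
#' @param prev optional previous transition matrix supplying fallback rows.
#' @return H x H matrix with rows summing to 1.
#' @export
reestimate_A <- function(post, prev = NULL) {
  stopifnot(inherits(post, "hmm_posteriors"))
  H <- post$H
  if (H == 1L) return(matrix(1, 1L, 1L))
  if (post$T < 2L) stop("need T >= 2 to re-estimate transitions")
  num <- if (!is.null(post$xi_sum)) post$xi_sum
         else apply(post$xi, c(1L, 2L), sum)
  den <- rowSums(num)
  A <- num
  for (h in seq_len(H)) {
    if (den[h] > 1e-300) {
      A[h, ] <- num[h, ] / den[h]
    } else if (!is.null(prev)) {
      A[h, ] <- prev[h, ]
    } else {
      A[h, ] <- 1 / H
    }
  }
  A
}
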