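#' Time-evolving posterior of a single candidate edge
#'
#' Fits the smallest possible non-stationary model for child i and
#' candidate regulator j: a 2-state HMM whose hidden graphs are the empty
#' parent set and `{j}`. The inner Baum-Welch EM (emission update,
#' forward-backward, prior/transition/CPD re-estimation) is run to
#' convergence and the posterior of the with-parent state is returned as
#' the per-time probability that the edge j -> i is active.
#'
#' The fitted 2-state model competes against the two stationary
#' alternatives — no parent at all, and the parent active at every time
#' point — under the BWBIC criterion (the identification of hidden graphs
#' belongs to the search machinery and is the same whichever metric the
#' outer search uses for acceptance). The winner classifies the edge:
#' `"null"` (presence identically 0: the parent carries no signal and
#' must not dilute the configuration posteriors), `"static"` (presence
#' identically 1), or `"dynamic"` (the 2-state posterior itself). Ties
#' favor the simpler model.
#'
#' @param data a [discrete_timeseries()].
#' @param node child node index i.
#' @param parent candidate parent index j (different from i).
#' @param cfg a [search_config()]; its ablation switches also freeze this
#'   HMM's transition matrix.
#' @param null_fit optional precomputed [refine_hmdbn()] result for the
#'   empty parent set (cached by the search).
#' @return An object of class `edge_posterior`: `parent`, `presence`
#'   (length-T vector in `[0, 1]`), `mode` (`"null"`, `"static"`,
#'   `"dynamic"`), and the converged 2-state `fit` (a `node_hmdbn`).
#' @export
single_edge_hmm <- function(data, node, parent, cfg = search_config(),
                            null_fit = NULL) {
  if (node == parent) stop("a node cannot regulate itself across one slice")
  guard_cfg <- cfg
  guard_cfg$score <- "bwbic"
  hgs <- hidden_graph_set(node, list(integer(0), parent))
  r <- data$arities[node]
  T_ <- ncol(data$values) - 1L
  # init CPDs from whole-series counts: marginal table for the empty graph,
  # conditional-on-parent table for {j}
  cnt <- expected_counts(data, node, hgs, matrix(1, 2L, T_) / 2)
  cnt$counts <- lapply(cnt$counts, function(n) 2 * n)  # undo the 1/2 split
  theta_init <- mle_cpd(cnt, smoothing = 0.5)
  fit <- refine_hmdbn(data, node, hgs, guard_cfg, theta_init = theta_init)
  if (is.null(null_fit) || null_fit$cfg_score != "bwbic")
    null_fit <- refine_hmdbn(data, node,
                             hidden_graph_set(node, list(integer(0))),
                             guard_cfg)
  static_fit <- refine_hmdbn(data, node,
                             hidden_graph_set(node, list(parent)),
                             guard_cfg)
  mode <- if (null_fit$score >= max(fit$score, static_fit$score)) "null"
          else if (static_fit$score >= fit$score) "static"
          else "dynamic"
  presence <- switch(mode,
                     null = rep(0, T_),
                     static = rep(1, T_),
                     dynamic = fit$post$gamma[2L, ])
  structure(list(parent = parent, presence = presence, mode = mode,
                 fit = fit),
            class = "edge_posterior")
}

#' Combine single-edge posteriors into parent-configuration posteriors
#'
#' Treats the candidate edges as independent per time point: the posterior
#' of the configuration with active subset `c` of the candidate set S is
#' the product of `presence_j(t)` over j in c and `1 - presence_j(t)` over
#' j outside c, renormalized per column. Configurations are enumerated in
#' binary-counting order with the first element of S as the lowest bit.
#'
#' @param edges list of [single_edge_hmm()] results, one per candidate
#'   parent, in ascending parent order.
#' @return `2^|S| x T` matrix with columns summing to 1 and an attribute
#'   `configs`: the list of parent subsets matching the rows.
#' @export
combine_edge_posteriors <- function(edges) {
  m <- length(edges)
  if (!m) stop("need at least one edge posterior")
  parents <- vapply(edges, function(e) e$parent, numeric(1L))
  T_ <- length(edges[[1L]]$presence)
  P <- matrix(1, 2^m, T_)
  configs <- vector("list", 2^m)
  for (c_ in 0:(2^m - 1L)) {
    row <- rep(1, T_)
    sel <- integer(0)
    for (k in seq_len(m)) {
      p <- edges[[k]]$presence
      if (bitwAnd(bitwShiftR(c_, k - 1L), 1L) == 1L) {
        row <- row * p
        sel <- c(sel, parents[k])
      } else {
        row <- row * (1 - p)
      }
    }
    P[c_ + 1L, ] <- row
    configs[[c_ + 1L]] <- sort(as.integer(sel))
  }
  cs <- colSums(P)
  zero <- cs <= 0
  if (any(zero)) {
    P[, zero] <- 1 / 2^m
    cs[zero] <- 1
  }
  P <- sweep(P, 2L, cs, "/")
  attr(P, "configs") <- configs
  P
}

#' Identify putative hidden graphs from configuration posteriors
#'
#' Keeps the configurations whose expected occupancy (posterior summed over
#' time) exceeds `support_threshold * T`; the globally dominant
#' configuration is always kept, and at most `H_max` graphs are retained
#' (highest occupancy first; ties favor fewer parents, then the lower
#' configuration index). Graphs are returned in configuration order.
#'
#' @param combined a [combine_edge_posteriors()] matrix.
#' @param node child node index for the resulting [hidden_graph_set()].
#' @param support_threshold occupancy fraction of T below which a
#'   configuration is dropped (default 0.05).
#' @param H_max maximum number of hidden graphs (default 6).
#' @return A [hidden_graph_set()] with attribute `keep_rows`, the indices
#'   of the retained rows of `combined`.
#' @export
identify_hidden_graphs <- function(combined, node, support_threshold = 0.05,
                                   H_max = 6L) {
  configs <- attr(combined, "configs")
  if (is.null(configs)) stop("combined must carry a 'configs' attribute")
  occ <- rowSums(combined)
  T_ <- ncol(combined)
  sizes <- lengths(configs)
  pref <- order(-occ, sizes, seq_along(occ))
  keep <- which(occ > support_threshold * T_)
  keep <- union(pref[1L], keep)          # always keep the dominant config
  keep <- pref[pref %in% keep]
  if (length(keep) > H_max) keep <- keep[seq_len(H_max)]
  keep <- sort(keep)                     # stable configuration order
  hgs <- hidden_graph_set(node, configs[keep])
  attr(hgs, "keep_rows") <- keep
  hgs
}

#' Fit a node's non-stationary model for a fixed hidden-graph set
#'
#' The inner EM of the structural search: alternates the emission update
#' (maximum-likelihood CPDs from expected counts), forward-backward, and
#' re-estimation of the prior and transition matrix, until the relative
#' log-likelihood change falls below `tol` or `max_iter` iterations. The
#' log-likelihood sequence is nondecreasing (exact M-steps); the converged
#' model is scored with the criterion named in `cfg$score` (BWBIC on the
#' soft expected counts, or BIC/BDe on the argmax hard segmentation).
#'
#' @param data a [discrete_timeseries()].
#' @param node child node index.
#' @param hgs a [hidden_graph_set()] for that node.
#' @param cfg a [search_config()]; ablation switches freeze the transition
#'   matrix (see [apply_ablation()]).
#' @param gamma_init optional H x T posterior used (via its per-time
#'   argmax) to initialize the CPDs; defaults to a uniform split.
#' @param theta_init optional [mle_cpd()] table overriding CPD
#'   initialization.
#' @param max_iter,tol inner-EM stopping rule.
#' @return An object of class `node_hmdbn`: `node`, `hgs`, `spec`
#'   ([node_hmm_spec()] at convergence), `cpd` (unsmoothed), `post`
#'   (`gamma`, `loglik`), `counts`, `score`, `loglik_trace`, `converged`.
#' @export
refine_hmdbn <- function(data, node, hgs, cfg = search_config(),
                         gamma_init = NULL, theta_init = NULL,
                         max_iter = 100L, tol = 1e-5) {
  H <- hgs$H
  T_ <- ncol(data$values) - 1L
  sq <- graph_sequences(data, node, hgs)
  r <- sq$r

  counts_of <- function(gamma) {
    counts <- vector("list", H)
    for (h in seq_len(H))
      counts[[h]] <- .soft_counts_kernel(sq$jseq[[h]], sq$kseq, gamma[h, ],
                                         as.integer(sq$q[h]), r)
    structure(list(counts = counts,
                   occupancy = vapply(counts, sum, numeric(1L)),
                   q = sq$q, r = r, T = T_, node = node),
              class = "expected_counts")
  }
  emission_of <- function(cpd) {
    B <- matrix(0, H, T_)
    for (h in seq_len(H))
      B[h, ] <- .emission_row_kernel(cpd$theta[[h]], sq$jseq[[h]], sq$kseq)
    B
  }
  finish <- function(pi, A, gamma, loglik, trace, converged, n_iter,
                     xi_sum = NULL) {
    counts <- counts_of(gamma)
    cpd <- mle_cpd(counts, smoothing = 0)
    spec <- node_hmm_spec(pi, A, pmin(emission_of(cpd), 1))
    # BIC/BDe demarcate time points by the Viterbi path (Viterbi-training
    # convention): under sticky optimized transitions near-tied posteriors
    # stay in one regime instead of donating per-point selection noise to
    # whichever graph fits each observation best.
    score <- switch(cfg$score,
      bwbic = bwbic_score(counts, cpd, r) +
        chain_score(gamma, xi_sum, pi, A, cfg, T_),
      bic = bic_score(data, node, hgs, viterbi(spec)),
      bde = bde_score(data, node, hgs, viterbi(spec),
                      alpha = cfg$bde_alpha))
    structure(list(node = node, hgs = hgs, spec = spec, cpd = cpd,
                   post = structure(list(gamma = gamma, loglik = loglik,
                                         H = H, T = T_),
                                    class = "hmm_posteriors"),
                   counts = counts, score = score, cfg_score = cfg$score,
                   loglik_trace = trace,
                   converged = converged, n_iter = n_iter),
              class = "node_hmdbn")
  }

  # Stationary fast path: one graph, posteriors are identically 1.
  if (H == 1L) {
    gamma <- matrix(1, 1L, T_)
    counts <- counts_of(gamma)
    cpd <- mle_cpd(counts, smoothing = 0)
    B <- emission_of(cpd)
    loglik <- sum(log(pmax(B[1L, ], 1e-12)))
    return(finish(1, matrix(1, 1L, 1L), gamma, loglik,
                  trace = loglik, converged = TRUE, n_iter = 1L))
  }

  # initialization
  if (is.null(theta_init)) {
    g0 <- if (is.null(gamma_init)) matrix(1 / H, H, T_)
          else hard_gamma(hard_segments_from_gamma(gamma_init), H)
    theta <- mle_cpd(counts_of(g0), smoothing = 0.5)
  } else {
    theta <- theta_init
  }
  pi <- rep(1 / H, H)
  A <- init_transition(H, cfg)
  frozen <- transitions_frozen(cfg)

  em <- .em_refine_kernel(pi, A, theta$theta, sq$jseq, sq$kseq,
                          as.integer(sq$q), r, frozen,
                          as.integer(max_iter), tol)
  if (!em$converged && cfg$verbose)
    warning(sprintf("inner EM for node %d (H = %d) stopped at %d iterations without meeting tol",
                    node, H, max_iter), call. = FALSE)
  finish(em$pi, em$A, em$gamma, em$loglik, em$trace, em$converged,
         em$n_iter, xi_sum = em$xi_sum)
}

# Expected log-probability of the hidden-graph chain at the re-estimated
# prior and transition matrix, minus the BIC penalty for their free
# parameters. This is the part of the structural-EM objective that the
# M-step maximizes over (pi, A); it is what lets persistent regimes share
# information across segments and what charges a candidate for erratic
# switching between hidden graphs. When an ablation freezes the transition
# matrix nothing is optimized there, so the term contributes neither
# likelihood nor parameters and the criterion reduces to the expected-count
# marginal likelihood alone. Zero for a single graph either way, so the
# stationary limit always reduces to plain BIC.
chain_score <- function(gamma, xi_sum, pi, A, cfg, T_) {
  H <- length(pi)
  if (H == 1L || transitions_frozen(cfg)) return(0)
  xlogy <- function(x, y) ifelse(x > 0, x * log(pmax(y, 1e-300)), 0)
  ll <- sum(xlogy(gamma[, 1L], pi))
  if (!is.null(xi_sum)) ll <- ll + sum(xlogy(xi_sum, A))
  d_chain <- (H - 1) + H * (H - 1)
  ll - d_chain / 2 * log(T_)
}
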