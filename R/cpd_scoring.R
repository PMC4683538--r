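#' Hidden-graph set for one node
#'
#' The candidate parent-set configurations G_i^(1..H) a node may switch
#' between over time. Edges always point from the previous time slice, so a
#' node is never its own parent and any directed structure (cycles included,
#' when read as a static graph) is admissible.
#'
#' @param node 1-based index of the child node.
#' @param graphs list of integer vectors of parent node indices (possibly
#'   empty); duplicates are not allowed.
#' @return An object of class `hidden_graph_set`.
#' @export
hidden_graph_set <- function(node, graphs) {
  node <- as.integer(node)
  if (!length(graphs)) stop("need at least one hidden graph")
  graphs <- lapply(graphs, function(g) sort(as.integer(g)))
  if (any(vapply(graphs, function(g) node %in% g, logical(1L))))
    stop("a node cannot be its own parent (previous-slice edges only)")
  keys <- vapply(graphs, paste, "", collapse = ",")
  if (anyDuplicated(keys)) stop("hidden graphs must be distinct parent sets")
  structure(list(node = node, graphs = graphs, H = length(graphs)),
            class = "hidden_graph_set")
}

#' @export
print.hidden_graph_set <- function(x, ...) {
  cat(sprintf("hidden_graph_set: node %d, H = %d graphs\n", x$node, x$H))
  for (h in seq_len(x$H))
    cat(sprintf("  G^(%d): {%s}\n", h, paste(x$graphs[[h]], collapse = ", ")))
  invisible(x)
}

# Per-graph parent-configuration index sequences j(t-1) for t = 1..T,
# 0-based, plus the child observation sequence k(t). Computed once per
# (data, node, graph set) and reused across EM iterations.
graph_sequences <- function(data, node, hgs) {
  x <- data$values
  jseq <- lapply(hgs$graphs, function(g) {
    if (!length(g)) integer(ncol(x) - 1L)
    else .config_seq_kernel(x, g, data$arities[g])
  })
  list(jseq = jseq,
       kseq = x[node, -1L],
       q = vapply(hgs$graphs, function(g)
         if (length(g)) prod(data$arities[g]) else 1L, numeric(1L)),
       r = data$arities[node])
}

#' Expected (soft) contingency counts per hidden graph
#'
#' For each hidden graph h, `counts[[h]][j+1, k+1]` accumulates
#' `sum_t gamma[h, t] * [parents_h(t-1) = j] * [x_i(t) = k]`; `occupancy[h]`
#' is the expected sample size attributed to graph h, `sum_t gamma[h, t]`.
#' With a one-hot gamma these reduce to hard contingency counts.
#'
#' @param data a [discrete_timeseries()].
#' @param node child node index.
#' @param hgs a [hidden_graph_set()] for that node.
#' @param gamma H x T posterior matrix with normalized columns.
#' @return An object of class `expected_counts` with `counts` (list of
#'   q_h x r matrices), `occupancy`, `q`, `r`, `T`.
#' @export
expected_counts <- function(data, node, hgs, gamma) {
  gamma <- as.matrix(gamma)
  T_ <- ncol(data$values) - 1L
  if (nrow(gamma) != hgs$H || ncol(gamma) != T_)
    stop("gamma must be H x T (", hgs$H, " x ", T_, ")")
  sq <- graph_sequences(data, node, hgs)
  counts <- vector("list", hgs$H)
  for (h in seq_len(hgs$H))
    counts[[h]] <- .soft_counts_kernel(sq$jseq[[h]], sq$kseq, gamma[h, ],
                                       as.integer(sq$q[h]), sq$r)
  structure(list(counts = counts,
                 occupancy = vapply(counts, sum, numeric(1L)),
                 q = sq$q, r = sq$r, T = T_, node = node),
            class = "expected_counts")
}

#' Maximum-likelihood multinomial CPD from expected counts
#'
#' `theta[j+1, k+1] = (N[j,k] + eps) / (sum_k N[j,k] + eps * r)` per hidden
#' graph. With `smoothing = 0` a configuration row with zero total count is
#' undefined and falls back to the uniform distribution.
#'
#' @param counts an [expected_counts()] object.
#' @param smoothing pseudo-count added to every cell (default 0.5).
#' @return An object of class `cpd_table`: list `theta` of q_h x r matrices.
#' @export
mle_cpd <- function(counts, smoothing = 0.5) {
  stopifnot(inherits(counts, "expected_counts"), smoothing >= 0)
  r <- counts$r
  theta <- lapply(counts$counts, function(n) {
    tot <- rowSums(n) + smoothing * r
    th <- (n + smoothing) / tot
    zero <- tot == 0
    if (any(zero)) th[zero, ] <- 1 / r
    th
  })
  structure(list(theta = theta, r = r, q = counts$q),
            class = "cpd_table")
}

#' Emission-likelihood matrix from a CPD table
#'
#' `B[h, t] = theta_h[j_h(t-1), x_i(t)]`: the probability of the observed
#' child state at t under hidden graph h, given the parents' states at t-1.
#'
#' @param data,node,hgs as in [expected_counts()].
#' @param cpd a [mle_cpd()] result.
#' @return H x T numeric matrix.
#' @export
emission_matrix <- function(data, node, hgs, cpd) {
  sq <- graph_sequences(data, node, hgs)
  T_ <- length(sq$kseq)
  B <- matrix(0, hgs$H, T_)
  for (h in seq_len(hgs$H))
    B[h, ] <- .emission_row_kernel(cpd$theta[[h]], sq$jseq[[h]], sq$kseq)
  B
}

#' Baum-Welch BIC (BWBIC) score of a node's non-stationary model
#'
#' Laplace approximation to the log marginal likelihood of the hidden-graph
#' set, evaluated with expected counts: for each graph h,
#' `sum_{j,k} N[h,j,k] * log theta[h,j,k] - (d_h / 2) * log Nhat_h`, where
#' `d_h = q_h (r - 1)` independent CPD parameters and `Nhat_h` is the
#' expected sample size of graph h. Conventions: `0 * log 0 = 0`, and
#' `log Nhat_h` is floored at 0 (i.e. `Nhat_h` below one observation) so
#' nearly unsupported graphs keep a finite penalty. Higher is better; node
#' scores add across nodes. With a single graph and a one-hot gamma the
#' score is exactly the stationary BIC.
#'
#' @param counts an [expected_counts()] object.
#' @param cpd the matching [mle_cpd()] table, computed with `smoothing = 0`.
#' @param arity child arity r; defaults to the one recorded in `counts`.
#' @return Scalar score.
#' @export
bwbic_score <- function(counts, cpd, arity = counts$r) {
  stopifnot(inherits(counts, "expected_counts"), inherits(cpd, "cpd_table"))
  s <- 0
  for (h in seq_along(counts$counts)) {
    n <- counts$counts[[h]]
    th <- cpd$theta[[h]]
    ll <- sum(ifelse(n > 0, n * log(th), 0))
    d <- counts$q[h] * (arity - 1)
    s <- s + ll - d / 2 * log(max(counts$occupancy[h], 1))
  }
  s
}

#' Hard segmentation from posteriors
#'
#' Per-time argmax over hidden graphs (ties toward the lower index), the
#' Viterbi-training-style demarcation used by the BIC/BDe baselines.
#'
#' @param gamma H x T posterior matrix.
#' @return Integer vector of length T of 1-based graph indices.
#' @export
hard_segments_from_gamma <- function(gamma) {
  max.col(t(as.matrix(gamma)), ties.method = "first")
}

# One-hot gamma from a hard time -> graph assignment.
hard_gamma <- function(assignment, H) {
  T_ <- length(assignment)
  g <- matrix(0, H, T_)
  g[cbind(assignment, seq_len(T_))] <- 1
  g
}

#' Hard-segmented BIC score
#'
#' Classical BIC applied separately to each hidden graph on the time points
#' demarcated to it, then summed: the stationary-metric baseline that
#' assumes each sample belongs entirely to one network. A graph assigned no
#' time points contributes 0.
#'
#' @param data,node,hgs as in [expected_counts()].
#' @param hard_segments integer vector of length T assigning each t to a
#'   graph (typically `hard_segments_from_gamma(gamma)`).
#' @return Scalar score.
#' @export
bic_score <- function(data, node, hgs, hard_segments) {
  T_ <- ncol(data$values) - 1L
  if (length(hard_segments) != T_) stop("hard_segments must have length T")
  counts <- expected_counts(data, node, hgs,
                            hard_gamma(hard_segments, hgs$H))
  bwbic_score(counts, mle_cpd(counts, smoothing = 0))
}

#' Hard-segmented BDe score
#'
#' Dirichlet-multinomial log marginal likelihood per hidden graph on its
#' demarcated time points, with a uniform equivalent-sample-size prior of
#' `alpha / (q_h * r)` per cell, summed over graphs. Computed in log space
#' via `lgamma`. Empty graphs contribute 0.
#'
#' @inheritParams bic_score
#' @param alpha equivalent sample size of the Dirichlet prior (default 1).
#' @return Scalar score.
#' @export
bde_score <- function(data, node, hgs, hard_segments, alpha = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  T_ <- ncol(data$values) - 1L
  if (length(hard_segments) != T_) stop("hard_segments must have length T")
  counts <- expected_counts(data, node, hgs,
                            hard_gamma(hard_segments, hgs$H))
  r <- counts$r
  s <- 0
  for (h in seq_along(counts$counts)) {
    n <- counts$counts[[h]]
    if (sum(n) == 0) next
    q <- counts$q[h]
    a_jk <- alpha / (q * r)
    a_j <- alpha / q
    nj <- rowSums(n)
    s <- s + sum(lgamma(a_j) - lgamma(a_j + nj)) +
      sum(lgamma(a_jk + n) - lgamma(a_jk))
  }
  s
}
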