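#' Search configuration for structural EM
#'
#' Bundles the knobs of the per-node greedy structure search and its inner
#' EM. `fixed_equal_transitions` and `fixed_self_transition` are the two
#' ablation switches: the first freezes every transition matrix at
#' row-uniform (no optimized dependence between successive networks), the
#' second freezes the self-transition probability at `s` with the remaining
#' mass spread uniformly. At most one may be set.
#'
#' @param score scoring criterion: `"bwbic"` (soft expected counts),
#'   `"bic"` or `"bde"` (argmax hard segmentation).
#' @param max_fanin maximum parents per node (default 3).
#' @param H_max maximum hidden graphs per node (default 6).
#' @param support_threshold occupancy fraction for
#'   [identify_hidden_graphs()] (default 0.05).
#' @param fixed_equal_transitions freeze transition matrices at row-uniform.
#' @param fixed_self_transition freeze self-transitions at this value in
#'   (0, 1), off-diagonal uniform; `NULL` to optimize transitions by EM.
#' @param candidate_parents optional allow-list of candidate regulator
#'   indices.
#' @param bde_alpha equivalent sample size of the BDe prior (default 1).
#' @param max_outer_iters cap on accepted moves per node (default 50).
#' @param seed integer seed recorded for reproducibility of optional
#'   randomized extensions; the default search is deterministic.
#' @param verbose print each accepted move.
#' @return An object of class `search_config`.
#' @export
search_config <- function(score = c("bwbic", "bic", "bde"),
                          max_fanin = 3L, H_max = 6L,
                          support_threshold = 0.05,
                          fixed_equal_transitions = FALSE,
                          fixed_self_transition = NULL,
                          candidate_parents = NULL,
                          bde_alpha = 1, max_outer_iters = 50L,
                          seed = 1L, verbose = FALSE) {
  score <- match.arg(score)
  if (max_fanin < 1L) stop("max_fanin must be >= 1")
  if (!is.null(fixed_self_transition)) {
    if (fixed_equal_transitions)
      stop("set at most one of fixed_equal_transitions / fixed_self_transition")
    if (fixed_self_transition <= 0 || fixed_self_transition >= 1)
      stop("fixed_self_transition must lie in (0, 1)")
  }
  structure(list(score = score, max_fanin = as.integer(max_fanin),
                 H_max = as.integer(H_max),
                 support_threshold = support_threshold,
                 fixed_equal_transitions = isTRUE(fixed_equal_transitions),
                 fixed_self_transition = fixed_self_transition,
                 candidate_parents = candidate_parents,
                 bde_alpha = bde_alpha,
                 max_outer_iters = as.integer(max_outer_iters),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "search_config")
}

transitions_frozen <- function(cfg) {
  cfg$fixed_equal_transitions || !is.null(cfg$fixed_self_transition)
}

# Initial (or frozen) transition matrix for H hidden graphs. The default
# strong self-transition encodes the change-point prior implicit in the
# model: regimes persist.
init_transition <- function(H, cfg, self = 0.9) {
  if (H == 1L) return(matrix(1, 1L, 1L))
  if (cfg$fixed_equal_transitions) return(matrix(1 / H, H, H))
  s <- if (!is.null(cfg$fixed_self_transition)) cfg$fixed_self_transition
       else self
  A <- matrix((1 - s) / (H - 1), H, H)
  diag(A) <- s
  A
}

#' Apply an ablation switch to an HMM specification
#'
#' Rewrites the transition matrix according to the configuration:
#' row-uniform under `fixed_equal_transitions`, or self-transition `s` with
#' off-diagonal mass `(1 - s) / (H - 1)` under `fixed_self_transition`.
#' With a single hidden graph the matrix is `[[1]]` regardless. Under
#' either switch the search never re-estimates the matrix.
#'
#' @param spec a [node_hmm_spec()].
#' @param cfg a [search_config()] with at most one ablation switch set.
#' @return The modified `node_hmm_spec`.
#' @export
apply_ablation <- function(spec, cfg) {
  stopifnot(inherits(spec, "node_hmm_spec"))
  if (!transitions_frozen(cfg)) return(spec)
  spec$A <- init_transition(spec$H, cfg)
  spec
}

set_key <- function(s) paste0("{", paste(sort(s), collapse = ","), "}")

# Evaluate one candidate stationary parent set: build the single-edge
# posteriors (cached), combine, identify hidden graphs, refine by EM.
# Distinct candidate sets frequently collapse to the same identified
# graph set (null parents contribute nothing), so converged refinements
# are cached by graph set.
evaluate_parent_set <- function(data, node, parents, cfg, edge_cache,
                                refine_cache = NULL, null_fit = NULL) {
  parents <- sort(parents)
  if (!length(parents)) {
    return(refine_hmdbn(data, node, hidden_graph_set(node, list(integer(0))),
                        cfg))
  }
  edges <- lapply(parents, function(j) {
    key <- as.character(j)
    if (is.null(edge_cache[[key]]))
      edge_cache[[key]] <- single_edge_hmm(data, node, j, cfg,
                                           null_fit = null_fit)
    edge_cache[[key]]
  })
  combined <- combine_edge_posteriors(edges)
  hgs <- identify_hidden_graphs(combined, node,
                                support_threshold = cfg$support_threshold,
                                H_max = cfg$H_max)
  gkey <- paste0("[", paste(vapply(hgs$graphs, paste, "", collapse = ","),
                            collapse = "|"), "]")
  if (!is.null(refine_cache) && !is.null(refine_cache[[gkey]]))
    return(refine_cache[[gkey]])
  keep <- attr(hgs, "keep_rows")
  gamma_init <- combined[keep, , drop = FALSE]
  cs <- colSums(gamma_init)
  gamma_init <- sweep(gamma_init, 2L, ifelse(cs > 0, cs, 1), "/")
  fit <- refine_hmdbn(data, node, hgs, cfg, gamma_init = gamma_init)
  if (!is.null(refine_cache)) refine_cache[[gkey]] <- fit
  fit
}

#' Learn one node's non-stationary sub-network
#'
#' Greedy hill climbing over stationary candidate parent sets, starting
#' from the empty set. Each step proposes every single-parent addition
#' (respecting `max_fanin` and the allow-list) and deletion; each candidate
#' set is transformed into a non-stationary model by the hidden-graph
#' builder and scored; the best strictly improving move is accepted and the
#' search stops when none improves. Ties favor the smaller parent set, then
#' the lexicographically smaller one. Deterministic given the data and
#' configuration.
#'
#' @param data a [discrete_timeseries()].
#' @param node node index to learn.
#' @param cfg a [search_config()].
#' @return The winning `node_hmdbn` (see [refine_hmdbn()]), with extra
#'   fields `stationary_parents` (the accepted candidate set) and `moves`
#'   (data frame of evaluated candidates: parent set, H, score, accepted).
#' @export
learn_node <- function(data, node, cfg = search_config()) {
  N <- nrow(data$values)
  pool <- if (is.null(cfg$candidate_parents)) setdiff(seq_len(N), node)
          else sort(setdiff(as.integer(cfg$candidate_parents), node))
  edge_cache <- new.env(parent = emptyenv())
  score_cache <- new.env(parent = emptyenv())
  refine_cache <- new.env(parent = emptyenv())
  scored <- function(parents) {
    key <- set_key(parents)
    if (is.null(score_cache[[key]]))
      score_cache[[key]] <- evaluate_parent_set(
        data, node, parents, cfg, edge_cache, refine_cache,
        null_fit = score_cache[[set_key(integer(0))]])
    score_cache[[key]]
  }
  log_rows <- list()
  note <- function(parents, fit, accepted) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      parents = set_key(parents), H = fit$hgs$H, score = fit$score,
      accepted = accepted)
  }

  current_set <- integer(0)
  current <- scored(current_set)
  note(current_set, current, TRUE)
  for (step in seq_len(cfg$max_outer_iters)) {
    cands <- list()
    if (length(current_set) < cfg$max_fanin)
      for (j in setdiff(pool, current_set))
        cands[[length(cands) + 1L]] <- sort(c(current_set, j))
    for (j in current_set)
      cands[[length(cands) + 1L]] <- setdiff(current_set, j)
    if (!length(cands)) break
    fits <- lapply(cands, scored)
    scores <- vapply(fits, function(f) f$score, numeric(1L))
    sizes <- lengths(cands)
    best <- order(-scores, sizes,
                  vapply(cands, set_key, ""))[1L]
    if (scores[best] > current$score) {
      current_set <- cands[[best]]
      current <- fits[[best]]
      note(current_set, current, TRUE)
      if (cfg$verbose)
        message(sprintf("node %d: accepted {%s} (H = %d, %s = %.3f)",
                        node, set_key(current_set), current$hgs$H,
                        cfg$score, current$score))
    } else {
      break
    }
  }
  current$stationary_parents <- current_set
  current$moves <- do.call(rbind, log_rows)
  current
}

#' Learn the full time-varying network
#'
#' Learns each node's non-stationary sub-network independently (the
#' likelihood and all scores factorize over nodes, and edges point across
#' time slices, so feedback loops need no special handling) and returns the
#' per-node models; results do not depend on the order nodes are visited.
#'
#' @param data a [discrete_timeseries()].
#' @param cfg a [search_config()].
#' @return An object of class `hmdbn_fit`: list of `node_hmdbn`, one per
#'   node, plus `var_names` and the configuration.
#' @seealso [assemble()] to decode and merge the per-node models.
#' @export
learn_network <- function(data, cfg = search_config()) {
  N <- nrow(data$values)
  nodes <- vector("list", N)
  for (i in seq_len(N)) {
    nodes[[i]] <- tryCatch(learn_node(data, i, cfg),
                           error = function(e)
                             stop("node ", i, " (", data$var_names[i],
                                  "): ", conditionMessage(e), call. = FALSE))
  }
  structure(list(nodes = nodes, var_names = data$var_names, cfg = cfg,
                 T = ncol(data$values) - 1L),
            class = "hmdbn_fit")
}

#' @export
print.hmdbn_fit <- function(x, ...) {
  H <- vapply(x$nodes, function(n) n$hgs$H, numeric(1L))
  cat(sprintf("hmdbn_fit: %d nodes over T = %d, score = %s; hidden graphs per node: %s\n",
              length(x$nodes), x$T, x$cfg$score,
              paste(H, collapse = " ")))
  invisible(x)
}
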