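#' Decode a node's hidden-graph path and transition times
#'
#' Default decoding takes the per-time posterior argmax of gamma (ties
#' toward the lower graph index), which directly reports the hidden graph
#' with the highest probability at each time point without any edge
#' threshold; Viterbi decoding of the joint MAP path is offered as an
#' alternative since the two can differ on ambiguous posteriors. A
#' transition time is the 1-based index of the first time point governed by
#' the new hidden graph.
#'
#' @param nh a `node_hmdbn` (from [refine_hmdbn()] or [learn_node()]).
#' @param mode `"posterior-argmax"` (default) or `"viterbi"`.
#' @return List with `path` (integer graph index per t) and
#'   `transition_times` (possibly empty integer vector).
#' @export
decode_node <- function(nh, mode = c("posterior-argmax", "viterbi")) {
  mode <- match.arg(mode)
  path <- switch(mode,
                 "posterior-argmax" = hard_segments_from_gamma(nh$post$gamma),
                 "viterbi" = viterbi(nh$spec))
  path <- as.integer(path)
  list(path = path,
       transition_times = which(diff(path) != 0L) + 1L)
}

#' Assemble per-node models into a global time-varying network
#'
#' Decodes every node and merges the node-wise parent sets into one
#' piecewise-constant network: the edge j -> i is present at time t iff j
#' is a parent in node i's decoded hidden graph at t. Breakpoints of all
#' nodes are merged, deduplicated and sorted to produce global segments.
#'
#' @param fit an [learn_network()] result (or a list of `node_hmdbn` over a
#'   common T).
#' @param mode decoding mode passed to [decode_node()].
#' @return An object of class `tv_network`: `n_nodes`, `T`, `paths`,
#'   `parents` (per node, per hidden graph), `node_transition_times`,
#'   `breakpoints`, `segments` (data frame `start`, `end`), `segment_edges`
#'   (per segment, 2-column matrix of parent, child), `var_names`.
#' @export
assemble <- function(fit, mode = c("posterior-argmax", "viterbi")) {
  mode <- match.arg(mode)
  nodes <- if (inherits(fit, "hmdbn_fit")) fit$nodes else fit
  var_names <- if (inherits(fit, "hmdbn_fit")) fit$var_names
               else paste0("V", seq_along(nodes))
  Ts <- vapply(nodes, function(n) n$post$T, numeric(1L))
  if (length(unique(Ts)) != 1L)
    stop("all nodes must be decoded over the same T")
  T_ <- as.integer(Ts[[1L]])
  N <- length(nodes)
  dec <- lapply(nodes, decode_node, mode = mode)
  paths <- lapply(dec, `[[`, "path")
  ttimes <- lapply(dec, `[[`, "transition_times")
  breakpoints <- sort(unique(unlist(ttimes)))
  starts <- c(1L, breakpoints)
  ends <- c(breakpoints - 1L, T_)
  segment_edges <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    t0 <- starts[s]
    el <- list()
    for (i in seq_len(N)) {
      pa <- nodes[[i]]$hgs$graphs[[paths[[i]][t0]]]
      if (length(pa)) el[[length(el) + 1L]] <- cbind(pa, i)
    }
    e <- if (length(el)) do.call(rbind, el)
         else matrix(integer(0), 0L, 2L)
    colnames(e) <- c("parent", "child")
    segment_edges[[s]] <- e
  }
  structure(list(n_nodes = N, T = T_, paths = paths,
                 parents = lapply(nodes, function(n) n$hgs$graphs),
                 node_transition_times = ttimes,
                 breakpoints = breakpoints,
                 segments = data.frame(start = starts, end = ends),
                 segment_edges = segment_edges,
                 var_names = var_names),
            class = "tv_network")
}

#' @export
print.tv_network <- function(x, ...) {
  cat(sprintf("tv_network: %d nodes, T = %d, %d segment(s); breakpoints: %s\n",
              x$n_nodes, x$T, nrow(x$segments),
              if (length(x$breakpoints)) paste(x$breakpoints, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Adjacency matrix of a time-varying network at one time point
#'
#' @param net a [assemble()] result.
#' @param t time index in `1..T`.
#' @return N x N logical matrix; `[j, i]` is `TRUE` iff edge j -> i is
#'   active at t (x_i(t) depends on x_j(t-1)).
#' @export
adjacency_at <- function(net, t) {
  if (t < 1L || t > net$T) stop("t out of range 1..", net$T)
  adj <- matrix(FALSE, net$n_nodes, net$n_nodes)
  for (i in seq_len(net$n_nodes)) {
    pa <- net$parents[[i]][[net$paths[[i]][t]]]
    if (length(pa)) adj[pa, i] <- TRUE
  }
  adj
}

#' Write per-segment edge lists as TSV
#'
#' One row per (segment, edge): `segment_start`, `segment_end`, `parent`,
#' `child`, with gene names.
#'
#' @param net a [assemble()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(net, path) {
  rows <- list()
  for (s in seq_len(nrow(net$segments))) {
    e <- net$segment_edges[[s]]
    if (!nrow(e)) next
    rows[[length(rows) + 1L]] <- data.frame(
      segment_start = net$segments$start[s],
      segment_end = net$segments$end[s],
      parent = net$var_names[e[, 1L]],
      child = net$var_names[e[, 2L]])
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(segment_start = integer(0), segment_end = integer(0),
                         parent = character(0), child = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the fitted model as JSON
#'
#' Serializes node-wise hidden graphs, posterior matrices, transition
#' times, and scores for downstream inspection or plotting.
#'
#' @param fit an [learn_network()] result.
#' @param net the matching [assemble()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(fit, net, path) {
  obj <- list(
    var_names = fit$var_names,
    T = net$T,
    score = fit$cfg$score,
    breakpoints = net$breakpoints,
    nodes = lapply(seq_along(fit$nodes), function(i) {
      nh <- fit$nodes[[i]]
      list(node = i, name = fit$var_names[i],
           hidden_graphs = lapply(nh$hgs$graphs, function(g)
             fit$var_names[g]),
           stationary_parents = fit$var_names[nh$stationary_parents],
           transition_times = net$node_transition_times[[i]],
           score = nh$score, loglik = nh$post$loglik,
           gamma = nh$post$gamma)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-segment SIF files for network viewers
#'
#' One SIF file per segment (`<prefix>_seg<k>_<start>-<end>.sif`), each row
#' `parent regulates child`.
#'
#' @param net a [assemble()] result.
#' @param prefix output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_segments_sif <- function(net, prefix) {
  files <- character(0)
  for (s in seq_len(nrow(net$segments))) {
    f <- sprintf("%s_seg%d_%d-%d.sif", prefix, s,
                 net$segments$start[s], net$segments$end[s])
    e <- net$segment_edges[[s]]
    lines <- if (nrow(e))
      paste(net$var_names[e[, 1L]], "regulates", net$var_names[e[, 2L]])
    else character(0)
    writeLines(lines, f)
    files <- c(files, f)
  }
  invisible(files)
}
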