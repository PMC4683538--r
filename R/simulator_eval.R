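# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ground-truth time-varying network specification
#'
#' A piecewise-constant binary network: a list of epochs, each an epoch
#' length (in observations) and an N x N logical adjacency (`[j, i]` means
#' j -> i, i.e. x_i(t) depends on x_j(t-1)). Children follow their parents
#' through a deterministic map (`"or"`, `"parity"`, or `"random"` lookup
#' tables drawn per epoch) with probability `dependence_strength`, else
#' draw uniformly; parentless nodes are uniform coin flips.
#'
#' @param n_nodes number of variables.
#' @param epochs list of `list(length =, adj =)` entries; consecutive
#'   epochs must differ.
#' @param dependence_strength probability the child follows its map.
#' @param family CPD map family.
#' @param maps for `family = "random"`, per-epoch list of per-node lookup
#'   tables (configuration index + 1 -> state).
#' @param seed integer seed recorded with the spec.
#' @return An object of class `true_network_spec`.
#' @export
true_network_spec <- function(n_nodes, epochs, dependence_strength = 0.9,
                              family = c("or", "parity", "random"),
                              maps = NULL, seed = 1L) {
  family <- match.arg(family)
  if (!length(epochs)) stop("need at least one epoch")
  for (e in epochs) {
    if (e$length < 1L) stop("epoch lengths must be >= 1")
    if (!all(dim(e$adj) == c(n_nodes, n_nodes)))
      stop("epoch adjacency must be n_nodes x n_nodes")
    if (any(diag(e$adj))) stop("self-edges are not allowed")
  }
  if (length(epochs) > 1L)
    for (e in seq_len(length(epochs) - 1L))
      if (identical(epochs[[e]]$adj, epochs[[e + 1L]]$adj))
        stop("consecutive epochs must differ")
  if (family == "random" && is.null(maps))
    stop("family 'random' requires lookup tables")
  structure(list(n_nodes = as.integer(n_nodes), epochs = epochs,
                 dependence_strength = dependence_strength,
                 family = family, maps = maps, seed = as.integer(seed),
                 n_obs = as.integer(
                   sum(vapply(epochs, `[[`, numeric(1L), "length")))),
            class = "true_network_spec")
}

#' @export
print.true_network_spec <- function(x, ...) {
  ne <- vapply(x$epochs, function(e) sum(e$adj), numeric(1L))
  cat(sprintf("true_network_spec: %d nodes, %d epochs (%s obs), edges per epoch: %s\n",
              x$n_nodes, length(x$epochs),
              paste(vapply(x$epochs, `[[`, numeric(1L), "length"),
                    collapse = "+"),
              paste(ne, collapse = " ")))
  invisible(x)
}

# Sample a random adjacency with n_edges edges and bounded fan-in.
random_adjacency <- function(n_nodes, n_edges, max_fanin) {
  adj <- matrix(FALSE, n_nodes, n_nodes)
  placed <- 0L
  while (placed < n_edges) {
    i <- sample.int(n_nodes, 1L)
    j <- sample.int(n_nodes, 1L)
    if (i == j || adj[j, i] || sum(adj[, i]) >= max_fanin) next
    adj[j, i] <- TRUE
    placed <- placed + 1L
  }
  adj
}

# Perturb adjacency by exactly n single-edge additions/deletions,
# respecting the fan-in cap and keeping at least one edge.
perturb_adjacency <- function(adj, n_changes, max_fanin) {
  for (k in seq_len(n_changes)) {
    fanin <- colSums(adj)
    addable <- which(!adj & row(adj) != col(adj) &
                       matrix(fanin, nrow(adj), ncol(adj),
                              byrow = TRUE) < max_fanin)
    removable <- which(adj)
    do_add <- if (!length(removable) ||
                  (length(addable) && stats::runif(1) < 0.5)) TRUE
              else FALSE
    if (do_add && length(addable)) {
      adj[addable[sample.int(length(addable), 1L)]] <- TRUE
    } else if (length(removable) > 1L) {
      adj[removable[sample.int(length(removable), 1L)]] <- FALSE
    } else if (length(addable)) {
      adj[addable[sample.int(length(addable), 1L)]] <- TRUE
    }
  }
  adj
}

# Draw epoch lengths ~ U[lo, hi], rescale to a fixed total; for the
# standard benchmark the rescaled lengths are re-drawn until they respect
# the stated 20-400 range.
draw_epoch_lengths <- function(n_epochs, total, lo = 20, hi = 400,
                               enforce_range = TRUE, min_len = 2L) {
  for (try in 1:1000) {
    u <- stats::runif(n_epochs, lo, hi)
    len <- round(u * total / sum(u))
    len[n_epochs] <- total - sum(len[-n_epochs])
    if (all(len >= min_len) &&
        (!enforce_range || all(len >= lo & len <= hi)))
      return(as.integer(len))
  }
  # fall back to an even split perturbed minimally
  len <- rep(total %/% n_epochs, n_epochs)
  len[n_epochs] <- total - sum(len[-n_epochs])
  as.integer(len)
}

#' Ten-node time-varying benchmark generator
#'
#' Draws a random instance of the small benchmark design: 10 binary nodes,
#' a base network of about 10 edges (fan-in at most 3), 7 epochs separated
#' by 6 single-edge changes, epoch lengths between 20 and 400 observations
#' rescaled to 1019 in total. With `segment_samples` set, epoch lengths are
#' instead rescaled so the average per-segment size equals it (the
#' sample-size-robustness variant).
#'
#' @param seed integer seed; different seeds give different topologies.
#' @param segment_samples optional average observations per epoch.
#' @param n_edges base edge count (default 10).
#' @param dependence_strength,family passed to [true_network_spec()].
#' @return A [true_network_spec()].
#' @export
make_benchmark_10node <- function(seed, segment_samples = NULL,
                                  n_edges = 10L, dependence_strength = 0.9,
                                  family = "or") {
  n_nodes <- 10L
  n_epochs <- 7L
  max_fanin <- 3L
  total <- if (is.null(segment_samples)) 1019L
           else as.integer(n_epochs * segment_samples)
  with_seed(seed, {
    lens <- draw_epoch_lengths(n_epochs, total,
                               enforce_range = is.null(segment_samples))
    adj <- random_adjacency(n_nodes, n_edges, max_fanin)
    epochs <- list(list(length = lens[1L], adj = adj))
    for (e in 2:n_epochs) {
      adj <- perturb_adjacency(adj, 1L, max_fanin)
      epochs[[e]] <- list(length = lens[e], adj = adj)
    }
    maps <- if (family == "random") draw_random_maps(epochs, n_nodes)
            else NULL
    true_network_spec(n_nodes, epochs,
                      dependence_strength = dependence_strength,
                      family = family, maps = maps, seed = seed)
  })
}

#' Hundred-node time-varying benchmark generator
#'
#' The larger design: 100 binary nodes, 50 base edges (fan-in at most 3),
#' 5 segments spanning 5000 observations, with 1-3 single-edge changes at
#' each segment boundary.
#'
#' @inheritParams make_benchmark_10node
#' @return A [true_network_spec()].
#' @export
make_benchmark_100node <- function(seed, dependence_strength = 0.9,
                                   family = "or") {
  n_nodes <- 100L
  n_epochs <- 5L
  max_fanin <- 3L
  with_seed(seed, {
    lens <- draw_epoch_lengths(n_epochs, 5000L, lo = 500, hi = 1500,
                               enforce_range = FALSE, min_len = 200L)
    adj <- random_adjacency(n_nodes, 50L, max_fanin)
    epochs <- list(list(length = lens[1L], adj = adj))
    for (e in 2:n_epochs) {
      adj <- perturb_adjacency(adj, sample(1:3, 1L), max_fanin)
      epochs[[e]] <- list(length = lens[e], adj = adj)
    }
    maps <- if (family == "random") draw_random_maps(epochs, n_nodes)
            else NULL
    true_network_spec(n_nodes, epochs,
                      dependence_strength = dependence_strength,
                      family = family, maps = maps, seed = seed)
  })
}

draw_random_maps <- function(epochs, n_nodes) {
  lapply(epochs, function(e)
    lapply(seq_len(n_nodes), function(i) {
      np <- sum(e$adj[, i])
      if (!np) return(integer(0))
      sample(0:1, 2^np, replace = TRUE)
    }))
}

# Epoch index of each observation column 1..n_obs.
epoch_of_column <- function(spec) {
  rep(seq_along(spec$epochs),
      vapply(spec$epochs, `[[`, numeric(1L), "length"))
}

#' Simulate a discrete time series from a true network
#'
#' The first column is drawn uniformly; each later column c is generated
#' under the adjacency of the epoch containing c: a child takes the value
#' of its CPD map applied to its parents at c-1 with probability exactly
#' `dependence_strength`, and the opposite state otherwise, so a strength
#' of 0.5 carries no information about the parents. Parentless nodes are
#' uniform coin flips. Fully determined by `seed`.
#'
#' @param spec a [true_network_spec()].
#' @param seed simulation seed; defaults to one derived from the spec seed
#'   so repeated calls are reproducible.
#' @return A [discrete_timeseries()] with `n_obs` columns (T = n_obs - 1).
#' @export
simulate_timeseries <- function(spec, seed = spec$seed + 700001L) {
  N <- spec$n_nodes
  M <- spec$n_obs
  ds <- spec$dependence_strength
  ep <- epoch_of_column(spec)
  with_seed(seed, {
    x <- matrix(0L, N, M)
    x[, 1L] <- sample(0:1, N, replace = TRUE)
    for (c_ in 2:M) {
      e <- ep[c_]
      adj <- spec$epochs[[e]]$adj
      prev <- x[, c_ - 1L]
      psum <- as.integer(crossprod(adj, prev))
      npar <- colSums(adj)
      v <- switch(spec$family,
                  or = as.integer(psum > 0L),
                  parity = psum %% 2L,
                  random = {
                    vv <- integer(N)
                    for (i in which(npar > 0L)) {
                      pa <- which(adj[, i])
                      j <- parent_config_index(prev[pa], rep(2L, length(pa)))
                      vv[i] <- spec$maps[[e]][[i]][j + 1L]
                    }
                    vv
                  })
      unif <- sample(0:1, N, replace = TRUE)
      follow <- stats::runif(N) < ds
      x[, c_] <- ifelse(npar > 0L, ifelse(follow, v, 1L - v), unif)
    }
    discrete_timeseries(x, arities = rep(2L, N))
  })
}

#' Per-observation precision/recall evaluation
#'
#' Compares the decoded time-varying network against the truth edge-by-edge
#' at every time point t = 1..T: `precision_t = TP_t / (TP_t + FP_t)`
#' (defined as 1 when nothing is predicted) and
#' `recall_t = TP_t / (TP_t + FN_t)` (1 when no true edges), averaged over
#' all t. F1 is computed from the averaged precision and recall by default;
#' `f1_mode = "per-time"` instead averages per-time F1 values.
#'
#' @param truth a [true_network_spec()].
#' @param predicted a [assemble()] result over the same nodes and T.
#' @param f1_mode `"averaged-pr"` (default) or `"per-time"`.
#' @return An object of class `eval_result`: `precision`, `recall`, `f1`.
#' @export
evaluate_network <- function(truth, predicted,
                             f1_mode = c("averaged-pr", "per-time")) {
  f1_mode <- match.arg(f1_mode)
  if (truth$n_nodes != predicted$n_nodes)
    stop("node count mismatch between truth and prediction")
  T_ <- truth$n_obs - 1L
  if (predicted$T != T_)
    stop("prediction covers T = ", predicted$T,
         " but the truth implies T = ", T_)
  ep <- epoch_of_column(truth)[-1L]       # truth epoch governing each t
  truth_breaks <- which(diff(ep) != 0L) + 1L
  bounds <- sort(unique(c(1L, truth_breaks, predicted$breakpoints)))
  ends <- c(bounds[-1L] - 1L, T_)
  psum <- rsum <- fsum <- 0
  for (s in seq_along(bounds)) {
    t0 <- bounds[s]
    len <- ends[s] - t0 + 1L
    tr <- truth$epochs[[ep[t0]]]$adj
    pr <- adjacency_at(predicted, t0)
    tp <- sum(pr & tr)
    fp <- sum(pr & !tr)
    fn <- sum(!pr & tr)
    p <- if (tp + fp == 0L) 1 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 1 else tp / (tp + fn)
    psum <- psum + len * p
    rsum <- rsum + len * r
    fsum <- fsum + len * (if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  precision <- psum / T_
  recall <- rsum / T_
  f1 <- if (f1_mode == "averaged-pr") {
    if (precision + recall == 0) 0
    else 2 * precision * recall / (precision + recall)
  } else fsum / T_
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("precision = %.3f, recall = %.3f, F1 = %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Run a simulation benchmark end to end
#'
#' Generates `n_datasets` random instances of the chosen design (dataset d
#' uses seed `seed + d - 1`), simulates each, learns the network with the
#' given configuration, decodes and assembles it, and evaluates against
#' the truth. Per-dataset failures are recorded, not fatal.
#'
#' @param design `"ten-node"` or `"hundred-node"`.
#' @param n_datasets number of random datasets.
#' @param cfg a [search_config()].
#' @param seed base seed.
#' @param segment_samples optional average per-segment size (ten-node
#'   design only).
#' @param decode_mode passed to [assemble()].
#' @param f1_mode passed to [evaluate_network()].
#' @return An object of class `benchmark_result`: `results` (data frame
#'   with one row per dataset: seed, precision, recall, f1), `medians`,
#'   `quartiles`, and the settings.
#' @export
run_benchmark <- function(design = c("ten-node", "hundred-node"),
                          n_datasets = 25L, cfg = search_config(),
                          seed = 1L, segment_samples = NULL,
                          decode_mode = "posterior-argmax",
                          f1_mode = "averaged-pr") {
  design <- match.arg(design)
  rows <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    ds_seed <- seed + d - 1L
    rows[[d]] <- tryCatch({
      spec <- if (design == "ten-node")
        make_benchmark_10node(ds_seed, segment_samples = segment_samples)
      else make_benchmark_100node(ds_seed)
      data <- simulate_timeseries(spec)
      fit <- learn_network(data, cfg)
      net <- assemble(fit, mode = decode_mode)
      ev <- evaluate_network(spec, net, f1_mode = f1_mode)
      data.frame(dataset = d, seed = ds_seed, precision = ev$precision,
                 recall = ev$recall, f1 = ev$f1, error = NA_character_)
    }, error = function(e)
      data.frame(dataset = d, seed = ds_seed, precision = NA_real_,
                 recall = NA_real_, f1 = NA_real_,
                 error = conditionMessage(e)))
  }
  results <- do.call(rbind, rows)
  ok <- results[!is.na(results$f1), , drop = FALSE]
  med <- function(v) stats::median(v)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    results = results,
    medians = list(precision = med(ok$precision), recall = med(ok$recall),
                   f1 = med(ok$f1)),
    quartiles = list(precision = qs(ok$precision), recall = qs(ok$recall),
                     f1 = qs(ok$f1)),
    design = design, n_datasets = n_datasets, seed = seed,
    segment_samples = segment_samples, score = cfg$score),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %s, %d dataset(s), score = %s%s\n",
              x$design, x$n_datasets, x$score,
              if (!is.null(x$segment_samples))
                sprintf(", avg %d samples/segment", x$segment_samples)
              else ""))
  cat(sprintf("  medians: precision = %.3f, recall = %.3f, F1 = %.3f\n",
              x$medians$precision, x$medians$recall, x$medians$f1))
  invisible(x)
}
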