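#' Null-model configuration
#'
#' Describes one of the four benchmark network models matched to a reference
#' network: fully connected, random regular, Erdos-Renyi G(n, p), or
#' preferential-attachment (Barabasi-Albert) scale-free.
#'
#' @param model `"fully_connected"`, `"random_regular"`, `"erdos_renyi"`, or
#'   `"scale_free"`
#' @param n_nodes node count
#' @param d degree (random regular only)
#' @param p link probability (Erdos-Renyi only)
#' @param m new links per added node (scale-free only)
#' @return object of class `null_config`
#' @export
null_config <- function(model = c("fully_connected", "random_regular",
                                  "erdos_renyi", "scale_free"),
                        n_nodes, d = NULL, p = NULL, m = NULL) {
  model <- match.arg(model)
  n_nodes <- as.integer(n_nodes)
  switch(model,
    random_regular = {
      stopifnot(!is.null(d), d < n_nodes)
      if ((n_nodes * d) %% 2 != 0) stop("n_nodes * d must be even for a regular graph")
    },
    erdos_renyi = stopifnot(!is.null(p), p > 0, p < 1),
    scale_free = stopifnot(!is.null(m), m >= 1, m < n_nodes),
    fully_connected = stopifnot(n_nodes >= 2)
  )
  structure(list(model = model, n_nodes = n_nodes, d = d, p = p, m = m),
            class = "null_config")
}

#' Generate one network from a null-model configuration
#'
#' @param config a [null_config()]
#' @param seed integer seed (ignored for the deterministic complete graph)
#' @param max_edges memory guard for the complete graph
#' @return igraph network with vertex names `"v1"..."vn"`
#' @export
generate_null <- function(config, seed = 1L, max_edges = 5e7) {
  g <- switch(config$model,
    fully_connected = make_complete(config$n_nodes, max_edges = max_edges),
    random_regular = make_random_regular(config$n_nodes, config$d, seed),
    erdos_renyi = make_erdos_renyi(config$n_nodes, config$p, seed),
    scale_free = make_scale_free(config$n_nodes, config$m, seed)
  )
  igraph::graph_attr(g, "name") <- config$model
  g
}

#' Complete graph
#'
#' @param n node count (>= 2)
#' @param max_edges guard: refuse to materialize more than this many edges
#' @return igraph complete graph on `n` named nodes
#' @export
make_complete <- function(n, max_edges = 5e7) {
  stopifnot(n >= 2)
  n_edges <- n * (n - 1) / 2
  if (n_edges > max_edges) {
    stop(sprintf(paste0("complete graph on %d nodes needs %.0f edges ",
                        "(max_edges = %.0f); consider halving n as in ",
                        "memory-constrained benchmark runs"),
                 n, n_edges, max_edges))
  }
  name_nodes(igraph::make_full_graph(n, directed = FALSE))
}

#' Random regular graph
#'
#' @param n node count; `n * d` must be even
#' @param d uniform degree, `d < n`
#' @param seed integer seed
#' @return igraph simple graph with every degree exactly `d`
#' @export
make_random_regular <- function(n, d, seed = 1L) {
  stopifnot(d < n)
  if ((n * d) %% 2 != 0) stop("n * d must be even: no d-regular graph exists")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  name_nodes(igraph::sample_k_regular(n, d, multiple = FALSE))
}

#' Erdos-Renyi G(n, p) graph
#'
#' @param n node count
#' @param p independent link probability, 0 < p < 1
#' @param seed integer seed
#' @return igraph simple graph
#' @export
make_erdos_renyi <- function(n, p, seed = 1L) {
  stopifnot(p > 0, p < 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  name_nodes(igraph::sample_gnp(n, p))
}

#' Preferential-attachment (Barabasi-Albert) graph
#'
#' Growth starts from a star on `m + 1` nodes; each subsequently added node
#' attaches `m` links to distinct existing nodes with probability
#' proportional to their degree, giving `m * (n - m)` edges in total.
#'
#' @param n node count
#' @param m links added per new node, `1 <= m < n`
#' @param seed integer seed
#' @return igraph simple graph
#' @export
make_scale_free <- function(n, m, seed = 1L) {
  stopifnot(m >= 1, m < n)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  start <- igraph::make_star(m + 1, mode = "undirected")
  g <- igraph::sample_pa(n, m = m, directed = FALSE, start.graph = start,
                         algorithm = "psumtree")
  name_nodes(g)
}

#' Null-model configurations matched to a reference network
#'
#' Returns the four standard benchmark configurations: a complete graph at
#' half the reference size (the memory-constrained benchmark convention), a
#' random regular graph at the rounded average degree (decremented if `n * d`
#' would be odd), an Erdos-Renyi graph at the reference density, and a
#' preferential-attachment graph with `m` new links per node (capped at the
#' floor of the reference average degree and at `n - 1`).
#'
#' @param reference igraph network
#' @param m scale-free attachment count (default 6)
#' @return named list of [null_config()] objects
#'   (`fully_connected`, `random_regular`, `erdos_renyi`, `scale_free`)
#' @export
matched_null_configs <- function(reference, m = 6L) {
  s <- network_summary(reference)
  d <- round(s$avg_degree)
  if ((s$n_nodes * d) %% 2 != 0) {
    d <- d - 1L
    message(sprintf("random-regular degree decremented to %d for feasibility", d))
  }
  list(
    fully_connected = null_config("fully_connected",
                                  n_nodes = max(2L, floor(s$n_nodes / 2))),
    random_regular = null_config("random_regular", n_nodes = s$n_nodes, d = d),
    erdos_renyi = null_config("erdos_renyi", n_nodes = s$n_nodes, p = s$density),
    scale_free = null_config("scale_free", n_nodes = s$n_nodes,
                             m = max(1L, min(m, floor(s$avg_degree),
                                             s$n_nodes - 1L)))
  )
}

#' Degree-matched control schedule
#'
#' For each node of a reference removal order, samples (without replacement)
#' a node of `net` whose intact-network degree equals the reference node's
#' degree; when a degree class is exhausted, falls back to the nearest
#' non-empty class. Used to test whether an observed resilience deficit is
#' explained by the degrees of the removed nodes alone.
#'
#' @param net igraph network
#' @param reference_order character vector of node names (subset of `net`)
#' @param seed integer seed
#' @return a `removal_schedule` (scheme `"custom"`) with one node per
#'   reference position
#' @export
degree_matched_schedule <- function(net, reference_order, seed = 1L) {
  nms <- node_names(net)
  if (!all(reference_order %in% nms)) stop("reference order has nodes outside the network")
  deg <- igraph::degree(net)
  names(deg) <- nms
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # pre-shuffled per-degree pools with consumption counters: O(N + E) overall
  perm <- sample.int(length(nms))
  pools <- split(perm, deg[perm])
  used <- vapply(pools, function(x) 0L, integer(1))
  pool_degs <- as.integer(names(pools))
  fallbacks <- 0L
  out <- character(length(reference_order))
  for (i in seq_along(reference_order)) {
    target <- deg[[reference_order[i]]]
    key <- match(target, pool_degs)
    if (is.na(key) || used[key] >= length(pools[[key]])) {
      fallbacks <- fallbacks + 1L
      open <- which(used < lengths(pools))
      key <- open[which.min(abs(pool_degs[open] - target))]
    }
    used[key] <- used[key] + 1L
    out[i] <- nms[pools[[key]][used[key]]]
  }
  if (fallbacks > 0) {
    message(sprintf("%d position(s) fell back to the nearest degree class", fallbacks))
  }
  structure(list(order = out, scheme = "custom", seed = as.integer(seed)),
            class = "removal_schedule")
}

name_nodes <- function(g) {
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}
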