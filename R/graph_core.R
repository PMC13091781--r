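#' Read an undirected edge list into a simple network
#'
#' Reads a whitespace/tab-separated two-column edge list (gene identifiers),
#' drops self-loops, and collapses duplicate and reversed-duplicate lines to a
#' single undirected edge. Lines starting with `#` are comments.
#'
#' @param path path to the edge-list file
#' @param has_header logical; if `TRUE` the first non-comment line is skipped
#' @return an undirected simple [igraph::igraph] with vertex names
#' @export
read_edge_list <- function(path, has_header = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (has_header && length(lines) > 0) lines <- lines[-1]
  if (length(lines) == 0) {
    warning("empty edge list: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed edge-list line %d: fewer than 2 columns", bad[1]))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  edges_to_network(from, to, name = basename(path))
}

#' Build a simple undirected network from endpoint vectors
#'
#' @param from,to character vectors of gene identifiers
#' @param name optional network label stored as graph attribute
#' @return simple undirected igraph; self-loops dropped (count reported via
#'   message), duplicates collapsed
#' @export
edges_to_network <- function(from, to, name = "network") {
  stopifnot(length(from) == length(to))
  loops <- from == to
  if (any(loops)) {
    message(sprintf("dropped %d self-loop line(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::graph_attr(g, "name") <- name
  g
}

#' Write a canonical edge list
#'
#' Endpoints are sorted lexicographically within each edge and edges sorted
#' lexicographically, so reading the output back recovers the same network.
#'
#' @param net an igraph network with vertex names
#' @param path output path
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1), drop = FALSE]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Graph union of several networks
#'
#' Node set and edge set unions with deduplication; mirrors building a
#' consensus interactome from several independently curated interaction maps.
#'
#' @param networks non-empty list of igraph networks with vertex names
#' @return simple undirected igraph
#' @export
union_networks <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 1)
  els <- lapply(networks, function(g) igraph::as_edgelist(g, names = TRUE))
  all_nodes <- unique(unlist(lapply(networks, function(g) {
    igraph::V(g)$name
  })))
  el <- do.call(rbind, els)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  missing <- setdiff(all_nodes, igraph::V(g)$name)
  if (length(missing) > 0) g <- igraph::add_vertices(g, length(missing), name = missing)
  g
}

#' Whole-network summary statistics
#'
#' @param net igraph network with at least one node
#' @return list with `n_nodes`, `n_edges`, `avg_degree` (2E/N), `density`
#'   (2E/(N(N-1)), `NA` for N < 2), `n_components` (isolated nodes count as
#'   size-1 components)
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  stopifnot(n >= 1)
  e <- igraph::ecount(net)
  list(
    n_nodes = n,
    n_edges = e,
    avg_degree = 2 * e / n,
    density = if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_,
    n_components = igraph::count_components(net)
  )
}

#' Per-node topology descriptors
#'
#' Degree, local clustering coefficient, and mean neighbor degree, all on the
#' intact network. Clustering is 0 for degree < 2; neighbor degree is `NA`
#' for isolated nodes.
#'
#' @param net igraph network
#' @return data.frame with columns `gene`, `degree`, `clustering`,
#'   `neighbor_degree`
#' @export
node_topology <- function(net) {
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  knn <- igraph::knn(net)$knn  # NaN for isolated nodes
  nd <- as.numeric(knn)
  nd[deg == 0] <- NA_real_
  nms <- igraph::V(net)$name
  if (is.null(nms)) nms <- as.character(seq_len(igraph::vcount(net)))
  data.frame(gene = nms, degree = as.integer(deg), clustering = cc,
             neighbor_degree = nd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gaussian-weighted running median trend
#'
#' Smoothed-median trend of y against x on a log-spaced grid; a plotting
#' utility for degree-dependent profiles (clustering coefficient, neighbor
#' degree).
#'
#' @param x,y numeric vectors
#' @param bandwidth kernel bandwidth on the log10(x) scale
#' @param n_grid number of grid points
#' @return data.frame with columns `x`, `trend`
#' @export
smoothed_median_trend <- function(x, y, bandwidth = 0.15, n_grid = 50) {
  keep <- is.finite(x) & is.finite(y) & x > 0
  x <- x[keep]; y <- y[keep]
  lx <- log10(x)
  grid <- seq(min(lx), max(lx), length.out = n_grid)
  trend <- vapply(grid, function(g) {
    w <- exp(-0.5 * ((lx - g) / bandwidth)^2)
    w <- w / sum(w)
    ord <- order(y)
    cw <- cumsum(w[ord])
    y[ord][which(cw >= 0.5)[1]]
  }, numeric(1))
  data.frame(x = 10^grid, trend = trend)
}
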