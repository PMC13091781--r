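# Shared oracles and fixture builders. Oracles deliberately avoid the code
# paths they check: component recounting goes through igraph, entropies and
# hypergeometric tails are summed from first principles.

# a removal_schedule for an explicit node order
manual_schedule <- function(order, scheme = "custom", seed = 0L) {
  structure(list(order = order, scheme = scheme, seed = as.integer(seed)),
            class = "removal_schedule")
}

# brute-force fragmentation entropies: recount components after isolating
# each node in turn (edge deletion via igraph), entropy summed directly
brute_force_S <- function(net, order) {
  n <- igraph::vcount(net)
  S <- numeric(n + 1)
  ent <- function(g) {
    sizes <- igraph::components(g)$csize
    p <- sizes / n
    -sum(p * log(p)) / log(n)
  }
  S[1] <- ent(net)
  g <- net
  for (k in seq_along(order)) {
    g <- igraph::delete_edges(g, igraph::incident(g, order[k]))
    S[k + 1] <- ent(g)
  }
  S
}

# random simple graph with vertex names, mixed densities
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("g", seq_len(n))
  g
}

# upper hypergeometric tail P(X >= k) summed from binomial coefficients
hyper_tail_oracle <- function(k, K, N, n) {
  j <- seq(max(k, max(0, n - (N - K))), min(n, K))
  if (length(j) == 0 || min(n, K) < k) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# exact discrete power-law sampler (inverse CDF on the truncated pmf)
rdpl <- function(n, alpha, xmax = 1e5) {
  k <- seq_len(xmax)
  pm <- k^(-alpha)
  sample.int(xmax, n, replace = TRUE, prob = pm / sum(pm))
}

# small barbell: two cliques joined through one dedicated bridge node,
# anchored on the last three members of each clique
barbell_graph <- function(clique_n = 10) {
  a <- paste0("a", seq_len(clique_n))
  b <- paste0("b", seq_len(clique_n))
  anchors <- c(utils::tail(a, 3), utils::tail(b, 3))
  pa <- utils::combn(a, 2); pb <- utils::combn(b, 2)
  edges_to_network(c(pa[1, ], pb[1, ], rep("BR", 6)),
                   c(pa[2, ], pb[2, ], anchors))
}

# mutation_counts object from a named integer vector over a network
counts_from_vector <- function(net, counts) {
  all_genes <- igraph::V(net)$name
  full <- integer(length(all_genes))
  names(full) <- all_genes
  full[names(counts)] <- as.integer(counts)
  structure(list(counts = full, n_samples = max(full) + 1L,
                 restricted_to_network = TRUE),
            class = "mutation_counts")
}
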