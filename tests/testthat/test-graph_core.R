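test_that("edge lists are read as simple undirected networks", {
  f <- withr::local_tempfile(lines = c("A B", "B A", "A A"))
  net <- suppressMessages(read_edge_list(f))
  expect_equal(igraph::vcount(net), 2)
  expect_equal(igraph::ecount(net), 1)

  f2 <- withr::local_tempfile(lines = c("# comment", "A\tB", "B\tC"))
  net2 <- read_edge_list(f2)
  expect_equal(igraph::vcount(net2), 3)
  expect_equal(igraph::ecount(net2), 2)

  f3 <- withr::local_tempfile(lines = "lonetoken")
  expect_error(read_edge_list(f3), "line 1")

  f4 <- withr::local_tempfile(lines = character(0))
  expect_warning(net4 <- read_edge_list(f4), "empty")
  expect_equal(igraph::vcount(net4), 0)
})

test_that("canonical write followed by re-read is the identity", {
  for (s in 1:5) {
    g <- random_test_graph(30, 0.15, seed = s)
    f <- withr::local_tempfile()
    write_edge_list(g, f)
    g2 <- read_edge_list(f)
    expect_setequal(igraph::V(g2)$name,
                    igraph::V(g)$name[igraph::degree(g) > 0])
    el <- function(x) {
      e <- igraph::as_edgelist(x)
      sw <- e[, 1] > e[, 2]
      e[sw, ] <- e[sw, c(2, 1), drop = FALSE]
      sort(paste(e[, 1], e[, 2]))
    }
    expect_identical(el(g), el(g2))
  }
})

test_that("graph union is an idempotent, commutative, associative set union", {
  g1 <- edges_to_network("A", "B")
  g2 <- edges_to_network("B", "C")
  u <- union_networks(list(g1, g2))
  expect_setequal(igraph::V(u)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(u), 2)
  # idempotence
  uu <- union_networks(list(g1, g1))
  expect_equal(igraph::ecount(uu), igraph::ecount(g1))

  # seven single-edge networks sharing one edge: set-union oracle
  pairs <- list(c("A", "B"), c("A", "B"), c("C", "D"), c("E", "F"),
                c("G", "H"), c("I", "J"), c("K", "L"))
  nets <- lapply(pairs, function(p) edges_to_network(p[1], p[2]))
  expect_equal(igraph::ecount(union_networks(nets)),
               length(unique(vapply(pairs, function(p) paste(sort(p), collapse = "-"), ""))))

  # associativity/commutativity on random graphs
  canon <- function(g) {
    e <- igraph::as_edgelist(g)
    sw <- e[, 1] > e[, 2]; e[sw, ] <- e[sw, c(2, 1), drop = FALSE]
    list(sort(igraph::V(g)$name), sort(paste(e[, 1], e[, 2])))
  }
  for (s in 1:3) {
    gs <- lapply(1:3, function(i) random_test_graph(15, 0.2, seed = s * 10 + i))
    left <- union_networks(list(union_networks(gs[1:2]), gs[[3]]))
    right <- union_networks(list(gs[[1]], union_networks(gs[2:3])))
    perm <- union_networks(rev(gs))
    expect_equal(canon(left), canon(right))
    expect_equal(canon(left), canon(perm))
  }
})

test_that("network summaries match hand counts", {
  tri <- edges_to_network(c("A", "B", "C"), c("B", "C", "A"))
  s <- network_summary(tri)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$avg_degree, 2)
  expect_equal(s$density, 1)
  expect_equal(s$n_components, 1)

  star <- edges_to_network(rep("C", 4), paste0("L", 1:4))
  s2 <- network_summary(star)
  expect_equal(s2$avg_degree, 1.6)  # 2*4/5
  expect_equal(s2$density, 0.4)     # 4/10
})

test_that("node topology descriptors follow a triangle-enumeration oracle", {
  tri <- edges_to_network(c("A", "B", "C"), c("B", "C", "A"))
  tt <- node_topology(tri)
  expect_true(all(tt$clustering == 1))

  star <- edges_to_network(rep("C", 4), paste0("L", 1:4))
  tst <- node_topology(star)
  expect_true(all(tst$clustering == 0))
  expect_equal(tst$neighbor_degree[tst$gene == "L1"], 4)

  # 4-cycle plus a chord, checked by enumerating triangles per node
  g <- edges_to_network(c("A", "B", "C", "D", "A"), c("B", "C", "D", "A", "C"))
  tg <- node_topology(g)
  cc_oracle <- function(net, v) {
    nb <- igraph::V(net)$name[igraph::neighbors(net, v)]
    if (length(nb) < 2) return(0)
    prs <- utils::combn(nb, 2)
    closed <- sum(vapply(seq_len(ncol(prs)), function(i) {
      igraph::are_adjacent(net, prs[1, i], prs[2, i])
    }, logical(1)))
    closed / ncol(prs)
  }
  for (v in tg$gene) {
    expect_equal(tg$clustering[tg$gene == v], cc_oracle(g, v), tolerance = 1e-12)
  }

  # invariants: cc bounds and degree-sum identity
  for (s in 1:3) {
    gg <- random_test_graph(60, 0.1, seed = s)
    tp <- node_topology(gg)
    expect_true(all(tp$clustering >= 0 & tp$clustering <= 1))
    expect_equal(sum(tp$degree), 2 * igraph::ecount(gg))
  }
})

test_that("degree-tail comparison recovers the generating model", {
  n_pl <- 0
  n_ln <- 0
  for (s in 1:20) {
    set.seed(s)
    fit_pl <- degree_tail_fit(rdpl(5000, 2.5))
    if (fit_pl$preferred == "power_law") n_pl <- n_pl + 1
    set.seed(s + 500)
    fit_ln <- degree_tail_fit(pmax(1, round(exp(rnorm(5000, 1, 1)))))
    if (fit_ln$preferred == "lognormal") n_ln <- n_ln + 1
    expect_gte(fit_pl$p_value, 0)
    expect_lte(fit_pl$p_value, 1)
  }
  expect_gte(n_pl, 18)  # >= 90% of 20 seeds
  expect_gte(n_ln, 18)

  # non-significant comparison must be declared inconclusive
  set.seed(1)
  f <- degree_tail_fit(rdpl(5000, 2.5), significance = 1e-12)
  expect_identical(f$preferred, "inconclusive")

  expect_error(degree_tail_fit(rep(3, 100)), "degenerate")
  expect_error(degree_tail_fit(c(1, 2, 3)), "at least 50")
})
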