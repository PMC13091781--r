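test_that("fragmentation entropy anchors are exact", {
  expect_identical(shannon_diversity(4, 4), 0)
  expect_equal(shannon_diversity(rep(1, 4), 4), 1)
  expect_equal(shannon_diversity(c(2, 1, 1), 4), 0.75)
  expect_error(shannon_diversity(c(2, 1), 4), "sum")
  expect_error(shannon_diversity(1, 1), "N < 2")
})

test_that("hand-computed path percolation and its integral are reproduced", {
  g <- edges_to_network(c("A", "B"), c("B", "C"))
  cv <- fragmentation_curve(g, manual_schedule(c("B", "A", "C")))
  expect_equal(cv$f, c(0, 1, 2, 3) / 3)
  expect_equal(cv$S, c(0, 1, 1, 1))
  expect_equal(integrate_resilience(cv), 1 / 6)

  # edgeless network: everything is a singleton from the start
  e <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(e)$name <- paste0("n", 1:4)
  cve <- fragmentation_curve(e, manual_schedule(paste0("n", 1:4)))
  expect_true(all(cve$S == 1))

  # single-trapezoid identity: S = (0,...,0,1) on a 1/N grid
  curve <- structure(list(f = seq(0, 1, by = 0.1), S = c(rep(0, 10), 1), N = 10),
                     class = "frag_curve")
  expect_equal(integrate_resilience(curve), 1 - 1 / 20)

  expect_error(fragmentation_curve(g, manual_schedule(c("B", "A"))),
               "permutation")
})

test_that("incremental curve equals brute-force component recounting", {
  set.seed(99)
  cases <- data.frame(n = sample(20:120, 12, replace = TRUE),
                      p = runif(12, 0.01, 0.25))
  for (i in seq_len(nrow(cases))) {
    g <- random_test_graph(cases$n[i], cases$p[i], seed = i)
    ord <- sample(igraph::V(g)$name)
    fast <- fragmentation_curve(g, manual_schedule(ord))
    expect_lt(max(abs(fast$S - brute_force_S(g, ord))), 1e-12)
  }
})

test_that("removal schedules respect scheme priorities and randomize ties", {
  star <- edges_to_network(rep("C", 4), paste0("L", 1:4))
  expect_identical(build_schedule(star, "degree", seed = 3)$order[1], "C")
  # clustering on a star is all-zero: any node can come first
  firsts <- vapply(1:50, function(s) build_schedule(star, "clustering", s)$order[1], "")
  expect_gt(length(unique(firsts)), 1)

  # triangle degree ties: all 6 orders equifrequent over 600 seeds
  tri <- edges_to_network(c("A", "B", "C"), c("B", "C", "A"))
  orders <- vapply(1:600, function(s) {
    paste(build_schedule(tri, "degree", seed = s)$order, collapse = "")
  }, "")
  tab <- table(orders)
  expect_equal(length(tab), 6)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  expect_error(build_schedule(tri, "custom"), "aux")
})

test_that("node-symmetric graphs give order-independent curves", {
  fc <- make_complete(40)
  c1 <- fragmentation_curve(fc, build_schedule(fc, "random", seed = 1))
  c2 <- fragmentation_curve(fc, build_schedule(fc, "degree", seed = 2))
  expect_equal(c1$S, c2$S)
})

test_that("the ideal resilience limit matches the closed form", {
  expect_equal(ideal_max_resilience(8731), 0.5 - 1 / (4 * log(8731)),
               tolerance = 1e-4)
  # approaches 1/2 from below as N grows
  expect_lt(ideal_max_resilience(1e4), ideal_max_resilience(1e6))
  expect_lt(ideal_max_resilience(1e6), 0.5)
})

test_that("neighborhood removal isolates a node with its remaining neighbors", {
  star <- edges_to_network(rep("C", 4), paste0("L", 1:4))
  cv <- neighborhood_fragmentation_curve(star, "degree", seed = 1)
  expect_equal(cv$f, c(0, 1))
  expect_equal(cv$S, c(0, 1))
  expect_equal(integrate_resilience(cv), 0.5)

  e <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(e)$name <- paste0("n", 1:5)
  cve <- neighborhood_fragmentation_curve(e, "random", seed = 1)
  expect_equal(length(cve$f), 6)  # one node per step
  expect_true(all(cve$S == 1))

  # group-boundary S values agree with per-step brute force
  g <- random_test_graph(40, 0.08, seed = 5)
  cvn <- neighborhood_fragmentation_curve(g, "random", seed = 7)
  expect_equal(cvn$S[length(cvn$S)], 1)
  expect_true(all(diff(cvn$f) > 0))
})

test_that("replicate estimates are reproducible and degenerate cases exact", {
  g <- random_test_graph(60, 0.1, seed = 1)
  e1 <- estimate_resilience(g, "random", n_reps = 5, seed = 42)
  e2 <- estimate_resilience(g, "random", n_reps = 5, seed = 42)
  expect_identical(e1$per_rep_R, e2$per_rep_R)
  expect_equal(e1$sem, sd(e1$per_rep_R) / sqrt(5))

  # a fully deterministic scheme has zero order variance
  aux <- seq_len(igraph::vcount(g)); names(aux) <- igraph::V(g)$name
  ed <- estimate_resilience(g, "custom", n_reps = 4, seed = 1, aux = aux)
  expect_equal(ed$sem, 0)
  expect_true(all(ed$per_rep_R == ed$per_rep_R[1]))

  # generated-model sources draw independent networks
  cfg <- null_config("erdos_renyi", 200, p = 0.05)
  em <- estimate_resilience(cfg, "random", n_networks = 3, n_reps = 2, seed = 9)
  expect_equal(em$n_reps, 6)
  expect_true(em$mean_R > 0 && em$mean_R < 1)
})

test_that("Welch comparison agrees with the textbook computation", {
  x <- c(0.40, 0.42, 0.41, 0.43, 0.39)
  y <- c(0.50, 0.52, 0.51, 0.49, 0.53)
  a <- structure(list(per_rep_R = x, mean_R = mean(x)), class = "resilience_estimate")
  b <- structure(list(per_rep_R = y, mean_R = mean(y)), class = "resilience_estimate")
  cmp <- compare_estimates(a, b)
  # hand Welch: t = (mx - my) / sqrt(sx^2/n + sy^2/m)
  se <- sqrt(var(x) / 5 + var(y) / 5)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  expect_equal(cmp$difference, mean(x) - mean(y))
  expect_true(cmp$ci95[1] <= cmp$difference && cmp$difference <= cmp$ci95[2])

  # clearly separated Normal samples
  set.seed(11)
  a2 <- structure(list(per_rep_R = rnorm(50, 0, 0.1), mean_R = 0), class = "resilience_estimate")
  b2 <- structure(list(per_rep_R = rnorm(50, 1, 0.1), mean_R = 1), class = "resilience_estimate")
  expect_lt(compare_estimates(a2, b2)$p_value, 1e-10)

  # identical constant replicate lists
  c1 <- structure(list(per_rep_R = rep(0.4, 3), mean_R = 0.4), class = "resilience_estimate")
  cmp0 <- compare_estimates(c1, c1)
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_value, 1)
  expect_error(compare_estimates(c1, structure(list(per_rep_R = 0.1), class = "resilience_estimate")),
               ">= 2")
})

test_that("heavy-tailed graphs are more vulnerable to targeted than random removal", {
  cfg <- null_config("scale_free", 2000, m = 6)
  er <- estimate_resilience(cfg, "random", n_networks = 2, n_reps = 3, seed = 3)
  ed <- estimate_resilience(cfg, "degree", n_networks = 2, n_reps = 3, seed = 3)
  ea <- estimate_resilience(cfg, "degree_adaptive", n_networks = 2, n_reps = 3, seed = 3)
  expect_gte(er$mean_R, ed$mean_R - 3 * (er$sem + ed$sem))
  expect_gt(er$mean_R, ed$mean_R)   # ordering of the benchmark table
  expect_lte(ea$mean_R, ed$mean_R)  # recomputation cannot weaken the attack
})
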