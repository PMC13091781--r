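test_that("leave-one-out scan: no-op exclusions and bridge dominance", {
  # strictly decreasing counts, all mutated: excluding the last-listed gene
  # re-inserts it at its own position, so its R_loo equals the baseline
  g <- random_test_graph(25, 0.2, seed = 2)
  cv <- seq(25, 1)
  names(cv) <- igraph::V(g)$name
  cts <- counts_from_vector(g, cv)
  it <- loo_impact_scan(g, cts, seed = 5)
  last_gene <- names(cv)[cv == 1]
  expect_equal(it$R_loo[it$gene == last_gene], attr(it, "baseline_R_m"),
               tolerance = 1e-12)
  expect_true(all(it$R_loo >= 0 & it$R_loo <= 1))
  expect_equal(nrow(it), 25)

  # barbell: the bridge node, mutated at low frequency, tops the table
  bb <- barbell_graph(10)
  genes <- igraph::V(bb)$name
  cvb <- rep(0L, length(genes)); names(cvb) <- genes
  mutated <- c(paste0("a", 1:5), paste0("b", 1:5), "BR")
  cvb[mutated] <- c(10:6, 10:6, 2L)  # bridge has the lowest positive count
  it_b <- loo_impact_scan(bb, counts_from_vector(bb, cvb), seed = 3)
  expect_identical(it_b$gene[which.max(it_b$R_loo)], "BR")

  expect_warning(loo_impact_scan(bb, counts_from_vector(bb, cvb), seed = 3,
                                 genes = c("BR", "zz")), "skipped")
})

test_that("scan is deterministic given the seed and supports the degree control", {
  g <- random_test_graph(40, 0.15, seed = 7)
  cv <- sample(0:8, 40, replace = TRUE)
  names(cv) <- igraph::V(g)$name
  cts <- counts_from_vector(g, cv)
  i1 <- loo_impact_scan(g, cts, seed = 11)
  i2 <- loo_impact_scan(g, cts, seed = 11)
  expect_identical(i1$R_loo, i2$R_loo)

  idg <- loo_impact_scan(g, cts, seed = 11, control_mode = "degree")
  expect_identical(attr(idg, "control_mode"), "degree")
  expect_equal(nrow(idg), sum(cv > 0))
  # degree control scores the top-degree genes
  deg <- igraph::degree(g)
  expect_true(all(deg[idg$gene] >= sort(deg, decreasing = TRUE)[nrow(idg)]))
})

test_that("peak-symmetry separation recovers a planted minority mode", {
  # two-component mixture with known labels
  set.seed(42)
  x <- c(rnorm(9500, 0.452, 1e-4), rnorm(500, 0.4535, 1e-4))
  truth <- c(rep(FALSE, 9500), rep(TRUE, 500))
  tab <- structure(data.frame(gene = paste0("g", 1:10000), degree = 1L,
                              mutated_samples = 1L, R_loo = x),
                   class = c("impact_table", "data.frame"))
  gr <- impact_groups(tab)
  n_high <- length(gr$high_impact)
  expect_lt(abs(n_high - 500), 0.15 * 500 + 50)
  recovered <- tab$gene[truth]
  expect_gte(length(intersect(gr$high_impact, recovered)) / 500, 0.95)

  # symmetric unimodal sample: almost nothing beyond the reflected flank
  set.seed(7)
  y <- rnorm(5000, 0.45, 1e-3)
  tab2 <- structure(data.frame(gene = paste0("g", 1:5000), degree = 1L,
                               mutated_samples = 1L, R_loo = y),
                    class = c("impact_table", "data.frame"))
  gr2 <- impact_groups(tab2)
  expect_lte(length(gr2$high_impact) / 5000, 0.01)
  expect_setequal(c(gr2$high_impact, gr2$low_impact), tab2$gene)
})

test_that("rankings sort by degree and impact with lexicographic ties", {
  tab <- structure(data.frame(
    gene = c("b", "a", "c"),
    degree = c(5L, 9L, 2L),
    mutated_samples = c(1L, 2L, 3L),
    R_loo = c(0.3, 0.2, 0.4)
  ), class = c("impact_table", "data.frame"))
  rk <- impact_ranking(tab, k = 2)
  expect_identical(rk$by_degree$gene, c("a", "b"))
  expect_identical(rk$by_impact$gene, c("c", "b"))

  tab$R_loo <- rep(0.5, 3)
  expect_identical(impact_ranking(tab, k = 3)$by_impact$gene, c("a", "b", "c"))
})

test_that("memory-effect curves are anchored at zero and consistent at full prefix", {
  sn <- synth_network(synth_config(seed = 2))
  cts <- suppressMessages(gene_mutation_counts(synth_mutations(sn$network, sn$truth), sn$network))
  n_mut <- sum(cts$counts > 0)
  mc <- memory_effect_curve(sn$network, cts, group_size = 5, n_reps = 6, seed = 3,
                            prefix_sizes = c(0, 50, n_mut))
  expect_equal(mc$delta[mc$prefix == 0], 0)  # shared seeds: exact
  expect_lte(abs(mc$delta[mc$prefix == 0]), 3 * mc$sem[mc$prefix == 0] + 1e-12)

  # full prefix reproduces the main mutation-vs-random contrast
  em <- estimate_resilience(sn$network, "mutation_frequency", n_reps = 10,
                            seed = 21, counts = cts)
  er <- estimate_resilience(sn$network, "random", n_reps = 10, seed = 22)
  d_full <- mc$delta[mc$prefix == n_mut]
  expect_lt(abs(d_full - (em$mean_R - er$mean_R)),
            3 * (mc$sem[mc$prefix == n_mut] + em$sem + er$sem) + 0.005)
})

test_that("memory effect drops where the planted early-fragmenting genes sit", {
  sn <- synth_network(synth_config(seed = 6))
  cts <- suppressMessages(gene_mutation_counts(synth_mutations(sn$network, sn$truth), sn$network))
  ranks <- rank(-cts$counts, ties.method = "max")[sn$truth$planted_high_impact]
  lo <- max(1, min(ranks) - 10)
  mc <- memory_effect_curve(sn$network, cts, group_size = 5, n_reps = 8, seed = 4,
                            prefix_sizes = c(0, lo, max(ranks) + 10))
  # before any planted gene enters the prefix: small deficit; after all
  # planted genes entered: strong deficit
  expect_gt(mc$delta[2], mc$delta[3])
  expect_lt(mc$delta[3], -0.02)
  expect_gt(mc$delta[2], mc$delta[3] / 3)
})

test_that("clustering-coefficient rank-sum test matches a hand-computed U", {
  topo <- data.frame(gene = paste0("g", 1:8),
                     degree = 2L,
                     clustering = c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.15, 0.05),
                     neighbor_degree = 1)
  res <- mutated_cc_test(topo, paste0("g", 1:4))
  # mutated group strictly above the rest: U = n1*n2, two-sided exact p
  expect_equal(unname(res$u_statistic), 16)
  expect_equal(res$median_mutated, 0.875)
  expect_lt(res$p_value, 0.05)

  # large shifted groups reach high significance
  topo2 <- data.frame(gene = paste0("h", 1:100), degree = 2L,
                      clustering = c(seq(0.5, 0.99, length.out = 50),
                                     seq(0.01, 0.4, length.out = 50)),
                      neighbor_degree = 1)
  expect_lt(mutated_cc_test(topo2, paste0("h", 1:50))$p_value, 0.001)

  # identical multisets: no signal
  topo3 <- data.frame(gene = paste0("k", 1:40), degree = 2L,
                      clustering = rep(c(0.2, 0.4, 0.6, 0.8), 10),
                      neighbor_degree = 1)
  expect_gt(mutated_cc_test(topo3, paste0("k", 1:20))$p_value, 0.5)
  expect_error(mutated_cc_test(topo3, character(0)), "non-empty")
})

test_that("catalog overlap is an exact string intersection", {
  expect_equal(catalog_overlap(c("A", "B"), c("C", "D"))$n_overlap, 0)
  res <- catalog_overlap(c("A", "B"), c("A", "B", "C"))
  expect_equal(res$n_overlap, 2)
  expect_equal(res$n_query, 2)
  res2 <- catalog_overlap(c("A", "A", "B"), c("B"))
  expect_equal(res2$n_query, 2)   # duplicates collapse
  expect_setequal(res2$overlap_genes, "B")
})
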