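#!/usr/bin/env Rscript

# Mutation-ordered vs random node failure on the synthetic interactome:
# removing genes in decreasing mutation frequency (ties randomized) vs
# uniformly at random, plus the two controls that localize the effect —
# a degree-matched random schedule (same degrees as the mutation order,
# different identities) and the clustering-coefficient-targeted order —
# and the memory-effect curve of cumulative frequency-ordered prefixes.
#
# Writes results/mutation_resilience.tsv and results/memory_effect.tsv.

suppressPackageStartupMessages(library(panresil))
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(seed = 1)
sn <- synth_network(cfg)
net <- sn$network
cts <- gene_mutation_counts(synth_mutations(net, sn$truth, cfg), net)

n_reps <- 30
e_m <- estimate_resilience(net, "mutation_frequency", n_reps = n_reps, seed = 11, counts = cts)
e_r <- estimate_resilience(net, "random", n_reps = n_reps, seed = 13)
e_cc <- estimate_resilience(net, "clustering", n_reps = n_reps, seed = 15)

# degree-matched control: same degree sequence as the mutation order,
# identities drawn at random within each degree class
dm_R <- vapply(seq_len(n_reps), function(r) {
  mo <- mutation_order_schedule(cts, seed = 17 + r)
  dm <- degree_matched_schedule(net, mo$order, seed = 1700 + r)
  integrate_resilience(fragmentation_curve(net, dm))
}, numeric(1))
e_dm <- list(mean_R = mean(dm_R), sem = sd(dm_R) / sqrt(n_reps), n_reps = n_reps,
             per_rep_R = dm_R)

cmp_mr <- compare_estimates(e_m, e_r)
cmp_dm <- compare_estimates(structure(e_dm, class = "resilience_estimate"), e_r)

tab <- data.frame(
  scheme = c("mutation_frequency", "random", "degree_matched_control", "clustering"),
  mean_R = c(e_m$mean_R, e_r$mean_R, e_dm$mean_R, e_cc$mean_R),
  sem = c(e_m$sem, e_r$sem, e_dm$sem, e_cc$sem),
  n_reps = n_reps
)
write.table(tab, "results/mutation_resilience.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, digits = 5)
cat(sprintf("\nR_r - R_m = %.4f (Welch p = %.3g): mutation ordering fragments faster.\n",
            -cmp_mr$difference, cmp_mr$p_value))
cat(sprintf("Degree-matched control vs random: diff = %.4f (p = %.3g) — the\n",
            cmp_dm$difference, cmp_dm$p_value))
cat("deficit is positional, not a degree artifact, when this difference vanishes.\n")

mc <- memory_effect_curve(net, cts, group_size = 5, n_reps = 15, seed = 23)
write.table(mc, "results/memory_effect.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
drop_at <- mc$prefix[which(mc$delta < min(mc$delta) / 2)[1]]
cat(sprintf("Memory effect: delta(0) = %.4f; largest deficit %.4f; half-depth reached at prefix %d.\n",
            mc$delta[1], min(mc$delta), drop_at))
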