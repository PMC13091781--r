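# panresil

Fragmentation-entropy resilience analysis of gene interaction networks
under somatic-mutation-driven node failures.

A mutation is modeled as a node failure on the interactome: every edge
incident to the gene is deleted and the node remains as an isolated size-1
component. Fragmentation at failure fraction *f* is the normalized Shannon
entropy of component-size proportions *p*ᵢ = *n*ᵢ/*N*,

    S(f) = -(1/log N) Σᵢ pᵢ log pᵢ,

and resilience is the complement of its integral over the whole failure
range,

    R = 1 - ∫₀¹ S(f) df  ∈ [0, 1].

Higher *R* means the network fragments later and less. The package is for
systems biologists who want to (a) benchmark an interactome's resilience
against matched standard models (complete, random regular, Erdős–Rényi,
preferential-attachment), (b) compare mutation-frequency-ordered node
failures against random and degree/clustering-targeted ones, (c) rank
individual mutated genes by their leave-one-out impact on global
resilience and separate the resulting bimodal distribution into high- and
low-impact groups, (d) quantify the cumulative (memory) effect of
high-frequency genes, and (e) run over-representation statistics (Fisher +
Benjamini–Hochberg) on the recovered gene groups. A synthetic interactome
generator with planted bridge genes makes the whole pipeline testable
without any downloads.

Each fragmentation curve costs O((N+E)·α) via reverse union-find, so
full-size ensembles (n = 17,462, ~600k edges) run in ~0.1 s per curve.

## Worked example

The numbered scripts under `analysis/` run the full study on the default
synthetic interactome (8 clustered modules × 60 genes joined only through
8 planted bridge genes; 2,000-sample mutation cohort) and write their
tables under `results/`. For example:

```sh
Rscript analysis/03_mutation_resilience.R
```

prints

```
                  scheme  mean_R        sem n_reps
1     mutation_frequency 0.31067 2.4625e-04     30
2                 random 0.37898 2.4585e-03     30
3 degree_matched_control 0.37986 3.1829e-03     30
4             clustering 0.44150 3.3743e-05     30

R_r - R_m = 0.0683 (Welch p = 1.09e-22): mutation ordering fragments faster.
Degree-matched control vs random: diff = 0.0009 (p = 0.827)
```

Removing genes by decreasing mutation frequency fragments the network far
faster than random removal, while removing random genes *with the same
degrees* does not — the deficit is positional, not a degree artifact. The
per-gene scan then finds who is responsible:

```sh
Rscript analysis/04_gene_impact.R
```

```
high-impact group: 8 genes; planted recovered: 8/8
top enriched set: planted_bridge (adj p = 1.08e-16, overlap 8/8)
mode separation: 44.21 IQRs (mutation order) vs 0.05 (degree control)
         gene degree mutated_samples    R_loo
28  BRIDGE_01      6             157 0.326698
24  BRIDGE_06      6             170 0.324935
...
```

All eight planted bridges — moderate-degree genes invisible to hub
rankings (degree 6 vs hub degree 30) and mid-table by mutation frequency —
top the leave-one-out impact ranking, are isolated as a separated second
mode, and their gene set is the most enriched term. The degree-ordered
control produces a single-peaked distribution (mode separation 0.05 IQRs):
the bimodality is specific to the mutated gene list.

`analysis/05_real_data.R` runs the identical pipeline on a user-supplied
edge list and mutation table (plus optional GMT collection and driver-gene
catalog).

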