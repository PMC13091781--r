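#' Read a gene-level somatic mutation table
#'
#' Expects a TSV with a sample identifier column and a gene column (an
#' MAF-like extract is accepted by naming the two columns). Duplicate
#' (sample, gene) rows are retained in storage; downstream counting collapses
#' them to binary per-sample incidence.
#'
#' @param path TSV path with a header line
#' @param sample_col,gene_col column names holding the sample and gene ids
#' @return object of class `mutation_table`: data.frame `records` with
#'   columns `sample_id`, `gene`, plus `n_samples`, `n_genes`
#' @export
read_mutation_table <- function(path, sample_col = "sample_id", gene_col = "gene") {
  stopifnot(file.exists(path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (nrow(df) == 0) {
    warning("empty mutation table")
    return(mutation_table(character(0), character(0)))
  }
  missing <- setdiff(c(sample_col, gene_col), names(df))
  if (length(missing) > 0) {
    stop(sprintf("mutation table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  mutation_table(as.character(df[[sample_col]]), as.character(df[[gene_col]]))
}

#' Construct a mutation table from vectors
#'
#' @param sample_id,gene equal-length character vectors of incidence records
#' @return a `mutation_table`
#' @export
mutation_table <- function(sample_id, gene) {
  stopifnot(length(sample_id) == length(gene))
  structure(list(
    records = data.frame(sample_id = sample_id, gene = gene,
                         stringsAsFactors = FALSE),
    n_samples = length(unique(sample_id)),
    n_genes = length(unique(gene))
  ), class = "mutation_table")
}

#' Per-gene mutated-sample counts restricted to a network
#'
#' A gene counts as mutated in a sample if at least one record links them;
#' record multiplicity is ignored. Genes absent from the network are dropped
#' (with a message); network genes with no mutations get count 0.
#'
#' @param table a `mutation_table`
#' @param net igraph network
#' @return object of class `mutation_counts`: named integer vector `counts`
#'   over all network genes, `n_samples`, `restricted_to_network = TRUE`
#' @export
gene_mutation_counts <- function(table, net) {
  nms <- node_names(net)
  rec <- unique(table$records)
  in_net <- rec$gene %in% nms
  n_dropped <- length(unique(rec$gene[!in_net]))
  if (n_dropped > 0) {
    message(sprintf("dropped %d mutated gene(s) absent from the network", n_dropped))
  }
  rec <- rec[in_net, , drop = FALSE]
  counts <- integer(length(nms))
  names(counts) <- nms
  if (nrow(rec) > 0) {
    tab <- table(rec$gene)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(counts = counts, n_samples = table$n_samples,
                 restricted_to_network = TRUE),
            class = "mutation_counts")
}

#' Mutation-frequency removal schedule
#'
#' Mutated genes (count > 0) in decreasing order of mutated-sample count,
#' sampling uniformly at random among genes with identical counts; the
#' non-mutated network genes follow in uniform random order. The schedule
#' covers every network node exactly once.
#'
#' @param counts a `mutation_counts` (network-restricted)
#' @param seed integer seed for tie-breaking and the random suffix
#' @return a `removal_schedule` with scheme `"mutation_frequency"`
#' @export
mutation_order_schedule <- function(counts, seed = 1L) {
  stopifnot(inherits(counts, "mutation_counts"), counts$restricted_to_network)
  cts <- counts$counts
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm <- sample.int(length(cts))
  # stable sort on shuffled input = uniform permutation within each tie group,
  # including the all-tied count-0 suffix
  ord <- perm[order(-cts[perm])]
  structure(list(order = names(cts)[ord], scheme = "mutation_frequency",
                 seed = as.integer(seed)),
            class = "removal_schedule")
}
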