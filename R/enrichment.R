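#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' then gene identifiers. Duplicate genes within a set are collapsed.
#'
#' @param path GMT file path
#' @param source label stored on the collection
#' @return object of class `gene_set_collection`: named list `sets` of
#'   character vectors, plus `source`
#' @export
read_gmt <- function(path, source = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file")
    return(gene_set_collection(list(), source = source))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad) > 0) stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, source = source)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (unique term names, non-empty)
#' @param source label
#' @return a `gene_set_collection`
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (length(sets) > 0) {
    stopifnot(!is.null(names(sets)), anyDuplicated(names(sets)) == 0,
              all(lengths(sets) > 0))
    sets <- lapply(sets, unique)
  }
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' Over-representation analysis with Fisher's exact test
#'
#' One-sided (enrichment) Fisher exact test per term on the 2x2 table of
#' query/background membership against set membership; sets are intersected
#' with the background before testing. P-values are Benjamini-Hochberg
#' adjusted across all tested terms and flagged at adjusted p < 0.05.
#'
#' @param query character vector of genes (non-empty, subset of `background`)
#' @param background character vector: the gene universe
#' @param sets a `gene_set_collection`
#' @return object of class `enrichment_table`: data.frame with columns
#'   `term`, `overlap_k`, `set_size_K`, `p_value`, `adj_p`, `overlap`
#'   (display "k/K"), `significant`; sorted by `p_value`
#' @export
ora_test <- function(query, background, sets) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0) stop("empty query gene set")
  if (!all(query %in% background)) stop("query must be a subset of the background")
  N <- length(background)
  n <- length(query)
  terms <- names(sets$sets)
  K <- integer(length(terms)); k <- integer(length(terms))
  for (i in seq_along(terms)) {
    s <- intersect(sets$sets[[i]], background)
    K[i] <- length(s)
    k[i] <- length(intersect(s, query))
  }
  # one-sided Fisher p = upper hypergeometric tail P(X >= k)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  adj <- bh_adjust(p)
  out <- data.frame(term = terms, overlap_k = k, set_size_K = K,
                    p_value = p, adj_p = adj,
                    overlap = sprintf("%d/%d", k, K),
                    significant = adj < 0.05,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, capped at 1 and monotone in the sorted order.
#'
#' @param p_values numeric vector in \[0, 1\]
#' @return adjusted p-values in the input order
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
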