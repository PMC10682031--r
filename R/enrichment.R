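# Over-representation analysis of differentially spliced genes against
# generic gene-to-term annotations (GO namespaces, pathways, any term map).

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the selected gene set contains more of the
#' term's genes than expected by chance: one-sided upper-tail hypergeometric
#' `P(X >= k)` with `X ~ Hypergeom(N, K, n)` where `N` is the universe size,
#' `K` the term size within the universe, `n` the selected-set size and `k`
#' the overlap. FDR is Benjamini-Hochberg across all tested terms. Terms with
#' no gene in the universe are skipped. Depletion is not tested.
#'
#' @param selected character vector of selected gene ids (e.g. differentially
#'   spliced genes). Genes outside the universe are dropped with a warning.
#' @param universe character vector of background gene ids.
#' @param term_map data.frame from [read_term_map()] (`gene_id`, `term_id`,
#'   `term_name`, `namespace`).
#' @return data.frame sorted by P-value: `term_id`, `term_name`, `namespace`,
#'   `k`, `n`, `K`, `N`, `p_value`, `fdr`.
#' @export
enrich <- function(selected, universe, term_map) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(selected) == 0) stopf("selected gene set is empty")
  outside <- setdiff(selected, universe)
  if (length(outside) > 0) {
    warnf("dropping %d selected gene(s) not in the universe", length(outside))
    selected <- intersect(selected, universe)
  }
  if (length(selected) == 0) stopf("no selected genes remain within the universe")
  N <- length(universe)
  n <- length(selected)
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  tm <- tm[!duplicated(tm[, c("gene_id", "term_id")]), , drop = FALSE]
  if (nrow(tm) == 0) {
    return(data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  }
  terms <- split(tm, tm$term_id)
  rows <- lapply(terms, function(t) {
    K <- nrow(t)
    k <- sum(t$gene_id %in% selected)
    data.frame(term_id = t$term_id[1], term_name = t$term_name[1],
               namespace = t$namespace[1], k = k, n = n, K = K, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$fdr <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results as TSV
#'
#' @param res data.frame from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
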