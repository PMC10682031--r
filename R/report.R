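# Summary surfaces: event-type distribution tables and the AS-rate statistic.

#' Event-type distribution table
#'
#' Counts events per type and reports each type's share of the total as a
#' percentage rounded half-up to one decimal (the reporting convention of the
#' printed distributions, e.g. cassette 26.7% = 5884 of 22,065). Every type
#' of the nine-type vocabulary is reported, absent ones with count 0. Rows
#' are sorted by count descending, ties broken by type name.
#'
#' @param x a [detect_events()]/[diff_splice()] table (column `event_type`)
#'   or a character vector of event types.
#' @return data.frame with `event_type`, `count`, `percent`; attribute
#'   `total` holds the event total.
#' @export
event_type_distribution <- function(x) {
  types <- if (is.data.frame(x)) x$event_type else as.character(x)
  extra <- setdiff(unique(types), EVENT_TYPES)
  lev <- c(EVENT_TYPES, extra)
  counts <- table(factor(types, levels = lev))
  total <- sum(counts)
  df <- data.frame(event_type = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$percent <- if (total == 0) 0 else round_half_up(100 * df$count / total, 1)
  df <- df[order(-df$count, df$event_type), , drop = FALSE]
  rownames(df) <- NULL
  # internal consistency: percents must recompute from the counts column
  if (total > 0) {
    stopifnot(identical(df$percent, round_half_up(100 * df$count / sum(df$count), 1)))
  }
  attr(df, "total") <- total
  df
}

#' Alternative-splicing rate
#'
#' Share of reference genes harboring at least one AS event, as a percentage
#' rounded half-up to two decimals (e.g. 7895 of 25,197 genes = 31.33).
#'
#' @param n_genes_with_events number of genes with events (numerator).
#' @param n_reference_genes number of reference genes (denominator, > 0).
#' @return percentage rounded to two decimals.
#' @export
as_rate <- function(n_genes_with_events, n_reference_genes) {
  if (any(n_reference_genes <= 0)) stopf("reference gene count must be positive")
  if (any(n_genes_with_events < 0) || any(n_genes_with_events > n_reference_genes)) {
    stopf("need 0 <= n_genes_with_events <= n_reference_genes")
  }
  round_half_up(100 * n_genes_with_events / n_reference_genes, 2)
}

#' Tiered summary report
#'
#' Distribution tables for all events and for each significance tier, plus
#' gene/event counts and the AS rate over the annotated genes.
#'
#' @param results data.frame from [diff_splice()].
#' @param n_reference_genes optional reference-gene total for the AS rate
#'   (default: number of distinct genes in `results`).
#' @return list with elements `all`, `sig`, `ext` (distribution tables),
#'   `counts` (data.frame of tiered gene/event counts) and `as_rate`.
#' @export
splice_report <- function(results, n_reference_genes = NULL) {
  sig <- results[results$tier %in% c("SIG", "EXT"), , drop = FALSE]
  ext <- results[results$tier == "EXT", , drop = FALSE]
  genes_with <- length(unique(results$gene_id))
  if (is.null(n_reference_genes)) n_reference_genes <- genes_with
  counts <- data.frame(
    tier = c("all", "SIG+EXT", "EXT"),
    n_events = c(nrow(results), nrow(sig), nrow(ext)),
    n_genes = c(genes_with, length(unique(sig$gene_id)),
                length(unique(ext$gene_id))),
    stringsAsFactors = FALSE
  )
  list(all = event_type_distribution(results),
       sig = event_type_distribution(sig),
       ext = event_type_distribution(ext),
       counts = counts,
       as_rate = if (n_reference_genes > 0)
         as_rate(min(genes_with, n_reference_genes), n_reference_genes) else NA_real_)
}
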