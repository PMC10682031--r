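# Per-event, per-sample evidence: inclusion/exclusion junction-read totals,
# PSI, FPKM and expression matching.

#' Count junction reads supporting one event in one sample
#'
#' Sums the sample's junction counts over the event's inclusion and exclusion
#' junction sets; junctions absent from the table count as zero.
#'
#' @param event one-row slice of a [detect_events()] table.
#' @param junctions junction count table: named list `sample_id ->` named
#'   count vector keyed by [jx_key()].
#' @param sample_id which sample to count.
#' @return data.frame with `event_id`, `sample_id`, `inclusion_total`,
#'   `exclusion_total`, `n_inclusion_junctions`, `n_exclusion_junctions`.
#' @export
count_event_reads <- function(event, junctions, sample_id) {
  v <- junctions[[sample_id]]
  if (is.null(v)) v <- stats::setNames(numeric(0), character(0))
  inc <- event$inclusion_junctions[[1]]
  exc <- event$exclusion_junctions[[1]]
  if (length(intersect(inc, exc)) > 0) {
    stopf("event %s has overlapping inclusion/exclusion junction sets", event$event_id)
  }
  data.frame(
    event_id = event$event_id,
    sample_id = sample_id,
    inclusion_total = sum(v[intersect(inc, names(v))]),
    exclusion_total = sum(v[intersect(exc, names(v))]),
    n_inclusion_junctions = length(inc),
    n_exclusion_junctions = length(exc),
    stringsAsFactors = FALSE
  )
}

# Pooled inclusion/exclusion totals for all events over a set of samples.
# One vectorized key lookup per sample (not per event) keeps this linear in
# the total number of junction-set entries.
pool_event_counts <- function(events, junctions, sample_ids) {
  n <- nrow(events)
  side_total <- function(key_list, v) {
    keys <- unlist(key_list, use.names = FALSE)
    if (length(keys) == 0) return(numeric(n))
    idx <- rep.int(seq_len(n), lengths(key_list))
    val <- unname(v[keys])
    val[is.na(val)] <- 0
    tot <- numeric(n)
    agg <- rowsum(val, idx)
    tot[as.integer(rownames(agg))] <- agg[, 1]
    tot
  }
  inc_tot <- numeric(n)
  exc_tot <- numeric(n)
  for (s in sample_ids) {
    v <- junctions[[s]]
    if (is.null(v) || length(v) == 0) next
    inc_tot <- inc_tot + side_total(events$inclusion_junctions, v)
    exc_tot <- exc_tot + side_total(events$exclusion_junctions, v)
  }
  data.frame(event_id = events$event_id,
             inclusion_total = inc_tot, exclusion_total = exc_tot,
             n_inclusion_junctions = lengths(events$inclusion_junctions),
             n_exclusion_junctions = lengths(events$exclusion_junctions),
             stringsAsFactors = FALSE)
}

#' Percent-spliced-in from event counts
#'
#' PSI with per-side junction-count normalization:
#' `psi = (I/nI) / (I/nI + E/nE)` where `I`, `E` are the inclusion and
#' exclusion totals and `nI`, `nE` the junction-set sizes. The normalization
#' compensates for the inclusion form offering more junction opportunities
#' (a cassette has two inclusion junctions against one exclusion junction).
#' Undefined (both totals zero, or an empty junction side) propagates as `NA`,
#' never as zero.
#'
#' @param counts data.frame as returned by [count_event_reads()] (any number
#'   of rows; vectorized).
#' @return numeric vector of PSI values in `[0, 1]` or `NA`.
#' @export
compute_psi <- function(counts) {
  with(counts, {
    ri <- ifelse(n_inclusion_junctions > 0, inclusion_total / n_inclusion_junctions, NA_real_)
    re <- ifelse(n_exclusion_junctions > 0, exclusion_total / n_exclusion_junctions, NA_real_)
    out <- ri / (ri + re)
    out[!is.na(ri) & !is.na(re) & (ri + re) == 0] <- NA_real_
    out
  })
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fpkm = count / ((length/1000) * (library/1e6))`. Fragments, not read
#' pairs: single-end data counts each read as one fragment.
#'
#' @param fragment_count fragments assigned to the feature.
#' @param transcript_length feature length in bases (> 0).
#' @param total_mapped_fragments library size in mapped fragments (> 0).
#' @return FPKM (vectorized).
#' @export
compute_fpkm <- function(fragment_count, transcript_length, total_mapped_fragments) {
  if (any(transcript_length <= 0)) stopf("transcript_length must be positive")
  if (any(total_mapped_fragments <= 0)) stopf("total_mapped_fragments must be positive")
  if (any(fragment_count < 0)) stopf("fragment_count must be non-negative")
  fragment_count / ((transcript_length / 1000) * (total_mapped_fragments / 1e6))
}

#' Are two expression levels within a fold tolerance?
#'
#' Used to restrict splicing-rate comparisons to genes expressed at similar
#' levels in both conditions. Symmetric; zero expression never matches.
#'
#' @param fpkm_a,fpkm_b non-negative expression values (vectorized).
#' @param max_fold maximum tolerated ratio (default 2).
#' @return logical vector.
#' @export
expression_matched <- function(fpkm_a, fpkm_b, max_fold = 2.0) {
  if (any(fpkm_a < 0) || any(fpkm_b < 0)) stopf("FPKM values must be non-negative")
  fpkm_a > 0 & fpkm_b > 0 & pmax(fpkm_a / fpkm_b, fpkm_b / fpkm_a) <= max_fold
}

#' Per-sample PSI table for a set of events
#'
#' @param events data.frame from [detect_events()].
#' @param junctions junction count table (named list of named count vectors).
#' @return data.frame `event_id`, `gene_id` plus one PSI column per sample.
#' @export
psi_table <- function(events, junctions) {
  out <- data.frame(event_id = events$event_id, gene_id = events$gene_id,
                    stringsAsFactors = FALSE)
  for (s in names(junctions)) {
    cnt <- pool_event_counts(events, junctions, s)
    out[[s]] <- compute_psi(cnt)
  }
  out
}
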