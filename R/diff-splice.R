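# The core differential-splicing statistic: a junction-count Fisher exact
# test and an exon/gene coverage Fisher exact test per event, combined by
# Fisher's method, BH-adjusted across events, and gated by a fold-change rule
# with a condition-exclusivity clause.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided P-value: with both margins fixed, sums the hypergeometric
#' probabilities of every table whose point probability does not exceed that
#' of the observed table (relative tolerance `1e-7` on the comparison, so
#' ties under floating point are included). Any table with a zero margin
#' carries no information and returns 1.
#'
#' @param a,b,c,d non-negative integer cell counts (`a b / c d`).
#' @return two-sided P-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) stopf("cell counts must be non-negative")
  if (any(cells != round(cells))) stopf("cell counts must be integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  n <- r1 + r2
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Junction-read P-value between two conditions
#'
#' Two-sided Fisher's exact test on the raw (unnormalized) pooled inclusion
#' and exclusion junction-read totals of one event in the two conditions.
#' An event with zero reads in both conditions is untestable and returns `NA`
#' (excluded from multiple-testing adjustment downstream).
#'
#' @param inc_a,exc_a inclusion/exclusion totals in condition A.
#' @param inc_b,exc_b totals in condition B.
#' @return P-value or `NA`.
#' @export
junction_pvalue <- function(inc_a, exc_a, inc_b, exc_b) {
  if (inc_a + exc_a + inc_b + exc_b == 0) return(NA_real_)
  fisher_exact_2x2(inc_a, exc_a, inc_b, exc_b)
}

#' Coverage P-value between two conditions
#'
#' Fisher's exact test on alternative-region versus remaining-gene fragment
#' coverage: table `(exon_a, gene_a - exon_a; exon_b, gene_b - exon_b)`.
#'
#' @param exon_cov_a,gene_cov_a alternative-exon and whole-gene fragment
#'   counts in condition A (`exon <= gene` required).
#' @param exon_cov_b,gene_cov_b same for condition B.
#' @return P-value.
#' @export
coverage_pvalue <- function(exon_cov_a, gene_cov_a, exon_cov_b, gene_cov_b) {
  if (exon_cov_a > gene_cov_a || exon_cov_b > gene_cov_b) {
    stopf("exon coverage exceeds gene coverage")
  }
  fisher_exact_2x2(exon_cov_a, gene_cov_a - exon_cov_a,
                   exon_cov_b, gene_cov_b - exon_cov_b)
}

#' Combine the junction and coverage P-values
#'
#' Default is Fisher's method: `X2 = -2(ln p1 + ln p2)` referred to a
#' chi-square distribution with 4 degrees of freedom. `"stouffer"` combines
#' the one-sided-equivalent Z scores instead.
#'
#' @param p_junction,p_coverage P-values in `(0, 1]` (vectorized).
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return combined P-value(s).
#' @export
combine_pvalues <- function(p_junction, p_coverage, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  n <- max(length(p_junction), length(p_coverage))
  p_junction <- rep_len(p_junction, n)
  p_coverage <- rep_len(p_coverage, n)
  ok <- !is.na(p_junction) & !is.na(p_coverage)
  if (any(p_junction[ok] <= 0 | p_junction[ok] > 1) ||
      any(p_coverage[ok] <= 0 | p_coverage[ok] > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  if (method == "fisher") {
    stats::pchisq(-2 * (log(p_junction) + log(p_coverage)), df = 4, lower.tail = FALSE)
  } else {
    z <- (stats::qnorm(p_junction, lower.tail = FALSE) +
            stats::qnorm(p_coverage, lower.tail = FALSE)) / sqrt(2)
    stats::pnorm(z, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across events, returned in input order (a thin
#' wrapper around [stats::p.adjust()]; `NA` inputs stay `NA` and do not count
#' toward the number of tests).
#'
#' @param pvalues numeric vector of P-values.
#' @return adjusted P-values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Fold rule on splicing levels
#'
#' A difference qualifies when one condition's level is at least `threshold`
#' times the other's, or when the event is present in only one condition
#' (exactly one level is zero or undefined while the other is positive:
#' `breed_exclusive`, infinite fold).
#'
#' @param level_a,level_b non-negative splicing levels (vectorized); `NA`
#'   means undefined and is treated as absence when the other level is
#'   positive.
#' @param threshold minimum fold (default 4).
#' @return data.frame with `fold`, `breed_exclusive`, `passes`.
#' @export
fold_rule <- function(level_a, level_b, threshold = 4.0) {
  n <- max(length(level_a), length(level_b))
  level_a <- rep_len(level_a, n); level_b <- rep_len(level_b, n)
  if (any(level_a < 0, na.rm = TRUE) || any(level_b < 0, na.rm = TRUE)) {
    stopf("levels must be non-negative")
  }
  za <- is.na(level_a) | level_a == 0
  zb <- is.na(level_b) | level_b == 0
  fold <- rep(NA_real_, n)
  excl <- xor(za, zb)
  both_pos <- !za & !zb
  fold[both_pos] <- pmax(level_a[both_pos] / level_b[both_pos],
                         level_b[both_pos] / level_a[both_pos])
  fold[excl] <- Inf
  passes <- excl | (!is.na(fold) & fold >= threshold)
  data.frame(fold = fold, breed_exclusive = excl, passes = passes)
}

#' Significance tier
#'
#' `EXT` when the adjusted P-value is below `alpha_ext` and the fold rule
#' passes; `SIG` below `alpha_sig` with the fold rule; otherwise `NS`. Both
#' P-value and fold conditions must hold.
#'
#' @param p_adjusted adjusted P-values (`NA` means untestable, tier `NS`).
#' @param fold_passes logical from [fold_rule()].
#' @param alpha_sig,alpha_ext tier thresholds (defaults 0.05 and 0.01).
#' @return character vector of `"NS"`, `"SIG"`, `"EXT"`.
#' @export
call_significance <- function(p_adjusted, fold_passes, alpha_sig = 0.05,
                              alpha_ext = 0.01) {
  tier <- rep("NS", max(length(p_adjusted), length(fold_passes)))
  p_adjusted <- rep_len(p_adjusted, length(tier))
  fold_passes <- rep_len(fold_passes, length(tier))
  ok <- !is.na(p_adjusted) & !is.na(fold_passes) & fold_passes
  tier[ok & p_adjusted < alpha_sig] <- "SIG"
  tier[ok & p_adjusted < alpha_ext] <- "EXT"
  tier
}

#' Differential alternative-splicing analysis
#'
#' For every event: pools junction reads per condition (replicates summed),
#' computes condition PSIs and the junction Fisher P-value on the raw
#' inclusion/exclusion 2x2; pools alternative-region and whole-gene coverage
#' per condition and computes the coverage Fisher P-value; combines the two
#' P-values (Fisher's method by default), adjusts across events
#' (Benjamini-Hochberg by default), applies the fold rule to the condition
#' splicing levels, and assigns significance tiers.
#'
#' When one of the two P-values is untestable the other stands in as the
#' combined value; events with neither are reported with `NA` P-values and
#' tier `NS`, and do not enter the adjustment.
#'
#' @param events data.frame from [detect_events()].
#' @param junctions junction count table (named list of named count vectors).
#' @param samples_a,samples_b sample ids of the two conditions.
#' @param coverage optional coverage table (named list of named count
#'   vectors; features keyed by event id and gene id). Without it the
#'   coverage channel is skipped.
#' @param level_stat splicing level fed to the fold rule: `"psi"` (default)
#'   or `"inclusion_total"` (raw per-condition inclusion read totals).
#' @param fold_threshold fold-rule threshold (default 4).
#' @param alpha_sig,alpha_ext tier thresholds on the adjusted P-value.
#' @param combination_method `"fisher"` or `"stouffer"`.
#' @param adjustment_method `"bh"` or `"none"`.
#' @return data.frame with the standard result columns (see
#'   [write_results_tsv()]).
#' @export
diff_splice <- function(events, junctions, samples_a, samples_b,
                        coverage = NULL, level_stat = c("psi", "inclusion_total"),
                        fold_threshold = 4.0, alpha_sig = 0.05,
                        alpha_ext = 0.01,
                        combination_method = c("fisher", "stouffer"),
                        adjustment_method = c("bh", "none")) {
  level_stat <- match.arg(level_stat)
  combination_method <- match.arg(combination_method)
  adjustment_method <- match.arg(adjustment_method)
  n <- nrow(events)
  cnt_a <- pool_event_counts(events, junctions, samples_a)
  cnt_b <- pool_event_counts(events, junctions, samples_b)
  psi_a <- compute_psi(cnt_a)
  psi_b <- compute_psi(cnt_b)
  p_junction <- vapply(seq_len(n), function(i) {
    junction_pvalue(cnt_a$inclusion_total[i], cnt_a$exclusion_total[i],
                    cnt_b$inclusion_total[i], cnt_b$exclusion_total[i])
  }, numeric(1))

  p_coverage <- rep(NA_real_, n)
  if (!is.null(coverage)) {
    pool_cov <- function(samples, ids) {
      tot <- numeric(length(ids))
      for (s in samples) {
        v <- coverage[[s]]
        if (is.null(v)) next
        hit <- ids %in% names(v)
        tot[hit] <- tot[hit] + v[ids[hit]]
      }
      tot
    }
    ex_a <- pool_cov(samples_a, events$event_id)
    ge_a <- pool_cov(samples_a, events$gene_id)
    ex_b <- pool_cov(samples_b, events$event_id)
    ge_b <- pool_cov(samples_b, events$gene_id)
    for (i in seq_len(n)) {
      if (ge_a[i] + ge_b[i] == 0) next
      p_coverage[i] <- coverage_pvalue(ex_a[i], ge_a[i], ex_b[i], ge_b[i])
    }
  }

  p_combined <- rep(NA_real_, n)
  both <- !is.na(p_junction) & !is.na(p_coverage)
  p_combined[both] <- combine_pvalues(p_junction[both], p_coverage[both],
                                      method = combination_method)
  only_j <- !is.na(p_junction) & is.na(p_coverage)
  only_c <- is.na(p_junction) & !is.na(p_coverage)
  p_combined[only_j] <- p_junction[only_j]
  p_combined[only_c] <- p_coverage[only_c]

  p_adjusted <- if (adjustment_method == "bh") bh_adjust(p_combined) else p_combined

  lev_a <- if (level_stat == "psi") psi_a else cnt_a$inclusion_total
  lev_b <- if (level_stat == "psi") psi_b else cnt_b$inclusion_total
  fr <- if (n > 0) fold_rule(lev_a, lev_b, threshold = fold_threshold)
        else data.frame(fold = numeric(0), breed_exclusive = logical(0), passes = logical(0))
  tier <- call_significance(p_adjusted, fr$passes, alpha_sig, alpha_ext)

  data.frame(
    event_id = events$event_id, gene_id = events$gene_id,
    event_type = events$event_type, chrom = events$chrom,
    start = events$start, end = events$end, strand = events$strand,
    psi_a = psi_a, psi_b = psi_b,
    p_junction = p_junction, p_coverage = p_coverage,
    p_combined = p_combined, p_adjusted = p_adjusted,
    fold = fr$fold, breed_exclusive = fr$breed_exclusive, tier = tier,
    stringsAsFactors = FALSE
  )
}
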