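# Independent oracles and fixture builders shared across the suite.

# Brute-force two-sided Fisher P for a 2x2 table: enumerate every table with
# the observed margins via binomial coefficients and sum the probabilities of
# tables no more likely than the observed one.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || n - c1 == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  po <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  min(1, sum(pr[pr <= po * (1 + 1e-7)]))
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# n-subsets of a universe of size N whose first K elements carry the term.
hyper_tail_oracle <- function(k, K, N, n) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Exon-table builder: tx is a named list transcript -> numeric vector of
# alternating starts/ends (0-based half-open), all one gene.
make_gene <- function(tx, strand = "+", gene_id = "g1", chrom = "chrT") {
  rows <- lapply(names(tx), function(t) {
    v <- tx[[t]]
    data.frame(chrom = chrom, start = v[c(TRUE, FALSE)], end = v[c(FALSE, TRUE)],
               strand = strand, gene_id = gene_id, transcript_id = t,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Mirror an exon table about coordinate M and flip its strand.
mirror_flip <- function(ex, M = 100000) {
  s <- M - ex$end
  e <- M - ex$start
  ex$start <- s
  ex$end <- e
  ex$strand <- ifelse(ex$strand == "+", "-", "+")
  ex
}

all_types_config <- function(per_type = 5L, ...) {
  sim_config(events_per_type = stats::setNames(rep(as.integer(per_type), 9),
                                               c("retain_intron", "mutually_exclusive",
                                                 "cassette_multi", "cassette",
                                                 "alt5prime", "alt3prime",
                                                 "altstart", "altend", "unknown")),
             ...)
}

event_key <- function(d) paste(d$gene_id, d$event_type, d$start, d$end)
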