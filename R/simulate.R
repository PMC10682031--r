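# Seeded synthetic-data generator: plants one alternative-splicing event of a
# requested type per gene as a two-isoform gene on a synthetic chromosome,
# then simulates junction-read and coverage evidence for a two-condition
# design with known ground truth.

#' Simulation configuration
#'
#' @param events_per_type named integer vector: how many events to plant per
#'   type (names from the nine-type vocabulary). Default: five of each type.
#' @param psi_a,psi_b true inclusion levels per condition; scalar or one
#'   value per event (recycled). Defaults 0.8 vs 0.2 — a four-fold level
#'   difference, the boundary the fold rule flags.
#' @param event_depth expected junction fragments per event per sample.
#' @param n_replicates samples per condition (default 1: one pooled library
#'   per condition).
#' @param seed integer seed; fixes all generator output byte-for-byte.
#' @param exon_length,intron_length,shift template geometry in bases (shift is
#'   the donor/acceptor displacement of the alt-site templates).
#' @param gene_gap intergenic spacing on the synthetic chromosome.
#' @param chrom synthetic chromosome name.
#' @param origin first gene offset (must leave room for junction-read
#'   overhangs).
#' @param gene_depth_factor whole-gene coverage rate as a multiple of
#'   `event_depth`.
#' @param library_size nominal mapped fragments per sample (for FPKM).
#' @param overdispersion `NULL` for Poisson event totals, otherwise the
#'   negative-binomial size parameter.
#' @return a `sim_config` list.
#' @export
sim_config <- function(events_per_type = NULL, psi_a = 0.8, psi_b = 0.2,
                       event_depth = 500, n_replicates = 1, seed = 1,
                       exon_length = 200, intron_length = 300, shift = 60,
                       gene_gap = 5000, chrom = "simchr1", origin = 1000,
                       gene_depth_factor = 4, library_size = 2e7,
                       overdispersion = NULL) {
  if (is.null(events_per_type)) {
    events_per_type <- stats::setNames(rep(5L, length(EVENT_TYPES)), EVENT_TYPES)
  }
  bad <- setdiff(names(events_per_type), EVENT_TYPES)
  if (length(bad)) stopf("unknown event type(s): %s", paste(bad, collapse = ", "))
  if (any(events_per_type < 0)) stopf("events_per_type counts must be >= 0")
  if (any(psi_a < 0 | psi_a > 1) || any(psi_b < 0 | psi_b > 1)) {
    stopf("psi values must lie in [0, 1]")
  }
  if (event_depth <= 0) stopf("event_depth must be positive")
  if (exon_length < 1 || intron_length < 1 || shift < 1 ||
      shift >= intron_length - shift) {
    stopf("invalid template geometry (need 1 <= shift < intron_length - shift)")
  }
  structure(list(
    events_per_type = events_per_type, psi_a = psi_a, psi_b = psi_b,
    event_depth = event_depth, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed), exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length), shift = as.integer(shift),
    gene_gap = as.integer(gene_gap), chrom = chrom,
    origin = as.integer(origin), gene_depth_factor = gene_depth_factor,
    library_size = library_size, overdispersion = overdispersion
  ), class = "sim_config")
}

# One event template in transcription-space coordinates. Returns isoform exon
# matrices plus the event's alt region and junction sets (as intervals);
# strand-dependent choices (which alternative exon is "the" alt region) are
# resolved after mapping to the genome.
event_template <- function(type, E, I, d) {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end"); m
  }
  slot <- function(i) c((i - 1) * (E + I), (i - 1) * (E + I) + E)
  A <- slot(1); B <- slot(2); C <- slot(3); D <- slot(4)
  jn <- function(up, down) c(up[2], down[1])
  switch(type,
    cassette = list(
      iso1 = ex(A, B, C), iso2 = ex(A, C), alt = B,
      incl = list(jn(A, B), jn(B, C)), excl = list(jn(A, C))),
    cassette_multi = list(
      iso1 = ex(A, B, C, D), iso2 = ex(A, D), alt = c(B[1], C[2]),
      incl = list(jn(A, B), jn(B, C), jn(C, D)), excl = list(jn(A, D))),
    mutually_exclusive = list(
      iso1 = ex(A, B, D), iso2 = ex(A, C, D), alt = NULL,
      alt_pair = list(B, C),
      incl_pair = list(list(jn(A, B), jn(B, D)), list(jn(A, C), jn(C, D)))),
    retain_intron = list(
      iso1 = ex(A, B, C, D), iso2 = ex(A, c(B[1], C[2]), D),
      alt = c(B[2], C[1]),
      incl = list(jn(A, B), jn(C, D)), excl = list(c(B[2], C[1]))),
    alt5prime = {
      Ax <- c(A[1], A[2] + d); Bs <- c(A[2] + d + I, A[2] + d + I + E)
      list(iso1 = ex(A, Bs), iso2 = ex(Ax, Bs), alt = c(A[2], A[2] + d),
           incl = list(jn(Ax, Bs)), excl = list(jn(A, Bs)))
    },
    alt3prime = {
      Bx <- c(B[1] + d, B[2])
      list(iso1 = ex(A, B), iso2 = ex(A, Bx), alt = c(B[1], B[1] + d),
           incl = list(jn(A, B)), excl = list(jn(A, Bx)))
    },
    altstart = list(
      iso1 = ex(A, C), iso2 = ex(B, C), alt = NULL,
      alt_pair = list(A, B),
      incl_pair = list(list(jn(A, C)), list(jn(B, C)))),
    altend = list(
      iso1 = ex(A, B), iso2 = ex(A, C), alt = NULL,
      alt_pair = list(B, C),
      incl_pair = list(list(jn(A, B)), list(jn(A, C)))),
    unknown = {
      A2 <- c(A[1], A[2] + d); B2 <- c(B[1] - d, B[2])
      list(iso1 = ex(A, B), iso2 = ex(A2, B2), alt = c(A[2], B[1]),
           incl = NULL, excl = NULL,
           unk_pair = list(list(jn(A, B)), list(jn(A2, B2))))
    },
    stopf("unknown event type: %s", type))
}

mirror_iv <- function(iv, L) c(L - iv[2], L - iv[1])

#' Generate a synthetic annotation with planted events
#'
#' Each requested event occupies its own gene, realized as exactly two
#' isoforms on a single synthetic chromosome; genes alternate strand and are
#' placed non-overlapping. Deterministic: no randomness is consumed, so a
#' given configuration always yields identical output.
#'
#' @param config a [sim_config()].
#' @return list with `exons` (exon table, see [read_gtf()]) and `truth`
#'   (data.frame: `event_id`, `gene_id`, `event_type`, `chrom`, `start`,
#'   `end`, `strand`, `psi_a`, `psi_b`, `differential`, `gene_start`,
#'   `gene_end`, list-columns `inclusion_junctions`/`exclusion_junctions`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ept <- config$events_per_type
  types <- rep(names(ept), times = ept)
  n <- length(types)
  if (n == 0) {
    return(list(exons = empty_exon_table(), truth = empty_truth()))
  }
  psi_a <- rep_len(config$psi_a, n)
  psi_b <- rep_len(config$psi_b, n)
  E <- config$exon_length; I <- config$intron_length; d <- config$shift
  offset <- config$origin
  exon_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    type <- types[i]
    strand <- if (i %% 2 == 1) "+" else "-"
    gid <- sprintf("G%05d", i)
    tpl <- event_template(type, E, I, d)
    L <- max(tpl$iso1[, 2], tpl$iso2[, 2])
    map_iv <- function(iv) {
      g <- if (strand == "+") iv else mirror_iv(iv, L)
      g + offset
    }
    map_ex <- function(m) {
      g <- t(apply(m, 1, map_iv))
      g[order(g[, 1]), , drop = FALSE]
    }
    g1 <- map_ex(tpl$iso1); g2 <- map_ex(tpl$iso2)
    jkeys <- function(ivs) {
      sort(vapply(ivs, function(iv) {
        g <- map_iv(iv)
        jx_key(config$chrom, g[1], g[2], strand)
      }, ""))
    }
    if (!is.null(tpl$alt)) {
      alt_g <- map_iv(tpl$alt)
      if (is.null(tpl$unk_pair)) {
        incl <- jkeys(tpl$incl); excl <- jkeys(tpl$excl)
      } else {
        sides <- canonical_sides(jkeys(tpl$unk_pair[[1]]), jkeys(tpl$unk_pair[[2]]))
        incl <- sides$inclusion; excl <- sides$exclusion
      }
    } else {
      # alt region = the alternative exon with the lower genomic start;
      # its isoform's junctions are the inclusion side
      p1 <- map_iv(tpl$alt_pair[[1]]); p2 <- map_iv(tpl$alt_pair[[2]])
      first_lower <- p1[1] < p2[1]
      alt_g <- if (first_lower) p1 else p2
      incl <- jkeys(tpl$incl_pair[[if (first_lower) 1 else 2]])
      excl <- jkeys(tpl$incl_pair[[if (first_lower) 2 else 1]])
    }
    gene_start <- offset
    gene_end <- offset + L
    mk <- function(m, tid) {
      data.frame(chrom = config$chrom, start = as.integer(m[, 1]),
                 end = as.integer(m[, 2]), strand = strand, gene_id = gid,
                 transcript_id = tid, stringsAsFactors = FALSE)
    }
    exon_rows[[i]] <- rbind(mk(g1, paste0(gid, ".t1")), mk(g2, paste0(gid, ".t2")))
    truth_rows[[i]] <- data.frame(
      event_id = as_event_id(gid, type, alt_g[1], alt_g[2]),
      gene_id = gid, event_type = type, chrom = config$chrom,
      start = as.integer(alt_g[1]), end = as.integer(alt_g[2]),
      strand = strand, psi_a = psi_a[i], psi_b = psi_b[i],
      gene_start = as.integer(gene_start), gene_end = as.integer(gene_end),
      stringsAsFactors = FALSE)
    truth_rows[[i]]$inclusion_junctions <- I(list(incl))
    truth_rows[[i]]$exclusion_junctions <- I(list(excl))
    offset <- offset + L + config$gene_gap
  }
  exons <- do.call(rbind, c(exon_rows, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  fr <- fold_rule(truth$psi_a, truth$psi_b, threshold = 4.0)
  truth$differential <- fr$passes
  list(exons = validate_exon_table(exons), truth = truth)
}

empty_truth <- function() {
  df <- data.frame(event_id = character(), gene_id = character(),
                   event_type = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   psi_a = numeric(), psi_b = numeric(),
                   gene_start = integer(), gene_end = integer(),
                   stringsAsFactors = FALSE)
  df$inclusion_junctions <- I(list())
  df$exclusion_junctions <- I(list())
  df$differential <- logical(0)
  df
}

#' Simulate junction-read counts and coverage from a truth table
#'
#' Per event, condition and replicate: the event total is Poisson with mean
#' `event_depth` (negative binomial when `overdispersion` is set); the
#' inclusion total is binomial with success probability
#' `w = nI*psi / (nI*psi + nE*(1-psi))` — per-junction read rates proportional
#' to isoform abundance, which the per-side-normalized PSI estimator inverts
#' back to `psi`. Inclusion reads are split uniformly at random across the
#' event's inclusion junctions, exclusion reads likewise. Whole-gene coverage
#' is Poisson at `gene_depth_factor * event_depth`; alternative-region
#' coverage is binomial within it at a psi-scaled length fraction.
#' All draws are governed by `config$seed`.
#'
#' @param truth truth table from [generate_annotation()].
#' @param config the same [sim_config()].
#' @return list with `junctions` (named list `sample ->` named count vector)
#'   and `coverage` (named list `sample ->` named count vector keyed by event
#'   and gene ids), plus `samples_a`/`samples_b` sample-id vectors.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nE <- nrow(truth)
  n_inc <- lengths(truth$inclusion_junctions)
  n_exc <- lengths(truth$exclusion_junctions)
  gene_len <- truth$gene_end - truth$gene_start
  alt_len <- truth$end - truth$start
  gene_rate <- config$gene_depth_factor * config$event_depth
  samples_a <- paste0("A", seq_len(config$n_replicates))
  samples_b <- paste0("B", seq_len(config$n_replicates))
  junctions <- list()
  coverage <- list()
  for (cond in c("a", "b")) {
    psi <- if (cond == "a") truth$psi_a else truth$psi_b
    for (r in seq_len(config$n_replicates)) {
      sid <- paste0(toupper(cond), r)
      total <- if (is.null(config$overdispersion)) {
        stats::rpois(nE, config$event_depth)
      } else {
        stats::rnbinom(nE, size = config$overdispersion, mu = config$event_depth)
      }
      w <- ifelse(n_inc == 0, 0,
                  n_inc * psi / pmax(n_inc * psi + n_exc * (1 - psi), .Machine$double.eps))
      w[n_exc == 0 & n_inc > 0] <- 1
      inc <- stats::rbinom(nE, total, w)
      exc <- total - inc
      acc <- list()
      for (i in seq_len(nE)) {
        ik <- truth$inclusion_junctions[[i]]
        ek <- truth$exclusion_junctions[[i]]
        if (length(ik) > 0 && inc[i] > 0) {
          split_i <- if (length(ik) == 1) inc[i] else
            as.vector(stats::rmultinom(1, inc[i], rep(1, length(ik))))
          acc[[length(acc) + 1L]] <- stats::setNames(split_i, ik)
        }
        if (length(ek) > 0 && exc[i] > 0) {
          split_e <- if (length(ek) == 1) exc[i] else
            as.vector(stats::rmultinom(1, exc[i], rep(1, length(ek))))
          acc[[length(acc) + 1L]] <- stats::setNames(split_e, ek)
        }
      }
      v <- unlist(acc)
      if (is.null(v)) v <- stats::setNames(numeric(0), character(0))
      cnt <- tapply(v, names(v), sum)
      jx <- stats::setNames(as.numeric(cnt), names(cnt))
      jx <- jx[order(names(jx))]
      junctions[[sid]] <- jx
      gene_cov <- stats::rpois(nE, gene_rate)
      frac <- pmin(1, psi * alt_len / gene_len)
      exon_cov <- stats::rbinom(nE, gene_cov, frac)
      coverage[[sid]] <- stats::setNames(
        c(exon_cov, gene_cov), c(truth$event_id, truth$gene_id))
    }
  }
  list(junctions = junctions, coverage = coverage,
       samples_a = samples_a, samples_b = samples_b)
}

#' Generate a gene-to-term annotation map with optional planted enrichment
#'
#' Background terms draw their genes uniformly from the universe; a planted
#' term draws preferentially from a named gene subset so that its
#' over-representation P-value under [enrich()] is small when that subset is
#' selected.
#'
#' @param genes character vector: the gene universe.
#' @param n_terms number of background terms.
#' @param term_size integer range of term sizes, `c(min, max)`.
#' @param enriched optional list with elements `term_id`, `genes` (the
#'   favored subset, must lie within `genes`) and optional `size`.
#' @param seed integer seed.
#' @return term-map data.frame (`gene_id`, `term_id`, `term_name`,
#'   `namespace`).
#' @export
generate_term_map <- function(genes, n_terms = 20, term_size = c(5, 20),
                              enriched = NULL, seed = 1) {
  genes <- unique(genes)
  if (!is.null(enriched) && length(setdiff(enriched$genes, genes)) > 0) {
    stopf("enriched subset contains genes outside the universe")
  }
  set.seed(seed)
  namespaces <- c("BP", "CC", "MF", "pathway")
  rows <- lapply(seq_len(n_terms), function(i) {
    sz <- sample(seq(term_size[1], min(term_size[2], length(genes))), 1)
    data.frame(gene_id = sample(genes, sz),
               term_id = sprintf("T%04d", i),
               term_name = sprintf("synthetic term %d", i),
               namespace = namespaces[(i - 1) %% length(namespaces) + 1],
               stringsAsFactors = FALSE)
  })
  if (!is.null(enriched)) {
    sz <- if (is.null(enriched$size)) length(enriched$genes) else enriched$size
    core <- enriched$genes[seq_len(min(sz, length(enriched$genes)))]
    pad <- if (sz > length(core)) {
      sample(setdiff(genes, core), sz - length(core))
    } else character(0)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = c(core, pad), term_id = enriched$term_id,
      term_name = "planted enriched term", namespace = "BP",
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df[!duplicated(df[, c("gene_id", "term_id")]), , drop = FALSE]
}

#' Write a full simulation to disk
#'
#' Writes `annotation.gtf`, one `<sample>.junctions.bed` per sample (TopHat
#' dialect), `coverage.tsv` and `truth.tsv` into a directory.
#'
#' @param annotation list from [generate_annotation()].
#' @param counts list from [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(annotation, counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(gtf = file.path(dir, "annotation.gtf"),
                coverage = file.path(dir, "coverage.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_gtf(annotation$exons, paths$gtf)
  write_coverage_tsv(counts$coverage, paths$coverage)
  truth <- annotation$truth
  tout <- truth
  tout$inclusion_junctions <- vapply(truth$inclusion_junctions, paste, "", collapse = ";")
  tout$exclusion_junctions <- vapply(truth$exclusion_junctions, paste, "", collapse = ";")
  utils::write.table(tout, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(counts$junctions)) {
    p <- file.path(dir, paste0(s, ".junctions.bed"))
    write_junction_bed(counts$junctions[[s]], p)
    paths[[paste0("bed_", s)]] <- p
  }
  invisible(paths)
}

#' Read a truth table written by [write_simulation()]
#'
#' @param path path to `truth.tsv`.
#' @return truth data.frame with junction list-columns restored.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split_keys <- function(x) {
    lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0)
           else strsplit(s, ";", fixed = TRUE)[[1]])
  }
  df$inclusion_junctions <- I(split_keys(df$inclusion_junctions))
  df$exclusion_junctions <- I(split_keys(df$exclusion_junctions))
  df
}
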