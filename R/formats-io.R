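# Readers and writers for the standard files the pipeline touches.
# All coordinates are converted at these boundaries: GTF is 1-based inclusive,
# BED is 0-based half-open, internal representation is 0-based half-open.

#' Read exon models from a GTF annotation
#'
#' Parses `exon` features of an Ensembl-dialect GTF (attributes `gene_id` and
#' `transcript_id`) into a transcript-model table. GTF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention
#' (GTF `start s, end e` becomes `[s-1, e)`).
#'
#' Validation enforced per transcript: all exons on one chromosome and one of
#' the two strands (`"."` is rejected for transcript features), exons sorted,
#' non-overlapping and non-abutting (at least one intronic base between
#' consecutive exons).
#'
#' @param path path to a GTF file.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`, one row per exon, sorted by transcript and
#'   start. An empty annotation yields a zero-row table with a warning.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(content) == 0) {
    warnf("GTF file %s contains no features", path)
    return(empty_exon_table())
  }
  nfield <- lengths(strsplit(lines[content], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    stopf("malformed GTF line %d in %s: expected 9 tab-separated fields, got %d",
          content[which(nfield < 9)[1]], path, min(nfield))
  }
  gr <- rtracklayer::import(path, format = "gtf", feature.type = "exon")
  if (length(gr) == 0) {
    warnf("GTF file %s contains no exon features", path)
    return(empty_exon_table())
  }
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id) ||
      anyNA(md$gene_id) || anyNA(md$transcript_id)) {
    stopf("GTF exon features in %s must carry gene_id and transcript_id", path)
  }
  ex <- data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = BiocGenerics::start(gr) - 1L,
    end    = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    stringsAsFactors = FALSE
  )
  validate_exon_table(ex)
}

empty_exon_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             transcript_id = character(), stringsAsFactors = FALSE)
}

#' Validate a transcript-model exon table
#'
#' @param ex data.frame as returned by [read_gtf()].
#' @return the table, sorted by transcript and start, invisibly valid.
#' @export
validate_exon_table <- function(ex) {
  required <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(required, names(ex))
  if (length(miss)) stopf("exon table missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(ex) == 0) return(ex)
  check_strand(ex$strand, "transcript exon")
  if (any(ex$start < 0) || any(ex$start >= ex$end)) {
    stopf("invalid exon interval (need 0 <= start < end)")
  }
  ex <- ex[order(ex$transcript_id, ex$start, ex$end), , drop = FALSE]
  rownames(ex) <- NULL
  for (tid in unique(ex$transcript_id)) {
    sub <- ex[ex$transcript_id == tid, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1 || length(unique(sub$strand)) > 1) {
      stopf("transcript %s has exons on multiple chromosomes or strands", tid)
    }
    if (length(unique(sub$gene_id)) > 1) {
      stopf("transcript %s assigned to multiple genes", tid)
    }
    if (nrow(sub) > 1) {
      gap <- sub$start[-1] - sub$end[-nrow(sub)]
      if (any(gap < 1)) {
        stopf("transcript %s has overlapping or abutting exons (intron gap >= 1 required)", tid)
      }
    }
  }
  ex
}

#' Write an exon table as GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open intervals are written as
#' 1-based inclusive GTF exon features. Round-trips coordinates exactly.
#'
#' @param ex exon table (see [read_gtf()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ex, path) {
  ex <- validate_exon_table(ex)
  ex <- ex[order(ex$gene_id, ex$transcript_id, ex$start), , drop = FALSE]
  lines <- sprintf(
    "%s\tdiffAS\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a junction BED12 file (TopHat junctions.bed dialect)
#'
#' Each record has exactly two blocks whose sizes are the read overhangs on
#' either side of the intron; the `score` column holds the junction read
#' count. The intron is recovered as
#' `[chromStart + blockSize1, chromEnd - blockSize2)` (0-based half-open).
#' Records with a block count other than two are skipped with a warning;
#' unstranded (`"."`) or negative-score records are rejected. Duplicate
#' junctions within one file have their counts summed.
#'
#' @param path path to a BED12 file.
#' @param sample_id sample label (attached as an attribute).
#' @return named numeric vector of read counts, names are [jx_key()] keys,
#'   with attribute `sample_id`.
#' @export
read_junction_bed <- function(path, sample_id) {
  if (!file.exists(path)) stopf("junction BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) {
    counts <- stats::setNames(numeric(0), character(0))
    attr(counts, "sample_id") <- sample_id
    return(counts)
  }
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) stopf("%s is not BED12 (no block structure)", path)
  nb <- S4Vectors::elementNROWS(blocks)
  if (any(nb != 2)) {
    warnf("%s: skipping %d record(s) with block count != 2", path, sum(nb != 2))
    gr <- gr[nb == 2]
    blocks <- blocks[nb == 2]
  }
  if (length(gr) == 0) {
    counts <- stats::setNames(numeric(0), character(0))
    attr(counts, "sample_id") <- sample_id
    return(counts)
  }
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score) || anyNA(score)) stopf("%s: missing score (read count) column", path)
  if (any(score < 0)) stopf("%s: negative junction read count", path)
  strand <- as.character(BiocGenerics::strand(gr))
  check_strand(strand, sprintf("junction in %s", path))
  bw <- IRanges::width(blocks)
  w1 <- vapply(bw, `[`, integer(1), 1L)
  w2 <- vapply(bw, `[`, integer(1), 2L)
  intron_start <- (BiocGenerics::start(gr) - 1L) + w1
  intron_end <- BiocGenerics::end(gr) - w2
  if (any(intron_start >= intron_end)) {
    stopf("%s: block sizes leave no intron (chromStart+size1 >= chromEnd-size2)", path)
  }
  keys <- jx_key(as.character(GenomicRanges::seqnames(gr)),
                 intron_start, intron_end, strand)
  counts <- tapply(as.numeric(score), keys, sum)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  attr(counts, "sample_id") <- sample_id
  counts
}

#' Read several junction BED files into a junction count table
#'
#' @param paths character vector of BED12 paths, named by sample id (unnamed
#'   paths use the file base name).
#' @return named list: sample id -> named count vector (see
#'   [read_junction_bed()]).
#' @export
read_junction_beds <- function(paths) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.bed$", "", basename(paths))
  ids[!nzchar(ids)] <- sub("\\.bed$", "", basename(paths))[!nzchar(ids)]
  stats::setNames(lapply(seq_along(paths), function(i) {
    read_junction_bed(paths[[i]], ids[[i]])
  }), ids)
}

#' Write junction counts as TopHat-dialect BED12
#'
#' Inverse of [read_junction_bed()]: each junction becomes a two-block record
#' with symmetric overhangs, score = read count. Junction start must be at
#' least `overhang` bases from the chromosome start.
#'
#' @param counts named numeric vector (names are [jx_key()] keys).
#' @param path output path.
#' @param overhang block size written on each side of the intron (bases).
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(counts, path, overhang = 50L) {
  if (length(counts) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  j <- jx_unkey(names(counts))
  ord <- order(j$chrom, j$start, j$end, j$strand)
  j <- j[ord, , drop = FALSE]
  cnt <- as.numeric(counts)[ord]
  if (any(j$start < overhang)) stopf("junction too close to chromosome start for overhang %d", overhang)
  cs <- j$start - overhang
  ce <- j$end + overhang
  lines <- sprintf(
    "%s\t%d\t%d\tJUNC%05d\t%g\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
    j$chrom, cs, ce, seq_len(nrow(j)), cnt, j$strand, cs, ce,
    overhang, overhang, j$end - j$start + overhang)
  writeLines(lines, path)
  invisible(path)
}

#' Read a coverage table (sample, feature, fragment count)
#'
#' @param path TSV with columns `sample_id`, `feature_id`, `count`. Feature
#'   ids are either event ids (alternative-region coverage) or gene ids
#'   (whole-gene coverage).
#' @return named list: sample id -> named numeric vector of counts.
#' @export
read_coverage_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "feature_id", "count"), names(df))
  if (length(miss)) stopf("coverage table %s missing columns: %s", path, paste(miss, collapse = ", "))
  if (any(df$count < 0)) stopf("coverage table %s has negative counts", path)
  lapply(split(df, df$sample_id), function(s) {
    stats::setNames(as.numeric(s$count), s$feature_id)
  })
}

#' Write a coverage table
#'
#' @param coverage named list as returned by [read_coverage_tsv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(coverage, path) {
  rows <- lapply(names(coverage), function(s) {
    v <- coverage[[s]]
    data.frame(sample_id = s, feature_id = names(v), count = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- data.frame(sample_id = character(), feature_id = character(), count = numeric())
  df <- df[order(df$sample_id, df$feature_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RESULT_COLUMNS <- c("event_id", "gene_id", "event_type", "chrom", "start",
                    "end", "strand", "psi_a", "psi_b", "p_junction",
                    "p_coverage", "p_combined", "p_adjusted", "fold",
                    "breed_exclusive", "tier")

#' Write differential-splicing results as TSV
#'
#' One row per event with both condition PSIs, the junction and coverage
#' P-values, the combined and adjusted P-values, the level fold change, the
#' exclusivity flag and the significance tier (`NS`/`SIG`/`EXT`). Missing
#' values are written as `"."`. Numeric columns are serialized at full double
#' precision so the table round-trips losslessly through
#' [read_results_tsv()].
#'
#' @param results data.frame as returned by [diff_splice()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  miss <- setdiff(RESULT_COLUMNS, names(results))
  if (length(miss)) stopf("results table missing columns: %s", paste(miss, collapse = ", "))
  out <- results[, RESULT_COLUMNS, drop = FALSE]
  if (nrow(out) == 0) {
    writeLines(paste(RESULT_COLUMNS, collapse = "\t"), path)
    return(invisible(path))
  }
  fmt <- function(x) {
    if (is.numeric(x)) {
      s <- vapply(x, function(v) {
        if (is.na(v)) "." else if (is.infinite(v)) ifelse(v > 0, "Inf", "-Inf")
        else sprintf("%.17g", v)
      }, "")
      s
    } else if (is.logical(x)) {
      ifelse(is.na(x), ".", ifelse(x, "TRUE", "FALSE"))
    } else {
      x <- as.character(x)
      ifelse(is.na(x), ".", x)
    }
  }
  txt <- vapply(out, fmt, character(nrow(out)))
  if (nrow(out) == 1) txt <- matrix(txt, nrow = 1, dimnames = list(NULL, names(out)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(RESULT_COLUMNS, collapse = "\t"), con)
  if (nrow(out) > 0) {
    writeLines(apply(txt, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a differential-splicing results TSV
#'
#' Companion reader for [write_results_tsv()].
#'
#' @param path path written by [write_results_tsv()].
#' @return data.frame with the standard result columns; `"."` becomes `NA`.
#' @export
read_results_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                          colClasses = "character")
  miss <- setdiff(RESULT_COLUMNS, names(df))
  if (length(miss)) stopf("results file %s missing columns: %s", path, paste(miss, collapse = ", "))
  num <- c("start", "end", "psi_a", "psi_b", "p_junction", "p_coverage",
           "p_combined", "p_adjusted", "fold")
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$breed_exclusive <- as.logical(df$breed_exclusive)
  if (nrow(df) > 0 && any(!df$tier %in% c("NS", "SIG", "EXT"), na.rm = TRUE)) {
    stopf("results file %s has tier values outside NS/SIG/EXT", path)
  }
  df
}

#' Read a gene-to-term annotation map
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`,
#'   `namespace`. Duplicate (gene, term) rows are collapsed.
#' @return data.frame of unique gene/term annotations.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "term_id", "term_name", "namespace")
  miss <- setdiff(required, names(df))
  if (length(miss)) stopf("term map %s missing columns: %s", path, paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warnf("term map %s is empty", path)
    return(df[, required])
  }
  df <- df[!duplicated(df[, c("gene_id", "term_id")]), required, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene-to-term annotation map
#'
#' @param term_map data.frame as returned by [read_term_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(term_map, path) {
  utils::write.table(term_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
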