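# Splice-graph reconstruction: exon clusters and classification of local
# structural differences between isoforms into the nine event categories.

#' Extract the annotated splice-junction universe
#'
#' One junction per adjacent exon pair per transcript, deduplicated across
#' transcripts. Single-exon transcripts contribute nothing.
#'
#' @param ex exon table (see [read_gtf()]).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, `key`,
#'   sorted by position.
#' @export
extract_junctions <- function(ex) {
  ex <- validate_exon_table(ex)
  out <- list()
  for (tid in unique(ex$transcript_id)) {
    sub <- ex[ex$transcript_id == tid, , drop = FALSE]
    if (nrow(sub) < 2) next
    out[[tid]] <- data.frame(
      chrom = sub$chrom[-nrow(sub)],
      start = sub$end[-nrow(sub)],
      end = sub$start[-1],
      strand = sub$strand[-nrow(sub)],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  j <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  j$key <- jx_key(j$chrom, j$start, j$end, j$strand)
  j <- j[!duplicated(j$key), , drop = FALSE]
  j <- j[order(j$chrom, j$start, j$end, j$strand), , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Reconstruct exon clusters per gene
#'
#' Single-linkage merge of exons overlapping by at least one base; the cluster
#' interval is the union of its members. Abutting exons (half-open intervals
#' sharing only a boundary) are kept distinct. All transcripts of a gene must
#' lie on one chromosome and strand.
#'
#' @param ex exon table (see [read_gtf()]).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `n_members`, sorted by gene and start.
#' @export
build_exon_clusters <- function(ex) {
  ex <- validate_exon_table(ex)
  out <- list()
  for (gid in unique(ex$gene_id)) {
    sub <- ex[ex$gene_id == gid, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1 || length(unique(sub$strand)) > 1) {
      stopf("gene %s has transcripts on multiple chromosomes or strands", gid)
    }
    # 0-based half-open -> 1-based closed; overlap >= 1 base is overlap in
    # both conventions. min.gapwidth = 0 keeps abutting intervals distinct.
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hits <- IRanges::findOverlaps(ir, red)
    nm <- tabulate(S4Vectors::subjectHits(hits), nbins = length(red))
    out[[gid]] <- data.frame(
      gene_id = gid,
      chrom = sub$chrom[1],
      start = BiocGenerics::start(red) - 1L,
      end = BiocGenerics::end(red),
      strand = sub$strand[1],
      n_members = nm,
      stringsAsFactors = FALSE
    )
  }
  cl <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(cl)) {
    cl <- data.frame(gene_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     n_members = integer(), stringsAsFactors = FALSE)
  }
  cl <- cl[order(cl$gene_id, cl$start), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Donor/acceptor polarity of a junction side
#'
#' On the plus strand the lower-coordinate side of an intron is the donor
#' (5' splice site); on the minus strand it is the acceptor. Flipping the
#' strand always flips the answer.
#'
#' @param junction_side `"lower_coord"` or `"higher_coord"`.
#' @param strand `"+"` or `"-"`.
#' @return `"donor"` or `"acceptor"`.
#' @export
strand_polarity <- function(junction_side, strand) {
  junction_side <- match.arg(junction_side, c("lower_coord", "higher_coord"))
  check_strand(strand, "junction")
  if ((junction_side == "lower_coord") == (strand == "+")) "donor" else "acceptor"
}

# ---- pairwise classifier ----------------------------------------------------

tx_junctions <- function(exm) {
  n <- nrow(exm)
  if (n < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = exm$end[-n], end = exm$start[-1])
}

# Segment states over the elementary segmentation of a transcript pair:
# 2 = exonic, 1 = intronic (inside the transcript span), 0 = outside.
segment_states <- function(exm, seg_start, seg_end) {
  st <- integer(length(seg_start))
  span_lo <- min(exm$start); span_hi <- max(exm$end)
  st[seg_start >= span_lo & seg_end <= span_hi] <- 1L
  for (i in seq_len(nrow(exm))) {
    inside <- seg_start >= exm$start[i] & seg_end <= exm$end[i]
    st[inside] <- 2L
  }
  st
}

# Exon fragments of one transcript clipped to a region, annotated with the
# original exon boundaries and the exon's ordinal position.
region_fragments <- function(exm, rs, re) {
  keep <- exm$end > rs & exm$start < re
  sub <- exm[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(fstart = integer(), fend = integer(),
                      ostart = integer(), oend = integer(), idx = integer()))
  }
  data.frame(fstart = pmax(sub$start, rs), fend = pmin(sub$end, re),
             ostart = sub$start, oend = sub$end, idx = which(keep))
}

in_region <- function(j, rs, re) j[j$start >= rs & j$end <= re, , drop = FALSE]

jset_keys <- function(j, chrom, strand) {
  if (nrow(j) == 0) return(character(0))
  sort(jx_key(chrom, j$start, j$end, strand))
}

# A "full internal exon" fragment equals its original exon and sits strictly
# inside the region.
is_full_internal <- function(f, rs, re) {
  f$fstart == f$ostart & f$fend == f$oend & f$fstart > rs & f$fend < re
}

make_event <- function(type, gene_id, chrom, strand, alt_start, alt_end,
                       inclusion, exclusion, reason = NA_character_) {
  list(event_type = type, gene_id = gene_id, chrom = chrom, strand = strand,
       start = as.integer(alt_start), end = as.integer(alt_end),
       inclusion = sort(unique(inclusion)), exclusion = sort(unique(exclusion)),
       reason = reason)
}

# Classify one difference region between a pair of isoforms. rs/re bound the
# region; left_flank/right_flank say whether a shared exonic block borders it.
# Returns an event record or NULL (no junction-level difference).
classify_region <- function(rs, re, f1, f2, j1, j2, jall1, jall2,
                            left_flank, right_flank, chrom, strand, gene_id) {
  k1 <- jset_keys(j1, chrom, strand)
  k2 <- jset_keys(j2, chrom, strand)
  if (length(k1) == 0 && length(k2) == 0) return(NULL)   # boundary overhang
  if (identical(k1, k2)) return(NULL)                    # no junction change

  spans_region <- function(j) nrow(j) == 1 && j$start == rs && j$end == re

  # retain_intron: one side a single exon fragment covering the whole region
  # with no junctions, the other side intronic with exactly the region's
  # junction. Inclusion evidence uses the retaining isoform's constitutive
  # junctions flanking its composite exon.
  if (left_flank && right_flank) {
    ri <- function(fr, jr, fo, jo, jall_r) {
      if (nrow(fr) == 1 && fr$fstart == rs && fr$fend == re && nrow(jr) == 0 &&
          nrow(fo) == 0 && spans_region(jo)) {
        flank <- jall_r[jall_r$end == fr$ostart | jall_r$start == fr$oend, , drop = FALSE]
        make_event("retain_intron", gene_id, chrom, strand, rs, re,
                   jset_keys(flank, chrom, strand),
                   jset_keys(jo, chrom, strand))
      } else NULL
    }
    ev <- ri(f1, j1, f2, j2, jall1)
    if (is.null(ev)) ev <- ri(f2, j2, f1, j1, jall2)
    if (!is.null(ev)) return(ev)

    # mutually exclusive: one full internal exon on each side, non-overlapping,
    # each spliced to both flanks.
    if (nrow(f1) == 1 && nrow(f2) == 1 &&
        is_full_internal(f1, rs, re) && is_full_internal(f2, rs, re) &&
        (f1$fend <= f2$fstart || f2$fend <= f1$fstart)) {
      exp1 <- jset_keys(data.frame(start = c(rs, f1$fend), end = c(f1$fstart, re)), chrom, strand)
      exp2 <- jset_keys(data.frame(start = c(rs, f2$fend), end = c(f2$fstart, re)), chrom, strand)
      if (identical(k1, exp1) && identical(k2, exp2)) {
        lower_first <- f1$fstart < f2$fstart
        alt <- if (lower_first) f1 else f2
        make_event("mutually_exclusive", gene_id, chrom, strand,
                   alt$fstart, alt$fend,
                   if (lower_first) k1 else k2,
                   if (lower_first) k2 else k1) -> ev
        return(ev)
      }
    }

    # cassette / cassette_multi: k >= 1 full internal exons chained on one
    # side, a single spanning junction on the other.
    cas <- function(fi, ji, fo, jo) {
      kx <- nrow(fi)
      if (kx >= 1 && all(is_full_internal(fi, rs, re)) &&
          nrow(fo) == 0 && spans_region(jo)) {
        fi <- fi[order(fi$fstart), , drop = FALSE]
        expected <- jset_keys(data.frame(start = c(rs, fi$fend),
                                         end = c(fi$fstart, re)), chrom, strand)
        if (identical(jset_keys(ji, chrom, strand), expected)) {
          make_event(if (kx == 1) "cassette" else "cassette_multi",
                     gene_id, chrom, strand, fi$fstart[1], fi$fend[kx],
                     expected, jset_keys(jo, chrom, strand))
        } else NULL
      } else NULL
    }
    ev <- cas(f1, j1, f2, j2)
    if (is.null(ev)) ev <- cas(f2, j2, f1, j1)
    if (!is.null(ev)) return(ev)

    # alternative donor/acceptor site: one side extends a flanking exon into
    # the region, the other splices across the whole region.
    alt_site <- function(fx, jx, fo, jo) {
      if (nrow(fx) != 1 || nrow(fo) != 0 || !spans_region(jo)) return(NULL)
      left_ext <- fx$fstart == rs && fx$ostart < rs && fx$fend < re
      right_ext <- fx$fend == re && fx$oend > re && fx$fstart > rs
      if (left_ext == right_ext) return(NULL)
      expected <- if (left_ext) data.frame(start = fx$fend, end = re)
                  else data.frame(start = rs, end = fx$fstart)
      if (!identical(jset_keys(jx, chrom, strand),
                     jset_keys(expected, chrom, strand))) return(NULL)
      side <- if (left_ext) "lower_coord" else "higher_coord"
      type <- if (strand_polarity(side, strand) == "donor") "alt5prime" else "alt3prime"
      make_event(type, gene_id, chrom, strand, fx$fstart, fx$fend,
                 jset_keys(jx, chrom, strand), jset_keys(jo, chrom, strand))
    }
    ev <- alt_site(f1, j1, f2, j2)
    if (is.null(ev)) ev <- alt_site(f2, j2, f1, j1)
    if (!is.null(ev)) return(ev)
  }

  # transcript-boundary variation: alternative first/last exon clusters.
  if (xor(left_flank, right_flank)) {
    left_terminal <- !left_flank
    term <- function(fx, jx, exm_n) {
      if (nrow(fx) != 1 || fx$fstart != fx$ostart || fx$fend != fx$oend) return(NULL)
      if (left_terminal) {
        if (nrow(jx) != 1 || jx$start != fx$fend || jx$end != re) return(NULL)
      } else {
        if (nrow(jx) != 1 || jx$end != fx$fstart || jx$start != rs) return(NULL)
      }
      fx
    }
    t1 <- term(f1, j1); t2 <- term(f2, j2)
    if (!is.null(t1) && !is.null(t2) &&
        (t1$fend <= t2$fstart || t2$fend <= t1$fstart)) {
      type <- if (left_terminal == (strand == "+")) "altstart" else "altend"
      lower_first <- t1$fstart < t2$fstart
      alt <- if (lower_first) t1 else t2
      return(make_event(type, gene_id, chrom, strand, alt$fstart, alt$fend,
                        jset_keys(if (lower_first) j1 else j2, chrom, strand),
                        jset_keys(if (lower_first) j2 else j1, chrom, strand)))
    }
  }

  # fallback: structurally different but matching no template.
  u1 <- setdiff(k1, k2)
  u2 <- setdiff(k2, k1)
  if (length(u1) == 0 && length(u2) == 0) return(NULL)
  sides <- canonical_sides(u1, u2)
  make_event("unknown", gene_id, chrom, strand, rs, re,
             sides$inclusion, sides$exclusion,
             reason = sprintf(
               "no template: %d/%d exon fragments, %d/%d junctions in region [%d,%d)",
               nrow(f1), nrow(f2), nrow(j1), nrow(j2), rs, re))
}

classify_pair <- function(ex1, ex2, chrom, strand, gene_id) {
  if (nrow(ex1) == nrow(ex2) &&
      all(ex1$start == ex2$start) && all(ex1$end == ex2$end)) return(list())
  bnds <- sort(unique(c(ex1$start, ex1$end, ex2$start, ex2$end)))
  ss <- bnds[-length(bnds)]
  se <- bnds[-1]
  s1 <- segment_states(ex1, ss, se)
  s2 <- segment_states(ex2, ss, se)
  agree_exon <- s1 == 2L & s2 == 2L
  differ <- s1 != s2
  jall1 <- tx_junctions(ex1)
  jall2 <- tx_junctions(ex2)
  # difference regions: maximal runs not interrupted by shared exonic
  # sequence (shared intronic stretches do not synchronize the pair).
  run <- rle(agree_exon)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  events <- list()
  for (i in seq_along(run$values)) {
    if (run$values[i]) next
    idx <- starts[i]:ends[i]
    if (!any(differ[idx])) next
    rs <- ss[idx[1]]
    re <- se[idx[length(idx)]]
    ev <- classify_region(
      rs, re,
      region_fragments(ex1, rs, re), region_fragments(ex2, rs, re),
      in_region(jall1, rs, re), in_region(jall2, rs, re),
      jall1, jall2,
      left_flank = idx[1] > 1 && agree_exon[idx[1] - 1L],
      right_flank = idx[length(idx)] < length(ss) && agree_exon[idx[length(idx)] + 1L],
      chrom, strand, gene_id)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  events
}

#' Detect and classify alternative-splicing events
#'
#' Compares the isoforms of each multi-transcript gene pairwise, matches every
#' local structural difference against the nine event templates in the fixed
#' priority order retain_intron, mutually_exclusive, cassette_multi, cassette,
#' alt5prime, alt3prime, altstart, altend, and labels anything unmatched as
#' `unknown` (with the triggering structure recorded in `reason`). Duplicate
#' events arising from different isoform pairs (same type, region and junction
#' sets) are emitted once. Output is invariant to transcript input order.
#'
#' @param ex exon table (see [read_gtf()]).
#' @return data.frame with one row per event: `event_id`, `gene_id`,
#'   `event_type`, `chrom`, `start`, `end`, `strand` (the alternative region),
#'   list-columns `inclusion_junctions` and `exclusion_junctions` holding
#'   junction keys, and `reason` (non-`NA` only for `unknown`).
#' @export
detect_events <- function(ex) {
  ex <- validate_exon_table(ex)
  all_events <- list()
  for (gid in unique(ex$gene_id)) {
    sub <- ex[ex$gene_id == gid, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1 || length(unique(sub$strand)) > 1) {
      stopf("gene %s has transcripts on multiple chromosomes or strands", gid)
    }
    tids <- sort(unique(sub$transcript_id))
    if (length(tids) < 2) next
    chrom <- sub$chrom[1]; strand <- sub$strand[1]
    exl <- lapply(tids, function(t) {
      e <- sub[sub$transcript_id == t, c("start", "end"), drop = FALSE]
      e[order(e$start), , drop = FALSE]
    })
    for (i in seq_len(length(tids) - 1L)) {
      for (j in (i + 1L):length(tids)) {
        evs <- classify_pair(exl[[i]], exl[[j]], chrom, strand, gid)
        all_events <- c(all_events, evs)
      }
    }
  }
  events_to_frame(all_events)
}

events_to_frame <- function(events) {
  if (length(events) == 0) {
    return(data.frame(event_id = character(), gene_id = character(),
                      event_type = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      inclusion_junctions = I(list()),
                      exclusion_junctions = I(list()),
                      reason = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    gene_id = vapply(events, `[[`, "", "gene_id"),
    event_type = vapply(events, `[[`, "", "event_type"),
    chrom = vapply(events, `[[`, "", "chrom"),
    start = vapply(events, `[[`, integer(1), "start"),
    end = vapply(events, `[[`, integer(1), "end"),
    strand = vapply(events, `[[`, "", "strand"),
    reason = vapply(events, `[[`, NA_character_, "reason"),
    stringsAsFactors = FALSE
  )
  df$inclusion_junctions <- I(lapply(events, `[[`, "inclusion"))
  df$exclusion_junctions <- I(lapply(events, `[[`, "exclusion"))
  key <- paste(df$gene_id, df$event_type, df$chrom, df$start, df$end, df$strand,
               vapply(df$inclusion_junctions, paste, "", collapse = ";"),
               vapply(df$exclusion_junctions, paste, "", collapse = ";"),
               sep = "#")
  keep <- !duplicated(key)
  df <- df[keep, , drop = FALSE]
  key <- key[keep]
  # canonical order (input-order invariant), then ids; suffix on collisions
  df <- df[order(df$gene_id, df$chrom, df$start, df$end, df$event_type, key), , drop = FALSE]
  ids <- as_event_id(df$gene_id, df$event_type, df$start, df$end)
  dup <- ave(seq_along(ids), ids, FUN = seq_along)
  ids[dup > 1] <- paste0(ids[dup > 1], "#", dup[dup > 1])
  df$event_id <- ids
  rownames(df) <- NULL
  df[, c("event_id", "gene_id", "event_type", "chrom", "start", "end",
         "strand", "inclusion_junctions", "exclusion_junctions", "reason")]
}

#' Export events as GTF-like feature lines
#'
#' One feature per alternative region with `event_id` and `event_type`
#' attributes.
#'
#' @param events data.frame from [detect_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_gtf <- function(events, path) {
  lines <- sprintf(
    "%s\tdiffAS\tas_event\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; event_id \"%s\"; event_type \"%s\";",
    events$chrom, events$start + 1L, events$end, events$strand,
    events$gene_id, events$event_id, events$event_type)
  writeLines(lines, path)
  invisible(path)
}

#' Export events as a TSV table
#'
#' Junction sets are serialized as `;`-separated key lists.
#'
#' @param events data.frame from [detect_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- events
  out$inclusion_junctions <- vapply(events$inclusion_junctions, paste, "", collapse = ";")
  out$exclusion_junctions <- vapply(events$exclusion_junctions, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#'
#' @param path input path.
#' @return events data.frame with junction list-columns restored.
#' @export
read_events_tsv <- function(path) {
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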