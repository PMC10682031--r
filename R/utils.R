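#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# Conversion to/from 1-based inclusive happens only in the readers/writers.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Decimal rounding, ties away from zero
#'
#' Plain half-up decimal rounding (0.5 rounds up), as used for the reported
#' percentage tables. Base `round()` rounds half to even, which disagrees with
#' conventional printed percentages on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # tiny eps absorbs binary representation error below the rounding scale
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Splice junction identifier
#'
#' Junctions are keyed by chromosome, the 0-based half-open intron interval
#' and the strand, e.g. `"chr1:150-350:+"`. Strand is part of the identity:
#' donor/acceptor polarity is meaningless without it.
#'
#' @param chrom chromosome name.
#' @param start first intron base (0-based).
#' @param end one past the last intron base.
#' @param strand `"+"` or `"-"`.
#' @return character vector of junction keys.
#' @export
jx_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Parse junction keys back into a data frame
#'
#' @param keys character vector produced by [jx_key()].
#' @return data.frame with columns chrom, start, end, strand.
#' @export
jx_unkey <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stopf("malformed junction key: %s", keys[bad][1])
  coords <- strsplit(vapply(parts, `[[`, "", 2), "-", fixed = TRUE)
  data.frame(
    chrom  = vapply(parts, `[[`, "", 1),
    start  = as.integer(vapply(coords, `[[`, "", 1)),
    end    = as.integer(vapply(coords, `[[`, "", 2)),
    strand = vapply(parts, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
}

# Deterministic event identifier shared by the detector and the generator.
as_event_id <- function(gene_id, event_type, start, end) {
  sprintf("%s|%s|%d-%d", gene_id, event_type, as.integer(start), as.integer(end))
}

# Canonical assignment of two junction-key sets to inclusion/exclusion when no
# template dictates it (the "unknown" class): the side whose sorted key string
# sorts first becomes the inclusion side. Order-invariant by construction.
canonical_sides <- function(keys1, keys2) {
  k1 <- paste(sort(keys1), collapse = ";")
  k2 <- paste(sort(keys2), collapse = ";")
  if (k1 <= k2) list(inclusion = keys1, exclusion = keys2)
  else          list(inclusion = keys2, exclusion = keys1)
}

check_strand <- function(strand, context = "feature") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stopf("invalid strand '%s' for %s (must be '+' or '-')",
          as.character(strand[bad][1]), context)
  }
  invisible(strand)
}

# Nine event-type vocabulary, fixed classifier priority order.
EVENT_TYPES <- c("retain_intron", "mutually_exclusive", "cassette_multi",
                 "cassette", "alt5prime", "alt3prime", "altstart", "altend",
                 "unknown")
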