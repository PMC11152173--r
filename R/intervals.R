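#' Genomic interval tibbles
#'
#' Intervals are plain tibbles with columns `chrom` (character), `start`
#' (0-based inclusive), `end` (0-based exclusive) and `strand` (`"+"`,
#' `"-"`, or `"*"` for strand-agnostic records). All coordinate arithmetic
#' in the package happens in this 0-based half-open convention; input
#' dialects are converted once at the file boundary.
#'
#' @param chrom,start,end,strand Vectors recycled to a common length.
#' @return An interval tibble.
#' @export
#' @examples
#' interval_tbl("chr1", 100, 150, "+")
interval_tbl <- function(chrom, start, end, strand = "+") {
  tbl <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand)
  )
  validate_intervals(tbl)
  tbl
}

validate_intervals <- function(tbl, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(tbl)))
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad) > 0) {
    abort(sprintf("invalid interval at row %d: start=%d end=%d",
                  bad[1], tbl$start[bad[1]], tbl$end[bad[1]]))
  }
  bad <- which(!tbl$strand %in% c("+", "-", "*"))
  if (length(bad) > 0) {
    abort(sprintf("invalid strand '%s' at row %d", tbl$strand[bad[1]], bad[1]))
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(tbl$chrom), names(chrom_lengths))
    if (length(unknown) > 0) {
      abort(paste0("unknown chromosome: ", unknown[1]))
    }
    bad <- which(tbl$end > chrom_lengths[tbl$chrom])
    if (length(bad) > 0) {
      abort(sprintf("interval out of bounds at row %d: %s:[%d,%d) > length %d",
                    bad[1], tbl$chrom[bad[1]], tbl$start[bad[1]],
                    tbl$end[bad[1]],
                    chrom_lengths[[tbl$chrom[bad[1]]]]))
    }
  }
  invisible(tbl)
}

#' Overlap fraction between paired intervals
#'
#' Fraction of the shorter interval covered by the intersection, the
#' similarity used for replicate concordance. Zero when chromosome or
#' strand differ (a `"*"` strand matches either).
#'
#' @param a,b Interval tibbles of equal row count; row i of `a` is compared
#'   with row i of `b`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' overlap_fraction(interval_tbl("chr1", 0, 100), interval_tbl("chr1", 70, 170))
overlap_fraction <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  inter <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  shorter <- pmin(a$end - a$start, b$end - b$start)
  frac <- inter / shorter
  same <- a$chrom == b$chrom &
    (a$strand == b$strand | a$strand == "*" | b$strand == "*")
  ifelse(same, frac, 0)
}

#' Extend intervals with genomic context
#'
#' Widens each interval by `context_len` nt on both sides, clipped at the
#' chromosome boundaries. The original span is carried along in
#' `core_start`/`core_end` so the site's offset within the window is never
#' lost.
#'
#' @param intervals Interval tibble.
#' @param context_len Non-negative extension in nt.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return The widened interval tibble with `core_start`, `core_end`.
#' @export
add_context <- function(intervals, context_len, chrom_lengths) {
  stopifnot(context_len >= 0)
  validate_intervals(intervals, chrom_lengths)
  intervals %>%
    mutate(
      core_start = .data$start,
      core_end = .data$end,
      start = pmax(0L, .data$start - as.integer(context_len)),
      end = pmin(as.integer(chrom_lengths[.data$chrom]),
                 .data$end + as.integer(context_len))
    )
}

#' Extend crosslink positions
#'
#' Widens each interval by `flank` nt on both sides (so a single crosslinked
#' base becomes a `2*flank + 1` nt span), clipped at chromosome bounds when
#' lengths are supplied.
#'
#' @param intervals Interval tibble.
#' @param flank Non-negative extension in nt, each side.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return The widened interval tibble.
#' @export
extend_crosslinks <- function(intervals, flank, chrom_lengths = NULL) {
  stopifnot(flank >= 0)
  out <- intervals %>%
    mutate(start = pmax(0L, .data$start - as.integer(flank)),
           end = .data$end + as.integer(flank))
  if (!is.null(chrom_lengths)) {
    out <- out %>%
      mutate(end = pmin(as.integer(chrom_lengths[.data$chrom]), .data$end))
  }
  out
}

# window-local (1-based, strand-oriented) <-> genomic (0-based) position maps
local_to_genomic <- function(window, local) {
  if (window$strand == "-") window$end - local else window$start + local - 1L
}

genomic_to_local <- function(window, pos) {
  if (window$strand == "-") window$end - pos else pos - window$start + 1L
}

as_granges <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = ifelse(tbl$strand == "*", "*", tbl$strand)
  )
}
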