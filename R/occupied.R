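#' Build the occupied-region library
#'
#' Collects every genomic span assumed unavailable for pairing: both arms of
#' every interaction with score at least `score_min` (default 0.5, a lower
#' cutoff than for trusted sites, implementing a deliberately conservative
#' notion of "occupied"), plus any RNA-binding-protein intervals. Spans are
#' merged per strand within each origin, so overlapping RRI and RBP spans
#' both survive with distinct origin tags.
#'
#' @param records Interaction tibble (all replicates concatenated), or NULL.
#' @param score_min Score cutoff for interactions entering the library.
#' @param rbp_intervals Optional interval tibble of RBP binding sites
#'   (already crosslink-extended if they come from single-base tracks, see
#'   [extend_crosslinks()]).
#' @return An object of class `rri_occupied` wrapping an interval tibble
#'   with an `origin` column (`"rri"` or `"rbp"`).
#' @export
build_occupied_library <- function(records = NULL, score_min = 0.5,
                                   rbp_intervals = NULL) {
  parts <- list()
  if (!is.null(records) && nrow(records) > 0) {
    keep <- filter_by_score(records, score_min)
    if (nrow(keep) > 0) {
      arms <- bind_rows(arm_intervals(keep, 1), arm_intervals(keep, 2)) %>%
        mutate(origin = "rri")
      parts <- c(parts, list(arms))
    }
  }
  if (!is.null(rbp_intervals) && nrow(rbp_intervals) > 0) {
    parts <- c(parts, list(
      rbp_intervals %>%
        select(all_of(c("chrom", "start", "end", "strand"))) %>%
        mutate(origin = "rbp")
    ))
  }
  tbl <- if (length(parts) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), origin = character())
  } else {
    bind_rows(parts) %>%
      group_by(.data$origin, .data$strand) %>%
      dplyr::group_modify(function(d, key) {
        gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
          d$chrom, IRanges::IRanges(d$start + 1L, d$end)))
        tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
      }) %>%
      ungroup() %>%
      select(all_of(c("chrom", "start", "end", "strand", "origin"))) %>%
      arrange(.data$chrom, .data$start, .data$end, .data$strand)
  }
  structure(list(tbl = tbl), class = "rri_occupied")
}

#' @export
print.rri_occupied <- function(x, ...) {
  cat("<rri_occupied>", nrow(x$tbl), "merged spans (",
      sum(x$tbl$origin == "rri"), "rri /", sum(x$tbl$origin == "rbp"),
      "rbp )\n")
  invisible(x)
}

#' Query an occupied-region library
#'
#' @param index An `rri_occupied` library.
#' @param window A single-row interval tibble.
#' @return The stored spans overlapping the window on its strand (spans on
#'   `"*"` occupy both strands).
#' @export
occupied_query <- function(index, window) {
  stopifnot(inherits(index, "rri_occupied"), nrow(window) == 1)
  tbl <- index$tbl
  tbl %>%
    filter(.data$chrom == window$chrom,
           .data$start < window$end, .data$end > window$start,
           .data$strand == "*" | window$strand == "*" |
             .data$strand == window$strand)
}

#' Occupancy mask over a window
#'
#' Boolean mask in window-local, strand-oriented order (position 1 is the 5'
#' end of the window's strand): `TRUE` where the genomic position is covered
#' by an occupied span on the window's strand or by a strand-agnostic span.
#'
#' @param index An `rri_occupied` library.
#' @param window Single-row interval tibble.
#' @param exclude Optional interval tibble: stored spans overlapping any of
#'   these intervals (same chrom/strand) are ignored — used to lift a site's
#'   own arms out of its positive-instance mask.
#' @return Logical vector of length `window$end - window$start`.
#' @export
occupied_mask <- function(index, window, exclude = NULL) {
  hits <- occupied_query(index, window)
  if (!is.null(exclude) && nrow(hits) > 0 && nrow(exclude) > 0) {
    drop <- vapply(seq_len(nrow(hits)), function(r) {
      any(hits$chrom[r] == exclude$chrom &
            hits$start[r] < exclude$end & hits$end[r] > exclude$start &
            (hits$strand[r] == "*" | exclude$strand == "*" |
               hits$strand[r] == exclude$strand))
    }, logical(1))
    hits <- hits[!drop, ]
  }
  w <- window$end - window$start
  mask <- rep(FALSE, w)
  if (nrow(hits) > 0) {
    for (r in seq_len(nrow(hits))) {
      a <- max(hits$start[r], window$start) - window$start + 1L
      b <- min(hits$end[r], window$end) - window$start
      mask[a:b] <- TRUE
    }
  }
  if (window$strand == "-") rev(mask) else mask
}

#' Serialize an occupied library to BED
#'
#' @param index An `rri_occupied` library.
#' @param path Output BED file; the origin tag becomes the name column.
#' @export
write_occupied_bed <- function(index, path) {
  write_bed(index$tbl, path)
}
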