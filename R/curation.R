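#' Filter interactions by score
#'
#' Keeps records whose score is at least `score_min` (the trusted-site EM
#' score cutoff, default 1, when applied after replicate concordance).
#'
#' @param records Interaction tibble.
#' @param score_min Non-negative cutoff.
#' @return The filtered tibble, input order preserved.
#' @export
filter_by_score <- function(records, score_min) {
  stopifnot(score_min >= 0)
  records %>% filter(.data$score >= score_min)
}

# all concordant matches between two replicate tables: records a (in ra) and
# b (in rb) match when both arms overlap >= threshold, in either arm pairing
pairwise_matches <- function(ra, rb, overlap_threshold) {
  if (nrow(ra) == 0 || nrow(rb) == 0) {
    return(tibble(ia = integer(), ib = integer(), ovl = double()))
  }
  hit_tbl <- function(arm_a, arm_b) {
    # disjoint seqlevels between replicates are expected, not a problem
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(as_granges(arm_a), as_granges(arm_b)))
    ia <- S4Vectors::queryHits(hits)
    ib <- S4Vectors::subjectHits(hits)
    tibble(ia = ia, ib = ib,
           f = overlap_fraction(arm_a[ia, ], arm_b[ib, ]))
  }
  straight <- dplyr::inner_join(
    hit_tbl(arm_intervals(ra, 1), arm_intervals(rb, 1)),
    hit_tbl(arm_intervals(ra, 2), arm_intervals(rb, 2)),
    by = c("ia", "ib"), suffix = c("1", "2")
  )
  swapped <- dplyr::inner_join(
    hit_tbl(arm_intervals(ra, 1), arm_intervals(rb, 2)),
    hit_tbl(arm_intervals(ra, 2), arm_intervals(rb, 1)),
    by = c("ia", "ib"), suffix = c("1", "2")
  )
  combined <- bind_rows(straight, swapped) %>%
    mutate(ovl = pmin(.data$f1, .data$f2)) %>%
    filter(.data$ovl >= overlap_threshold)
  if (nrow(combined) == 0) {
    return(tibble(ia = integer(), ib = integer(), ovl = double()))
  }
  combined %>%
    group_by(.data$ia, .data$ib) %>%
    summarise(ovl = max(.data$ovl), .groups = "drop")
}

#' Select trusted RRI sites by replicate concordance
#'
#' A site from the first replicate is trusted when every other replicate
#' contains a record whose two arms overlap the site's arms by at least
#' `overlap_threshold` (relative to the shorter interval; the arm pairing
#' may be swapped). Grouping is greedy one-to-one: candidate sites are
#' processed by descending score (coordinate tie-break) and claim, per
#' replicate, their best-overlapping still-unclaimed match, so each input
#' record supports at most one trusted site. The representative of a group
#' is its highest-scoring member. The score filter (`score_min`) is applied
#' after concordance, matching the curation order of the method.
#'
#' @param replicates A list of interaction tibbles (one per replicate), or a
#'   single tibble whose `replicate_id` column is used to split.
#' @param overlap_threshold Concordance overlap fraction in (0, 1].
#' @param score_min Trusted-site score cutoff applied to the representative.
#' @return A tibble of class `rri_trusted`: representative record columns
#'   plus `site_id`, `n_support` and a `support` list-column of per-replicate
#'   record ids.
#' @export
curate_trusted <- function(replicates, overlap_threshold = 0.30,
                           score_min = 1.0) {
  if (is.data.frame(replicates)) {
    replicates <- split(replicates, replicates$replicate_id)
  }
  if (length(replicates) == 0) abort("at least one replicate table required")
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  tabs <- unname(replicates)
  ref <- tabs[[1]]
  others <- tabs[-1]

  if (nrow(ref) == 0) {
    trusted_idx <- integer(0)
    groups <- list()
  } else {
    match_tbls <- lapply(others, function(tb)
      pairwise_matches(ref, tb, overlap_threshold))
    ord <- order(-ref$score, ref$chrom1, ref$start1, ref$end1,
                 ref$chrom2, ref$start2, ref$end2)
    used <- lapply(others, function(tb) rep(FALSE, nrow(tb)))
    trusted_idx <- integer(0)
    groups <- list()
    for (i in ord) {
      claim <- integer(length(others))
      ok <- TRUE
      for (k in seq_along(others)) {
        m <- match_tbls[[k]] %>% filter(.data$ia == i, !used[[k]][.data$ib])
        if (nrow(m) == 0) { ok <- FALSE; break }
        tb <- others[[k]]
        pick <- m %>%
          mutate(s = tb$score[.data$ib],
                 c1 = tb$chrom1[.data$ib], p1 = tb$start1[.data$ib]) %>%
          arrange(desc(.data$ovl), .data$c1, .data$p1, .data$ib)
        claim[k] <- pick$ib[1]
      }
      if (!ok) next
      for (k in seq_along(others)) used[[k]][claim[k]] <- TRUE
      trusted_idx <- c(trusted_idx, i)
      groups <- c(groups, list(claim))
    }
  }

  if (length(trusted_idx) == 0) {
    out <- ref[integer(0), ] %>%
      mutate(site_id = character(), n_support = integer(),
             support = list())
  } else {
    rows <- lapply(seq_along(trusted_idx), function(t) {
      i <- trusted_idx[t]
      members <- bind_rows(c(
        list(ref[i, ]),
        lapply(seq_along(others), function(k) others[[k]][groups[[t]][k], ])
      ))
      rep_row <- members %>%
        arrange(desc(.data$score), .data$record_id) %>%
        dplyr::slice(1)
      rep_row$support <- list(members$record_id)
      rep_row$n_support <- nrow(members)
      rep_row
    })
    out <- bind_rows(rows) %>%
      mutate(site_id = site_identifier(.))
  }
  out <- filter_by_score(out, score_min) %>%
    arrange(.data$chrom1, .data$start1, .data$end1,
            .data$chrom2, .data$start2)
  class(out) <- c("rri_trusted", class(out))
  out
}
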