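# Build one window description (sequence, local core range, mask) for an arm.
arm_window <- function(arm_iv, genome, occupied, config, exclude = NULL) {
  cl <- chrom_lengths(genome)
  win <- add_context(arm_iv, config$context_len, cl)
  seq <- extract_sequence(genome, win)
  # local (strand-oriented, 1-based) indices of the original site
  if (win$strand == "-") {
    core <- c(genomic_to_local(win, win$core_end - 1L),
              genomic_to_local(win, win$core_start))
  } else {
    core <- c(genomic_to_local(win, win$core_start),
              genomic_to_local(win, win$core_end - 1L))
  }
  mask <- occupied_mask(occupied, win[, c("chrom", "start", "end", "strand")],
                        exclude = exclude)
  list(window = win, seq = seq, core = core, mask = mask)
}

#' Build positive prediction instances for trusted sites
#'
#' For each trusted site, both arms are extended by the genomic context,
#' occupancy masks are derived from the occupied library (with the site's
#' own arms lifted out of the mask, so replicate copies of the same site
#' cannot mask its core), and up to `n_suboptimals` seed-in-core duplexes
#' are predicted.
#'
#' @param trusted Output of [curate_trusted()] (or any interaction tibble
#'   with a `site_id` column).
#' @param genome Genome (`DNAStringSet` or named character vector).
#' @param occupied An `rri_occupied` library.
#' @param config An [rri_config()].
#' @return Instance tibble of class `rri_instances`: one row per site with
#'   window coordinates, core ranges, sequences, masks (list-columns),
#'   predicted `duplexes` (list-column of `rri_duplexes`), `n_duplexes` and
#'   `polarity = "positive"`. Sites without a valid duplex are retained with
#'   `n_duplexes = 0` (later reported NA).
#' @export
build_positive_instances <- function(trusted, genome, occupied,
                                     config = rri_config()) {
  if (!"site_id" %in% names(trusted)) {
    trusted <- trusted %>% mutate(site_id = site_identifier(trusted))
  }
  rows <- lapply(seq_len(nrow(trusted)), function(r) {
    rec <- trusted[r, ]
    own_arms <- bind_rows(arm_intervals(rec, 1), arm_intervals(rec, 2))
    w1 <- arm_window(arm_intervals(rec, 1), genome, occupied, config,
                     exclude = own_arms)
    w2 <- arm_window(arm_intervals(rec, 2), genome, occupied, config,
                     exclude = own_arms)
    dup <- predict_duplexes(w1$seq, w2$seq, w1$core, w2$core,
                            w1$mask, w2$mask, config, mode = "positive")
    instance_row(rec$site_id, "positive", w1, w2, dup)
  })
  out <- bind_rows(rows)
  class(out) <- c("rri_instances", class(out))
  out
}

instance_row <- function(site_id, polarity, w1, w2, dup) {
  tibble(
    site_id = site_id,
    instance_id = paste0(site_id, ":", substr(polarity, 1, 3)),
    polarity = polarity,
    chrom1 = w1$window$chrom, win1_start = w1$window$start,
    win1_end = w1$window$end, strand1 = w1$window$strand,
    chrom2 = w2$window$chrom, win2_start = w2$window$start,
    win2_end = w2$window$end, strand2 = w2$window$strand,
    core1 = list(w1$core), core2 = list(w2$core),
    seq1 = w1$seq, seq2 = w2$seq,
    mask1 = list(w1$mask), mask2 = list(w2$mask),
    duplexes = list(dup),
    n_duplexes = nrow(dup)
  )
}

#' Construct the negative instance of a positive site
#'
#' The negative uses the same context windows as its positive (negatives are
#' predicted in close proximity to the site) but additionally masks the site
#' cores and every occupied span, then predicts "flanking" duplexes whose
#' pairs lie entirely in the unmasked context — guaranteeing disjointness
#' from all reliable interaction sites.
#'
#' @param positive_instances An `rri_instances` tibble of positive
#'   instances.
#' @param occupied The full `rri_occupied` library (including the sites'
#'   own arms).
#' @param config An [rri_config()].
#' @return Instance tibble (`polarity = "negative"`); instances whose
#'   context is fully masked (no legal pairs) are kept with
#'   `n_duplexes = 0` and flagged by a message.
#' @export
make_negative_instances <- function(positive_instances, occupied,
                                    config = rri_config()) {
  rows <- lapply(seq_len(nrow(positive_instances)), function(r) {
    p <- positive_instances[r, ]
    w1 <- list(window = tibble(chrom = p$chrom1, start = p$win1_start,
                               end = p$win1_end, strand = p$strand1),
               seq = p$seq1, core = p$core1[[1]])
    w2 <- list(window = tibble(chrom = p$chrom2, start = p$win2_start,
                               end = p$win2_end, strand = p$strand2),
               seq = p$seq2, core = p$core2[[1]])
    m1 <- occupied_mask(occupied, w1$window) |
      range_to_logical(nchar(w1$seq), w1$core)
    m2 <- occupied_mask(occupied, w2$window) |
      range_to_logical(nchar(w2$seq), w2$core)
    dup <- predict_duplexes(w1$seq, w2$seq, core1 = NULL, core2 = NULL,
                            m1, m2, config, mode = "negative")
    w1$mask <- m1; w2$mask <- m2
    instance_row(p$site_id, "negative", w1, w2, dup)
  })
  out <- bind_rows(rows)
  dropped <- sum(out$n_duplexes == 0)
  if (dropped > 0) {
    inform(sprintf("%d negative instance(s) have no valid duplex", dropped))
  }
  class(out) <- c("rri_instances", class(out))
  out
}

# map a window-local pair index back to a genomic 0-based position
pairs_to_genomic <- function(instance_row) {
  dup <- instance_row$duplexes[[1]]
  w1 <- tibble(chrom = instance_row$chrom1, start = instance_row$win1_start,
               end = instance_row$win1_end, strand = instance_row$strand1)
  w2 <- tibble(chrom = instance_row$chrom2, start = instance_row$win2_start,
               end = instance_row$win2_end, strand = instance_row$strand2)
  purrr::map(dup$pairs, function(p) {
    tibble(chrom1 = w1$chrom, pos1 = local_to_genomic(w1, p$i),
           chrom2 = w2$chrom, pos2 = local_to_genomic(w2, p$j))
  })
}
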