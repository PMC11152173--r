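# Synthetic interactome fixtures with known ground truth: a random genome
# into which complementary site pairs are planted (site B overwritten with
# the mutated reverse complement of site A), replicate interaction tables
# with boundary jitter and score noise, decoy rows, and energy-matched
# GC-helix decoys in the flanking context so that the energy-only baseline
# is uninformative by construction while real features remain predictive.
#
# The generator also emits a dense background-occupancy track covering the
# genomic context of every planted arm (minus the site itself and the decoy
# islands). Under the additive energy model, unmasked random context admits
# long low-energy chance pairings whose extent simply reads out the
# unmasked window geometry; the occupancy background confines predictions
# to the planted site (positives) and the calibrated decoy helix
# (negatives), which is what makes the per-site energy matching effective.

#' Generate a random genome
#'
#' @param n_chrom Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param length Length of each chromosome (nt).
#' @param gc_bias Probability of G or C at each position.
#' @param seed RNG seed; the same seed reproduces the genome exactly.
#' @return A [Biostrings::DNAStringSet].
#' @export
#' @examples
#' g <- sim_genome(1, 1000, seed = 1)
sim_genome <- function(n_chrom = 2L, length = 100000L, gc_bias = 0.5,
                       seed = 1L) {
  stopifnot(length > 0, gc_bias >= 0, gc_bias <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
         G = gc_bias / 2, T = (1 - gc_bias) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_chrom))))
}

# overwrite interval iv (strand-oriented RNA string) in a character genome
write_oriented <- function(chrseqs, iv, rna) {
  dna <- chartr("U", "T", rna)
  if (iv$strand == "-") {
    dna <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
  }
  s <- chrseqs[[iv$chrom]]
  substr(s, iv$start + 1L, iv$end) <- dna
  chrseqs[[iv$chrom]] <- s
  chrseqs
}

mutate_rna <- function(rna, rate) {
  chars <- strsplit(rna, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (h in hit) {
    chars[h] <- sample(setdiff(c("A", "C", "G", "U"), chars[h]), 1)
  }
  paste(chars, collapse = "")
}

# sample a non-overlapping interval, respecting already reserved spans
reserve_interval <- function(reserved, chroms, lens, width, gap = 10L,
                             within = NULL, max_try = 200L) {
  for (t in seq_len(max_try)) {
    if (is.null(within)) {
      chrom <- sample(chroms, 1)
      start <- sample.int(lens[[chrom]] - width, 1) - 1L
    } else {
      chrom <- within$chrom
      lo <- max(0L, within$lo)
      hi <- min(lens[[chrom]] - width, within$hi)
      if (hi < lo) return(NULL)
      start <- if (hi == lo) lo else sample(lo:hi, 1)
    }
    end <- start + width
    clash <- reserved$chrom == chrom &
      reserved$start < end + gap & reserved$end > start - gap
    if (!any(clash)) {
      return(tibble(chrom = chrom, start = start, end = end))
    }
  }
  NULL
}

#' Plant a synthetic interactome
#'
#' Plants `n_sites` complementary site pairs into a genome: site B's
#' sequence is overwritten with the reverse complement of site A, mutated
#' at `mutation_rate`. Each replicate reports every planted pair with
#' independent uniform boundary jitter and a score drawn from
#' `score_range`, plus `n_decoys` random non-complementary low-score rows.
#' For every planted pair a GC-only decoy helix is additionally written
#' into the flanking context of both arms, its length calibrated from the
#' site's own internally computed duplex energy (`L = round(-E/2)`, the GC
#' pair energy being -2) so that positive and negative instances have
#' matched minimum energies — the construction that makes the energy-only
#' baseline uninformative.
#'
#' @param genome A `DNAStringSet` (e.g. from [sim_genome()]); returned
#'   modified.
#' @param n_sites Number of planted interacting pairs.
#' @param site_len_range Min/max site length (nt).
#' @param mutation_rate Per-base substitution rate applied to the planted
#'   complement.
#' @param n_replicates Number of replicate tables.
#' @param boundary_jitter Maximum absolute per-boundary jitter (nt).
#' @param score_range Planted-pair scores are drawn uniformly from this
#'   range.
#' @param n_decoys Decoy rows per replicate.
#' @param decoy_score_range Decoy scores (kept below the trusted cutoff).
#' @param decoy_helix Write the energy-matched flanking helices?
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param config An [rri_config()] (energy model for the calibration).
#' @return List of class `rri_sim`: `genome` (modified), `replicates`
#'   (named list of interaction tibbles), `truth` (planted coordinates,
#'   decoy helix spans, per-site planted energy and helix length), and
#'   `occluders` (strand-agnostic background-occupancy intervals covering
#'   the planted arms' genomic context minus the sites and decoy islands;
#'   pass as `rbp_intervals` to [build_training_data()]).
#' @export
sim_interactome <- function(genome, n_sites = 150L,
                            site_len_range = c(30L, 60L),
                            mutation_rate = 0.10, n_replicates = 3L,
                            boundary_jitter = 5L, score_range = c(1, 5),
                            n_decoys = 50L, decoy_score_range = c(0, 0.4),
                            decoy_helix = TRUE, seed = 1L,
                            config = rri_config()) {
  set.seed(seed)
  chrseqs <- as.list(setNames(as.character(genome), names(genome)))
  lens <- chrom_lengths(genome)
  chroms <- names(lens)
  decoy_cap <- 50L
  reserved <- tibble(chrom = character(), start = integer(), end = integer())

  placed <- list()
  for (s in seq_len(n_sites)) {
    width <- sample(site_len_range[1]:site_len_range[2], 1)
    armA <- reserve_interval(reserved, chroms, lens, width)
    if (is.null(armA)) abort("sim_interactome: genome too crowded for n_sites")
    reserved <- bind_rows(reserved, armA)
    armB <- reserve_interval(reserved, chroms, lens, width)
    if (is.null(armB)) abort("sim_interactome: genome too crowded for n_sites")
    reserved <- bind_rows(reserved, armB)
    armA$strand <- sample(c("+", "-"), 1)
    armB$strand <- sample(c("+", "-"), 1)
    dA <- dB <- NULL
    if (decoy_helix) {
      side <- sample(c(-1L, 1L), 2, replace = TRUE)
      place_flank <- function(arm, dir) {
        for (t in 1:20) {
          gap <- sample(15:85, 1)
          lo <- if (dir > 0) arm$end + gap else arm$start - gap - decoy_cap
          iv <- reserve_interval(reserved, chroms, lens, decoy_cap,
                                 within = list(chrom = arm$chrom,
                                               lo = lo, hi = lo),
                                 max_try = 1L)
          if (!is.null(iv)) return(iv)
        }
        NULL
      }
      dA <- place_flank(armA, side[1])
      if (!is.null(dA)) reserved <- bind_rows(reserved, dA)
      dB <- place_flank(armB, side[2])
      if (!is.null(dB)) reserved <- bind_rows(reserved, dB)
      if (!is.null(dA)) dA$strand <- armA$strand
      if (!is.null(dB)) dB$strand <- armB$strand
    }
    placed[[s]] <- list(armA = armA, armB = armB, dA = dA, dB = dB,
                        width = width)
  }

  truth_rows <- list()
  for (s in seq_len(n_sites)) {
    p <- placed[[s]]
    seqA <- extract_sequence(chrseqs_to_set(chrseqs), p$armA)
    target <- mutate_rna(revcomp_rna(seqA), mutation_rate)
    n_mut <- sum(strsplit(target, "")[[1]] !=
                   strsplit(revcomp_rna(seqA), "")[[1]])
    chrseqs <- write_oriented(chrseqs, p$armB, target)
    # internal duplex energy of the planted pair (cores only, no context)
    seqB <- extract_sequence(chrseqs_to_set(chrseqs), p$armB)
    dup <- predict_duplexes(seqA, seqB, c(1L, nchar(seqA)),
                            c(1L, nchar(seqB)), config = config,
                            mode = "positive")
    e_planted <- if (nrow(dup) > 0) min(dup$energy) else NA_real_
    helix_len <- NA_integer_
    if (!is.null(p$dA) && !is.null(p$dB) && !is.na(e_planted)) {
      helix_len <- max(config$seed_len + 2L,
                       min(decoy_cap, as.integer(round(-e_planted / 2))))
      helix <- paste(sample(c("G", "C"), helix_len, replace = TRUE),
                     collapse = "")
      ivA <- p$dA; ivA$end <- ivA$start + helix_len
      ivB <- p$dB; ivB$end <- ivB$start + helix_len
      chrseqs <- write_oriented(chrseqs, ivA, helix)
      chrseqs <- write_oriented(chrseqs, ivB, revcomp_rna(helix))
      p$dA <- ivA; p$dB <- ivB
    }
    truth_rows[[s]] <- tibble(
      pair_id = sprintf("site_%04d", s),
      chrom1 = p$armA$chrom, start1 = p$armA$start, end1 = p$armA$end,
      strand1 = p$armA$strand,
      chrom2 = p$armB$chrom, start2 = p$armB$start, end2 = p$armB$end,
      strand2 = p$armB$strand,
      n_mutations = n_mut, e_planted = e_planted,
      helix_len = helix_len,
      decoy1_start = if (is.null(p$dA)) NA_integer_ else p$dA$start,
      decoy1_end = if (is.null(p$dA)) NA_integer_ else p$dA$end,
      decoy2_start = if (is.null(p$dB)) NA_integer_ else p$dB$start,
      decoy2_end = if (is.null(p$dB)) NA_integer_ else p$dB$end
    )
  }
  truth <- bind_rows(truth_rows)

  jitter1 <- function(x, lo, hi) {
    pmin(hi, pmax(lo, x + sample(-boundary_jitter:boundary_jitter,
                                 length(x), replace = TRUE)))
  }
  replicates <- setNames(vector("list", n_replicates),
                         paste0("rep", seq_len(n_replicates)))
  for (r in seq_len(n_replicates)) {
    s1 <- jitter1(truth$start1, 0L, truth$end1 - 6L)
    e1 <- jitter1(truth$end1, s1 + 5L, lens[truth$chrom1])
    s2 <- jitter1(truth$start2, 0L, truth$end2 - 6L)
    e2 <- jitter1(truth$end2, s2 + 5L, lens[truth$chrom2])
    planted <- tibble(
      record_id = sprintf("rep%d_%05d", r, seq_len(n_sites)),
      replicate_id = paste0("rep", r),
      chrom1 = truth$chrom1, start1 = as.integer(s1), end1 = as.integer(e1),
      strand1 = truth$strand1,
      chrom2 = truth$chrom2, start2 = as.integer(s2), end2 = as.integer(e2),
      strand2 = truth$strand2,
      score = round(runif(n_sites, score_range[1], score_range[2]), 3)
    )
    decoys <- NULL
    if (n_decoys > 0) {
      dw <- sample(site_len_range[1]:site_len_range[2], n_decoys,
                   replace = TRUE)
      dc1 <- sample(chroms, n_decoys, replace = TRUE)
      dp1 <- vapply(seq_len(n_decoys),
                    function(i) sample.int(lens[[dc1[i]]] - dw[i], 1) - 1L,
                    integer(1))
      dc2 <- sample(chroms, n_decoys, replace = TRUE)
      dp2 <- vapply(seq_len(n_decoys),
                    function(i) sample.int(lens[[dc2[i]]] - dw[i], 1) - 1L,
                    integer(1))
      decoys <- tibble(
        record_id = sprintf("rep%d_d%04d", r, seq_len(n_decoys)),
        replicate_id = paste0("rep", r),
        chrom1 = dc1, start1 = dp1, end1 = dp1 + dw, strand1 = sample(
          c("+", "-"), n_decoys, replace = TRUE),
        chrom2 = dc2, start2 = dp2, end2 = dp2 + dw, strand2 = sample(
          c("+", "-"), n_decoys, replace = TRUE),
        score = round(runif(n_decoys, decoy_score_range[1],
                            decoy_score_range[2]), 3)
      )
    }
    replicates[[r]] <- bind_rows(planted, decoys)
  }

  occluders <- background_occupancy(truth, reserved, lens,
                                    config$context_len + 10L, margin = 6L)
  structure(list(genome = chrseqs_to_set(chrseqs), replicates = replicates,
                 truth = truth, occluders = occluders, seed = seed),
            class = "rri_sim")
}

chrseqs_to_set <- function(chrseqs) {
  Biostrings::DNAStringSet(unlist(chrseqs))
}

# strand-agnostic occupancy covering [arm - reach, arm + reach] of every
# planted arm, minus every reserved span (arms and decoy islands) widened by
# `margin`, so only the sites themselves and the decoy helices stay open
background_occupancy <- function(truth, reserved, lens, reach, margin = 6L) {
  arms <- bind_rows(
    tibble(chrom = truth$chrom1, start = truth$start1, end = truth$end1),
    tibble(chrom = truth$chrom2, start = truth$start2, end = truth$end2)
  )
  out <- purrr::map(unique(arms$chrom), function(ch) {
    a <- arms %>% filter(.data$chrom == ch)
    r <- reserved %>% filter(.data$chrom == ch)
    win <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, a$start - reach + 1L),
      end = pmin(lens[[ch]], a$end + reach)))
    res <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, r$start - margin + 1L), end = r$end + margin))
    keep <- IRanges::setdiff(win, res)
    tibble(chrom = ch, start = IRanges::start(keep) - 1L,
           end = IRanges::end(keep), strand = "*",
           name = "background")
  }) %>% bind_rows()
  out %>% arrange(.data$chrom, .data$start)
}

#' Generate random RBP binding intervals
#'
#' @param genome A `DNAStringSet`.
#' @param n_sites Number of intervals.
#' @param len_range Min/max interval width (width 1 emulates crosslink
#'   positions; widen with [extend_crosslinks()]).
#' @param seed RNG seed.
#' @return Interval tibble with a `name` column, BED-ready.
#' @export
sim_rbp_bed <- function(genome, n_sites = 20L, len_range = c(1L, 1L),
                        seed = 1L) {
  set.seed(seed)
  lens <- chrom_lengths(genome)
  if (n_sites == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character()))
  }
  w <- sample(len_range[1]:len_range[2], n_sites, replace = TRUE)
  chrom <- sample(names(lens), n_sites, replace = TRUE)
  start <- vapply(seq_len(n_sites),
                  function(i) sample.int(lens[[chrom[i]]] - w[i], 1) - 1L,
                  integer(1))
  tibble(chrom = chrom, start = start, end = start + w,
         strand = sample(c("+", "-"), n_sites, replace = TRUE),
         name = sprintf("rbp_%04d", seq_len(n_sites)))
}
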