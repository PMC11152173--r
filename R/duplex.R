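RNA_CODE <- c(A = 0L, C = 1L, G = 2L, U = 3L)

encode_rna <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  codes <- RNA_CODE[chars]
  codes[is.na(codes)] <- -1L
  unname(codes)
}

# legal antiparallel pair? (codes)
pair_type <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return("GC")
  if ((a == "A" && b == "U") || (a == "U" && b == "A")) return("AU")
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return("GU")
  NA_character_
}

range_to_logical <- function(n, rng) {
  v <- rep(FALSE, n)
  if (!is.null(rng) && length(rng) == 2 && rng[1] <= rng[2]) {
    v[rng[1]:rng[2]] <- TRUE
  }
  v
}

#' Enumerate seed candidates
#'
#' Finds every run of `seed_len` consecutive legal antiparallel base pairs
#' whose positions lie entirely inside the two site cores and are unmasked —
#' the anchors that a predicted duplex must contain.
#'
#' @param seq1,seq2 RNA sequences (5'->3').
#' @param core1,core2 Length-2 integer vectors: 1-based inclusive local
#'   index range of the original site within each sequence.
#' @param mask1,mask2 Logical occupancy masks (TRUE = unavailable), or NULL.
#' @param seed_len Required seed length in base pairs.
#' @return Tibble of seed start pairs `(i, j)` (the first pair of the run:
#'   pairs are `(i+t, j-t)` for `t = 0 .. seed_len-1`), ordered by `i` then
#'   `j`.
#' @export
#' @examples
#' find_seeds("GGGGG", "CCCCC", c(1, 5), c(1, 5))
find_seeds <- function(seq1, seq2, core1, core2, mask1 = NULL, mask2 = NULL,
                       seed_len = 5L) {
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  if (is.null(mask1)) mask1 <- rep(FALSE, n1)
  if (is.null(mask2)) mask2 <- rep(FALSE, n2)
  q1 <- range_to_logical(n1, core1) & !mask1
  q2 <- range_to_logical(n2, core2) & !mask2
  c1 <- strsplit(seq1, "")[[1]]; c2 <- strsplit(seq2, "")[[1]]
  legal <- outer(c1, c2, Vectorize(function(a, b) !is.na(pair_type(a, b))))
  ok <- legal & outer(q1, q2, `&`)
  out_i <- integer(0); out_j <- integer(0)
  if (n1 >= seed_len && n2 >= seed_len) {
    for (i in 1:(n1 - seed_len + 1L)) {
      for (j in seq_len(n2)[seq_len(n2) >= seed_len]) {
        hit <- TRUE
        for (t in 0:(seed_len - 1L)) {
          if (!ok[i + t, j - t]) { hit <- FALSE; break }
        }
        if (hit) { out_i <- c(out_i, i); out_j <- c(out_j, j) }
      }
    }
  }
  tibble(i = out_i, j = out_j) %>% arrange(.data$i, .data$j)
}

#' Duplex energy
#'
#' Additive energy of an ordered antiparallel pair chain: the sum of pair
#' energies (GC, AU, GU) plus `loop_penalty` for every unpaired nucleotide
#' enclosed between consecutive pairs on either side. Pure recomputation of
#' the score the dynamic program optimizes.
#'
#' @param pairs Tibble or matrix of 1-based local index pairs `(i, j)`, `i`
#'   ascending, `j` descending.
#' @param seq1,seq2 RNA sequences.
#' @param config An [rri_config()] (pair energies, loop penalty).
#' @return Energy (numeric scalar).
#' @export
duplex_energy <- function(pairs, seq1, seq2, config = rri_config()) {
  pairs <- as.data.frame(pairs)
  c1 <- strsplit(seq1, "")[[1]]; c2 <- strsplit(seq2, "")[[1]]
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    ty <- pair_type(c1[pairs[r, 1]], c2[pairs[r, 2]])
    if (is.na(ty)) {
      abort(sprintf("illegal base pair %s-%s at (%d,%d)",
                    c1[pairs[r, 1]], c2[pairs[r, 2]],
                    pairs[r, 1], pairs[r, 2]))
    }
    e <- e + config$pair_energies[[ty]]
    if (r > 1) {
      gap1 <- pairs[r, 1] - pairs[r - 1, 1] - 1L
      gap2 <- pairs[r - 1, 2] - pairs[r, 2] - 1L
      e <- e + config$loop_penalty * (gap1 + gap2)
    }
  }
  e
}

# maximal run of stacked qualifying pairs; returns c(start_pair_idx, len) or NULL
seed_span <- function(pairs, q1, q2, seed_len) {
  n <- nrow(pairs)
  best <- NULL
  run_start <- 0L; run_len <- 0L
  for (r in seq_len(n)) {
    qual <- q1[pairs$i[r]] && q2[pairs$j[r]]
    stacked <- r > 1 && pairs$i[r] == pairs$i[r - 1] + 1L &&
      pairs$j[r] == pairs$j[r - 1] - 1L
    if (qual && (run_len == 0L || !stacked)) {
      run_start <- r; run_len <- 1L
    } else if (qual && stacked) {
      run_len <- run_len + 1L
    } else {
      run_len <- 0L
    }
    if (run_len >= seed_len &&
        (is.null(best) || run_len > best[2])) {
      best <- c(run_start, run_len)
    }
  }
  best
}

#' Predict constrained suboptimal duplexes
#'
#' Seed-anchored, occupancy-masked intermolecular duplex prediction between
#' two windows: a dynamic program over pair states returns up to
#' `n_suboptimals` energetically best duplexes, each containing at least one
#' seed of `seed_len` consecutive base pairs inside the qualifying region
#' (the site cores for positive instances; the unmasked context for
#' negative instances). Duplexes may stretch beyond the cores into context
#' but never across masked positions; results are deterministic under the
#' fixed tie-breaking (energy, then the first pair's indices).
#'
#' @param seq1,seq2 RNA window sequences (5'->3').
#' @param core1,core2 1-based inclusive local core ranges, or NULL (used
#'   only when `mode = "positive"`).
#' @param mask1,mask2 Logical occupancy masks, or NULL for none.
#' @param config An [rri_config()].
#' @param mode `"positive"` (seed must lie within the cores) or
#'   `"negative"` (seed anywhere unmasked; the caller is expected to have
#'   masked the cores).
#' @return Tibble of class `rri_duplexes`: one row per duplex with `rank`,
#'   `energy`, `n_pairs`, `seed_start`, `seed_len` (position/length of the
#'   maximal qualifying run, in pair indices) and a `pairs` list-column of
#'   `(i, j)` tibbles. Zero rows when no valid duplex exists.
#' @export
predict_duplexes <- function(seq1, seq2, core1 = NULL, core2 = NULL,
                             mask1 = NULL, mask2 = NULL,
                             config = rri_config(),
                             mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  empty <- tibble(rank = integer(), energy = double(), n_pairs = integer(),
                  seed_start = integer(), seed_len = integer(),
                  pairs = list())
  class(empty) <- c("rri_duplexes", class(empty))
  if (n1 == 0 || n2 == 0) return(empty)
  if (is.null(mask1)) mask1 <- rep(FALSE, n1)
  if (is.null(mask2)) mask2 <- rep(FALSE, n2)
  if (mode == "positive") {
    q1 <- range_to_logical(n1, core1) & !mask1
    q2 <- range_to_logical(n2, core2) & !mask2
  } else {
    q1 <- !mask1
    q2 <- !mask2
  }
  res <- duplex_dp_cpp(encode_rna(seq1), encode_rna(seq2), mask1, mask2,
                       q1, q2, config$seed_len, config$max_loop,
                       config$loop_penalty,
                       config$pair_energies[["GC"]],
                       config$pair_energies[["AU"]],
                       config$pair_energies[["GU"]],
                       config$n_suboptimals)
  if (length(res) == 0) return(empty)
  rows <- purrr::map2(res, seq_along(res), function(d, r) {
    p <- tibble(i = d$pairs[, 1] + 1L, j = d$pairs[, 2] + 1L)
    sp <- seed_span(p, q1, q2, config$seed_len)
    tibble(rank = r, energy = d$energy, n_pairs = nrow(p),
           seed_start = sp[1], seed_len = sp[2], pairs = list(p))
  })
  out <- bind_rows(rows)
  class(out) <- c("rri_duplexes", class(out))
  out
}

#' Adapter for an external duplex predictor
#'
#' Runs a user-supplied hybridization tool in place of the internal dynamic
#' program and maps its output onto the same duplex representation, so
#' downstream feature extraction is unchanged. The command template receives
#' the two window sequences, the seed length and the suboptimal count via
#' [sprintf()]-style placeholders `{seq1} {seq2} {seed_len} {n}` and must
#' print CSV with columns `start1,end1,start2,end2,hybridDP,E` (1-based
#' inclusive window-local coordinates; `hybridDP` a dot-bracket hybrid
#' string with `&` separating the sides). Parsed duplexes are re-validated
#' against the instance's cores and masks; offending predictions are
#' dropped with a warning.
#'
#' @inheritParams predict_duplexes
#' @param command Command template string; the tool must write CSV to
#'   stdout.
#' @return An `rri_duplexes` tibble, as from [predict_duplexes()].
#' @export
external_predictor_adapter <- function(command, seq1, seq2,
                                       core1 = NULL, core2 = NULL,
                                       mask1 = NULL, mask2 = NULL,
                                       config = rri_config(),
                                       mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  if (is.null(mask1)) mask1 <- rep(FALSE, n1)
  if (is.null(mask2)) mask2 <- rep(FALSE, n2)
  cmd <- command
  cmd <- gsub("{seq1}", seq1, cmd, fixed = TRUE)
  cmd <- gsub("{seq2}", seq2, cmd, fixed = TRUE)
  cmd <- gsub("{seed_len}", config$seed_len, cmd, fixed = TRUE)
  cmd <- gsub("{n}", config$n_suboptimals, cmd, fixed = TRUE)
  out <- tryCatch(system(cmd, intern = TRUE),
                  warning = function(w) abort(paste("external predictor failed:", cmd)),
                  error = function(e) abort(paste("external predictor failed:", cmd)))
  tab <- tryCatch(
    readr::read_csv(I(paste(out, collapse = "\n")),
                    col_types = readr::cols(), progress = FALSE),
    error = function(e) abort("external predictor output is not parseable CSV"))
  need <- c("start1", "end1", "start2", "end2", "hybridDP", "E")
  if (!all(need %in% names(tab))) {
    abort(paste("external predictor output lacks column:",
                setdiff(need, names(tab))[1]))
  }
  if (mode == "positive") {
    q1 <- range_to_logical(n1, core1) & !mask1
    q2 <- range_to_logical(n2, core2) & !mask2
  } else {
    q1 <- !mask1; q2 <- !mask2
  }
  rows <- list()
  for (r in seq_len(nrow(tab))) {
    p <- hybrid_dp_to_pairs(tab$hybridDP[r], tab$start1[r], tab$end2[r])
    valid <- !is.null(p) && nrow(p) > 0 &&
      all(p$i >= 1 & p$i <= n1 & p$j >= 1 & p$j <= n2) &&
      !any(mask1[p$i]) && !any(mask2[p$j]) &&
      !is.null(seed_span(p, q1, q2, config$seed_len))
    if (!valid) {
      warn(sprintf("external prediction %d rejected (seed/mask constraint)", r))
      next
    }
    rows <- c(rows, list(tibble(
      rank = NA_integer_, energy = tab$E[r], n_pairs = nrow(p),
      seed_start = seed_span(p, q1, q2, config$seed_len)[1],
      seed_len = seed_span(p, q1, q2, config$seed_len)[2],
      pairs = list(p))))
  }
  if (length(rows) == 0) {
    out <- predict_duplexes(seq1, seq2, core1, core2, mask1, mask2,
                            config, mode)[0, ]
    return(out)
  }
  res <- bind_rows(rows) %>%
    arrange(.data$energy) %>%
    head(config$n_suboptimals) %>%
    mutate(rank = row_number())
  class(res) <- c("rri_duplexes", class(res))
  res
}

# dot-bracket hybrid ("(((...(((&)))...)))") to pair list; side 1 starts at
# start1, side 2's paired region ends at end2 (both 1-based inclusive)
hybrid_dp_to_pairs <- function(dp, start1, end2) {
  halves <- strsplit(dp, "&", fixed = TRUE)[[1]]
  if (length(halves) != 2) return(NULL)
  a <- strsplit(halves[1], "")[[1]]
  b <- strsplit(halves[2], "")[[1]]
  ia <- which(a == "(") + start1 - 1L
  jb <- which(b == ")")
  if (length(ia) != length(jb)) return(NULL)
  # side 2 runs 5'->3'; the k-th '(' pairs with the k-th ')' counted from the end
  j_positions <- (end2 - length(b) + 1L) + jb - 1L
  tibble(i = ia, j = rev(j_positions))
}
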