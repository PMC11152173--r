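# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation: plain loops and direct arithmetic.

# --- exhaustive duplex enumeration ------------------------------------------
# Enumerates every legal antiparallel pair chain (i ascending, j descending,
# per-side gaps <= max_loop, no masked position) containing at least one run
# of >= seed_len stacked pairs at qualifying positions, and returns their
# energies sorted ascending.
oracle_enumerate_energies <- function(seq1, seq2, q1, q2, mask1, mask2,
                                      seed_len, max_loop, loop_penalty,
                                      pair_e) {
  c1 <- strsplit(seq1, "")[[1]]
  c2 <- strsplit(seq2, "")[[1]]
  n1 <- length(c1); n2 <- length(c2)
  pe <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) return(pair_e[["GC"]])
    if (key %in% c("AU", "UA")) return(pair_e[["AU"]])
    if (key %in% c("GU", "UG")) return(pair_e[["GU"]])
    NA_real_
  }
  legal <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (!mask1[i] && !mask2[j]) legal[i, j] <- pe(c1[i], c2[j])
  }
  has_seed <- function(ci, cj) {
    run <- 0L
    for (t in seq_along(ci)) {
      qual <- q1[ci[t]] && q2[cj[t]]
      stack <- t > 1 && ci[t] == ci[t - 1] + 1L && cj[t] == cj[t - 1] - 1L
      if (qual && (t == 1 || !stack || run == 0L)) run <- 1L
      else if (qual) run <- run + 1L
      else run <- 0L
      if (run >= seed_len) return(TRUE)
    }
    FALSE
  }
  energies <- c()
  recurse <- function(ci, cj, e) {
    if (has_seed(ci, cj)) energies[[length(energies) + 1L]] <<- e
    i <- ci[length(ci)]; j <- cj[length(cj)]
    for (di in 1:(max_loop + 1L)) {
      for (dj in 1:(max_loop + 1L)) {
        i2 <- i + di; j2 <- j - dj
        if (i2 > n1 || j2 < 1) next
        if (is.na(legal[i2, j2])) next
        recurse(c(ci, i2), c(cj, j2),
                e + legal[i2, j2] + loop_penalty * ((di - 1) + (dj - 1)))
      }
    }
  }
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (!is.na(legal[i, j])) recurse(i, j, legal[i, j])
  }
  sort(as.numeric(unlist(energies)))
}

oracle_random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# --- brute-force replicate-concordance curation -----------------------------
# Direct loop implementation of the documented greedy-with-consumption
# semantics on plain data frames.
oracle_curate_ids <- function(tables, thr, score_min) {
  ovl1 <- function(c1, s1, e1, t1, c2, s2, e2, t2) {
    if (c1 != c2 || t1 != t2) return(0)
    inter <- min(e1, e2) - max(s1, s2)
    if (inter <= 0) return(0)
    inter / min(e1 - s1, e2 - s2)
  }
  pair_ovl <- function(a, b) {
    straight <- min(
      ovl1(a$chrom1, a$start1, a$end1, a$strand1,
           b$chrom1, b$start1, b$end1, b$strand1),
      ovl1(a$chrom2, a$start2, a$end2, a$strand2,
           b$chrom2, b$start2, b$end2, b$strand2))
    swapped <- min(
      ovl1(a$chrom1, a$start1, a$end1, a$strand1,
           b$chrom2, b$start2, b$end2, b$strand2),
      ovl1(a$chrom2, a$start2, a$end2, a$strand2,
           b$chrom1, b$start1, b$end1, b$strand1))
    max(straight, swapped)
  }
  ref <- as.data.frame(tables[[1]])
  others <- lapply(tables[-1], as.data.frame)
  ord <- order(-ref$score, ref$chrom1, ref$start1, ref$end1,
               ref$chrom2, ref$start2, ref$end2)
  used <- lapply(others, function(tb) rep(FALSE, nrow(tb)))
  kept <- character(0)
  best_score <- numeric(0)
  for (i in ord) {
    claims <- integer(length(others))
    ok <- TRUE
    for (k in seq_along(others)) {
      tb <- others[[k]]
      cand <- data.frame(ib = integer(0), ovl = numeric(0))
      for (b in seq_len(nrow(tb))) {
        if (used[[k]][b]) next
        o <- pair_ovl(ref[i, ], tb[b, ])
        if (o >= thr) cand <- rbind(cand, data.frame(ib = b, ovl = o))
      }
      if (nrow(cand) == 0) { ok <- FALSE; break }
      cand <- cand[order(-cand$ovl, tb$chrom1[cand$ib], tb$start1[cand$ib],
                         cand$ib), ]
      claims[k] <- cand$ib[1]
    }
    if (!ok) next
    for (k in seq_along(others)) used[[k]][claims[k]] <- TRUE
    scores <- c(ref$score[i],
                vapply(seq_along(others),
                       function(k) others[[k]]$score[claims[k]], numeric(1)))
    if (max(scores) >= score_min) {
      kept <- c(kept, ref$record_id[i])
      best_score <- c(best_score, max(scores))
    }
  }
  kept
}

# --- shared small fixtures ---------------------------------------------------
# built once per test run; moderate size keeps the suite fast
fixture_env <- new.env()

small_fixture <- function() {
  if (is.null(fixture_env$small)) {
    g <- sim_genome(2, 30000, seed = 401)
    sim <- sim_interactome(g, n_sites = 25, n_decoys = 10, seed = 401)
    cfg <- rri_config(rng_seed = 401)
    td <- build_training_data(sim$replicates, sim$genome, cfg,
                              rbp_intervals = sim$occluders)
    fixture_env$small <- list(sim = sim, cfg = cfg, td = td)
  }
  fixture_env$small
}

# a second, differently seeded "organism" for merge/external-validation tests
small_fixture_b <- function() {
  if (is.null(fixture_env$small_b)) {
    g <- sim_genome(2, 30000, gc_bias = 0.45, seed = 402)
    sim <- sim_interactome(g, n_sites = 20, n_decoys = 10, seed = 402)
    cfg <- rri_config(rng_seed = 401)
    td <- build_training_data(sim$replicates, sim$genome, cfg,
                              rbp_intervals = sim$occluders)
    fixture_env$small_b <- list(sim = sim, cfg = cfg, td = td)
  }
  fixture_env$small_b
}

tiny_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

# the full-scale study fixture: 2 chromosomes x 100 kb, 150 planted pairs,
# 3 replicates, 10% mutation, 5-nt boundary jitter, energy-matched decoys
default_fixture <- function() {
  if (is.null(fixture_env$default)) {
    g <- sim_genome(2, 100000, seed = 101)
    sim <- sim_interactome(g, seed = 101)
    cfg <- rri_config(rng_seed = 101)
    td <- build_training_data(sim$replicates, sim$genome, cfg,
                              rbp_intervals = sim$occluders)
    fixture_env$default <- list(sim = sim, cfg = cfg, td = td)
  }
  fixture_env$default
}

# independent per-feature recomputation of the hand-crafted block
oracle_handcrafted <- function(row, cfg) {
  dup <- row$duplexes[[1]]
  e <- dup$energy
  b <- as.data.frame(dup$pairs[[which.min(e)]])
  ch1 <- strsplit(row$seq1, "")[[1]]
  ch2 <- strsplit(row$seq2, "")[[1]]
  npair <- nrow(b)
  ngc <- nau <- ngu <- 0
  for (t in seq_len(npair)) {
    two <- paste0(ch1[b$i[t]], ch2[b$j[t]])
    if (two %in% c("GC", "CG")) ngc <- ngc + 1
    else if (two %in% c("AU", "UA")) nau <- nau + 1
    else ngu <- ngu + 1
  }
  unp <- 0
  longest <- 1
  run <- 1
  if (npair > 1) {
    for (t in 2:npair) {
      unp <- unp + (b$i[t] - b$i[t - 1] - 1) + (b$j[t - 1] - b$j[t] - 1)
      if (b$i[t] == b$i[t - 1] + 1 && b$j[t] == b$j[t - 1] - 1) {
        run <- run + 1
      } else {
        run <- 1
      }
      longest <- max(longest, run)
    }
  }
  len1 <- max(b$i) - min(b$i) + 1
  len2 <- max(b$j) - min(b$j) + 1
  ent <- function(s, k) {
    n <- nchar(s)
    km <- substring(s, 1:(n - k + 1), k:n)
    p <- table(km) / length(km)
    -sum(p * log2(p))
  }
  sub1 <- paste(ch1[min(b$i):max(b$i)], collapse = "")
  sub2 <- paste(ch2[min(b$j):max(b$j)], collapse = "")
  core1 <- row$core1[[1]]; core2 <- row$core2[[1]]
  cs1 <- paste(ch1[core1[1]:core1[2]], collapse = "")
  cs2 <- paste(ch2[core2[1]:core2[2]], collapse = "")
  gcf <- function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  ntf <- function(s, n) mean(strsplit(s, "")[[1]] == n)
  c(e_min = min(e), e_mean = mean(e), n_duplexes = nrow(dup),
    n_pairs = npair, len1 = len1, len2 = len2, len_sum = len1 + len2,
    n_gc = ngc, n_au = nau, n_gu = ngu, n_unpaired = unp,
    max_stack = longest,
    e_per_len = min(e) / (len1 + len2),
    e_per_gc = if (ngc > 0) min(e) / ngc else 0,
    no_gc = as.numeric(ngc == 0),
    e_per_pair = min(e) / npair,
    s1_gc = gcf(sub1), s1_frac_a = ntf(sub1, "A"),
    s1_frac_c = ntf(sub1, "C"), s1_frac_g = ntf(sub1, "G"),
    s1_frac_u = ntf(sub1, "U"), s1_comp1 = ent(sub1, 1),
    s1_comp2 = if (nchar(sub1) >= 2) ent(sub1, 2) else 0,
    s2_gc = gcf(sub2), s2_frac_a = ntf(sub2, "A"),
    s2_frac_c = ntf(sub2, "C"), s2_frac_g = ntf(sub2, "G"),
    s2_frac_u = ntf(sub2, "U"), s2_comp1 = ent(sub2, 1),
    s2_comp2 = if (nchar(sub2) >= 2) ent(sub2, 2) else 0,
    core1_gc = gcf(cs1), core1_comp1 = ent(cs1, 1),
    core1_comp2 = if (nchar(cs1) >= 2) ent(cs1, 2) else 0,
    core1_len = nchar(cs1),
    core2_gc = gcf(cs2), core2_comp1 = ent(cs2, 1),
    core2_comp2 = if (nchar(cs2) >= 2) ent(cs2, 2) else 0,
    core2_len = nchar(cs2))
}
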