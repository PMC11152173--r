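test_that("composition and complexity features match direct arithmetic", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content("GAUC"), 0.5)
  expect_error(gc_content(""), "empty")

  expect_equal(sequence_complexity("AAAA", 1), 0)
  expect_equal(sequence_complexity("ACGU", 1), 2)
  # k-mer tally oracle: "ACACAC" k=2 -> {AC:3, CA:2}
  expect_equal(sequence_complexity("ACACAC", 2),
               -(3 / 5 * log2(3 / 5) + 2 / 5 * log2(2 / 5)),
               tolerance = 1e-12)
  expect_error(sequence_complexity("AC", 3), "shorter than k")
})

test_that("hand-crafted features are forced by the scoring on a known duplex", {
  cfg <- rri_config()
  g <- tiny_genome(c(chr1 = paste0(strrep("A", 20), strrep("G", 5),
                                   strrep("A", 20), strrep("C", 5),
                                   strrep("A", 20))))
  sites <- tibble::tibble(
    record_id = "s1", replicate_id = "r", chrom1 = "chr1", start1 = 20L,
    end1 = 25L, strand1 = "+", chrom2 = "chr1", start2 = 45L, end2 = 50L,
    strand2 = "+", score = 2)
  cfg_small <- rri_config(context_len = 5L)
  inst <- build_eval_instances(sites, g, config = cfg_small)
  expect_equal(inst$n_duplexes, 1)
  fv <- handcrafted_features(inst[1, ], cfg_small)
  expect_equal(unname(fv["e_min"]), -10)
  expect_equal(unname(fv["n_pairs"]), 5)
  expect_equal(unname(fv["n_gc"]), 5)
  expect_equal(unname(fv["e_per_len"]), -1)
  expect_equal(unname(fv["e_per_gc"]), -2)
  expect_equal(unname(fv["no_gc"]), 0)
  expect_equal(unname(fv["max_stack"]), 5)
  expect_equal(unname(fv["n_unpaired"]), 0)
  expect_equal(unname(fv["s1_gc"]), 1)
  expect_equal(unname(fv["core1_len"]), 5)
})

test_that("hand-crafted features equal an independent recomputation", {
  fx <- small_fixture()
  inst <- fx$td$instances
  inst <- inst[inst$n_duplexes > 0, ]
  n <- 0
  for (r in seq_len(nrow(inst))) {
    row <- inst[r, ]
    fv <- handcrafted_features(row, fx$cfg)
    dup <- row$duplexes[[1]]
    # independent recomputation with plain loops
    e <- dup$energy
    b <- dup$pairs[[which.min(e)]]
    ch1 <- strsplit(row$seq1, "")[[1]]
    ch2 <- strsplit(row$seq2, "")[[1]]
    npair <- nrow(b)
    ngc <- 0; nau <- 0; ngu <- 0
    for (t in seq_len(npair)) {
      two <- paste0(ch1[b$i[t]], ch2[b$j[t]])
      if (two %in% c("GC", "CG")) ngc <- ngc + 1
      else if (two %in% c("AU", "UA")) nau <- nau + 1
      else ngu <- ngu + 1
    }
    unp <- 0
    if (npair > 1) {
      for (t in 2:npair) {
        unp <- unp + (b$i[t] - b$i[t - 1] - 1) + (b$j[t - 1] - b$j[t] - 1)
      }
    }
    sub1 <- paste(ch1[min(b$i):max(b$i)], collapse = "")
    expect_equal(unname(fv["e_min"]), min(e))
    expect_equal(unname(fv["e_mean"]), mean(e))
    expect_equal(unname(fv["n_duplexes"]), nrow(dup))
    expect_equal(unname(fv["n_pairs"]), npair)
    expect_equal(unname(fv["n_gc"]), ngc)
    expect_equal(unname(fv["n_au"]), nau)
    expect_equal(unname(fv["n_gu"]), ngu)
    expect_equal(unname(fv["n_unpaired"]), unp)
    expect_equal(unname(fv["len1"]), max(b$i) - min(b$i) + 1)
    expect_equal(unname(fv["e_per_pair"]), min(e) / npair)
    expect_equal(unname(fv["s1_gc"]),
                 sum(strsplit(sub1, "")[[1]] %in% c("G", "C")) / nchar(sub1))
    expect_true(all(is.finite(fv)))
    n <- n + 1
  }
  expect_gte(n, 40)
})

test_that("interaction graphs have the forced node and edge structure", {
  cfg <- rri_config(context_len = 5L)
  g <- tiny_genome(c(chr1 = paste0(strrep("A", 20), "GGG",
                                   strrep("A", 20), "CCC",
                                   strrep("A", 20))))
  sites <- tibble::tibble(
    record_id = "s1", replicate_id = "r", chrom1 = "chr1", start1 = 20L,
    end1 = 23L, strand1 = "+", chrom2 = "chr1", start2 = 43L, end2 = 46L,
    strand2 = "+", score = 2)
  cfg3 <- rri_config(context_len = 5L, seed_len = 3L)
  inst <- build_eval_instances(sites, g, config = cfg3)
  gr <- build_interaction_graph(inst[1, ])
  expect_equal(nrow(gr$nodes), 6)
  expect_equal(sum(gr$edges$label == "b"), 4)
  expect_equal(sum(gr$edges$label == "p"), 3)

  # duplicate duplexes do not duplicate edges
  inst2 <- inst
  dup <- inst2$duplexes[[1]]
  inst2$duplexes[[1]] <- dplyr::bind_rows(dup, dup)
  gr2 <- build_interaction_graph(inst2[1, ])
  expect_equal(dplyr::arrange(gr2$edges, from, to, label),
               dplyr::arrange(gr$edges, from, to, label))
})

test_that("multi-duplex graphs take the union of pair edges", {
  fx <- small_fixture()
  inst <- fx$td$instances
  inst <- inst[inst$n_duplexes > 1, ]
  row <- inst[1, ]
  gr <- build_interaction_graph(row)
  # set-union oracle over all suboptimal pair sets
  allp <- unique(do.call(rbind, lapply(row$duplexes[[1]]$pairs, as.matrix)))
  expect_equal(sum(gr$edges$label == "p"), nrow(allp))
})

test_that("graph-kernel vectors are normalized, invariant and deterministic", {
  # single isolated node, radius 0, distance 0 -> one unit feature
  g1 <- list(nodes = tibble::tibble(node = 1L, label = "A", side = 1L,
                                    pos = 1L),
             edges = tibble::tibble(from = integer(), to = integer(),
                                    label = character()))
  v1 <- nspdk_features(g1, radius = 0, distance = 0, hash_bits = 16)
  expect_equal(nrow(v1), 1)
  expect_equal(v1$value, 1)

  # path graph A-C-G: permuting node ids leaves the vector unchanged
  g_path <- list(
    nodes = tibble::tibble(node = 1:3, label = c("A", "C", "G"),
                           side = 1L, pos = 1:3),
    edges = tibble::tibble(from = c(1L, 2L), to = c(2L, 3L),
                           label = c("b", "b")))
  g_perm <- list(
    nodes = tibble::tibble(node = 1:3, label = c("G", "C", "A"),
                           side = 1L, pos = 1:3),
    edges = tibble::tibble(from = c(3L, 2L), to = c(2L, 1L),
                           label = c("b", "b")))
  va <- nspdk_features(g_path, 1, 2, 16)
  vb <- nspdk_features(g_perm, 1, 2, 16)
  expect_equal(va, vb)
  expect_equal(sum(va$value^2), 1, tolerance = 1e-12)

  # determinism across calls
  expect_identical(nspdk_features(g_path, 2, 4, 16),
                   nspdk_features(g_path, 2, 4, 16))
})

test_that("nspdk bucket counts match explicit tuple enumeration on a path", {
  g_path <- list(
    nodes = tibble::tibble(node = 1:3, label = c("A", "C", "G"),
                           side = 1L, pos = 1:3),
    edges = tibble::tibble(from = c(1L, 2L), to = c(2L, 3L),
                           label = c("b", "b")))
  v <- nspdk_features(g_path, radius = 1, distance = 2, hash_bits = 20)
  # hand enumeration: unordered (u,v) pairs with d <= 2 in a 3-node path are
  # (1,1),(2,2),(3,3),(1,2),(2,3),(1,3) = 6, each counted at radii {0,1},
  # giving 12 tuples in total (modulo bucket collisions)
  expect_equal(sum(v$value^2), 1, tolerance = 1e-12)
  # recover raw integer counts from the normalized vector: with all node
  # labels distinct every bucket holds a small integer count whose unit is
  # the smallest nonzero value
  unit <- min(v$value)
  counts <- round(v$value / unit)
  expect_equal(sum(counts), 12L)
  expect_equal(v$value, counts / sqrt(sum(counts^2)), tolerance = 1e-9)
})

test_that("feature tables are stable, finite, and flag NA instances", {
  fx <- small_fixture()
  f1 <- build_feature_table(fx$td$instances, fx$cfg)
  f2 <- build_feature_table(fx$td$instances, fx$cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_identical(attr(f1, "graph_matrix"), attr(f2, "graph_matrix"))
  dense <- as.matrix(f1[, rriclass:::dense_feature_names(f1)])
  expect_true(all(is.finite(dense)))
  expect_equal(ncol(attr(f1, "graph_matrix")), 2^fx$cfg$hash_bits)
  expect_equal(sort(c(f1$instance_id, attr(f1, "na_instances"))),
               sort(fx$td$instances$instance_id))
  # graph rows are unit vectors
  norms <- sqrt(Matrix::rowSums(attr(f1, "graph_matrix")^2))
  expect_true(all(abs(norms - 1) < 1e-9))
})
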