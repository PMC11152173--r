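test_that("seed enumeration is exhaustive over forced cases", {
  s <- find_seeds("GGGGG", "CCCCC", c(1, 5), c(1, 5), seed_len = 5)
  expect_equal(nrow(s), 1)
  expect_equal(c(s$i, s$j), c(1L, 5L))

  expect_equal(nrow(find_seeds("GGGGG", "AAAAA", c(1, 5), c(1, 5),
                               seed_len = 5)), 0)

  s4 <- find_seeds("GGGGGG", "CCCCCC", c(1, 6), c(1, 6), seed_len = 5)
  expect_equal(nrow(s4), 4)
  expect_equal(s4$i, c(1L, 1L, 2L, 2L))
  expect_equal(s4$j, c(5L, 6L, 5L, 6L))

  # masking one core position removes the seeds that use it
  m1 <- rep(FALSE, 5)
  m1[3] <- TRUE
  expect_equal(nrow(find_seeds("GGGGG", "CCCCC", c(1, 5), c(1, 5),
                               mask1 = m1, seed_len = 5)), 0)
})

test_that("duplex energy is the stated additive score", {
  cfg <- rri_config()
  expect_equal(duplex_energy(tibble::tibble(i = 1:5, j = 5:1),
                             "GGGGG", "CCCCC", cfg), -10)
  expect_equal(duplex_energy(tibble::tibble(i = 1:3, j = 3:1),
                             "GAG", "CUC", cfg), -5)
  expect_equal(duplex_energy(tibble::tibble(i = c(1L, 3L), j = c(2L, 1L)),
                             "GAG", "CC", cfg), -3.5)
  expect_error(duplex_energy(tibble::tibble(i = 1L, j = 1L), "A", "C", cfg),
               "illegal base pair")
})

test_that("prediction is seed-anchored, mask-respecting, energy-ranked", {
  cfg <- rri_config()
  top <- predict_duplexes("AAGGGGGAA", "AACCCCCAA", c(3, 7), c(3, 7),
                          config = cfg)
  expect_equal(nrow(top) > 0, TRUE)
  expect_equal(top$energy[1], -10)
  expect_equal(top$n_pairs[1], 5)
  expect_equal(top$pairs[[1]]$i, 3:7)
  expect_equal(top$pairs[[1]]$j, 7:3)
  expect_true(all(diff(top$energy) >= 0))

  m <- rep(FALSE, 9)
  m[3:7] <- TRUE
  none <- predict_duplexes("AAGGGGGAA", "AACCCCCAA", c(3, 7), c(3, 7),
                           mask1 = m, config = cfg)
  expect_equal(nrow(none), 0)
})

test_that("the DP equals exhaustive enumeration on small random instances", {
  set.seed(101)
  cfg <- rri_config(seed_len = 3L, max_loop = 2L, n_suboptimals = 5L)
  n_nonempty <- 0
  for (case in 1:50) {
    n1 <- sample(7:12, 1)
    n2 <- sample(7:12, 1)
    s1 <- oracle_random_seq(n1)
    s2 <- oracle_random_seq(n2)
    m1 <- runif(n1) < 0.15
    m2 <- runif(n2) < 0.15
    q1 <- !m1
    q2 <- !m2
    dp <- predict_duplexes(s1, s2, c(1, n1), c(1, n2), m1, m2, cfg,
                           mode = "positive")
    all_e <- oracle_enumerate_energies(
      s1, s2, q1, q2, m1, m2, cfg$seed_len, cfg$max_loop,
      cfg$loop_penalty, cfg$pair_energies)
    topk <- utils::head(all_e, cfg$n_suboptimals)
    expect_equal(dp$energy, topk, tolerance = 1e-9)
    if (length(topk) > 0) n_nonempty <- n_nonempty + 1
  }
  expect_gt(n_nonempty, 15)
})

test_that("every emitted duplex re-validates its structural invariants", {
  fx <- small_fixture()
  cfg <- fx$cfg
  inst <- fx$td$instances
  n_checked <- 0
  for (r in seq_len(nrow(inst))) {
    row <- inst[r, ]
    dup <- row$duplexes[[1]]
    if (nrow(dup) == 0) next
    q1 <- if (row$polarity == "positive") {
      rriclass:::range_to_logical(nchar(row$seq1), row$core1[[1]]) &
        !row$mask1[[1]]
    } else !row$mask1[[1]]
    q2 <- if (row$polarity == "positive") {
      rriclass:::range_to_logical(nchar(row$seq2), row$core2[[1]]) &
        !row$mask2[[1]]
    } else !row$mask2[[1]]
    for (d in seq_len(nrow(dup))) {
      p <- dup$pairs[[d]]
      # antiparallel and loop-limited
      expect_true(all(diff(p$i) >= 1) && all(diff(p$i) <= cfg$max_loop + 1))
      expect_true(all(diff(p$j) <= -1) && all(diff(p$j) >= -cfg$max_loop - 1))
      # no masked position pairs
      expect_false(any(row$mask1[[1]][p$i]))
      expect_false(any(row$mask2[[1]][p$j]))
      # energy recomputes exactly
      expect_equal(duplex_energy(p, row$seq1, row$seq2, cfg), dup$energy[d],
                   tolerance = 1e-9)
      # a qualifying seed exists (in-core for positives, context for negatives)
      sp <- rriclass:::seed_span(p, q1, q2, cfg$seed_len)
      expect_false(is.null(sp))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("adding occupied positions never improves the best energy", {
  set.seed(202)
  cfg <- rri_config(seed_len = 3L)
  for (case in 1:20) {
    n <- 20
    s1 <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                collapse = "")
    base <- predict_duplexes(s1, s2, c(1, n), c(1, n), config = cfg)
    m1 <- runif(n) < 0.25
    masked <- predict_duplexes(s1, s2, c(1, n), c(1, n), mask1 = m1,
                               config = cfg)
    if (nrow(base) == 0) {
      expect_equal(nrow(masked), 0)
    } else if (nrow(masked) > 0) {
      expect_gte(masked$energy[1], base$energy[1] - 1e-9)
    }
  }
})

test_that("the external-predictor adapter parses, validates and falls back", {
  cfg <- rri_config(seed_len = 3L)
  # mock tool emitting one fixed 3-pair duplex on GGG/CCC cores
  mock <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "echo 'start1,end1,start2,end2,hybridDP,E'",
               "echo '3,5,3,5,(((&))),-6.0'"), mock)
  Sys.chmod(mock, "0755")
  res <- external_predictor_adapter(mock, "AAGGGAA", "AACCCAA",
                                    c(3, 5), c(3, 5), config = cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$energy, -6.0)
  expect_equal(res$pairs[[1]]$i, 3:5)
  expect_equal(res$pairs[[1]]$j, 5:3)

  # duplex whose seed misses the core is rejected with a warning
  expect_warning(
    out <- external_predictor_adapter(mock, "GGGAAAA", "CCCAAAA",
                                      c(5, 7), c(5, 7), config = cfg),
    "rejected")
  expect_equal(nrow(out), 0)

  expect_error(
    external_predictor_adapter("/nonexistent/tool_xyz", "GGG", "CCC",
                               c(1, 3), c(1, 3), config = cfg))
})
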