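# toy labeled feature table: two informative columns among noise, one
# instance per site (groups are trivial singletons)
toy_features <- function(n = 60, seed = 5, informative = TRUE) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  tb <- tibble::tibble(
    instance_id = sprintf("i%03d", 1:n),
    site_id = sprintf("s%03d", 1:n),
    label = y,
    f_sig1 = if (informative) y + rnorm(n, sd = 0.05) else rnorm(n),
    f_sig2 = if (informative) -y + rnorm(n, sd = 0.05) else rnorm(n),
    f_n1 = rnorm(n), f_n2 = rnorm(n), f_n3 = rnorm(n), f_n4 = rnorm(n)
  )
  attr(tb, "fingerprint") <- "toy"
  class(tb) <- c("rri_features", class(tb))
  tb
}

test_that("importance pruning drops constants, keeps signal, honors cutoff 0", {
  set.seed(9)
  n <- 80
  y <- rep(c(0, 1), n / 2)
  x <- cbind(
    signal = y + rnorm(n, sd = 0.05),
    constant = rep(1, n),
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  kept <- prune_features(x, y, importance_cutoff = 1e-4, rng_seed = 4)
  expect_true("signal" %in% kept)
  expect_false("constant" %in% kept)

  expect_equal(prune_features(x, y, importance_cutoff = 0, rng_seed = 4),
               colnames(x))
  expect_error(prune_features(x, rep(1, n), 1e-4, 4), "both classes")
})

test_that("training on separable features reaches perfect CV F1", {
  tb <- toy_features(60)
  cfg <- rri_config(rng_seed = 5, search_iters = 4L)
  m <- train_rri_model(tb, cfg, use_graph = FALSE)
  expect_s3_class(m, "rri_model")
  expect_equal(nrow(m$cv_report), cfg$cv_folds)
  expect_equal(mean(m$cv_report$f1), 1.0)
  expect_true(m$family %in% c("xgb", "ranger"))
  expect_true(all(c("f_sig1", "f_sig2") %in% m$feature_names))
})

test_that("permuted labels give chance-level cross-validated F1", {
  f1s <- vapply(1:3, function(s) {
    tb <- toy_features(80, seed = 100 + s, informative = FALSE)
    cv <- cross_validate(tb, rri_config(rng_seed = s), family = "xgb",
                         use_graph = FALSE)
    cv$f1_mean
  }, numeric(1))
  expect_lt(mean(f1s), 0.75)
  expect_gt(mean(f1s), 0.2)
})

test_that("training is deterministic and degenerate inputs error", {
  tb <- toy_features(40)
  cfg <- rri_config(rng_seed = 7, search_iters = 3L)
  m1 <- train_rri_model(tb, cfg, use_graph = FALSE)
  m2 <- train_rri_model(tb, cfg, use_graph = FALSE)
  expect_identical(m1$cv_report, m2$cv_report)
  expect_identical(m1$feature_names, m2$feature_names)
  expect_identical(m1$search, m2$search)

  bad <- tb
  bad$label <- 1
  expect_error(train_rri_model(bad, cfg), "both classes")
  expect_error(train_rri_model(tb[1:6, ], cfg), "at least")
})

test_that("site-grouped stratified folds balance classes within one instance", {
  fx <- small_fixture()
  f <- fx$td$features
  folds <- rriclass:::grouped_folds(f$site_id, f$label, 5, 11)
  for (k in 1:5) {
    in_fold <- folds == k
    expect_lte(abs(sum(f$label[in_fold] == 1) - sum(f$label[in_fold] == 0)),
               1)
    # grouping: a site never spans folds
    expect_true(all(tapply(folds, f$site_id, function(v)
      length(unique(v))) == 1))
  }
})

test_that("merging feature tables intersects columns and concatenates rows", {
  a <- toy_features(20, seed = 1)
  b <- toy_features(20, seed = 2)
  m <- merge_feature_tables(list(A = a, B = b))
  expect_equal(nrow(m), 40)
  expect_equal(sort(unique(m$source)), c("A", "B"))
  expect_setequal(rriclass:::dense_feature_names(m),
                  setdiff(names(a), c("instance_id", "site_id", "label")))

  b2 <- b
  b2$f_extra <- 1
  b2$f_n4 <- NULL
  m2 <- merge_feature_tables(list(a, b2))
  expect_setequal(
    setdiff(rriclass:::dense_feature_names(m2), "source"),
    intersect(setdiff(names(a), c("instance_id", "site_id", "label")),
              setdiff(names(b2), c("instance_id", "site_id", "label"))))

  c_none <- a
  names(c_none)[4:9] <- paste0("other_", 1:6)
  expect_error(merge_feature_tables(list(a, c_none)), "no common")
  expect_error(merge_feature_tables(list(a)), ">= 2 tables")
})

test_that("graph-block merges require identical hash sizes", {
  fx <- small_fixture()
  f <- fx$td$features
  half1 <- f[1:10, ]
  half2 <- f[11:20, ]
  attr(half1, "graph_matrix") <- attr(f, "graph_matrix")[1:10, ]
  attr(half1, "hash_bits") <- attr(f, "hash_bits")
  attr(half1, "fingerprint") <- attr(f, "fingerprint")
  attr(half2, "graph_matrix") <- attr(f, "graph_matrix")[11:20, ]
  attr(half2, "hash_bits") <- attr(f, "hash_bits")
  attr(half2, "fingerprint") <- attr(f, "fingerprint")
  merged <- merge_feature_tables(list(x = half1, y = half2))
  expect_equal(nrow(attr(merged, "graph_matrix")), 20)

  attr(half2, "hash_bits") <- 12L
  expect_error(merge_feature_tables(list(x = half1, y = half2)),
               "hash_bits mismatch")
})

test_that("evaluation reproduces in-memory predictions after save/load", {
  fx <- small_fixture()
  cfg <- rri_config(rng_seed = 401, search_iters = 3L)
  m <- train_rri_model(fx$td$features, cfg)
  preds <- evaluate_sites(m, fx$td$features)
  expect_equal(nrow(preds), nrow(fx$td$features) +
                 length(attr(fx$td$features, "na_instances")))

  path <- withr::local_tempfile(fileext = ".tar")
  save_rri_model(m, path)
  m2 <- load_rri_model(path)
  preds2 <- evaluate_sites(m2, fx$td$features)
  expect_identical(preds, preds2)
  expect_equal(m2$feature_names, m$feature_names)

  # fingerprint guard
  other <- fx$td$features
  attr(other, "fingerprint") <- "0000000000000000"
  expect_error(evaluate_sites(m, other), "fingerprint")
  expect_no_error(evaluate_sites(m, other, force = TRUE))
})

test_that("eval mode labels planted holdout sites and emits NA rows", {
  fx <- small_fixture()
  cfg <- rri_config(rng_seed = 401, search_iters = 3L)
  m <- train_rri_model(fx$td$features, cfg)

  # planted truth sites as putative candidates
  sites <- fx$sim$truth %>%
    dplyr::transmute(record_id = pair_id, replicate_id = "eval",
                     chrom1, start1, end1, strand1,
                     chrom2, start2, end2, strand2, score = 1)
  preds <- classify_sites(m, sites, fx$sim$genome,
                          occupied = fx$td$occupied)
  called <- preds$predicted_label[!is.na(preds$predicted_label)]
  expect_gte(mean(called == 1), 0.9)

  # a pairing-free site cannot be classified -> NA row
  g <- tiny_genome(c(chrA = strrep("A", 800)))
  na_site <- tibble::tibble(
    record_id = "na1", replicate_id = "eval", chrom1 = "chrA",
    start1 = 200L, end1 = 240L, strand1 = "+", chrom2 = "chrA",
    start2 = 500L, end2 = 540L, strand2 = "+", score = 1)
  na_pred <- classify_sites(m, na_site, g)
  expect_equal(nrow(na_pred), 1)
  expect_true(is.na(na_pred$predicted_label))
  expect_match(na_pred$site_id, "chrA:201-240")
})
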