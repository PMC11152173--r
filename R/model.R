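# Assemble the model matrix (dense block + observed graph columns) as a
# dgCMatrix. With `feature_names` given (evaluation), columns are aligned to
# that exact name set and order.
assemble_matrix <- function(features, use_graph = TRUE,
                            feature_names = NULL) {
  dense_names <- dense_feature_names(features)
  dense <- as.matrix(features[, dense_names, drop = FALSE])
  rownames(dense) <- features$instance_id
  gm <- if (use_graph) attr(features, "graph_matrix") else NULL
  if (is.null(feature_names)) {
    if (!is.null(gm)) {
      observed <- Matrix::colSums(gm != 0) > 0
      x <- cbind(Matrix::Matrix(dense, sparse = TRUE),
                 gm[, observed, drop = FALSE])
    } else {
      x <- Matrix::Matrix(dense, sparse = TRUE)
    }
  } else {
    have_dense <- intersect(feature_names, colnames(dense))
    need_graph <- setdiff(feature_names, colnames(dense))
    parts <- list()
    if (length(have_dense) > 0) {
      parts$dense <- Matrix::Matrix(dense[, have_dense, drop = FALSE],
                                    sparse = TRUE)
    }
    if (length(need_graph) > 0) {
      if (is.null(gm)) {
        abort("feature table lacks the graph block this model requires")
      }
      missing <- setdiff(need_graph, colnames(gm))
      if (length(missing) > 0) {
        abort(paste("feature table lacks model features:",
                    paste(head(missing, 5), collapse = ", ")))
      }
      parts$graph <- gm[, need_graph, drop = FALSE]
    }
    x <- do.call(cbind, unname(parts))
    x <- x[, feature_names, drop = FALSE]
  }
  x
}

#' Drop uninformative features by forest importance
#'
#' Fits a random forest with a fixed seed and retains the features whose
#' impurity importance reaches `importance_cutoff`; at least one feature
#' (the most important) is always kept. This is the cheap pre-filter run
#' before hyperparameter search.
#'
#' @param x Numeric matrix or `dgCMatrix` with column names.
#' @param y Binary labels (0/1) with both classes present.
#' @param importance_cutoff Minimum importance score.
#' @param rng_seed Seed for the forest.
#' @param num_trees Forest size.
#' @return Character vector of retained feature names (input order).
#' @export
prune_features <- function(x, y, importance_cutoff = 1e-4, rng_seed = 1L,
                           num_trees = 500L) {
  if (length(unique(y)) < 2) abort("prune_features: both classes required")
  xd <- as.matrix(x)
  fit <- ranger::ranger(
    x = xd, y = factor(y, levels = c(0, 1)),
    num.trees = num_trees, importance = "impurity",
    seed = rng_seed, num.threads = 1L
  )
  imp <- fit$variable.importance
  keep <- names(imp)[imp >= importance_cutoff]
  if (length(keep) == 0) keep <- names(imp)[which.max(imp)]
  colnames(xd)[colnames(xd) %in% keep]
}

# grouped stratified fold assignment: groups (e.g. sites) stay together,
# folds balanced on each group's positive fraction
grouped_folds <- function(groups, labels, k, rng_seed) {
  info <- tibble(group = groups, label = labels) %>%
    group_by(.data$group) %>%
    summarise(frac_pos = mean(.data$label), size = n(), .groups = "drop")
  set.seed(rng_seed)
  info <- info[sample.int(nrow(info)), ] %>%
    arrange(desc(.data$frac_pos))
  idx <- seq_len(nrow(info))
  fold_of_group <- ((idx - 1L) %% k) + 1L
  # snake order to balance sizes
  block <- ((idx - 1L) %/% k) %% 2L == 1L
  fold_of_group[block] <- k + 1L - fold_of_group[block]
  info$fold <- fold_of_group
  folds <- info$fold[match(groups, info$group)]
  if (length(unique(folds)) < k) {
    abort("grouped_folds: not enough groups to fill all folds")
  }
  folds
}

default_params <- list(
  xgb = list(nrounds = 150L, eta = 0.1, max_depth = 4L,
             min_child_weight = 1, subsample = 1, colsample_bytree = 1),
  ranger = list(num.trees = 500L, mtry_frac = 0.3, min.node.size = 1L)
)

draw_params <- function(family) {
  if (family == "xgb") {
    list(nrounds = sample(50:300, 1), eta = runif(1, 0.03, 0.3),
         max_depth = sample(2:8, 1), min_child_weight = sample(1:10, 1),
         subsample = runif(1, 0.6, 1), colsample_bytree = runif(1, 0.5, 1))
  } else {
    list(num.trees = sample(200:800, 1), mtry_frac = runif(1, 0.1, 0.9),
         min.node.size = sample(1:10, 1))
  }
}

fit_classifier <- function(family, params, x, y, class_weight, rng_seed) {
  if (family == "xgb") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    spw <- if (class_weight) sum(y == 0) / max(1, sum(y == 1)) else 1
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", tree_method = "hist",
                    eta = params$eta, max_depth = params$max_depth,
                    min_child_weight = params$min_child_weight,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    scale_pos_weight = spw, nthread = 1,
                    seed = rng_seed),
      data = dtrain, nrounds = params$nrounds, verbose = 0
    )
    list(family = "xgb", fit = booster)
  } else {
    xd <- as.matrix(x)
    mtry <- max(1L, floor(params$mtry_frac * ncol(xd)))
    cw <- if (class_weight) {
      n <- length(y)
      c(n / (2 * max(1, sum(y == 0))), n / (2 * max(1, sum(y == 1))))
    } else c(1, 1)
    fit <- ranger::ranger(
      x = xd, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num.trees, mtry = mtry,
      min.node.size = params$min.node.size, class.weights = cw,
      seed = rng_seed, num.threads = 1L
    )
    list(family = "ranger", fit = fit)
  }
}

predict_prob <- function(classifier, x) {
  if (classifier$family == "xgb") {
    as.numeric(predict(classifier$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  } else {
    as.numeric(predict(classifier$fit, data = as.matrix(x),
                       num.threads = 1L)$predictions[, "1"])
  }
}

cv_metrics_for <- function(family, params, x, y, folds, class_weight,
                           rng_seed) {
  k <- max(folds)
  purrr::map(seq_len(k), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
      abort("cross-validation fold without both classes")
    }
    cls <- fit_classifier(family, params, x[tr, , drop = FALSE], y[tr],
                          class_weight, rng_seed + f)
    prob <- predict_prob(cls, x[!tr, , drop = FALSE])
    pred <- as.integer(prob >= 0.5)
    yt <- y[!tr]
    pr <- pr_curve(yt, prob)
    tibble(fold = f, f1 = f1_score(yt, pred),
           precision = precision_score(yt, pred),
           recall = recall_score(yt, pred),
           aucpr = pr$auc, n_test = sum(!tr))
  }) %>% bind_rows()
}

#' Train an RRI site classifier
#'
#' Full model selection on a feature table: forest-importance pruning, then
#' bounded randomized hyperparameter search over the two tree-ensemble
#' families (histogram gradient boosting and random forest), scored by mean
#' site-grouped stratified cross-validated F1, followed by a final refit on
#' all data. Deterministic under the config seed.
#'
#' @param features An `rri_features` table with a binary `label` column.
#' @param config An [rri_config()] (`cv_folds`, `search_iters`,
#'   `importance_cutoff`, `rng_seed`).
#' @param use_graph Include the graph-kernel feature block?
#' @param class_weight Weight classes inversely to frequency (interactome
#'   training sets are usually imbalanced)?
#' @param families Candidate classifier families.
#' @return An object of class `rri_model`: the fitted classifier, retained
#'   feature names, pruning record, per-fold CV report of the winning
#'   configuration, config fingerprint and training-set identity.
#' @export
train_rri_model <- function(features, config = rri_config(),
                            use_graph = TRUE, class_weight = TRUE,
                            families = c("xgb", "ranger")) {
  y <- features$label
  if (any(is.na(y))) abort("train_rri_model: unlabeled rows in features")
  if (length(unique(y)) < 2) abort("train_rri_model: both classes required")
  if (length(y) < 2 * config$cv_folds) {
    abort(sprintf("train_rri_model: need at least %d instances",
                  2 * config$cv_folds))
  }
  x_all <- assemble_matrix(features, use_graph)
  set.seed(config$rng_seed)
  retained <- prune_features(x_all, y, config$importance_cutoff,
                             config$rng_seed)
  x <- x_all[, retained, drop = FALSE]
  folds <- grouped_folds(features$site_id, y, config$cv_folds,
                         config$rng_seed)

  set.seed(config$rng_seed + 1L)
  draws <- purrr::map(seq_len(config$search_iters), function(i) {
    family <- sample(families, 1)
    c(list(family = family), draw_params(family))
  })
  search <- purrr::map(seq_along(draws), function(i) {
    d <- draws[[i]]
    cv <- cv_metrics_for(d$family, d, x, y, folds, class_weight,
                         config$rng_seed)
    tibble(iter = i, family = d$family, mean_f1 = mean(cv$f1),
           params = list(d), cv = list(cv))
  }) %>% bind_rows()
  best <- search %>%
    arrange(desc(.data$mean_f1), .data$iter) %>%
    dplyr::slice(1)
  final <- fit_classifier(best$family, best$params[[1]], x, y, class_weight,
                          config$rng_seed)
  structure(list(
    classifier = final,
    family = best$family,
    params = best$params[[1]][setdiff(names(best$params[[1]]), "family")],
    feature_names = retained,
    pruned = setdiff(colnames(x_all), retained),
    n_candidate_features = ncol(x_all),
    cv_report = best$cv[[1]],
    search = search %>% select(all_of(c("iter", "family", "mean_f1"))),
    use_graph = use_graph,
    class_weight = class_weight,
    fingerprint = attr(features, "fingerprint"),
    hash_bits = attr(features, "hash_bits"),
    training_set = list(n = length(y), n_pos = sum(y == 1),
                        n_neg = sum(y == 0),
                        sources = if ("source" %in% names(features))
                          unique(features$source) else "training"),
    config = config
  ), class = "rri_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rri_model <- function(x, ...) {
  cat("<rri_model>", x$family, "|", length(x$feature_names), "features |",
      sprintf("CV F1 %.3f +/- %.3f\n", mean(x$cv_report$f1),
              sd(x$cv_report$f1)))
  invisible(x)
}

#' Merge feature tables into a mixed training set
#'
#' Joins feature tables from different data sources (e.g. organisms) for
#' mixed-model training: rows are concatenated, dense columns are reduced
#' to the intersection of the tables' column names (canonical order = first
#' table), graph blocks are concatenated when their hash sizes agree, and a
#' `source` provenance column is added.
#'
#' @param tables Named list of >= 2 `rri_features` tables.
#' @return A combined `rri_features` table.
#' @export
merge_feature_tables <- function(tables) {
  if (length(tables) < 2) abort("merge_feature_tables: need >= 2 tables")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("set", seq_along(tables))
  }
  dense_sets <- purrr::map(tables, dense_feature_names)
  common <- Reduce(intersect, dense_sets)
  if (length(common) == 0) abort("merge_feature_tables: no common features")
  bits <- purrr::map(tables, ~ attr(.x, "hash_bits"))
  has_graph <- !purrr::map_lgl(bits, is.null)
  if (any(has_graph) && !all(has_graph)) {
    abort("merge_feature_tables: graph block present in only some tables")
  }
  if (all(has_graph) && length(unique(unlist(bits))) > 1) {
    abort("merge_feature_tables: hash_bits mismatch between graph blocks")
  }
  out <- purrr::imap(tables, function(tb, nm) {
    as_tibble(tb)[, c(intersect(feature_meta_cols, names(tb)), common)] %>%
      mutate(source = nm)
  }) %>% bind_rows()
  if (all(has_graph)) {
    attr(out, "graph_matrix") <- do.call(
      rbind, purrr::map(tables, ~ attr(.x, "graph_matrix")))
    attr(out, "hash_bits") <- bits[[1]]
  }
  attr(out, "fingerprint") <- hash64_cpp(paste(
    purrr::map_chr(tables, ~ attr(.x, "fingerprint") %||% ""),
    collapse = "+"))
  attr(out, "na_instances") <-
    unlist(purrr::map(tables, ~ attr(.x, "na_instances")), use.names = FALSE)
  class(out) <- c("rri_features", class(out))
  out
}

#' Label candidate sites with a trained model
#'
#' @param model An `rri_model`.
#' @param features An `rri_features` table built for the candidate sites
#'   (label column may be NA). Its fingerprint and feature names must match
#'   the model unless `force = TRUE`.
#' @param force Skip the fingerprint/feature-name compatibility check.
#' @return Tibble with one row per input site: the positions-based site
#'   identifier (1-based inclusive), `predicted_label` (0/1, NA for sites
#'   without a valid duplex) and `prob_relevant`.
#' @export
evaluate_sites <- function(model, features, force = FALSE) {
  stopifnot(inherits(model, "rri_model"))
  if (!force) {
    if (!identical(attr(features, "fingerprint"), model$fingerprint)) {
      abort("feature table fingerprint does not match the model (use force = TRUE to override)")
    }
    if (nrow(features) > 0) {
      avail <- c(dense_feature_names(features),
                 colnames(attr(features, "graph_matrix")) %||% character(0))
      missing <- setdiff(model$feature_names, avail)
      if (length(missing) > 0) {
        abort(paste("features missing for this model:",
                    paste(head(missing, 5), collapse = ", ")))
      }
    }
  }
  if (nrow(features) > 0) {
    x <- assemble_matrix(features, model$use_graph,
                         feature_names = model$feature_names)
    prob <- predict_prob(model$classifier, x)
    scored <- tibble(site_id = features$site_id,
                     instance_id = features$instance_id,
                     predicted_label = as.integer(prob >= 0.5),
                     prob_relevant = prob)
  } else {
    scored <- tibble(site_id = character(), instance_id = character(),
                     predicted_label = integer(), prob_relevant = double())
  }
  na_ids <- attr(features, "na_instances") %||% character(0)
  if (length(na_ids) > 0) {
    scored <- bind_rows(scored, tibble(
      site_id = sub(":(pos|neg|eva)$", "", na_ids), instance_id = na_ids,
      predicted_label = NA_integer_, prob_relevant = NA_real_))
  }
  scored
}

#' Persist a trained model
#'
#' Writes a single archive holding the serialized classifier and a JSON
#' metadata sidecar (feature names, config fingerprint, CV report,
#' training-set identity).
#'
#' @param model An `rri_model`.
#' @param path Output archive (tar) path.
#' @export
save_rri_model <- function(model, path) {
  tmp <- tempfile("rrimodel")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  obj <- model
  if (model$family == "xgb") {
    obj$classifier$fit <- xgboost::xgb.save.raw(model$classifier$fit)
    obj$classifier$serialized <- "xgb_raw"
  }
  saveRDS(obj, file.path(tmp, "classifier.rds"), version = 2)
  meta <- list(
    family = model$family,
    params = model$params,
    feature_names = model$feature_names,
    fingerprint = model$fingerprint,
    cv_report = model$cv_report,
    training_set = model$training_set
  )
  jsonlite::write_json(meta, file.path(tmp, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                   basename(path))
  old <- setwd(tmp)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(out, files = c("classifier.rds", "metadata.json"),
             tar = "internal")
  invisible(path)
}

#' Load a persisted model
#' @param path Archive written by [save_rri_model()].
#' @return The restored `rri_model`.
#' @export
load_rri_model <- function(path) {
  tmp <- tempfile("rrimodel")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  utils::untar(normalizePath(path), exdir = tmp, tar = "internal")
  obj <- readRDS(file.path(tmp, "classifier.rds"))
  if (identical(obj$classifier$serialized, "xgb_raw")) {
    obj$classifier$fit <- xgboost::xgb.load.raw(obj$classifier$fit)
    obj$classifier$serialized <- NULL
  }
  obj
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model: per-fold cross-validation report
#' @param x An `rri_model`.
#' @param ... Unused.
#' @return Tibble with one row per CV fold of the winning configuration.
#' @export
tidy.rri_model <- function(x, ...) {
  x$cv_report
}

#' One-row model summary
#' @param x An `rri_model`.
#' @param ... Unused.
#' @return Tibble: family, feature counts, mean/sd CV F1, mean AUC-PR,
#'   training-set size.
#' @export
glance.rri_model <- function(x, ...) {
  tibble(
    family = x$family,
    n_features = length(x$feature_names),
    n_candidate_features = x$n_candidate_features,
    cv_f1_mean = mean(x$cv_report$f1),
    cv_f1_sd = sd(x$cv_report$f1),
    cv_aucpr_mean = mean(x$cv_report$aucpr),
    n_train = x$training_set$n,
    n_pos = x$training_set$n_pos,
    n_neg = x$training_set$n_neg
  )
}
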