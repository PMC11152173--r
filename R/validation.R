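#' F1 score of binary predictions
#'
#' Harmonic mean of precision and recall on the positive class; defined as
#' 0 when precision + recall is 0.
#'
#' @param labels,predictions Equal-length binary (0/1) vectors.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    abort("f1_score: length mismatch")
  }
  p <- precision_score(labels, predictions)
  r <- recall_score(labels, predictions)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @rdname f1_score
#' @export
precision_score <- function(labels, predictions) {
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  if (tp + fp == 0) return(0)
  tp / (tp + fp)
}

#' @rdname f1_score
#' @export
recall_score <- function(labels, predictions) {
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  if (tp + fn == 0) return(0)
  tp / (tp + fn)
}

#' Precision-recall curve and AUC-PR
#'
#' Thresholds at every distinct score, descending, with tied scores grouped
#' at a single threshold; the area is the step-wise (right-continuous)
#' integral, which avoids the optimism of linear interpolation in PR space.
#' The chance baseline is the positive-class prevalence.
#'
#' @param labels Binary (0/1) labels, both classes present.
#' @param scores Real-valued scores, higher = more positive.
#' @return Object of class `rri_pr`: list with `points` (tibble
#'   `threshold`, `recall`, `precision`), `auc`, and `baseline`.
#' @export
#' @examples
#' pr <- pr_curve(c(1, 1, 0, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
#' pr$auc
pr_curve <- function(labels, scores) {
  if (length(labels) != length(scores)) abort("pr_curve: length mismatch")
  if (length(unique(labels)) < 2) {
    abort("pr_curve: both classes required")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  npos <- sum(lab == 1)
  cum_tp <- cumsum(lab == 1)
  cum_pp <- seq_along(lab)
  # group ties: keep the last index of each distinct score
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  pts <- tibble(
    threshold = sc[keep],
    recall = cum_tp[keep] / npos,
    precision = cum_tp[keep] / cum_pp[keep]
  )
  auc <- sum(diff(c(0, pts$recall)) * pts$precision)
  structure(list(points = pts, auc = auc,
                 baseline = npos / length(lab)),
            class = "rri_pr")
}

#' @export
print.rri_pr <- function(x, ...) {
  cat(sprintf("<rri_pr> %d points | AUC-PR %.4f | baseline %.4f\n",
              nrow(x$points), x$auc, x$baseline))
  invisible(x)
}

#' Plot a precision-recall curve
#' @param object An `rri_pr` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rri_pr <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  subtitle = sprintf("AUC-PR %.3f (baseline %.3f)",
                                     object$auc, object$baseline)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Energy-only baseline scores
#'
#' The thermodynamic strawman: each instance is scored by the negated
#' minimum duplex energy, so more stable sites rank higher. Instances with
#' no duplex are excluded and reported in attribute `na_instances`.
#'
#' @param instances An `rri_instances` tibble (or a feature table with an
#'   `e_min` column).
#' @return Tibble `instance_id`, `score`.
#' @export
energy_baseline_scores <- function(instances) {
  if ("e_min" %in% names(instances)) {
    out <- tibble(instance_id = instances$instance_id,
                  score = -instances$e_min)
    attr(out, "na_instances") <- attr(instances, "na_instances") %||%
      character(0)
    return(out)
  }
  has <- instances$n_duplexes > 0
  out <- tibble(
    instance_id = instances$instance_id[has],
    score = vapply(instances$duplexes[has],
                   function(d) -min(d$energy), double(1))
  )
  attr(out, "na_instances") <- instances$instance_id[!has]
  out
}

#' Cross-validate a classifier configuration
#'
#' Site-grouped stratified k-fold cross-validation: all instances derived
#' from one site share a fold (no leakage between a site's positive and
#' negative instance), folds are balanced on class, and the fold split is
#' fixed by the config seed. Reports per-fold F1, precision, recall and
#' AUC-PR with mean and sd.
#'
#' @param features An `rri_features` table with binary labels.
#' @param config An [rri_config()].
#' @param family `"xgb"` (histogram gradient boosting) or `"ranger"`
#'   (random forest).
#' @param params Hyperparameter list; defaults per family.
#' @param use_graph Include the graph feature block?
#' @param class_weight Inverse-frequency class weighting?
#' @return Object of class `rri_cv`: `folds` tibble + aggregate fields.
#' @export
cross_validate <- function(features, config = rri_config(), family = "xgb",
                           params = NULL, use_graph = TRUE,
                           class_weight = TRUE) {
  y <- features$label
  if (any(is.na(y)) || length(unique(y)) < 2) {
    abort("cross_validate: binary labels with both classes required")
  }
  if (length(y) < 2 * config$cv_folds) {
    abort(sprintf("cross_validate: need at least %d instances",
                  2 * config$cv_folds))
  }
  params <- params %||% default_params[[family]]
  x <- assemble_matrix(features, use_graph)
  folds <- grouped_folds(features$site_id, y, config$cv_folds,
                         config$rng_seed)
  per_fold <- cv_metrics_for(family, params, x, y, folds, class_weight,
                             config$rng_seed)
  structure(list(
    folds = per_fold,
    family = family,
    params = params,
    f1_mean = mean(per_fold$f1), f1_sd = sd(per_fold$f1),
    aucpr_mean = mean(per_fold$aucpr), aucpr_sd = sd(per_fold$aucpr),
    prevalence = mean(y)
  ), class = "rri_cv")
}

#' @export
print.rri_cv <- function(x, ...) {
  cat(sprintf("<rri_cv> %s | F1 %.3f +/- %.3f | AUC-PR %.3f +/- %.3f\n",
              x$family, x$f1_mean, x$f1_sd, x$aucpr_mean, x$aucpr_sd))
  invisible(x)
}

#' @rdname cross_validate
#' @param x An `rri_cv` object.
#' @param ... Unused.
#' @export
tidy.rri_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @export
glance.rri_cv <- function(x, ...) {
  tibble(family = x$family, f1_mean = x$f1_mean, f1_sd = x$f1_sd,
         aucpr_mean = x$aucpr_mean, aucpr_sd = x$aucpr_sd,
         prevalence = x$prevalence, n_folds = nrow(x$folds))
}

#' Plot per-fold cross-validation metrics
#' @param object An `rri_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rri_cv <- function(object, ...) {
  long <- object$folds %>%
    tidyr::pivot_longer(cols = c("f1", "precision", "recall", "aucpr"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' External (train-on-A, test-on-B) validation
#'
#' Applies a trained model to an independently built labeled feature table
#' — e.g. data from a different organism — and reports F1 and the PR curve.
#'
#' @param model An `rri_model`.
#' @param features Labeled `rri_features` table.
#' @param force Skip compatibility checks (see [evaluate_sites()]).
#' @return List with `f1`, `precision`, `recall`, `pr` (an `rri_pr`) and
#'   the `predictions` tibble.
#' @export
validate_model <- function(model, features, force = FALSE) {
  preds <- evaluate_sites(model, features, force = force)
  scored <- preds %>% filter(!is.na(.data$predicted_label))
  y <- features$label[match(scored$instance_id, features$instance_id)]
  list(
    f1 = f1_score(y, scored$predicted_label),
    precision = precision_score(y, scored$predicted_label),
    recall = recall_score(y, scored$predicted_label),
    pr = pr_curve(y, scored$prob_relevant),
    predictions = preds
  )
}
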