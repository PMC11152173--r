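#' End-to-end training-data construction
#'
#' Runs the full curation-to-features pipeline: replicate-concordance and
#' score curation of trusted sites, occupied-region library construction
#' from all input interactions (score >= `score_min_occupied`) plus
#' optional RBP intervals, context extension, positive (seed-in-core) and
#' negative (context-flanking) duplex prediction, and feature extraction.
#'
#' @param replicates List of interaction tibbles (from
#'   [read_interactions()] or [sim_interactome()]), one per replicate.
#' @param genome Genome (`DNAStringSet` or named character vector).
#' @param config An [rri_config()].
#' @param rbp_intervals Optional interval tibble of RBP sites (crosslink
#'   tracks should be widened with [extend_crosslinks()] by
#'   `config$crosslink_flank` first; that is done here when all intervals
#'   have width 1).
#' @param graph Compute graph-kernel features?
#' @return List of class `rri_training`: `trusted`, `occupied`,
#'   `instances` (positives then negatives) and `features`.
#' @export
build_training_data <- function(replicates, genome, config = rri_config(),
                                rbp_intervals = NULL, graph = TRUE) {
  trusted <- curate_trusted(replicates, config$overlap_threshold,
                            config$score_min_trusted)
  all_records <- bind_rows(replicates)
  if (!is.null(rbp_intervals) && nrow(rbp_intervals) > 0 &&
      all(rbp_intervals$end - rbp_intervals$start == 1L)) {
    rbp_intervals <- extend_crosslinks(rbp_intervals, config$crosslink_flank,
                                       chrom_lengths(genome))
  }
  occupied <- build_occupied_library(all_records, config$score_min_occupied,
                                     rbp_intervals)
  positives <- build_positive_instances(trusted, genome, occupied, config)
  negatives <- make_negative_instances(positives, occupied, config)
  instances <- bind_rows(positives, negatives)
  class(instances) <- c("rri_instances", class(instances))
  features <- build_feature_table(instances, config, graph = graph)
  structure(list(trusted = trusted, occupied = occupied,
                 instances = instances, features = features),
            class = "rri_training")
}

#' @export
print.rri_training <- function(x, ...) {
  cat("<rri_training>", nrow(x$trusted), "trusted sites |",
      sum(x$instances$polarity == "positive"), "pos /",
      sum(x$instances$polarity == "negative"), "neg instances |",
      nrow(x$features), "feature rows\n")
  invisible(x)
}

#' Build evaluation instances for putative sites
#'
#' Treats each candidate site like a positive training site (seed anchored
#' in the site, context extension, occupancy masking with the site's own
#' arms lifted out) so a trained model can judge it.
#'
#' @param sites Interaction tibble of candidate sites (a `score` column is
#'   optional; `record_id` is generated when absent).
#' @param genome Genome.
#' @param occupied An `rri_occupied` library, or NULL for no masking.
#' @param config An [rri_config()].
#' @return An `rri_instances` tibble with `polarity = "eval"`.
#' @export
build_eval_instances <- function(sites, genome, occupied = NULL,
                                 config = rri_config()) {
  if (is.null(occupied)) occupied <- build_occupied_library(NULL)
  if (!"record_id" %in% names(sites)) {
    sites <- sites %>% mutate(record_id = sprintf("eval_%05d", row_number()))
  }
  if (!"score" %in% names(sites)) sites <- sites %>% mutate(score = 0)
  sites <- sites %>% mutate(site_id = site_identifier(sites))
  inst <- build_positive_instances(sites, genome, occupied, config)
  inst %>%
    mutate(polarity = "eval",
           instance_id = paste0(.data$site_id, ":eva")) -> out
  class(out) <- c("rri_instances", class(out))
  out
}

#' Classify putative RRI sites end to end
#'
#' @param model A trained `rri_model`.
#' @param sites Interaction tibble of candidate sites.
#' @param genome Genome.
#' @param occupied Optional `rri_occupied` library used for masking.
#' @param config Config used to build features; defaults to the model's.
#' @param force Passed to [evaluate_sites()].
#' @return Predictions tibble (see [evaluate_sites()]); sites without a
#'   valid duplex get `predicted_label = NA`.
#' @export
classify_sites <- function(model, sites, genome, occupied = NULL,
                           config = NULL, force = FALSE) {
  config <- config %||% model$config
  inst <- build_eval_instances(sites, genome, occupied, config)
  feats <- build_feature_table(inst, config, graph = model$use_graph)
  evaluate_sites(model, feats, force = force)
}
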