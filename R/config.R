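#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one place. Defaults
#' are the method's published operating point: replicate-concordance overlap
#' threshold 30%, trusted-site score cutoff 1, occupied-region score cutoff
#' 0.5, 150-nt genomic context, 5-bp seeds, up to 5 suboptimal duplexes per
#' instance, and crosslink flanks of 5 nt.
#'
#' @param overlap_threshold Minimum reciprocal (relative to the shorter
#'   interval) overlap fraction for two replicate sites to be considered the
#'   same interaction. In (0, 1].
#' @param score_min_trusted Minimum interaction score (ChiRA EM-style) for a
#'   replicate-concordant site to be kept as trusted.
#' @param score_min_occupied Lower score cutoff for interactions entering
#'   the occupied-region library; deliberately below `score_min_trusted` so
#'   occupancy is defined conservatively.
#' @param context_len Genomic context (nt) added on each side of a site arm
#'   before duplex prediction.
#' @param seed_len Required number of consecutive base pairs forming the
#'   seed that anchors a predicted duplex.
#' @param n_suboptimals Maximum number of suboptimal duplexes kept per
#'   instance.
#' @param crosslink_flank Extension (nt, each side) applied to single-base
#'   crosslink positions when building the occupied library.
#' @param max_loop Maximum unpaired nucleotides allowed between consecutive
#'   base pairs, per side.
#' @param loop_penalty Energy penalty per enclosed unpaired nucleotide.
#' @param pair_energies Named vector of pair energies (arbitrary additive
#'   units, lower = more stable) for GC, AU and GU pairs.
#' @param graph_radius,graph_distance,hash_bits Graph-kernel parameters:
#'   Weisfeiler-Lehman neighborhood radius, maximum node-pair distance, and
#'   log2 of the hashed feature-space size (in `[8, 28]`).
#' @param importance_cutoff Random-forest importance threshold below which
#'   features are dropped before model search.
#' @param cv_folds Number of stratified cross-validation folds.
#' @param search_iters Number of randomized hyperparameter draws during
#'   model selection.
#' @param rng_seed Integer seed controlling every stochastic step.
#' @return A list of class `rri_config`.
#' @export
#' @examples
#' cfg <- rri_config(rng_seed = 7)
#' cfg$overlap_threshold
rri_config <- function(overlap_threshold = 0.30,
                       score_min_trusted = 1.0,
                       score_min_occupied = 0.5,
                       context_len = 150L,
                       seed_len = 5L,
                       n_suboptimals = 5L,
                       crosslink_flank = 5L,
                       max_loop = 3L,
                       loop_penalty = 0.5,
                       pair_energies = c(GC = -2.0, AU = -1.0, GU = -0.5),
                       graph_radius = 2L,
                       graph_distance = 4L,
                       hash_bits = 16L,
                       importance_cutoff = 1e-4,
                       cv_folds = 5L,
                       search_iters = 50L,
                       rng_seed = 1L) {
  stopifnot(
    overlap_threshold > 0, overlap_threshold <= 1,
    context_len >= 0, seed_len >= 1, seed_len <= 63, n_suboptimals >= 1,
    crosslink_flank >= 0, max_loop >= 0,
    hash_bits >= 8, hash_bits <= 28,
    all(c("GC", "AU", "GU") %in% names(pair_energies)),
    cv_folds >= 2, search_iters >= 1
  )
  structure(list(
    overlap_threshold = overlap_threshold,
    score_min_trusted = score_min_trusted,
    score_min_occupied = score_min_occupied,
    context_len = as.integer(context_len),
    seed_len = as.integer(seed_len),
    n_suboptimals = as.integer(n_suboptimals),
    crosslink_flank = as.integer(crosslink_flank),
    max_loop = as.integer(max_loop),
    loop_penalty = loop_penalty,
    pair_energies = pair_energies,
    graph_radius = as.integer(graph_radius),
    graph_distance = as.integer(graph_distance),
    hash_bits = as.integer(hash_bits),
    importance_cutoff = importance_cutoff,
    cv_folds = as.integer(cv_folds),
    search_iters = as.integer(search_iters),
    rng_seed = as.integer(rng_seed)
  ), class = "rri_config")
}

#' Configuration fingerprint
#'
#' Stable 64-bit hex digest of the feature-shaping config fields (curation
#' cutoffs, context, energy model, graph-kernel parameters); stamped on
#' feature tables and trained models so mismatched artifacts are refused at
#' evaluation. Model-search fields (fold count, search iterations, seed) do
#' not enter the digest: they change the classifier, not the feature space.
#'
#' @param config An [rri_config()].
#' @return A 16-character hex string.
#' @export
config_fingerprint <- function(config) {
  stopifnot(inherits(config, "rri_config"))
  fields <- c("overlap_threshold", "score_min_trusted", "score_min_occupied",
              "context_len", "seed_len", "n_suboptimals", "crosslink_flank",
              "max_loop", "loop_penalty", "pair_energies", "graph_radius",
              "graph_distance", "hash_bits")
  flat <- paste(
    fields,
    vapply(config[fields],
           function(x) paste(format(x, digits = 15), collapse = ","),
           character(1)),
    sep = "=", collapse = ";"
  )
  hash64_cpp(flat)
}

#' @export
print.rri_config <- function(x, ...) {
  cat("<rri_config> fingerprint", config_fingerprint(x), "\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
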