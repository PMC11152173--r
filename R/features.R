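#' GC content of a sequence
#' @param seq Non-empty RNA/DNA sequence.
#' @return Fraction of G and C in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (nchar(seq) == 0) abort("gc_content: empty sequence")
  chars <- strsplit(toupper(seq), "")[[1]]
  mean(chars %in% c("G", "C"))
}

#' Sequence complexity (k-mer Shannon entropy)
#'
#' Shannon entropy, in bits, of the distribution of overlapping k-mers —
#' low for repetitive sequence, up to `2k` bits for maximally diverse RNA.
#'
#' @param seq Sequence of length at least `k`.
#' @param k k-mer size (>= 1).
#' @return Entropy in bits.
#' @export
#' @examples
#' sequence_complexity("ACGU", 1) # 2 bits
sequence_complexity <- function(seq, k = 1L) {
  stopifnot(k >= 1)
  n <- nchar(seq)
  if (n < k) abort("sequence_complexity: sequence shorter than k")
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  p <- table(kmers) / length(kmers)
  -sum(p * log2(p))
}

nt_fractions <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  c(frac_a = mean(chars == "A"), frac_c = mean(chars == "C"),
    frac_g = mean(chars == "G"), frac_u = mean(chars == "U"))
}

side_seq_features <- function(seq, prefix) {
  v <- c(gc = gc_content(seq), nt_fractions(seq),
         comp1 = sequence_complexity(seq, 1L),
         comp2 = if (nchar(seq) >= 2) sequence_complexity(seq, 2L) else 0)
  setNames(v, paste0(prefix, "_", names(v)))
}

#' Hand-crafted features of one prediction instance
#'
#' Interaction and sequence features over the instance's duplex set:
#' minimum and mean energy and duplex count; for the minimum-energy duplex
#' the pair count, per-side and summed interaction lengths, GC/AU/GU pair
#' counts, enclosed unpaired nucleotides and maximal contiguous stack; the
#' length-, GC- and pair-normalized energies (with a guard indicator when
#' no GC pair exists); per-side sequence composition and complexity of the
#' duplex-covered subsequences and of the site cores.
#'
#' @param instance One row of an `rri_instances` tibble.
#' @param config An [rri_config()].
#' @return Named numeric vector (NULL when the instance has no duplex).
#' @export
handcrafted_features <- function(instance, config = rri_config()) {
  dup <- instance$duplexes[[1]]
  if (nrow(dup) == 0) return(NULL)
  best <- dup[which.min(dup$energy), ]
  p <- best$pairs[[1]]
  c1 <- strsplit(instance$seq1, "")[[1]]
  c2 <- strsplit(instance$seq2, "")[[1]]
  types <- vapply(seq_len(nrow(p)),
                  function(r) pair_type(c1[p$i[r]], c2[p$j[r]]),
                  character(1))
  len1 <- max(p$i) - min(p$i) + 1L
  len2 <- max(p$j) - min(p$j) + 1L
  gaps1 <- if (nrow(p) > 1) diff(p$i) - 1L else integer(0)
  gaps2 <- if (nrow(p) > 1) -diff(p$j) - 1L else integer(0)
  stacked <- nrow(p) > 1 & c(FALSE, diff(p$i) == 1L & diff(p$j) == -1L)
  runs <- rle(stacked)
  max_stack <- 1L
  if (any(stacked)) {
    max_stack <- max(runs$lengths[runs$values]) + 1L
  }
  e <- best$energy
  n_gc <- sum(types == "GC")
  sub1 <- substr(instance$seq1, min(p$i), max(p$i))
  sub2 <- substr(instance$seq2, min(p$j), max(p$j))
  core1 <- instance$core1[[1]]; core2 <- instance$core2[[1]]
  cseq1 <- substr(instance$seq1, core1[1], core1[2])
  cseq2 <- substr(instance$seq2, core2[1], core2[2])
  core_feats <- function(cs, prefix) {
    setNames(c(gc_content(cs), sequence_complexity(cs, 1L),
               if (nchar(cs) >= 2) sequence_complexity(cs, 2L) else 0,
               nchar(cs)),
             paste0(prefix, c("_gc", "_comp1", "_comp2", "_len")))
  }
  c(
    e_min = e,
    e_mean = mean(dup$energy),
    n_duplexes = nrow(dup),
    n_pairs = nrow(p),
    len1 = len1, len2 = len2, len_sum = len1 + len2,
    n_gc = n_gc, n_au = sum(types == "AU"), n_gu = sum(types == "GU"),
    n_unpaired = sum(gaps1) + sum(gaps2),
    max_stack = max_stack,
    e_per_len = e / (len1 + len2),
    e_per_gc = if (n_gc > 0) e / n_gc else 0,
    no_gc = as.numeric(n_gc == 0),
    e_per_pair = e / nrow(p),
    side_seq_features(sub1, "s1"), side_seq_features(sub2, "s2"),
    core_feats(cseq1, "core1"), core_feats(cseq2, "core2")
  )
}

#' Interaction graph of one instance
#'
#' Encodes the instance's whole duplex set as one labeled graph: each side
#' contributes the window positions covered by the union span of its
#' duplexes as nucleotide-labeled nodes connected by backbone edges
#' (`"b"`); every distinct base pair occurring in any suboptimal adds one
#' pair edge (`"p"`) joining the two sides. Sequence and structural
#' alternatives are thereby represented jointly.
#'
#' @param instance One row of an `rri_instances` tibble (>= 1 duplex).
#' @return List with `nodes` (tibble: `node`, `label`, `side`, `pos`) and
#'   `edges` (tibble: `from`, `to`, `label`; 1-based node indices).
#' @export
build_interaction_graph <- function(instance) {
  dup <- instance$duplexes[[1]]
  if (nrow(dup) == 0) abort("build_interaction_graph: instance has no duplex")
  allp <- bind_rows(dup$pairs) %>% dplyr::distinct()
  span1 <- min(allp$i):max(allp$i)
  span2 <- min(allp$j):max(allp$j)
  c1 <- strsplit(instance$seq1, "")[[1]]
  c2 <- strsplit(instance$seq2, "")[[1]]
  nodes <- tibble(
    node = seq_len(length(span1) + length(span2)),
    label = c(c1[span1], c2[span2]),
    side = rep(1:2, c(length(span1), length(span2))),
    pos = c(span1, span2)
  )
  id1 <- function(i) match(i, span1)
  id2 <- function(j) match(j, span2) + length(span1)
  backbone <- bind_rows(
    if (length(span1) > 1)
      tibble(from = id1(span1[-length(span1)]), to = id1(span1[-1])),
    if (length(span2) > 1)
      tibble(from = id2(span2[-length(span2)]), to = id2(span2[-1]))
  )
  if (is.null(backbone)) backbone <- tibble(from = integer(), to = integer())
  edges <- bind_rows(
    backbone %>% mutate(label = "b"),
    tibble(from = id1(allp$i), to = id2(allp$j), label = "p")
  )
  list(nodes = nodes, edges = edges)
}

#' Graph-kernel feature vector
#'
#' NSPDK-style sparse features of a labeled graph: pairs of
#' Weisfeiler-Lehman-canonicalized neighborhood subgraphs (radius up to
#' `radius`) at shortest-path distance up to `distance`, hashed into
#' `2^hash_bits` buckets and L2-normalized. Fully deterministic and
#' invariant under node relabeling.
#'
#' @param graph Output of [build_interaction_graph()].
#' @param radius,distance,hash_bits Kernel parameters (see [rri_config()]).
#' @return Tibble with `index` (0-based bucket) and `value`.
#' @export
nspdk_features <- function(graph, radius = 2L, distance = 4L,
                           hash_bits = 16L) {
  stopifnot(radius >= 0, distance >= 0, hash_bits >= 1)
  edges <- as.matrix(graph$edges[, c("from", "to")]) - 1L
  storage.mode(edges) <- "integer"
  res <- nspdk_cpp(graph$nodes$label, edges, graph$edges$label,
                   as.integer(radius), as.integer(distance),
                   as.integer(hash_bits))
  tibble(index = res$index, value = res$value)
}

#' Build the feature table of an instance set
#'
#' Converts every instance with at least one duplex into one feature row:
#' the dense hand-crafted block as named tibble columns and (optionally)
#' the sparse hashed graph block as a `dgCMatrix` attached as attribute
#' `graph_matrix` (column `g<index>` = hash bucket). Instances without a
#' duplex are excluded and listed in attribute `na_instances`.
#'
#' @param instances An `rri_instances` tibble.
#' @param config An [rri_config()].
#' @param graph Include graph-kernel features?
#' @return Tibble of class `rri_features` with identifier columns
#'   (`instance_id`, `site_id`, `label`: 1 positive / 0 negative / NA for
#'   eval instances) followed by dense features; attributes `graph_matrix`,
#'   `hash_bits`, `fingerprint`, `na_instances`.
#' @export
build_feature_table <- function(instances, config = rri_config(),
                                graph = TRUE) {
  has_dup <- instances$n_duplexes > 0
  na_ids <- instances$instance_id[!has_dup]
  kept <- instances[has_dup, ]
  dense <- purrr::map(seq_len(nrow(kept)), function(r)
    handcrafted_features(kept[r, ], config))
  dense_tbl <- as_tibble(do.call(rbind, dense))
  label <- dplyr::case_when(
    kept$polarity == "positive" ~ 1,
    kept$polarity == "negative" ~ 0,
    TRUE ~ NA_real_
  )
  out <- bind_cols(
    tibble(instance_id = kept$instance_id, site_id = kept$site_id,
           label = label),
    dense_tbl
  )
  if (graph && nrow(kept) > 0) {
    trips <- purrr::map(seq_len(nrow(kept)), function(r) {
      g <- build_interaction_graph(kept[r, ])
      v <- nspdk_features(g, config$graph_radius, config$graph_distance,
                          config$hash_bits)
      v$row <- r
      v
    }) %>% bind_rows()
    gm <- Matrix::sparseMatrix(
      i = trips$row, j = trips$index + 1L, x = trips$value,
      dims = c(nrow(kept), 2^config$hash_bits),
      dimnames = list(kept$instance_id,
                      paste0("g", seq_len(2^config$hash_bits) - 1L))
    )
    attr(out, "graph_matrix") <- gm
  } else if (graph) {
    attr(out, "graph_matrix") <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = double(0),
      dims = c(0, 2^config$hash_bits),
      dimnames = list(NULL, paste0("g", seq_len(2^config$hash_bits) - 1L)))
  }
  attr(out, "hash_bits") <- if (graph) config$hash_bits else NULL
  attr(out, "fingerprint") <- config_fingerprint(config)
  attr(out, "na_instances") <- na_ids
  class(out) <- c("rri_features", class(out))
  out
}

feature_meta_cols <- c("instance_id", "site_id", "label", "source")

dense_feature_names <- function(features) {
  setdiff(names(features), feature_meta_cols)
}

#' Serialize a feature table
#'
#' Writes the dense block as TSV and the sparse graph block as a triplet
#' file (`instance_id  index  value`), both with a `#fingerprint` header so
#' mismatched configurations are detectable on reload.
#'
#' @param features An `rri_features` table.
#' @param path Base path; `<path>.tsv` and `<path>.graph.tsv` are written.
#' @export
write_feature_table <- function(features, path) {
  hdr <- paste0("#fingerprint=", attr(features, "fingerprint"))
  dense_path <- paste0(path, ".tsv")
  writeLines(hdr, dense_path)
  readr::write_tsv(as_tibble(features), dense_path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  gm <- attr(features, "graph_matrix")
  if (!is.null(gm)) {
    tr <- Matrix::summary(gm)
    gtbl <- tibble(instance_id = rownames(gm)[tr$i],
                   index = tr$j - 1L, value = tr$x)
    gpath <- paste0(path, ".graph.tsv")
    writeLines(c(hdr, paste0("#hash_bits=", attr(features, "hash_bits"))),
               gpath)
    readr::write_tsv(gtbl, gpath, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}
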