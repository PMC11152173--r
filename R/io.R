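#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each FASTA header as the chromosome name
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` or named character vector of sequences.
#' @return Named integer vector.
#' @export
chrom_lengths <- function(genome) {
  if (is.character(genome)) {
    setNames(nchar(genome), names(genome))
  } else {
    setNames(Biostrings::width(genome), names(genome))
  }
}

#' Extract strand-oriented RNA sequences
#'
#' Returns the 5'->3' RNA sequence (T mapped to U) of each interval;
#' minus-strand intervals are reverse-complemented. Ambiguity codes are
#' retained and simply never base-pair downstream.
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param intervals Interval tibble.
#' @return Character vector of RNA sequences, one per interval row.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' extract_sequence(g, interval_tbl("chr1", 0, 4, "+"))
extract_sequence <- function(genome, intervals) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  validate_intervals(intervals, chrom_lengths(genome))
  vapply(seq_len(nrow(intervals)), function(r) {
    s <- Biostrings::subseq(genome[[intervals$chrom[r]]],
                            start = intervals$start[r] + 1L,
                            end = intervals$end[r])
    if (intervals$strand[r] == "-") s <- Biostrings::reverseComplement(s)
    chartr("Tt", "Uu", toupper(as.character(s)))
  }, character(1))
}

# reverse complement in the RNA alphabet (keeps N and other codes)
revcomp_rna <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

interaction_cols <- c("chrom1", "start1", "end1", "strand1",
                      "chrom2", "start2", "end2", "strand2", "score")

#' Read a tabular interaction-summary file
#'
#' Parses a ChiRA-style interaction summary: one tab-separated row per
#' chimeric interaction with two genomic arms and a score. The file dialect
#' is 1-based inclusive; coordinates are converted once to the package's
#' internal 0-based half-open convention. Lines starting with `#` are
#' ignored. An optional `id` column supplies record identifiers; otherwise
#' they are generated as `<replicate_id>_<row>`.
#'
#' @param path Tab-separated file with header columns `chrom1 start1 end1
#'   strand1 chrom2 start2 end2 strand2 score` (order free, extras ignored).
#' @param replicate_id Label attached to every record from this file.
#' @return A tibble with one row per interaction: `record_id`,
#'   `replicate_id`, arm coordinates (internal convention) and `score`, in
#'   file order.
#' @export
read_interactions <- function(path, replicate_id) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(interaction_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("interaction table ", path, " is missing required column: ",
                 missing_cols[1]))
  }
  if (nrow(raw) == 0) {
    return(tibble(record_id = character(), replicate_id = character(),
                  chrom1 = character(), start1 = integer(), end1 = integer(),
                  strand1 = character(), chrom2 = character(),
                  start2 = integer(), end2 = integer(), strand2 = character(),
                  score = double()))
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric score '%s' at data row %d of %s",
                  raw$score[bad[1]], bad[1], path))
  }
  if (any(score < 0)) {
    abort(sprintf("negative score at data row %d of %s",
                  which(score < 0)[1], path))
  }
  num <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("non-integer %s '%s' at data row %d of %s",
                    col, raw[[col]][bad[1]], bad[1], path))
    }
    v
  }
  out <- tibble(
    record_id = if ("id" %in% names(raw)) raw$id
                else sprintf("%s_%05d", replicate_id, seq_len(nrow(raw))),
    replicate_id = replicate_id,
    chrom1 = raw$chrom1, start1 = num("start1") - 1L, end1 = num("end1"),
    strand1 = raw$strand1,
    chrom2 = raw$chrom2, start2 = num("start2") - 1L, end2 = num("end2"),
    strand2 = raw$strand2,
    score = score
  )
  for (arm in 1:2) {
    iv <- arm_intervals(out, arm)
    bad <- which(iv$start >= iv$end)
    if (length(bad) > 0) {
      abort(sprintf("start%d > end%d at data row %d of %s",
                    arm, arm, bad[1], path))
    }
    validate_intervals(iv)
  }
  if (anyDuplicated(out$record_id)) {
    abort(paste0("duplicate record_id in ", path))
  }
  out
}

#' Write an interaction table
#'
#' Inverse of [read_interactions()]: emits the 1-based inclusive tab
#' separated dialect, so read -> write -> read round-trips exactly.
#'
#' @param records Interaction tibble.
#' @param path Output file.
#' @export
write_interactions <- function(records, path) {
  out <- records %>%
    mutate(start1 = .data$start1 + 1L, start2 = .data$start2 + 1L) %>%
    select(all_of(c("id" = "record_id")), all_of(interaction_cols))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# view one arm of an interaction tibble as an interval tibble
arm_intervals <- function(records, arm) {
  tibble(
    chrom = records[[paste0("chrom", arm)]],
    start = records[[paste0("start", arm)]],
    end = records[[paste0("end", arm)]],
    strand = records[[paste0("strand", arm)]]
  )
}

#' Read a BED3/BED6 file
#'
#' BED is natively 0-based half-open, so coordinates pass through without
#' shifting. BED3 rows (and `.` strands) are strand-agnostic (`"*"`): they
#' are treated as occupying both strands downstream, the conservative
#' reading for crosslink tracks.
#'
#' @param path BED file; `#` comment lines ignored.
#' @return Interval tibble with an extra `name` column.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character()))
  }
  if (ncol(raw) < 3) abort(paste0(path, ": BED needs at least 3 columns"))
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid BED interval at data row %d of %s", bad[1], path))
  }
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep(".", nrow(raw))
  strand[is.na(strand)] <- "."
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad) > 0) {
    abort(sprintf("unknown strand '%s' at data row %d of %s",
                  strand[bad[1]], bad[1], path))
  }
  tibble(
    chrom = raw[[1]], start = start, end = end,
    strand = ifelse(strand == ".", "*", strand),
    name = if (ncol(raw) >= 4) raw[[4]] else sprintf("bed_%05d", seq_len(nrow(raw)))
  )
}

#' Write intervals as BED
#'
#' @param intervals Interval tibble; an optional `name` column becomes BED
#'   column 4 (an `origin` column is used when `name` is absent).
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  name <- if ("name" %in% names(intervals)) intervals$name
          else if ("origin" %in% names(intervals)) intervals$origin
          else sprintf("iv_%05d", seq_len(nrow(intervals)))
  out <- tibble(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = name, score = 0L,
    strand = ifelse(intervals$strand == "*", ".", intervals$strand)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# positions-based site identifier, 1-based inclusive in the output dialect
site_identifier <- function(records) {
  sprintf("%s:%d-%d:%s;%s:%d-%d:%s",
          records$chrom1, records$start1 + 1L, records$end1, records$strand1,
          records$chrom2, records$start2 + 1L, records$end2, records$strand2)
}
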