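#' Consensus-divergence (mismatch stratum) profile for one feature
#'
#' Each read is assigned its minimal achievable Hamming distance to the
#' feature's consensus over all windows and both strands: stratum 0-3, or
#' `unmapped_at_3` beyond three mismatches. Low-mismatch reads are
#' interpreted as deriving from modern, active copies of the element;
#' high-mismatch reads from degraded ancestral copies. Masses accumulate
#' per-read weights and are split by orientation (the strand of the
#' minimal-distance placement).
#'
#' @param reads data.frame with `id`, `seq` (pre-selected piRNA-length reads
#'   for the feature of interest), or named character vector; an optional
#'   `weight` column weights each read (default 1).
#' @param feature feature name.
#' @param library a `consensus_library` containing `feature`.
#' @return object of class `divergence_profile`: list with `feature` and
#'   `profile`, a data.frame with rows sense/antisense and columns
#'   `mm0`..`mm3`, `unmapped_at_3`, plus `fraction_perfect` and
#'   `fraction_modern` (strata 0-3) per orientation.
#' @export
mismatch_profile <- function(reads, feature, library) {
  if (!feature %in% names(library)) stop("feature not in library: ", feature)
  if (is.character(reads)) reads <- data.frame(id = seq_along(reads), seq = reads)
  w <- if ("weight" %in% names(reads)) reads$weight else rep(1, nrow(reads))
  strata <- c("mm0", "mm1", "mm2", "mm3", "unmapped_at_3")
  prof <- matrix(0, nrow = 2, ncol = 5,
                 dimnames = list(c("sense", "antisense"), strata))
  if (nrow(reads)) {
    best <- .best_hit_cpp(toupper(reads$seq), as.character(library[feature]))
    stratum <- ifelse(best$min_mm <= 3, best$min_mm + 1L, 5L)
    orient <- ifelse(best$strand == 1L, 1L, 2L)
    for (i in seq_len(nrow(reads))) {
      prof[orient[i], stratum[i]] <- prof[orient[i], stratum[i]] + w[i]
    }
  }
  df <- as.data.frame(prof)
  tot <- rowSums(df)
  df$fraction_perfect <- ifelse(tot > 0, df$mm0 / tot, NA_real_)
  df$fraction_modern <- ifelse(tot > 0, rowSums(df[, 1:4]) / tot, NA_real_)
  structure(list(feature = feature, profile = df),
            class = "divergence_profile")
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat("divergence profile for", x$feature, "\n")
  print(round(x$profile, 4))
  invisible(x)
}

#' Per-position coverage track for one feature
#'
#' Every aligned base increments the depth at its position by the alignment
#' weight; sense and antisense depths are kept separate, and depths are
#' scaled to reads per million (`1e6 / denominator`).
#'
#' @param alignments alignment data.frame for one feature.
#' @param feature feature name.
#' @param library a `consensus_library` (gives the track length).
#' @param denominator per-million scaling denominator (default `1e6` leaves
#'   depths unscaled).
#' @return object of class `coverage_track`: list with `feature`, `sense`
#'   and `antisense` numeric vectors (length = consensus length, 1-based
#'   indexing of 0-based positions), and `denominator`.
#' @export
coverage_track <- function(alignments, feature, library, denominator = 1e6) {
  if (!feature %in% names(library)) stop("feature not in library: ", feature)
  L <- nchar(library[[feature]])
  sense <- numeric(L); antisense <- numeric(L)
  aln <- alignments[alignments$feature == feature, , drop = FALSE]
  scale <- 1e6 / denominator
  for (i in seq_len(nrow(aln))) {
    if (aln$strand[i] == "+") {
      idx <- aln$five_prime_pos[i] + seq_len(aln$length[i])       # 1-based
      sense[idx] <- sense[idx] + aln$weight[i] * scale
    } else {
      idx <- aln$five_prime_pos[i] - aln$length[i] + 1L + seq_len(aln$length[i])
      antisense[idx] <- antisense[idx] + aln$weight[i] * scale
    }
  }
  structure(list(feature = feature, sense = sense, antisense = antisense,
                 denominator = denominator),
            class = "coverage_track")
}

#' Write coverage tracks as BedGraph-style TSV
#'
#' Columns: feature, start (0-based), end (exclusive), depth, strand; runs
#' of equal depth are merged.
#'
#' @param track a `coverage_track`.
#' @param path output path; lines are appended when `append = TRUE`.
#' @param append append to an existing file.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path, append = FALSE) {
  rows <- list()
  for (strand in c("+", "-")) {
    depth <- if (strand == "+") track$sense else track$antisense
    r <- rle(depth)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      rows[[strand]] <- data.frame(feature = track$feature,
                                   start = start[keep], end = end[keep],
                                   depth = signif(r$values[keep], 6),
                                   strand = strand)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), start = integer(), end = integer(),
               depth = numeric(), strand = character())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !append, append = append)
  invisible(path)
}
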