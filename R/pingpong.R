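#' 5'-5' overlap histogram for one feature's piRNAs
#'
#' For every sense alignment with 5' end at `s` and every antisense
#' alignment with 5' end (plus-strand coordinate) at `a`, the overlap is
#' `d = a - s + 1`; for each `d` in 1..20 the histogram accumulates the
#' read-weighted pair mass `weight_sense * weight_antisense`. `d = 10` is
#' the ping-pong signal. The aggregation is position-indexed for speed but
#' equals the all-pairs enumeration exactly.
#'
#' @param alignments alignment data.frame restricted to one feature;
#'   by default only piRNA-length reads (23-29 nt) are used.
#' @param restrict_pirna drop non-piRNA-length alignments first (default
#'   TRUE).
#' @return named numeric vector of length 20 (`"1"` .. `"20"`).
#' @export
overlap_histogram <- function(alignments, restrict_pirna = TRUE) {
  if (length(unique(alignments$feature)) > 1) {
    stop("overlap_histogram() expects alignments of a single feature")
  }
  if (restrict_pirna) {
    alignments <- alignments[size_class_of(alignments$length) == "piRNA", ,
                             drop = FALSE]
  }
  hist <- setNames(numeric(20), as.character(1:20))
  se <- alignments[alignments$strand == "+", , drop = FALSE]
  as_ <- alignments[alignments$strand == "-", , drop = FALSE]
  if (nrow(se) == 0 || nrow(as_) == 0) return(hist)
  ws <- tapply(se$weight, se$five_prime_pos, sum)          # mass per sense 5'
  wa <- tapply(as_$weight, as_$five_prime_pos, sum)        # mass per antisense 5'
  s_pos <- as.integer(names(ws)); a_pos <- as.integer(names(wa))
  for (d in 1:20) {
    m <- match(a_pos - d + 1L, s_pos)
    ok <- !is.na(m)
    if (any(ok)) hist[d] <- sum(wa[ok] * ws[m[ok]])
  }
  hist
}

#' Ping-pong signature statistics
#'
#' Summarizes a 5'-5' overlap histogram: the z-score of the 10-nt bin
#' against the other 19 bins, the count of distinct (sense 5', antisense 5')
#' position pairs at overlap 10, and the positional nucleotide biases of
#' secondary processing (fraction of antisense piRNA mass starting with
#' U/T, fraction of sense piRNA mass with A at read position 10). Both pair
#' definitions (weighted mass and distinct position pairs) are reported. A
#' zero-variance background yields `zscore_10 = NA` with `degenerate = TRUE`
#' (never infinity).
#'
#' @param histogram output of [overlap_histogram()].
#' @param alignments the same single-feature alignment table (used for
#'   distinct pairs and nucleotide biases).
#' @param reads data.frame with `id`, `seq` giving read sequences (insert
#'   orientation); required for the 1U/10A biases, which are `NA` when
#'   omitted.
#' @param restrict_pirna drop non-piRNA-length alignments first (default
#'   TRUE).
#' @return object of class `pingpong_stats`: list with `feature`,
#'   `histogram`, `pair_mass_10`, `distinct_pairs`, `zscore_10`,
#'   `degenerate`, `u1_antisense`, `a10_sense`.
#' @export
pingpong_stats <- function(histogram, alignments, reads = NULL,
                           restrict_pirna = TRUE) {
  feature <- if (nrow(alignments)) alignments$feature[1] else NA_character_
  if (restrict_pirna) {
    alignments <- alignments[size_class_of(alignments$length) == "piRNA", ,
                             drop = FALSE]
  }
  bg <- histogram[as.character(c(1:9, 11:20))]
  s <- sd(bg)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) NA_real_ else (histogram[["10"]] - mean(bg)) / s

  se <- alignments[alignments$strand == "+", , drop = FALSE]
  as_ <- alignments[alignments$strand == "-", , drop = FALSE]
  distinct_pairs <- 0L
  if (nrow(se) && nrow(as_)) {
    s_pos <- unique(se$five_prime_pos)
    a_pos <- unique(as_$five_prime_pos)
    distinct_pairs <- sum((s_pos + 9L) %in% a_pos)
  }

  u1 <- a10 <- NA_real_
  if (!is.null(reads)) {
    seqs <- setNames(toupper(reads$seq), reads$id)
    if (nrow(as_)) {
      first <- substring(seqs[as_$read_id], 1L, 1L)
      u1 <- sum(as_$weight * (first == "T")) / sum(as_$weight)
    }
    if (nrow(se)) {
      tenth <- substring(seqs[se$read_id], 10L, 10L)
      a10 <- sum(se$weight * (tenth == "A")) / sum(se$weight)
    }
  }
  structure(list(feature = feature, histogram = histogram,
                 pair_mass_10 = unname(histogram[["10"]]),
                 distinct_pairs = distinct_pairs,
                 zscore_10 = unname(z), degenerate = degenerate,
                 u1_antisense = unname(u1), a10_sense = unname(a10)),
            class = "pingpong_stats")
}

#' @export
print.pingpong_stats <- function(x, ...) {
  cat("ping-pong signature for", x$feature, "\n")
  cat(sprintf(" pair mass at 10 nt: %.4g (distinct pairs: %d)\n",
              x$pair_mass_10, x$distinct_pairs))
  cat(sprintf(" z-score(10): %s%s\n",
              format(x$zscore_10, digits = 4),
              if (x$degenerate) " [degenerate background]" else ""))
  cat(sprintf(" 1U antisense: %s;  10A sense: %s\n",
              format(x$u1_antisense, digits = 3),
              format(x$a10_sense, digits = 3)))
  invisible(x)
}

#' Ping-pong signature for one feature, from a full alignment table
#'
#' Convenience wrapper: restricts the alignment table to `feature` and the
#' piRNA size class, then computes [overlap_histogram()] and
#' [pingpong_stats()].
#'
#' @param alignments alignment data.frame (any number of features).
#' @param feature feature name.
#' @param reads optional reads for nucleotide biases.
#' @return a `pingpong_stats` object.
#' @export
pingpong_signature <- function(alignments, feature, reads = NULL) {
  aln <- alignments[alignments$feature == feature, , drop = FALSE]
  hist <- overlap_histogram(aln)
  pingpong_stats(hist, aln, reads = reads)
}
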