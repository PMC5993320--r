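#' Trim the 3' adapter from small-RNA reads
#'
#' Finds the leftmost position where a prefix of the adapter matches the read
#' through to its 3' end (overlap of at least `min_overlap` nt, at most
#' `max_mismatch` mismatches) and returns the 5' insert with its quality
#' slice. Reads in which no adapter is found are discarded by default
#' (`keep_untrimmed = TRUE` keeps them unchanged); reads whose insert is
#' empty (adapter at position 0) are always discarded.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param adapter 3' adapter sequence (length >= `min_overlap`).
#' @param min_overlap minimum adapter prefix length to accept (default 5).
#' @param max_mismatch mismatches tolerated in the overlap (default 1).
#' @param keep_untrimmed keep reads with no adapter hit instead of
#'   discarding them.
#' @return data.frame of trimmed reads (same columns), with attributes
#'   `n_input` and `n_trimmed`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, max_mismatch = 1L,
                         keep_untrimmed = FALSE) {
  adapter <- toupper(adapter)
  if (nchar(adapter) < min_overlap) {
    stop("adapter (", nchar(adapter), " nt) is shorter than min_overlap (",
         min_overlap, ")")
  }
  if (nrow(reads) == 0) {
    return(structure(reads, n_input = 0L, n_trimmed = 0L))
  }
  at <- .find_adapter_cpp(reads$seq, adapter, as.integer(min_overlap),
                          as.integer(max_mismatch))
  keep <- if (keep_untrimmed) at != 0L else at > 0L
  out <- reads[keep, , drop = FALSE]
  cut <- at[keep]
  hit <- cut > 0L
  out$seq[hit] <- substring(out$seq[hit], 1L, cut[hit])
  out$qual[hit] <- substring(out$qual[hit], 1L, cut[hit])
  rownames(out) <- NULL
  structure(out, n_input = nrow(reads), n_trimmed = nrow(out))
}

## fraction of bases at or above q_threshold, per read
.hiq_fraction <- function(qual, q_threshold) {
  vapply(phred_scores(qual), function(s) mean(s >= q_threshold), numeric(1))
}

#' Length/quality filtering and ncRNA subtraction
#'
#' Keeps reads strictly longer than `min_len` whose fraction of bases at
#' Phred >= `q_threshold` is at least `q_fraction` (both comparisons
#' inclusive, so a read with exactly 80% of bases at Q20 passes), then
#' removes reads that occur as an exact substring of any ncRNA reference on
#' either strand. Retained reads keep their input order.
#'
#' @param reads data.frame of (adapter-trimmed) reads: `id`, `seq`, `qual`.
#' @param min_len exclusive minimum length; default 18 keeps reads > 18 nt.
#' @param q_threshold Phred threshold (default 20).
#' @param q_fraction minimum fraction of bases at or above `q_threshold`
#'   (default 0.8).
#' @param ncrna `consensusLibrary` of contaminant sequences, or `NULL` to
#'   skip subtraction (an empty library logs a warning and skips).
#' @return list with `reads` (retained) and `report` (named integer vector of
#'   stage counts: input, length_pass, quality_pass, ncrna_subtracted,
#'   retained).
#' @export
filter_and_subtract <- function(reads, min_len = 18L, q_threshold = 20L,
                                q_fraction = 0.8, ncrna = NULL) {
  stopifnot(min_len >= 1, q_fraction > 0, q_fraction <= 1)
  n_input <- nrow(reads)
  reads <- reads[nchar(reads$seq) > min_len, , drop = FALSE]
  n_len <- nrow(reads)
  if (n_len > 0) {
    ok <- .hiq_fraction(reads$qual, q_threshold) >= q_fraction - 1e-12
    reads <- reads[ok, , drop = FALSE]
  }
  n_qual <- nrow(reads)
  if (is.null(ncrna) || length(ncrna) == 0) {
    if (!is.null(ncrna)) warning("empty ncRNA library: subtraction skipped")
  } else if (n_qual > 0) {
    # perfect-match substring on either strand; "X" separators prevent
    # matches spanning reference boundaries
    hay <- paste(c(as.character(ncrna), revcomp(as.character(ncrna))),
                 collapse = "X")
    hit <- stringi::stri_detect_fixed(hay, reads$seq)
    reads <- reads[!hit, , drop = FALSE]
  }
  rownames(reads) <- NULL
  report <- c(input = n_input, length_pass = n_len, quality_pass = n_qual,
              ncrna_subtracted = nrow(reads), retained = nrow(reads))
  list(reads = reads, report = report)
}

#' Full pre-processing: trim, filter, subtract
#'
#' Applies [trim_adapter()] then [filter_and_subtract()] and assembles the
#' six-stage ledger (input, adapter_trimmed, length_pass, quality_pass,
#' ncrna_subtracted, retained); counts are monotone non-increasing.
#'
#' @inheritParams trim_adapter
#' @inheritParams filter_and_subtract
#' @return list with `reads` and `report` (the six-stage named vector).
#' @export
preprocess_reads <- function(reads, adapter, ncrna = NULL, min_len = 18L,
                             q_threshold = 20L, q_fraction = 0.8,
                             min_overlap = 5L, max_mismatch = 1L,
                             keep_untrimmed = FALSE) {
  trimmed <- trim_adapter(reads, adapter, min_overlap = min_overlap,
                          max_mismatch = max_mismatch,
                          keep_untrimmed = keep_untrimmed)
  fs <- filter_and_subtract(trimmed, min_len = min_len,
                            q_threshold = q_threshold,
                            q_fraction = q_fraction, ncrna = ncrna)
  report <- c(input = attr(trimmed, "n_input"),
              adapter_trimmed = attr(trimmed, "n_trimmed"),
              fs$report[c("length_pass", "quality_pass", "ncrna_subtracted",
                          "retained")])
  list(reads = fs$reads, report = report)
}
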