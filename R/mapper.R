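#' Align reads to a consensus library at a fixed mismatch stratum
#'
#' Every read is scanned against every reference on both strands with a
#' sliding Hamming comparison (no indels). Only the best stratum is
#' reported: all placements whose mismatch count equals the read's minimum
#' `m*`, provided `m* <= max_mismatches`. Each hit carries weight `1/k`
#' where `k` is the number of reported hits, so one read contributes unit
#' mass split across multi-mapping placements. `N` in the read or reference
#' always counts as a mismatch.
#'
#' Coordinates are 0-based; for antisense (`-`) hits `five_prime_pos` is the
#' plus-strand coordinate of the read's 5' end (the right edge of the
#' aligned window), as required by the 10-nt ping-pong overlap convention.
#'
#' @param reads data.frame with `id` and `seq` columns (quality ignored), or
#'   a named character vector of sequences.
#' @param library a `consensus_library`.
#' @param max_mismatches maximum mismatches, 0..3 (0 = the perfect-match
#'   mode used for genome/transcript mapping).
#' @return list with
#'   * `alignments`: data.frame `read_id`, `feature`, `strand`,
#'     `five_prime_pos`, `length`, `mismatches`, `weight`, ordered by
#'     (read input order, feature, strand, position);
#'   * `mapped`: named logical, one entry per read;
#'   * `n_reads`, `n_mapped`.
#' @export
map_reads <- function(reads, library, max_mismatches = 0L) {
  if (!max_mismatches %in% 0:3) stop("max_mismatches must be in 0..3")
  if (is.character(reads)) {
    reads <- data.frame(id = if (is.null(names(reads)))
      sprintf("read_%06d", seq_along(reads)) else names(reads),
      seq = unname(reads))
  }
  seqs <- toupper(reads$seq)
  if (any(grepl("[^ACGTN]", seqs))) {
    bad <- which(grepl("[^ACGTN]", seqs))[1]
    stop("read '", reads$id[bad], "' contains characters outside {A,C,G,T,N}")
  }
  if (nrow(reads) && any(nchar(seqs) < 15)) {
    stop("reads shorter than 15 nt cannot be aligned")
  }
  empty <- data.frame(read_id = character(), feature = character(),
                      strand = character(), five_prime_pos = integer(),
                      length = integer(), mismatches = integer(),
                      weight = numeric())
  if (nrow(reads) == 0) {
    return(list(alignments = empty, mapped = setNames(logical(0), character(0)),
                n_reads = 0L, n_mapped = 0L))
  }
  hits <- .scan_reads_cpp(seqs, as.character(library),
                          as.integer(max_mismatches))
  mapped <- setNames(tabulate(hits$read, nbins = nrow(reads)) > 0, reads$id)
  if (length(hits$read) == 0) {
    return(list(alignments = empty, mapped = mapped,
                n_reads = nrow(reads), n_mapped = 0L))
  }
  k <- tabulate(hits$read, nbins = nrow(reads))[hits$read]
  aln <- data.frame(read_id = reads$id[hits$read],
                    feature = names(library)[hits$ref],
                    strand = ifelse(hits$strand == 1L, "+", "-"),
                    five_prime_pos = hits$five_prime_pos,
                    length = nchar(seqs)[hits$read],
                    mismatches = hits$mismatches,
                    weight = 1 / k)
  ord <- order(hits$read, hits$ref, match(aln$strand, c("+", "-")),
               aln$five_prime_pos)
  aln <- aln[ord, , drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln, mapped = mapped, n_reads = nrow(reads),
       n_mapped = sum(mapped))
}

#' Align a single read
#'
#' Convenience wrapper around [map_reads()] for one read.
#'
#' @param seq read sequence (>= 15 nt over `{A,C,G,T,N}`).
#' @param library a `consensus_library`.
#' @param max_mismatches 0..3.
#' @param id read id used in the output.
#' @return data.frame of best-stratum alignments (possibly empty).
#' @export
align_read <- function(seq, library, max_mismatches = 0L, id = "read") {
  map_reads(data.frame(id = id, seq = seq), library, max_mismatches)$alignments
}
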