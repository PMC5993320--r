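#' Consensus sequence library
#'
#' A named collection of reference sequences (TE/repeat consensuses,
#' transcripts, or ncRNA contaminants) against which small-RNA reads are
#' mapped. Sequences are stored uppercase over `{A,C,G,T,N}`; `U` is
#' transliterated to `T` on construction.
#'
#' @param sequences named character vector of sequences; names must be unique
#'   and non-empty.
#' @param category one of `"TE"`, `"repeat"`, `"transcript"`, `"ncRNA"`,
#'   recycled across sequences.
#' @return an object of class `consensus_library`: a named character vector of
#'   sequences with a `category` attribute.
#' @export
consensus_library <- function(sequences,
                              category = c("TE", "repeat", "transcript", "ncRNA")) {
  if (length(sequences) == 0) stop("library must contain at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("sequence names must be unique")
  seqs <- chartr("u", "t", sequences)
  seqs <- toupper(chartr("U", "T", seqs))
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence '", nm[which(bad)[1]], "' contains characters outside {A,C,G,T,N,U}")
  }
  category <- rep(match.arg(category, several.ok = TRUE), length.out = length(seqs))
  structure(seqs, category = category, class = "consensus_library")
}

#' @export
print.consensus_library <- function(x, ...) {
  cat("consensus_library with", length(x), "sequences\n")
  cat(" lengths:", paste(range(nchar(x)), collapse = "-"), "nt;",
      "categories:", paste(unique(attr(x, "category")), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.consensus_library` <- function(x, i) {
  y <- unclass(x)[i]
  structure(y, category = attr(x, "category")[if (is.character(i)) match(i, names(x)) else i],
            class = "consensus_library")
}

.open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a FASTA file into a consensus library
#'
#' Multi-line FASTA is accepted; order is preserved; lowercase is uppercased
#' and `U` becomes `T`.
#'
#' @param path FASTA file (optionally gzipped).
#' @param category category assigned to every record (see
#'   [consensus_library()]).
#' @return a `consensus_library`.
#' @export
read_fasta <- function(path, category = "TE") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0) stop("no FASTA records in ", path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  consensus_library(seqs, category = category)
}

#' Write a consensus library (or any named sequence set) to FASTA
#'
#' @param x `consensus_library` or named character vector.
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(as.character(x), names(x)))
  Biostrings::writeXStringSet(ss, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read small-RNA reads from a 4-line-record FASTQ file
#'
#' The strict 4-line dialect is enforced (no wrapped records). Sequences are
#' uppercased with `U` transliterated to `T`; qualities are Sanger Phred+33.
#' A record whose quality length differs from its sequence length, or whose
#' header lines are malformed, raises an error naming the record index.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return a data.frame with columns `id`, `seq`, `qual` (one row per read).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .open_text(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  n <- length(lines) / 4
  if (n == 0) return(data.frame(id = character(), seq = character(), qual = character()))
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seq <- toupper(chartr("Uu", "Tt", lines[seq(2, by = 4, length.out = n)]))
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], " in ", path,
                        ": missing '@'/'+' header")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " in ", path,
         ": sequence and quality lengths differ")
  }
  id <- sub("\\s.*$", "", substring(hdr, 2))
  bad <- which(!nzchar(id))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], " in ", path, ": empty id")
  data.frame(id = id, seq = seq, qual = qual)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  con <- .open_text(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

## Phred+33 decoding: list of integer vectors, one per read.
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

phred_string <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}
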