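#' Size-class calling and per-feature counting
#'
#' Accumulates alignment weights per (feature, size-class, strand) for one
#' sample. The size class is called from the read length: siRNA at exactly
#' 21 nt, piRNA at 23-29 nt, `"other"` otherwise (excluded from siRNA and
#' piRNA totals downstream).
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param sample sample name recorded in the output.
#' @return data.frame `sample`, `feature`, `class`, `strand`, `raw`
#'   (weighted counts).
#' @export
classify_and_count <- function(alignments, sample = "sample") {
  if (nrow(alignments) == 0) {
    return(data.frame(sample = character(), feature = character(),
                      class = character(), strand = character(),
                      raw = numeric()))
  }
  cls <- size_class_of(alignments$length)
  key <- interaction(alignments$feature, cls, alignments$strand, drop = TRUE,
                     sep = "\r")
  raw <- tapply(alignments$weight, key, sum)
  parts <- do.call(rbind, strsplit(names(raw), "\r", fixed = TRUE))
  out <- data.frame(sample = sample, feature = parts[, 1], class = parts[, 2],
                    strand = parts[, 3], raw = as.numeric(raw))
  out <- out[order(out$feature, out$class, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-sample count matrix
#'
#' Binds per-sample count tables from [classify_and_count()] with the
#' per-sample normalization denominators (by default the number of retained
#' reads that map anywhere in the analysis references).
#'
#' @param counts data.frame (or list of data.frames, rbind-ed) with columns
#'   `sample`, `feature`, `class`, `strand`, `raw`.
#' @param denominators named numeric vector, one positive entry per sample.
#' @return object of class `count_matrix` with elements `counts` (gains
#'   `cpm` and `absent` columns after [normalize_and_floor()]),
#'   `denominators`, and `floor_cpm` (NULL until floored).
#' @export
count_matrix <- function(counts, denominators) {
  if (is.list(counts) && !is.data.frame(counts)) counts <- do.call(rbind, counts)
  stopifnot(all(c("sample", "feature", "class", "strand", "raw") %in% names(counts)))
  if (any(counts$raw < 0) || any(!is.finite(counts$raw))) {
    stop("raw counts must be finite and non-negative")
  }
  miss <- setdiff(unique(counts$sample), names(denominators))
  if (length(miss)) stop("no denominator for sample(s): ", paste(miss, collapse = ", "))
  structure(list(counts = counts, denominators = denominators,
                 floor_cpm = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(unique(x$counts$sample)), "sample(s),",
      length(unique(x$counts$feature)), "feature(s)\n")
  if (!is.null(x$floor_cpm)) {
    cat(" CPM-normalized, floor", x$floor_cpm, "CPM;",
        sum(x$counts$absent), "entries floored-absent\n")
  }
  invisible(x)
}

#' CPM normalization and the low-expression floor
#'
#' Computes `cpm = raw * 1e6 / denominator[sample]` per cell, then applies
#' the low-expression floor: for each (sample, feature, class), if the CPM
#' summed over both strands is below `floor_cpm` the entry is marked absent
#' for that sample (distinct from a CPM of zero; downstream comparisons skip
#' features absent in all samples compared and treat one-sided absences as
#' zero). A feature at exactly the floor is retained.
#'
#' @param cm a `count_matrix`.
#' @param floor_cpm threshold in CPM; entries strictly below it are
#'   discarded (default 25).
#' @return the `count_matrix` with `cpm` and `absent` columns filled in.
#' @export
normalize_and_floor <- function(cm, floor_cpm = 25) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$denominators <= 0)) stop("normalization denominators must be > 0")
  counts <- cm$counts
  counts$cpm <- counts$raw * 1e6 / cm$denominators[counts$sample]
  key <- interaction(counts$sample, counts$feature, counts$class, drop = TRUE)
  strand_sum <- tapply(counts$cpm, key, sum)
  counts$absent <- as.numeric(strand_sum[key]) < floor_cpm
  cm$counts <- counts
  cm$floor_cpm <- floor_cpm
  cm
}

#' Strand-summed CPM for one sample and size class
#'
#' @param cm a floored `count_matrix` (see [normalize_and_floor()]).
#' @param sample sample name.
#' @param class `"siRNA"` or `"piRNA"`.
#' @param features features to report (default: all features present in the
#'   matrix for any sample).
#' @return data.frame `feature`, `cpm` (0 for features without counts),
#'   `absent` (TRUE when floored out or entirely uncounted).
#' @export
feature_cpm <- function(cm, sample, class, features = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$floor_cpm)) stop("call normalize_and_floor() first")
  if (!sample %in% names(cm$denominators)) stop("unknown sample: ", sample)
  counts <- cm$counts[cm$counts$sample == sample & cm$counts$class == class, ]
  if (is.null(features)) features <- sort(unique(cm$counts$feature))
  cpm <- tapply(counts$cpm, counts$feature, sum)
  absent <- tapply(counts$absent, counts$feature, any)
  out <- data.frame(feature = features,
                    cpm = as.numeric(cpm[features]),
                    absent = as.logical(absent[features]))
  out$absent[is.na(out$absent)] <- TRUE
  out$cpm[is.na(out$cpm)] <- 0
  out
}

#' Write a count matrix as TSV
#'
#' One row per (sample, feature, class, strand) with raw and CPM blocks;
#' numbers are serialized with 7 significant digits so a write/read
#' round trip agrees within 1e-6 relative. [read_count_table()] parses the
#' file back.
#'
#' @param cm a `count_matrix` (floored or not).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (is.null(counts$cpm)) {
    counts$cpm <- rep(NA_real_, nrow(counts))
    counts$absent <- rep(NA, nrow(counts))
  }
  counts$raw <- signif(counts$raw, 7)
  counts$cpm <- signif(counts$cpm, 7)
  counts$denominator <- cm$denominators[counts$sample]
  cols <- c("sample", "feature", "class", "strand", "raw", "cpm", "absent",
            "denominator")
  tryCatch(
    write.table(counts[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE),
    error = function(e) stop("cannot write count table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a count matrix written by [write_count_table()]
#'
#' @param path TSV path.
#' @return a `count_matrix`.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(sample = "character", feature = "character",
                                  class = "character", strand = "character"))
  den <- tapply(df$denominator, df$sample, function(x) x[1])
  cm <- count_matrix(df[, c("sample", "feature", "class", "strand", "raw")],
                     setNames(as.numeric(den), names(den)))
  if (!all(is.na(df$cpm))) {
    cm$counts$cpm <- df$cpm
    cm$counts$absent <- df$absent
  }
  cm
}
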