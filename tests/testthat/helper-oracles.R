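# Independent oracles, deliberately distinct from the package's code paths.

# Canonical representation of a hit set: sorted "feature|strand|pos|mm"
# strings, one per hit, collapsed to a single string per read.
hitset_key <- function(feature, strand, pos, mm) {
  if (length(feature) == 0) return("")
  paste(sort(paste(feature, strand, pos, mm, sep = "|")), collapse = ";")
}

# Brute-force mapper oracle over a whole read set: a literal sliding Hamming
# scan over both strands of every reference, done with vectorized integer
# comparisons in base R (fully independent of the package's C++ scanner).
# For each (reference, read length) a matrix tW holds every window as a
# column; the mismatch count of a read at every offset is then one
# colSums(tW != read) call. Returns one hitset_key() per read.
oracle_align_keys <- function(reads, library, max_mm) {
  ref_int <- lapply(setNames(as.character(library), names(library)), utf8ToInt)
  wcache <- new.env()
  windows <- function(f, l) {
    key <- paste(f, l)
    if (is.null(wcache[[key]])) {
      x <- ref_int[[f]]
      n_off <- length(x) - l + 1
      wcache[[key]] <- matrix(x[outer(seq_len(l), seq_len(n_off) - 1L, "+")],
                              nrow = l)
    }
    wcache[[key]]
  }
  rc_int <- function(v) {
    out <- v
    out[v == 65L] <- 84L; out[v == 84L] <- 65L   # A <-> T
    out[v == 67L] <- 71L; out[v == 71L] <- 67L   # C <-> G
    rev(out)
  }
  vapply(reads, function(r) {
    q_fwd <- utf8ToInt(r)
    q_rev <- rc_int(q_fwd)
    l <- length(q_fwd)
    feat <- character(); strand <- character(); pos <- integer(); mm <- integer()
    for (f in names(ref_int)) {
      if (l > length(ref_int[[f]])) next
      tw <- windows(f, l)
      for (st in c("+", "-")) {
        d <- colSums(tw != if (st == "+") q_fwd else q_rev)
        keep <- which(d <= max_mm)
        if (length(keep)) {
          feat <- c(feat, rep(f, length(keep)))
          strand <- c(strand, rep(st, length(keep)))
          pos <- c(pos, if (st == "+") keep - 1L else keep + l - 2L)
          mm <- c(mm, d[keep])
        }
      }
    }
    if (!length(mm)) return("")
    sel <- mm == min(mm)
    hitset_key(feat[sel], strand[sel], pos[sel], mm[sel])
  }, character(1), USE.NAMES = FALSE)
}

# Single-read variant returning a data.frame, for fine-grained unit checks.
oracle_align <- function(seq, library, max_mm) {
  len <- nchar(seq)
  hits <- list()
  for (f in names(library)) {
    subject <- Biostrings::DNAString(library[[f]])
    L <- length(subject)
    if (len > L) next
    starts <- seq_len(L - len + 1)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      }
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(q), subject,
                                        starting.at = starts,
                                        with.indels = FALSE)
      hits[[paste(f, strand)]] <- data.frame(
        feature = f, strand = strand,
        five_prime_pos = if (strand == "+") starts - 1L else starts + len - 2L,
        mismatches = mm)
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(hits)
  best <- min(hits$mismatches)
  if (best > max_mm) return(hits[0, , drop = FALSE])
  out <- hits[hits$mismatches == best, , drop = FALSE]
  out <- out[order(out$feature, match(out$strand, c("+", "-")),
                   out$five_prime_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs O(n^2) ping-pong histogram oracle.
oracle_overlap_hist <- function(alignments) {
  pir <- alignments[alignments$length >= 23 & alignments$length <= 29, ,
                    drop = FALSE]
  se <- pir[pir$strand == "+", , drop = FALSE]
  as_ <- pir[pir$strand == "-", , drop = FALSE]
  hist <- setNames(numeric(20), as.character(1:20))
  for (i in seq_len(nrow(se))) {
    for (j in seq_len(nrow(as_))) {
      d <- as_$five_prime_pos[j] - se$five_prime_pos[i] + 1L
      if (d >= 1 && d <= 20) {
        hist[d] <- hist[d] + se$weight[i] * as_$weight[j]
      }
    }
  }
  hist
}

# Definitional Spearman: Pearson correlation of hand-computed average ranks.
oracle_spearman <- function(a, b) {
  avg_rank <- function(x) {
    r <- numeric(length(x))
    for (v in unique(x)) {
      idx <- which(x == v)
      pos <- which(sort(x) == v)
      r[idx] <- mean(pos)
    }
    r
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Random alignment table generator for ping-pong oracle checks.
random_alignments <- function(n, feature = "TE_001", max_pos = 400) {
  data.frame(read_id = sprintf("r%04d", seq_len(n)), feature = feature,
             strand = sample(c("+", "-"), n, replace = TRUE),
             five_prime_pos = sample.int(max_pos, n, replace = TRUE) - 1L,
             length = sample(23:29, n, replace = TRUE),
             mismatches = 0L,
             weight = 1 / sample(1:3, n, replace = TRUE))
}

# Random reads drawn from a library with planted substitutions (plus some
# unrelated random reads), for mapper oracle instances.
random_reads_from <- function(library, n, mutate_up_to = 4) {
  feats <- sample(names(library), n, replace = TRUE)
  out <- character(n)
  for (i in seq_len(n)) {
    if (runif(1) < 0.1) {
      out[i] <- paste(sample(c("A", "C", "G", "T"), sample(20:28, 1),
                             replace = TRUE), collapse = "")
      next
    }
    s <- library[[feats[i]]]
    len <- sample(20:28, 1)
    st <- sample(nchar(s) - len + 1, 1)
    w <- substring(s, st, st + len - 1)
    ch <- strsplit(w, "")[[1]]
    for (p in sample(len, sample(0:mutate_up_to, 1))) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    w <- paste(ch, collapse = "")
    if (runif(1) < 0.5) {
      w <- chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1]]), collapse = ""))
    }
    out[i] <- w
  }
  out
}
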