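#' Simulation profile for one strain library
#'
#' Describes the statistical structure of one simulated ovarian small-RNA
#' library: which TE families reads come from, the siRNA/piRNA size mix, the
#' sense/antisense balance, the fraction of antisense piRNAs engaged in
#' ping-pong amplification (5'-5' overlap of exactly 10 nt with a sense
#' partner), the divergence mix (planted substitutions against the
#' consensus), and the contaminant and below-quality ("junk") fractions.
#'
#' @param te_abundances named numeric vector, expected read fraction per
#'   feature; must sum to 1.
#' @param n_reads total number of reads to emit.
#' @param seed integer seed; fixed seed + fixed library gives byte-identical
#'   output.
#' @param pingpong_fraction fraction of antisense piRNA reads generated as
#'   ping-pong partners of a sense read.
#' @param sense_fraction fraction of TE-derived reads on the sense strand.
#' @param size_distribution named numeric, probability per read length (nt)
#'   over `{21, 23..29}`; must sum to 1.
#' @param divergence_mix named numeric over `{"0","1","2","3","diverged"}`:
#'   fraction of TE reads carrying that many planted substitutions
#'   (`"diverged"` plants 7, guaranteeing failure at the 3-mismatch mapping
#'   stratum); must sum to 1.
#' @param contaminant_fraction fraction of reads drawn verbatim from the
#'   ncRNA contaminant set.
#' @param junk_fraction fraction of reads emitted with qualities below the
#'   80%-of-bases-at-Q20 filter, to exercise quality filtering.
#' @param u1_bias probability that an antisense read 5' end is placed on a
#'   consensus `A` (so the read starts with `U`/`T`); ping-pong pairs inherit
#'   the complementary 10A bias of the sense partner from the same placement.
#' @param adapter 3' adapter appended to every insert (>= 8 nt).
#' @return an object of class `sim_profile` (a validated list).
#' @export
sim_profile <- function(te_abundances,
                        n_reads,
                        seed,
                        pingpong_fraction = 0.5,
                        sense_fraction = 0.5,
                        size_distribution = c("21" = 0.25, "23" = 0.05, "24" = 0.1,
                                              "25" = 0.15, "26" = 0.2, "27" = 0.15,
                                              "28" = 0.07, "29" = 0.03),
                        divergence_mix = c("0" = 0.7, "1" = 0.15, "2" = 0.07,
                                           "3" = 0.03, "diverged" = 0.05),
                        contaminant_fraction = 0.1,
                        junk_fraction = 0,
                        u1_bias = 0.8,
                        adapter = "TGGAATTCTCGGGTGCCAAGG") {
  .check_frac_map <- function(x, what) {
    if (is.null(names(x)) || any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop(what, " must be a named non-negative vector summing to 1")
    }
  }
  .check_frac_map(te_abundances, "te_abundances")
  .check_frac_map(size_distribution, "size_distribution")
  .check_frac_map(divergence_mix, "divergence_mix")
  if (!all(names(divergence_mix) %in% c("0", "1", "2", "3", "diverged"))) {
    stop("divergence_mix names must be in {0,1,2,3,diverged}")
  }
  for (f in c(pingpong_fraction, sense_fraction, contaminant_fraction,
              junk_fraction, u1_bias)) {
    if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1) {
      stop("fractions must be single numbers in [0,1]")
    }
  }
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (nchar(adapter) < 8) stop("adapter must be at least 8 nt")
  structure(list(te_abundances = te_abundances, n_reads = as.integer(n_reads),
                 seed = as.integer(seed), pingpong_fraction = pingpong_fraction,
                 sense_fraction = sense_fraction,
                 size_distribution = size_distribution,
                 divergence_mix = divergence_mix,
                 contaminant_fraction = contaminant_fraction,
                 junk_fraction = junk_fraction, u1_bias = u1_bias,
                 adapter = toupper(adapter)),
            class = "sim_profile")
}

#' Generate a random TE consensus library
#'
#' i.i.d. bases at a target GC content; for sequences of 1 kb or more the
#' realized GC lands within a few percent of the target.
#'
#' @param n_te number of consensus sequences (>= 1).
#' @param length_range integer vector `c(min, max)` of lengths, >= 100 nt.
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed (deterministic output for a fixed seed).
#' @param prefix feature-name prefix.
#' @return a `consensus_library` with features named `<prefix>_001` ...
#' @export
generate_consensus_library <- function(n_te, length_range, gc = 0.4, seed = 1,
                                       prefix = "TE") {
  if (n_te < 1) stop("n_te must be >= 1")
  if (length(length_range) != 2 || any(length_range < 100) ||
      length_range[2] < length_range[1]) {
    stop("length_range must be c(min, max) with min >= 100 and max >= min")
  }
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  withr_seed <- .seed_guard(seed)
  on.exit(withr_seed())
  lens <- .sample_from(seq(length_range[1], length_range[2]), n_te)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s_%03d", prefix, seq_len(n_te))
  consensus_library(seqs, category = "TE")
}

## sample() that never falls into the scalar-expansion trap
.sample_from <- function(x, n, prob = NULL) {
  if (length(x) == 1) rep(x, n) else sample(x, n, replace = TRUE, prob = prob)
}

## Set the RNG to `seed`, return a restorer for the caller's on.exit().
.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Bundled synthetic ncRNA contaminant set
#'
#' Twenty synthetic stand-ins for the rRNA/tRNA/snRNA/miRNA sequences that
#' real libraries are depleted against. These are random sequences generated
#' once under a fixed seed and shipped with the package; they share no
#' biological homology with any real ncRNA (see the file name:
#' `ncrna_synthetic.fasta`).
#'
#' @return a `consensus_library` of category `"ncRNA"`.
#' @export
synthetic_ncrna <- function() {
  read_fasta(system.file("extdata", "ncrna_synthetic.fasta",
                         package = "srnaprofiler", mustWork = TRUE),
             category = "ncRNA")
}

## Sample one 5' plus-strand coordinate (1-based) in [lo, hi], preferring
## positions where chars == "A" with probability bias (the 1U/10A bias is
## created by placement, not by substitution, so planted mismatch counts in
## the truth table stay exact).
.sample_pos <- function(lo, hi, a_pos, bias) {
  if (hi < lo) stop("consensus too short for requested read length")
  if (bias > 0 && runif(1) < bias) {
    cand <- a_pos[a_pos >= lo & a_pos <= hi]
    if (length(cand)) return(if (length(cand) == 1) cand else sample(cand, 1))
  }
  if (lo == hi) lo else sample(lo:hi, 1)
}

## Plant m substitutions at distinct random positions; each changes the base.
.mutate <- function(seqs, m) {
  idx <- which(m > 0)
  if (!length(idx)) return(seqs)
  chars <- strsplit(seqs[idx], "")
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  for (k in seq_along(idx)) {
    s <- chars[[k]]
    pos <- sample(length(s), m[idx[k]])
    for (p in pos) s[p] <- sample(alt[[s[p]]], 1)
    chars[[k]] <- s
  }
  seqs[idx] <- vapply(chars, paste, character(1), collapse = "")
  seqs
}

## Quality strings: non-junk reads get Q30 bases with a 5% sprinkling of Q10
## (so ~95% of bases pass Q20, comfortably above the 80% filter); junk reads
## alternate Q10/Q30 so exactly half the bases pass, guaranteeing rejection.
.qualities <- function(lens, junk) {
  n <- length(lens)
  out <- character(n)
  q30 <- rawToChar(as.raw(63L)); q10 <- rawToChar(as.raw(43L))
  for (i in seq_len(n)) {
    L <- lens[i]
    if (junk[i]) {
      out[i] <- paste(rep(c(q10, q30), length.out = L), collapse = "")
    } else {
      out[i] <- paste(ifelse(runif(L) < 0.95, q30, q10), collapse = "")
    }
  }
  out
}

#' Simulate one strain's small-RNA library with ground truth
#'
#' Emits exactly `profile$n_reads` reads: TE-derived inserts (with planted
#' substitutions, strand choice, ping-pong pairing and 1U/10A placement
#' bias), exact-substring ncRNA contaminants, and optional below-quality
#' junk. Every insert gets the 3' adapter appended and a Phred+33 quality
#' string. The returned truth table has one record per emitted read.
#'
#' Ping-pong pairs are built on the same consensus with the sense 5' end at
#' `s` and the antisense 5' end (plus-strand coordinate) at `s + 9`, i.e. a
#' 5'-5' overlap of exactly 10 nt. Partner sense reads are drawn from the
#' sense read pool, so the realized strand balance matches `sense_fraction`.
#'
#' @param library a `consensus_library` of TE consensuses.
#' @param profile a [sim_profile()].
#' @param ncrna contaminant `consensus_library` (default: the bundled
#'   synthetic set).
#' @param fastq optional path; when given the reads are also written as
#'   FASTQ.
#' @param truth_tsv optional path; when given the truth table is written as
#'   TSV with columns read_id, feature, strand, five_prime_pos, mismatches,
#'   pingpong, contaminant.
#' @return list with `reads` (data.frame id/seq/qual) and `truth`
#'   (data.frame read_id, feature, strand, five_prime_pos (0-based),
#'   mismatches, pingpong, contaminant, junk).
#' @export
simulate_strain_reads <- function(library, profile, ncrna = synthetic_ncrna(),
                                  fastq = NULL, truth_tsv = NULL) {
  stopifnot(inherits(profile, "sim_profile"))
  feats <- names(profile$te_abundances)
  missing_feats <- setdiff(feats, names(library))
  if (length(missing_feats)) {
    stop("features absent from library: ", paste(missing_feats, collapse = ", "))
  }
  max_len <- max(as.integer(names(profile$size_distribution)))
  if (any(nchar(library[feats]) < max_len)) {
    stop("read lengths exceed the shortest consensus length")
  }
  restore <- .seed_guard(profile$seed)
  on.exit(restore())

  n <- profile$n_reads
  n_contam <- round(profile$contaminant_fraction * n)
  n_junk <- round(profile$junk_fraction * n)
  n_te <- n - n_contam - n_junk
  if (n_te < 0) stop("contaminant_fraction + junk_fraction exceed 1")

  sizes <- as.integer(names(profile$size_distribution))
  a_pos <- lapply(as.character(library[feats]),
                  function(s) which(strsplit(s, "")[[1]] == "A"))
  names(a_pos) <- feats

  ## --- TE-derived reads ----------------------------------------------------
  te <- NULL
  if (n_te > 0) {
    feature <- sample(feats, n_te, replace = TRUE, prob = profile$te_abundances)
    len <- .sample_from(sizes, n_te, profile$size_distribution)
    sense <- runif(n_te) < profile$sense_fraction
    mm_key <- sample(names(profile$divergence_mix), n_te, replace = TRUE,
                     prob = profile$divergence_mix)
    mm <- rep(7L, n_te)
    planted <- mm_key != "diverged"
    mm[planted] <- as.integer(mm_key[planted])
    pp <- rep(FALSE, n_te)
    partner_of <- rep(NA_integer_, n_te)

    as_pi <- which(!sense & len >= .PIRNA_RANGE[1])
    flagged <- as_pi[runif(length(as_pi)) < profile$pingpong_fraction]
    se_pi <- which(sense & len >= .PIRNA_RANGE[1])
    npair <- min(length(flagged), length(se_pi))
    if (npair > 0) {
      flagged <- flagged[seq_len(npair)]
      partners <- se_pi[seq_len(npair)]
      pp[flagged] <- TRUE
      pp[partners] <- TRUE
      partner_of[flagged] <- partners
      # partner must live on the same consensus
      feature[partners] <- feature[flagged]
    }

    pos5 <- integer(n_te)  # 1-based plus-strand coordinate of the 5' end
    for (i in seq_len(n_te)) {
      L <- nchar(library[[feature[i]]])
      if (sense[i]) {
        if (pp[i]) next  # placed via its antisense partner below
        pos5[i] <- if (L == len[i]) 1L else sample(seq_len(L - len[i] + 1), 1)
      } else {
        ap <- a_pos[[feature[i]]]
        if (pp[i]) {
          j <- partner_of[i]
          lo <- max(len[i], 10L)
          hi <- min(L, L - len[j] + 9L)
          pos5[i] <- .sample_pos(lo, hi, ap, profile$u1_bias)
          pos5[j] <- pos5[i] - 9L
        } else {
          pos5[i] <- .sample_pos(len[i], L, ap, profile$u1_bias)
        }
      }
    }

    seq_plus_start <- ifelse(sense, pos5, pos5 - len + 1L)
    window <- substring(as.character(library[feature]), seq_plus_start,
                        seq_plus_start + len - 1L)
    insert <- ifelse(sense, window, revcomp(window))
    insert <- .mutate(insert, mm)
    te <- data.frame(feature = feature, strand = ifelse(sense, "+", "-"),
                     five_prime_pos = pos5 - 1L, mismatches = mm,
                     pingpong = pp, contaminant = FALSE, junk = FALSE,
                     insert = insert)
  }

  ## --- contaminants: exact substrings of the ncRNA set --------------------
  contam <- NULL
  if (n_contam > 0) {
    src <- sample(names(ncrna), n_contam, replace = TRUE)
    len <- .sample_from(sizes, n_contam, profile$size_distribution)
    L <- nchar(as.character(ncrna[src]))
    start <- vapply(seq_len(n_contam), function(i) {
      if (L[i] <= len[i]) 1L else sample(seq_len(L[i] - len[i] + 1), 1L)
    }, integer(1))
    insert <- substring(as.character(ncrna[src]), start, start + len - 1L)
    contam <- data.frame(feature = src, strand = "+",
                         five_prime_pos = start - 1L, mismatches = 0L,
                         pingpong = FALSE, contaminant = TRUE, junk = FALSE,
                         insert = insert)
  }

  ## --- junk: random sequence, qualities guaranteed to fail the filter -----
  junk <- NULL
  if (n_junk > 0) {
    len <- .sample_from(sizes, n_junk, profile$size_distribution)
    insert <- vapply(len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    junk <- data.frame(feature = NA_character_, strand = NA_character_,
                       five_prime_pos = NA_integer_, mismatches = NA_integer_,
                       pingpong = FALSE, contaminant = FALSE, junk = TRUE,
                       insert = insert)
  }

  truth <- rbind(te, contam, junk)
  truth <- truth[sample(nrow(truth)), , drop = FALSE]
  truth$read_id <- sprintf("read_%06d", seq_len(nrow(truth)))
  rownames(truth) <- NULL

  full_seq <- paste0(truth$insert, profile$adapter)
  qual <- .qualities(nchar(full_seq), truth$junk)
  reads <- data.frame(id = truth$read_id, seq = full_seq, qual = qual)
  truth <- truth[, c("read_id", "feature", "strand", "five_prime_pos",
                     "mismatches", "pingpong", "contaminant", "junk", "insert")]

  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth_tsv)) {
    write.table(truth[, c("read_id", "feature", "strand", "five_prime_pos",
                          "mismatches", "pingpong", "contaminant")],
                truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}
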