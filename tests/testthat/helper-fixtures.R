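# Shared fixtures, built in code.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

q_string <- function(phred, len) {
  vapply(len, function(L) strrep(intToUtf8(phred + 33L), L), character(1))
}

small_library <- function(seed = 3, n = 5, lengths = c(800, 1200)) {
  generate_consensus_library(n, lengths, gc = 0.4, seed = seed)
}

# Ten hand-enumerated reads exercising every preprocessing stage:
# all 10 carry the full adapter; 3 are too short (<= 18 nt inserts),
# 2 fail the 80%-at-Q20 filter, 1 is an exact ncRNA substring, 4 are clean.
preprocess_fixture <- function(ncrna) {
  insert_ok <- c("ACGTACGTACGTACGTACGTACGTA",     # 25 nt clean
                 "TTGACCGTTGACCGTTGACCGTT",       # 23 nt clean
                 "CACGACGACTTACGATCCGTAGCAT",     # 25 nt clean
                 "GTTGACATATTTCCGAGGAGCCA")       # 23 nt clean
  insert_short <- c("ACGTACGTACGTACGTAC",         # 18 nt (boundary: removed)
                    "ACGTACGTACGTACG",            # 15 nt
                    "ACGTACGTAC")                 # 10 nt
  insert_lowq <- c("AGGTTACGGATCCATGGCAT",        # 20 nt, 15/20 at Q30 (75%)
                   "CCATTAGGCATGGATCCGTAA")       # 21 nt, all Q10
  insert_ncrna <- substring(ncrna[["tRNA_synthetic_01"]], 11, 34)  # 24 nt
  inserts <- c(insert_ok, insert_short, insert_lowq, insert_ncrna)
  seqs <- paste0(inserts, ADAPTER)
  qual <- character(10)
  for (i in c(1:7, 10)) qual[i] <- q_string(30, nchar(seqs[i]))
  qual[8] <- paste0(q_string(30, 15), q_string(10, 5),
                    q_string(30, nchar(ADAPTER)))
  qual[9] <- q_string(10, nchar(seqs[9]))
  data.frame(id = sprintf("fx_%02d", 1:10), seq = seqs, qual = qual)
}

# One simulated strain used by several modules' tests.
sim_strain <- function(library, n_reads = 4000, seed = 11,
                       contaminant_fraction = 0.1, ...) {
  ab <- setNames(rep(1 / length(library), length(library)), names(library))
  prof <- sim_profile(ab, n_reads = n_reads, seed = seed,
                      contaminant_fraction = contaminant_fraction, ...)
  simulate_strain_reads(library, prof)
}
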