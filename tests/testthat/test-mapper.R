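test_that("coordinate conventions match the plus-strand 5' definition", {
  lib <- small_library(seed = 4, n = 1, lengths = c(300, 300))
  s <- lib[[1]]

  sense <- substring(s, 11, 35)  # 0-based positions 10..34
  hit <- align_read(sense, lib, max_mismatches = 0)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$five_prime_pos, 10L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$weight, 1)

  anti <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(substring(s, 1, 25), "")[[1]]), collapse = ""))
  hit <- align_read(anti, lib, max_mismatches = 0)
  expect_equal(hit$strand, "-")
  expect_equal(hit$five_prime_pos, 24L)  # 5' of a minus read = right edge
})

test_that("multi-mapping weights sum to one per read", {
  dup <- consensus_library(c(te_a = strrep("ACGGTTCAACGGATCCTAGGACTA", 20),
                             te_b = strrep("ACGGTTCAACGGATCCTAGGACTA", 20)))
  read <- substring(dup[[1]], 31, 55)
  hits <- align_read(read, dup, max_mismatches = 1)
  expect_gt(nrow(hits), 1L)
  expect_equal(sum(hits$weight), 1)
  expect_true(all(hits$mismatches == min(hits$mismatches)))  # best stratum only
})

test_that("N always counts as a mismatch and bad characters error", {
  lib <- consensus_library(c(te = paste0(strrep("ACGT", 30))))
  read <- substring(lib[[1]], 1, 20)
  n_read <- paste0("N", substring(read, 2))
  expect_equal(align_read(read, lib, 0)$mismatches[1], 0L)
  expect_equal(nrow(align_read(n_read, lib, 0)), 0L)        # N breaks perfect
  expect_equal(min(align_read(n_read, lib, 1)$mismatches), 1L)
  expect_error(map_reads(data.frame(id = "x", seq = "ACGTXACGTACGTACGTACG"),
                         lib), "characters")
})

test_that("hit sets equal the brute-force sliding Hamming oracle", {
  set.seed(401)
  for (inst in 1:4) {
    lib <- generate_consensus_library(3, c(150, 400), gc = 0.45,
                                      seed = 500 + inst)
    reads <- random_reads_from(lib, 60)
    mm <- inst %% 4
    got <- map_reads(reads, lib, max_mismatches = mm)$alignments
    for (i in seq_along(reads)) {
      want <- oracle_align(reads[i], lib, mm)
      mine <- got[got$read_id == sprintf("read_%06d", i),
                  c("feature", "strand", "five_prime_pos", "mismatches")]
      rownames(mine) <- NULL
      if (is.null(want) || nrow(want) == 0) {
        expect_equal(nrow(mine), 0L)
      } else {
        expect_equal(mine, want)
      }
    }
  }
})

test_that("strand symmetry: reverse-complementing read and library swaps strands", {
  lib <- small_library(seed = 14, n = 2, lengths = c(200, 300))
  rc_lib <- consensus_library(setNames(
    chartr("ACGT", "TGCA",
           vapply(as.character(lib),
                  function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                  character(1))), names(lib)))
  reads <- random_reads_from(lib, 30)
  rc_reads <- chartr("ACGT", "TGCA",
                     vapply(reads, function(s)
                       paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                       character(1)))
  a <- map_reads(reads, lib, 2)$alignments
  b <- map_reads(unname(rc_reads), rc_lib, 2)$alignments
  key <- function(x) x[order(x$read_id, x$feature, x$mismatches),
                       c("read_id", "feature", "mismatches")]
  expect_equal(sort(table(a$strand)), sort(table(b$strand)))
  expect_equal(unname(as.matrix(key(a))), unname(as.matrix(key(b))))
})

test_that("mapped fraction matches the simulated contaminant load", {
  lib <- small_library(seed = 11, n = 4, lengths = c(500, 800))
  sim <- sim_strain(lib, n_reads = 2000, seed = 11,
                    contaminant_fraction = 0.15,
                    divergence_mix = c("0" = 0.9, "1" = 0.1))
  trimmed <- trim_adapter(sim$reads, ADAPTER)
  m <- map_reads(trimmed, lib, max_mismatches = 1)
  expect_equal(m$n_mapped / m$n_reads, 1 - 0.15, tolerance = 0.02 / 0.85)
  # determinism: identical call gives identical ordering
  m2 <- map_reads(trimmed, lib, max_mismatches = 1)
  expect_identical(m$alignments, m2$alignments)
})

test_that("degenerate inputs are handled", {
  lib <- small_library(seed = 2, n = 1, lengths = c(200, 200))
  empty <- map_reads(data.frame(id = character(), seq = character()), lib)
  expect_equal(nrow(empty$alignments), 0L)
  expect_equal(empty$n_mapped, 0L)
  expect_error(map_reads(data.frame(id = "s", seq = "ACGTACGTACGT"), lib),
               "15 nt")
  expect_error(map_reads(data.frame(id = "s", seq = strrep("ACGT", 5)), lib,
                         max_mismatches = 4), "max_mismatches")
})
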