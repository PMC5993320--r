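test_that("consensus generation honours length, GC and determinism", {
  lib <- generate_consensus_library(1, c(749, 749), gc = 0.5, seed = 1)
  expect_equal(nchar(lib[[1]]), 749)

  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_consensus_library(5, c(200, 400), seed = 7), f1)
  write_fasta(generate_consensus_library(5, c(200, 400), seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))

  lib <- generate_consensus_library(3, c(1000, 1000), gc = 0.25, seed = 3)
  gc <- vapply(as.character(lib), function(s) {
    b <- table(strsplit(s, "")[[1]])
    (sum(b["G"], na.rm = TRUE) + sum(b["C"], na.rm = TRUE)) / nchar(s)
  }, numeric(1))
  expect_gte(mean(gc), 0.20)
  expect_lte(mean(gc), 0.30)

  expect_error(generate_consensus_library(0, c(200, 300)), "n_te")
  expect_error(generate_consensus_library(2, c(50, 80)), "length_range")
  expect_error(generate_consensus_library(2, c(200, 300), gc = 1.2), "gc")
})

test_that("every ping-pong antisense read has a 10-nt-overlap sense partner", {
  lib <- small_library(seed = 5, n = 2, lengths = c(500, 500))
  ab <- setNames(c(0.5, 0.5), names(lib))
  # sense majority guarantees a partner for every flagged antisense read
  prof <- sim_profile(ab, n_reads = 200, seed = 11, pingpong_fraction = 1,
                      sense_fraction = 0.6, contaminant_fraction = 0,
                      size_distribution = c("24" = 0.3, "25" = 0.4, "26" = 0.3))
  tr <- simulate_strain_reads(lib, prof)$truth
  as_ <- tr[tr$strand == "-", ]
  se <- tr[tr$strand == "+", ]
  expect_gt(nrow(as_), 0)
  for (i in seq_len(nrow(as_))) {
    partners <- se$feature == as_$feature[i] &
      se$five_prime_pos == as_$five_prime_pos[i] - 9L
    expect_true(any(partners), label = paste("partner for antisense row", i))
  }
  expect_true(all(tr$pingpong[tr$strand == "-"]))
})

test_that("contaminant_fraction = 0 yields no contaminant truth records", {
  lib <- small_library(seed = 6, n = 2, lengths = c(300, 300))
  sim <- sim_strain(lib, n_reads = 300, seed = 2, contaminant_fraction = 0)
  expect_false(any(sim$truth$contaminant))
})

test_that("divergence mix is recovered in the truth table", {
  lib <- small_library(seed = 8, n = 3, lengths = c(600, 900))
  ab <- setNames(rep(1 / 3, 3), names(lib))
  prof <- sim_profile(ab, n_reads = 5000, seed = 4, contaminant_fraction = 0,
                      divergence_mix = c("0" = 0.1, "3" = 0.9))
  tr <- simulate_strain_reads(lib, prof)$truth
  expect_equal(mean(tr$mismatches == 0), 0.10, tolerance = 0.02 / 0.10)
})

test_that("simulation is deterministic and conserves abundance mass", {
  lib <- small_library(seed = 9, n = 4, lengths = c(400, 700))
  ab <- setNames(c(0.4, 0.3, 0.2, 0.1), names(lib))
  prof <- sim_profile(ab, n_reads = 10000, seed = 21,
                      contaminant_fraction = 0)
  a <- simulate_strain_reads(lib, prof)
  b <- simulate_strain_reads(lib, prof)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)

  obs <- table(factor(a$truth$feature, levels = names(ab))) / nrow(a$truth)
  se3 <- 3 * sqrt(ab * (1 - ab) / nrow(a$truth))
  expect_true(all(abs(as.numeric(obs) - ab) <= se3))

  # truth invariants: one record per read, positions within bounds
  expect_equal(nrow(a$truth), prof$n_reads)
  expect_true(all(a$truth$five_prime_pos >= 0 &
                    a$truth$five_prime_pos < nchar(lib[a$truth$feature])))
})

test_that("profile validation rejects malformed fraction maps", {
  ab <- c(TE_001 = 0.6, TE_002 = 0.5)
  expect_error(sim_profile(ab, n_reads = 10, seed = 1), "sum")
  expect_error(sim_profile(c(TE_001 = 1), n_reads = 0, seed = 1), "n_reads")
  expect_error(sim_profile(c(TE_001 = 1), n_reads = 10, seed = 1,
                           adapter = "ACGT"), "adapter")
  lib <- small_library(seed = 2, n = 1, lengths = c(300, 300))
  prof <- sim_profile(c(missing_feature = 1), n_reads = 10, seed = 1)
  expect_error(simulate_strain_reads(lib, prof), "absent from library")
})
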