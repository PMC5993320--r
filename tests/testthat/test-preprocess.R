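test_that("adapter trimming returns the 5' insert", {
  insert <- "ACGTACGTACGTACGTACGTA"  # 21 nt
  reads <- data.frame(id = "r1", seq = paste0(insert, ADAPTER),
                      qual = q_string(30, nchar(insert) + nchar(ADAPTER)))
  out <- trim_adapter(reads, ADAPTER)
  expect_equal(out$seq, insert)
  expect_equal(nchar(out$qual), nchar(insert))

  # read equal to the adapter: empty insert, discarded
  r <- data.frame(id = "r2", seq = ADAPTER, qual = q_string(30, nchar(ADAPTER)))
  expect_equal(nrow(trim_adapter(r, ADAPTER)), 0L)

  # no adapter: discarded by default, kept on request
  r <- data.frame(id = "r3", seq = "ACACACACACACACACACACACAC",
                  qual = q_string(30, 24))
  expect_equal(nrow(trim_adapter(r, ADAPTER)), 0L)
  expect_equal(trim_adapter(r, ADAPTER, keep_untrimmed = TRUE)$seq, r$seq)

  # partial 3' overlap (>= 5 nt) and one mismatch are tolerated
  r <- data.frame(id = "r4", seq = paste0(insert, substr(ADAPTER, 1, 6)),
                  qual = q_string(30, nchar(insert) + 6))
  expect_equal(trim_adapter(r, ADAPTER)$seq, insert)
  mis <- paste0(insert, sub("G", "T", substr(ADAPTER, 1, 8)))
  r <- data.frame(id = "r5", seq = mis, qual = q_string(30, nchar(mis)))
  expect_equal(trim_adapter(r, ADAPTER)$seq, insert)

  expect_error(trim_adapter(reads, "ACG"), "min_overlap")
})

test_that("simulated trimmed lengths equal the truth insert lengths", {
  lib <- small_library(seed = 12, n = 3, lengths = c(400, 600))
  sim <- sim_strain(lib, n_reads = 1000, seed = 7, contaminant_fraction = 0)
  out <- trim_adapter(sim$reads, ADAPTER)
  expect_equal(nrow(out), 1000L)
  expect_equal(nchar(out$seq),
               nchar(sim$truth$insert[match(out$id, sim$truth$read_id)]))
})

test_that("length filter is strict and quality filter is inclusive at 80%", {
  ncrna <- synthetic_ncrna()
  r18 <- data.frame(id = "len18", seq = strrep("ACT", 6), qual = q_string(40, 18))
  expect_equal(filter_and_subtract(r18)$report[["retained"]], 0L)
  r19 <- data.frame(id = "len19", seq = paste0(strrep("ACT", 6), "A"),
                    qual = q_string(40, 19))
  expect_equal(filter_and_subtract(r19)$report[["retained"]], 1L)

  # 15/20 bases at Q20 (75%) -> removed; 16/20 (exactly 80%) -> kept
  seq20 <- strrep("ACGTA", 4)
  q75 <- paste0(q_string(20, 15), q_string(10, 5))
  q80 <- paste0(q_string(20, 16), q_string(10, 4))
  expect_equal(filter_and_subtract(
    data.frame(id = "q75", seq = seq20, qual = q75), min_len = 10)$report[["retained"]], 0L)
  expect_equal(filter_and_subtract(
    data.frame(id = "q80", seq = seq20, qual = q80), min_len = 10)$report[["retained"]], 1L)

  # ncRNA subtraction is perfect-match, either strand
  frag <- substring(ncrna[[3]], 5, 30)
  reads <- data.frame(id = c("fwd", "rev", "clean"),
                      seq = c(frag,
                              chartr("ACGT", "TGCA",
                                     paste(rev(strsplit(frag, "")[[1]]), collapse = "")),
                              strrep("ACCGT", 5)),
                      qual = q_string(30, c(26, 26, 25)))
  fs <- filter_and_subtract(reads, ncrna = ncrna)
  expect_equal(fs$reads$id, "clean")
})

test_that("the ten-read fixture walks every stage of the ledger", {
  ncrna <- synthetic_ncrna()
  fx <- preprocess_fixture(ncrna)
  pp <- preprocess_reads(fx, adapter = ADAPTER, ncrna = ncrna)
  expect_equal(unname(pp$report),
               c(10L, 10L, 7L, 5L, 4L, 4L))
  expect_equal(names(pp$report),
               c("input", "adapter_trimmed", "length_pass", "quality_pass",
                 "ncrna_subtracted", "retained"))
  expect_equal(pp$reads$id, sprintf("fx_%02d", 1:4))  # order-stable
  # monotone non-increasing ledger
  expect_true(all(diff(pp$report) <= 0))
})

test_that("ncRNA subtraction is idempotent and empty libraries warn", {
  ncrna <- synthetic_ncrna()
  fx <- preprocess_fixture(ncrna)
  once <- preprocess_reads(fx, adapter = ADAPTER, ncrna = ncrna)$reads
  twice <- filter_and_subtract(once, ncrna = ncrna)
  expect_identical(twice$reads, once)
  expect_warning(filter_and_subtract(once, ncrna = ncrna[0]), "empty")
  expect_silent(filter_and_subtract(once, ncrna = NULL))
})
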