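two_sample_cm <- function(raw_a, raw_b, denom_a = 1e6, denom_b = 1e6,
                          floor = 0) {
  feats <- names(raw_a)
  counts <- rbind(
    data.frame(sample = "A", feature = feats, class = "piRNA", strand = "+",
               raw = unname(raw_a)),
    data.frame(sample = "B", feature = feats, class = "piRNA", strand = "+",
               raw = unname(raw_b)))
  normalize_and_floor(count_matrix(counts, c(A = denom_a, B = denom_b)),
                      floor_cpm = floor)
}

test_that("fold changes use the pseudocount and inclusive threshold", {
  cm <- two_sample_cm(c(te1 = 999, te2 = 55), c(te1 = 99, te2 = 55))
  rep <- fold_change_and_call(cm, "A", "B", threshold = 10, eps = 1)
  tab <- rep$table
  expect_equal(tab$fold[tab$feature == "te1"], 10)        # (999+1)/(99+1)
  expect_equal(tab$call[tab$feature == "te1"], "higher_in_a")  # >= is a call
  expect_equal(tab$fold[tab$feature == "te2"], 1)
  expect_equal(tab$call[tab$feature == "te2"], "none")
})

test_that("swapping samples inverts folds and exchanges call labels", {
  set.seed(90)
  raw_a <- setNames(rexp(30, 1 / 200), sprintf("te%02d", 1:30))
  raw_b <- setNames(rexp(30, 1 / 200), sprintf("te%02d", 1:30))
  cm <- two_sample_cm(raw_a, raw_b)
  ab <- fold_change_and_call(cm, "A", "B")
  ba <- fold_change_and_call(cm, "B", "A")
  expect_equal(ab$table$fold, 1 / ba$table$fold)
  expect_equal(ab$called$higher_in_a, ba$called$higher_in_b)
  expect_equal(ab$called$higher_in_b, ba$called$higher_in_a)

  # threshold monotonicity
  loose <- fold_change_and_call(cm, "A", "B", threshold = 2)
  tight <- fold_change_and_call(cm, "A", "B", threshold = 10)
  expect_true(all(tight$called$higher_in_a %in% loose$called$higher_in_a))
})

test_that("floored features are skipped or treated as zero", {
  cm <- two_sample_cm(c(lost = 4000, dead = 3, ok = 5000),
                      c(lost = 3, dead = 4, ok = 5000),
                      denom_a = 1e6, denom_b = 1e6, floor = 25)
  rep <- fold_change_and_call(cm, "A", "B")
  expect_false("dead" %in% rep$table$feature)   # absent in both: skipped
  lost <- rep$table[rep$table$feature == "lost", ]
  expect_equal(lost$cpm_b, 0)                   # one-sided absence -> 0 CPM
  expect_equal(lost$call, "higher_in_a")
})

test_that("set intersections enumerate all exclusive regions", {
  out <- intersect_sets(list(X = c("A", "B", "C"), Y = c("B", "C", "D")))
  expect_equal(nrow(out), 3L)
  shared <- out[out$region == "X&Y", ]
  expect_equal(shared$count, 2L)
  expect_equal(shared$members[[1]], c("B", "C"))
  expect_equal(out$count[out$region == "X"], 1L)

  same <- intersect_sets(list(a = c("p", "q"), b = c("p", "q"),
                              c = c("p", "q")))
  expect_equal(same$count[same$region == "a&b&c"], 2L)
  expect_true(all(same$count[same$region != "a&b&c"] == 0L))
  expect_error(intersect_sets(list(c("A"))), "named list")
})

test_that("Spearman matches its average-rank definition", {
  expect_equal(spearman_profile(1:10, (1:10)^3)$rho, 1.0)
  expect_equal(spearman_profile(1:10, rev(1:10))$rho, -1.0)
  set.seed(91)
  a <- sample(c(1, 2, 2, 3, 5, 5, 5, 8), 8)
  b <- sample(c(0, 0, 4, 4, 6, 7, 7, 9), 8)
  expect_equal(spearman_profile(a, b)$rho, oracle_spearman(a, b))
  # invariance under strictly monotone transforms
  expect_equal(spearman_profile(exp(a), b)$rho, spearman_profile(a, b)$rho)
  # degenerate cases flagged, not errored
  expect_true(spearman_profile(rep(1, 5), 1:5)$degenerate)
  expect_error(spearman_profile(1:4, 1:5), "equal length")
})

test_that("planted strain asymmetries are called exactly", {
  lib <- generate_consensus_library(20, c(300, 500), seed = 92)
  deficits <- names(lib)[1:4]
  w <- setNames(rep(1, 20), names(lib))
  w_m <- w; w_m[deficits] <- 1 / 30
  mk <- function(weights, seed) {
    prof <- sim_profile(weights / sum(weights), n_reads = 8000, seed = seed,
                        contaminant_fraction = 0,
                        divergence_mix = c("0" = 1))
    sim <- simulate_strain_reads(lib, prof)
    trim_adapter(sim$reads, ADAPTER)
  }
  reads <- list(P = mk(w, 1), M = mk(w_m, 2))
  counts <- list(); denom <- c(P = 0, M = 0)
  for (s in names(reads)) {
    m <- map_reads(reads[[s]], lib, 0)
    counts[[s]] <- classify_and_count(m$alignments, s)
    denom[s] <- m$n_mapped
  }
  cm <- normalize_and_floor(count_matrix(counts, denom), 25)
  rep <- fold_change_and_call(cm, "P", "M", class = "piRNA", threshold = 10)
  expect_setequal(rep$called$higher_in_a, deficits)
  expect_length(rep$called$higher_in_b, 0)
  expect_false(rep$spearman_degenerate)
})
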