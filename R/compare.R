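#' Pairwise fold changes and asymmetry calls
#'
#' Compares strand-summed CPM of one size class between two samples.
#' Features floored-absent in both samples are skipped; a one-sided absence
#' contributes 0 CPM. Folds use a pseudocount on both terms,
#' `fold = (cpm_a + eps) / (cpm_b + eps)`, so they stay finite; a feature is
#' called `higher_in_a` when `fold >= threshold` and `higher_in_b` when
#' `fold <= 1/threshold` (inclusive, so a feature exactly on the 10-fold
#' line counts as exceeding it).
#'
#' @param cm a floored `count_matrix`.
#' @param sample_a,sample_b sample names.
#' @param class `"siRNA"` or `"piRNA"`.
#' @param threshold fold-change call threshold (default 10).
#' @param eps pseudocount in CPM (default 1).
#' @return object of class `asymmetry_report`: list with `table`
#'   (data.frame feature, cpm_a, cpm_b, fold, call), `called` (features
#'   called either way, split by direction), `spearman_r` over features
#'   expressed in at least one sample, `samples`, `class`, `threshold`,
#'   `eps`.
#' @export
fold_change_and_call <- function(cm, sample_a, sample_b, class = "piRNA",
                                 threshold = 10, eps = 1) {
  stopifnot(class %in% c("siRNA", "piRNA"), threshold > 0, eps >= 0)
  a <- feature_cpm(cm, sample_a, class)
  b <- feature_cpm(cm, sample_b, class)
  keep <- !(a$absent & b$absent)
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  cpm_a <- ifelse(a$absent, 0, a$cpm)
  cpm_b <- ifelse(b$absent, 0, b$cpm)
  fold <- (cpm_a + eps) / (cpm_b + eps)
  call <- rep("none", length(fold))
  call[fold >= threshold] <- "higher_in_a"
  call[fold <= 1 / threshold] <- "higher_in_b"
  tab <- data.frame(feature = a$feature, cpm_a = cpm_a, cpm_b = cpm_b,
                    fold = fold, call = call)
  r <- spearman_profile(cpm_a, cpm_b)
  structure(list(table = tab,
                 called = list(higher_in_a = tab$feature[call == "higher_in_a"],
                               higher_in_b = tab$feature[call == "higher_in_b"]),
                 spearman_r = r$rho, spearman_degenerate = r$degenerate,
                 samples = c(a = sample_a, b = sample_b), class = class,
                 threshold = threshold, eps = eps),
            class = "asymmetry_report")
}

#' @export
print.asymmetry_report <- function(x, ...) {
  cat(sprintf("asymmetry report (%s): %s vs %s, %d features\n", x$class,
              x$samples[["a"]], x$samples[["b"]], nrow(x$table)))
  cat(sprintf(" >= %g-fold higher in %s: %d;  higher in %s: %d\n",
              x$threshold, x$samples[["a"]], length(x$called$higher_in_a),
              x$samples[["b"]], length(x$called$higher_in_b)))
  cat(sprintf(" Spearman R = %s\n", format(x$spearman_r, digits = 3)))
  invisible(x)
}

#' Venn-style partition of named feature sets
#'
#' For `k` named sets, returns all `2^k - 1` exclusive regions (features in
#' exactly that combination of sets) with member lists and counts, in a
#' deterministic order (regions sorted by their membership pattern).
#'
#' @param sets named list of >= 2 character vectors.
#' @return data.frame `region` (e.g. `"A&B"`), `count`, and a list-column
#'   `members`.
#' @export
intersect_sets <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list of at least two sets")
  }
  sets <- lapply(sets, unique)
  univ <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sets)))
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  names(patterns) <- names(sets)
  region <- apply(patterns, 1, function(p) paste(names(sets)[p], collapse = "&"))
  members <- lapply(seq_len(nrow(patterns)), function(i) {
    p <- unlist(patterns[i, ])
    univ[apply(memb, 1, function(m) all(m == p))]
  })
  out <- data.frame(region = region, count = lengths(members))
  out$members <- members
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation of two expression profiles
#'
#' Rank-based correlation with average ranks for ties (delegated to
#' `stats::cor`). A constant vector or a length mismatch yields a degenerate
#' result (`rho = NA`) rather than an error value.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return list with `rho` and `degenerate`.
#' @export
spearman_profile <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3 || sd(a) == 0 || sd(b) == 0 || anyNA(a) || anyNA(b)) {
    return(list(rho = NA_real_, degenerate = TRUE))
  }
  list(rho = unname(cor(a, b, method = "spearman")), degenerate = FALSE)
}

#' Scatter data for a pairwise comparison
#'
#' log10(CPM + eps) coordinates per feature with the asymmetry call, the
#' data behind the 10-fold scatter plots.
#'
#' @param report an `asymmetry_report`.
#' @return data.frame `feature`, `log10_cpm_a`, `log10_cpm_b`, `call`.
#' @export
scatter_data <- function(report) {
  stopifnot(inherits(report, "asymmetry_report"))
  data.frame(feature = report$table$feature,
             log10_cpm_a = log10(report$table$cpm_a + report$eps),
             log10_cpm_b = log10(report$table$cpm_b + report$eps),
             call = report$table$call)
}
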