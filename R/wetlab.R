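#' Relative expression by the 2^-ddCt method
#'
#' `dCt = target_ct - reference_ct` per record (reference: rp49);
#' `ddCt = dCt_sample - dCt_calibrator`; relative expression is
#' `2^(-ddCt)` (amplification efficiency fixed at 2). With replicate
#' vectors, per-replicate folds are computed pairwise and their mean and
#' SEM returned.
#'
#' @param sample list or data.frame with `target_ct` and `reference_ct`
#'   (scalars or equal-length replicate vectors).
#' @param calibrator same structure; the condition expression is relative to.
#' @return list with `fold` (per-replicate folds), `mean`, `sem` (`NA` for a
#'   single replicate).
#' @export
ddct <- function(sample, calibrator) {
  for (rec in list(sample, calibrator)) {
    if (!all(c("target_ct", "reference_ct") %in% names(rec))) {
      stop("records need target_ct and reference_ct")
    }
    if (anyNA(rec$target_ct) || anyNA(rec$reference_ct)) {
      stop("Ct values must be complete")
    }
  }
  dct_s <- sample$target_ct - sample$reference_ct
  dct_c <- calibrator$target_ct - calibrator$reference_ct
  if (length(dct_c) == 1) dct_c <- rep(dct_c, length(dct_s))
  if (length(dct_s) != length(dct_c)) stop("replicate counts differ")
  fold <- 2^(-(dct_s - dct_c))
  list(fold = fold, mean = mean(fold),
       sem = if (length(fold) > 1) sd(fold) / sqrt(length(fold)) else NA_real_)
}

#' Percent-input and enrichment for ChIP-qPCR
#'
#' The input Ct is adjusted for the fraction of chromatin used as input,
#' `adjusted_input_ct = input_ct - log2(1 / input_fraction)`, and
#' `percent_input = 100 * 2^(adjusted_input_ct - ip_ct)`. Enrichment of a
#' target locus is its percent-input divided by that of the control locus
#' (rp49). Replicate vectors return mean and SEM of per-replicate
#' enrichments.
#'
#' @param target list/data.frame with `ip_ct`, `input_ct`, `input_fraction`
#'   (scalars or replicate vectors).
#' @param control same structure for the normalization locus; `NULL` skips
#'   normalization.
#' @return list with `percent_input_target`, `percent_input_control`,
#'   `enrichment` (per replicate), `mean`, `sem`.
#' @export
chip_enrichment <- function(target, control = NULL) {
  pct <- function(rec) {
    if (any(rec$input_fraction <= 0) || any(rec$input_fraction > 1)) {
      stop("input_fraction must be in (0, 1]")
    }
    adj <- rec$input_ct - log2(1 / rec$input_fraction)
    100 * 2^(adj - rec$ip_ct)
  }
  p_t <- pct(target)
  if (is.null(control)) {
    return(list(percent_input_target = p_t, percent_input_control = NULL,
                enrichment = NULL, mean = mean(p_t),
                sem = if (length(p_t) > 1) sd(p_t) / sqrt(length(p_t)) else NA_real_))
  }
  p_c <- pct(control)
  if (length(p_c) == 1) p_c <- rep(p_c, length(p_t))
  if (length(p_t) != length(p_c)) stop("replicate counts differ")
  enr <- p_t / p_c
  list(percent_input_target = p_t, percent_input_control = p_c,
       enrichment = enr, mean = mean(enr),
       sem = if (length(enr) > 1) sd(enr) / sqrt(length(enr)) else NA_real_)
}

#' Read a Ct table (TSV)
#'
#' Expected columns: `sample`, `target_ct`, `reference_ct`, optionally
#' `replicate`; extra columns pass through.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "target_ct", "reference_ct")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  df
}
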