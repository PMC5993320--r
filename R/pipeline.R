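#' Build a pipeline run configuration
#'
#' Thresholds default to the analysis' standard values: length filter > 18
#' nt, quality 80% of bases at Phred >= 20, 25-CPM low-expression floor,
#' 10-fold asymmetry calls, perfect-match mapping.
#'
#' @param samples named character vector: sample name -> FASTQ path.
#' @param consensus path to the TE/repeat consensus FASTA.
#' @param ncrna path to the ncRNA contaminant FASTA (`NULL` skips
#'   subtraction).
#' @param adapter 3' adapter sequence.
#' @param out_dir output directory (created if needed); `NULL` disables file
#'   output.
#' @param min_len,q_threshold,q_fraction,floor_cpm,fold_threshold,max_mismatches
#'   pipeline thresholds.
#' @param pingpong_features features for which ping-pong signatures,
#'   divergence profiles and coverage tracks are computed (`NULL`: all
#'   features surviving the floor in any sample).
#' @param seed seed for any stochastic step (none in the core pipeline;
#'   recorded in the manifest).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(samples, consensus, ncrna = NULL,
                       adapter = "TGGAATTCTCGGGTGCCAAGG", out_dir = NULL,
                       min_len = 18L, q_threshold = 20L, q_fraction = 0.8,
                       floor_cpm = 25, fold_threshold = 10,
                       max_mismatches = 0L, pingpong_features = NULL,
                       seed = 1L) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named vector: name -> FASTQ path")
  }
  for (p in c(unname(samples), consensus, if (!is.null(ncrna)) ncrna)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  stopifnot(min_len >= 1, q_fraction > 0, q_fraction <= 1, floor_cpm >= 0,
            fold_threshold > 0, max_mismatches %in% 0:3)
  structure(list(samples = samples, consensus = consensus, ncrna = ncrna,
                 adapter = toupper(adapter), out_dir = out_dir,
                 min_len = as.integer(min_len),
                 q_threshold = as.integer(q_threshold),
                 q_fraction = q_fraction, floor_cpm = floor_cpm,
                 fold_threshold = fold_threshold,
                 max_mismatches = as.integer(max_mismatches),
                 pingpong_features = pingpong_features,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()];
#'   `samples` is a mapping of sample name to FASTQ path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$samples)) stop("config must define 'samples'")
  samples <- unlist(y$samples)
  y$samples <- NULL
  args <- c(list(samples = samples), y)
  do.call(run_config, args)
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full strain-comparison pipeline
#'
#' For each sample: adapter trimming, length/quality filtering, ncRNA
#' subtraction, mapping to the consensus library, size-class counting. Then
#' CPM normalization with the low-expression floor across samples,
#' per-feature ping-pong signatures, divergence profiles and coverage
#' tracks, and all pairwise asymmetry reports with Spearman correlations
#' and, for 2+ comparisons against the first sample, the Venn partition of
#' deficit sets. Re-running on identical inputs reproduces identical
#' outputs.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return list of class `pipeline_result`: `preprocess` (per-sample stage
#'   ledgers), `count_matrix`, `pingpong`, `divergence`, `coverage`
#'   (per-sample, per-feature), `comparisons` (per ordered pair),
#'   `intersections`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  library <- .stage("load_consensus", read_fasta(config$consensus))
  ncrna <- if (!is.null(config$ncrna)) {
    .stage("preprocess", read_fasta(config$ncrna, category = "ncRNA"))
  }
  samples <- names(config$samples)

  pre <- list(); reads <- list(); aln <- list(); counts <- list()
  denom <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    raw <- .stage("preprocess", read_fastq(config$samples[[s]]))
    pp <- .stage("preprocess", preprocess_reads(
      raw, adapter = config$adapter, ncrna = ncrna, min_len = config$min_len,
      q_threshold = config$q_threshold, q_fraction = config$q_fraction))
    pre[[s]] <- pp$report
    reads[[s]] <- pp$reads
    m <- .stage("map", map_reads(pp$reads, library,
                                 max_mismatches = config$max_mismatches))
    aln[[s]] <- m$alignments
    denom[s] <- m$n_mapped
    counts[[s]] <- .stage("quantify", classify_and_count(m$alignments, s))
  }
  cm <- .stage("quantify", {
    if (any(denom == 0)) stop("sample(s) with zero mapped reads: ",
                              paste(samples[denom == 0], collapse = ", "))
    normalize_and_floor(count_matrix(counts, denom), config$floor_cpm)
  })

  feats <- config$pingpong_features
  if (is.null(feats)) {
    present <- cm$counts[!cm$counts$absent & cm$counts$class == "piRNA", ]
    feats <- sort(unique(present$feature))
  }
  pp_stats <- list(); div <- list(); cov <- list()
  for (s in samples) {
    pp_stats[[s]] <- lapply(setNames(feats, feats), function(f) {
      .stage("pingpong", pingpong_signature(aln[[s]], f, reads = reads[[s]]))
    })
    div[[s]] <- lapply(setNames(feats, feats), function(f) {
      ids <- unique(aln[[s]]$read_id[aln[[s]]$feature == f &
                                       size_class_of(aln[[s]]$length) == "piRNA"])
      .stage("divergence",
             mismatch_profile(reads[[s]][reads[[s]]$id %in% ids, , drop = FALSE],
                              f, library))
    })
    cov[[s]] <- lapply(setNames(feats, feats), function(f) {
      .stage("divergence",
             coverage_track(aln[[s]][size_class_of(aln[[s]]$length) == "piRNA", ,
                                     drop = FALSE],
                            f, library, denominator = denom[[s]]))
    })
  }

  comparisons <- list()
  if (length(samples) >= 2) {
    for (i in seq_along(samples)[-1]) {
      key <- paste(samples[1], "vs", samples[i])
      comparisons[[key]] <- .stage("compare", fold_change_and_call(
        cm, samples[1], samples[i], class = "piRNA",
        threshold = config$fold_threshold))
    }
  }
  intersections <- NULL
  if (length(comparisons) >= 2) {
    deficit_sets <- lapply(comparisons, function(r) r$called$higher_in_a)
    intersections <- .stage("compare", intersect_sets(deficit_sets))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("srnaprofiler")),
    config = config[setdiff(names(config), "out_dir")],
    config_hash = .config_hash(config),
    stage_counts = pre, denominators = as.list(denom))

  result <- structure(list(preprocess = pre, count_matrix = cm,
                           pingpong = pp_stats, divergence = div,
                           coverage = cov, comparisons = comparisons,
                           intersections = intersections, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_bundle(result, config)
  result
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[sort(names(unclass(config)))]),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

.write_bundle <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  pre <- do.call(rbind, lapply(names(result$preprocess), function(s) {
    data.frame(sample = s, stage = names(result$preprocess[[s]]),
               count = as.integer(result$preprocess[[s]]))
  }))
  write.table(pre, out("preprocess_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_count_table(result$count_matrix, out("count_table.tsv"))
  pp <- do.call(rbind, lapply(names(result$pingpong), function(s) {
    do.call(rbind, lapply(result$pingpong[[s]], function(x) {
      cbind(data.frame(sample = s, feature = x$feature),
            as.data.frame(as.list(setNames(signif(x$histogram, 6),
                                           paste0("overlap_", 1:20)))),
            data.frame(distinct_pairs = x$distinct_pairs,
                       zscore_10 = signif(x$zscore_10, 6),
                       u1_antisense = signif(x$u1_antisense, 6),
                       a10_sense = signif(x$a10_sense, 6)))
    }))
  }))
  if (!is.null(pp)) write.table(pp, out("pingpong.tsv"), sep = "\t",
                                quote = FALSE, row.names = FALSE)
  dv <- do.call(rbind, lapply(names(result$divergence), function(s) {
    do.call(rbind, lapply(result$divergence[[s]], function(x) {
      cbind(data.frame(sample = s, feature = x$feature,
                       orientation = rownames(x$profile)),
            signif(x$profile, 6))
    }))
  }))
  if (!is.null(dv)) write.table(dv, out("divergence.tsv"), sep = "\t",
                                quote = FALSE, row.names = FALSE)
  first <- TRUE
  for (s in names(result$coverage)) {
    for (tr in result$coverage[[s]]) {
      write_coverage(tr, out("coverage.tsv"), append = !first)
      first <- FALSE
    }
  }
  for (key in names(result$comparisons)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", key)
    write.table(scatter_data(result$comparisons[[key]]),
                out(paste0("scatter_", slug, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$intersections)) {
    venn <- result$intersections
    venn$members <- vapply(venn$members, paste, character(1), collapse = ",")
    write.table(venn, out("venn_regions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$preprocess), "sample(s)\n")
  for (s in names(x$preprocess)) {
    cat(sprintf("  %s: %s\n", s,
                paste(names(x$preprocess[[s]]), x$preprocess[[s]],
                      sep = "=", collapse = ", ")))
  }
  cat(" comparisons:", length(x$comparisons), "\n")
  invisible(x)
}
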