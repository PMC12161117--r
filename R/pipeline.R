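#' @include AllClasses.R synthetic.R features.R groupstats.R classify.R
NULL

#' Read and validate a pipeline run configuration
#'
#' Configurations are nested key-value YAML. Recognised keys:
#' `mode` ("synthetic" or "files"), `input_dir` (files mode), `cohort`
#' (synthetic mode; arguments of [cohortSpec()] such as n_bd, n_hc,
#' duration, seed), `bands` (subset of the canonical band names), `q`
#' (FDR level), `welch` (feature t-test variant), `cv` (k, repeats),
#' `seed` and `out_dir`. Validation is fail-fast: unknown bands or
#' paradigms raise before any computation.
#'
#' @param x path to a YAML file, or an equivalent named list
#' @return validated configuration list
#' @export
readRunConfig <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  cfg$mode <- match.arg(cfg$mode %||% "synthetic", c("synthetic", "files"))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$q <- cfg$q %||% 0.05
  cfg$welch <- isTRUE(cfg$welch)
  cfg$epoch_s <- cfg$epoch_s %||% 6
  cfg$filter_order <- as.integer(cfg$filter_order %||% 4L)
  cfg$notch_q <- cfg$notch_q %||% 30
  cfg$cv <- modifyList(list(k = 5L, repeats = 10L), cfg$cv %||% list())
  bands <- cfg$bands %||% names(canonicalBands())
  unknown <- setdiff(bands, names(canonicalBands()))
  if (length(unknown))
    stop(sprintf("unknown band name(s) in config: %s",
                 paste(unknown, collapse = ", ")))
  cfg$bands <- bands
  paradigms <- cfg$paradigms %||% .PARADIGMS
  unknown <- setdiff(paradigms, .PARADIGMS)
  if (length(unknown))
    stop(sprintf("unknown paradigm(s) in config: %s",
                 paste(unknown, collapse = ", ")))
  cfg$paradigms <- paradigms
  if (cfg$mode == "files" && is.null(cfg$input_dir))
    stop("files mode requires 'input_dir'")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cohort_from_config <- function(cfg) {
  cc <- cfg$cohort %||% list()
  cohortSpec(nBD = cc$n_bd %||% 28L, nHC = cc$n_hc %||% 42L,
             fs = cc$fs %||% 250, duration = cc$duration %||% 180,
             subjectSd = cc$subject_sd %||% 0.3,
             oneOverFScale = cc$one_over_f %||% 8,
             paradigms = cfg$paradigms,
             seed = as.integer(cc$seed %||% cfg$seed))
}

.load_cohort_files <- function(cfg) {
  md <- utils::read.delim(file.path(cfg$input_dir, "metadata.tsv"))
  recs <- list()
  for (p in cfg$paradigms) {
    col <- paste0("file_", p)
    if (!col %in% colnames(md)) {
      warning(sprintf("metadata has no '%s' column; paradigm skipped", col))
      next
    }
    recs[[p]] <- lapply(seq_len(nrow(md)), function(i) {
      path <- file.path(cfg$input_dir, md[[col]][i])
      fmt <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
      readRecording(path, format = fmt, fs = cfg$fs %||% 250,
                    subjectId = md$subject_id[i], paradigm = p)
    })
    names(recs[[p]]) <- md$subject_id
  }
  list(recordings = recs, metadata = md, groundTruth = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end procedure: obtain a cohort (synthetic or from
#' files), preprocess every recording, compute per-band PLI connectivity
#' and the 12-feature matrix per paradigm, run the statistical layer
#' (edgewise FDR-corrected group comparison, per-electrode feature t-tests,
#' feature-cognition correlations) and the six-classifier benchmark, and
#' write all stage outputs plus a `manifest.json` and a human-readable
#' summary ranking the paradigms on (i) FDR-significant connectivity,
#' (ii) significant feature-cognition cells and (iii) best classifier
#' accuracy.
#'
#' @param config configuration list or YAML path (see [readRunConfig()])
#' @param out_dir output directory (overrides the config's `out_dir`)
#' @return (invisibly) list with the stage results and the manifest
#' @export
runPipeline <- function(config, out_dir = NULL) {
  cfg <- readRunConfig(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, started = format(Sys.time()),
                   r_version = as.character(getRversion()), stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }

  st <- t_stage(if (cfg$mode == "synthetic")
    generateCohort(.cohort_from_config(cfg)) else .load_cohort_files(cfg))
  cohort <- st$value
  manifest$stages$cohort <- list(seconds = st$seconds,
                                 n_subjects = nrow(cohort$metadata))

  bands <- canonicalBands()[cfg$bands]
  results <- list()
  for (p in names(cohort$recordings)) {
    recs <- cohort$recordings[[p]]
    st <- t_stage({
      pre <- lapply(recs, function(r)
        filterBroadband(rereferenceAverage(r), order = cfg$filter_order,
                        notch_q = cfg$notch_q))
      tensors <- lapply(pre, function(r)
        connectivityTensor(segmentEpochs(r, cfg$epoch_s), bands))
      fm <- buildFeatureMatrix(pre, cohort$metadata, epoch_s = cfg$epoch_s,
                               bands = canonicalBands(), preprocess = FALSE)
      list(tensors = tensors, fm = fm)
    })
    tensors <- st$value$tensors
    fm <- st$value$fm
    g <- cohort$metadata$group[match(names(tensors),
                                     cohort$metadata$subject_id)]
    edges <- edgewiseComparison(tensors[g == "BD"], tensors[g == "HC"],
                                q = cfg$q)
    t2 <- featureTTests(fm, welch = cfg$welch)
    corr <- featureCognitionCorrelation(fm)
    utils::write.table(edges, file.path(out_dir, sprintf("edges_%s.tsv", p)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(t2, file.path(out_dir, sprintf("table2_analog_%s.tsv", p)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(corr, file.path(out_dir, sprintf("correlations_%s.tsv", p)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(feature = rownames(SummarizedExperiment::assay(fm)),
                 SummarizedExperiment::assay(fm), check.names = FALSE),
      file.path(out_dir, sprintf("features_%s.tsv", p)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results[[p]] <- list(fm = fm, edges = edges, table2 = t2, corr = corr)
    manifest$stages[[paste0("features_", p)]] <- list(seconds = st$seconds)
  }

  st <- t_stage(runBenchmark(lapply(results, `[[`, "fm"),
                             k = cfg$cv$k, repeats = cfg$cv$repeats,
                             seed = cfg$seed))
  bench <- st$value
  manifest$stages$classify <- list(seconds = st$seconds)
  utils::write.table(bench, file.path(out_dir, "benchmark.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  lines <- c("Paradigm comparison summary", "===========================")
  for (p in names(results)) {
    e <- results[[p]]$edges
    sig_bands <- unique(e$band[e$significant])
    nsig <- sum(e$significant)
    ncorr <- attr(results[[p]]$corr, "n_significant")
    bestacc <- max(bench$acc_mean[bench$paradigm == p])
    lines <- c(lines, sprintf(
      "%-13s: %3d FDR-significant edges in {%s}; %d significant feature-cognition cells; best classifier accuracy %.1f%%",
      p, nsig, paste(sig_bands, collapse = ","), ncorr, bestacc))
  }
  lines <- c(lines, sprintf("Paradigm ranking by best accuracy: %s",
                            paste(attr(bench, "ranking"), collapse = " > ")))
  writeLines(lines, file.path(out_dir, "summary.txt"))

  manifest$outputs <- list.files(out_dir)
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(results = results, benchmark = bench, manifest = manifest))
}
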