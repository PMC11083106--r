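# End-to-end orchestration: simulate a cohort to disk, analyze a cohort
# from a manifest (or in memory), and the command-line surface.

#' Analyze a cohort of DWI cases in memory
#'
#' Pipeline order: b-pair selection, per-case SNR report, SNR QC filter,
#' ADC quantification of retained cases, cohort feature table, group
#' summary, normality screen, pairwise tests and ROC analysis.
#'
#' @param cases list; each element has `study`, `voi`, `noise_roi`
#'   (e.g. `skin_phantom` objects or equivalents read from disk).
#' @param cutoff SNR inclusion cutoff at the high b-value (default 2).
#' @param exempt_groups groups exempt from the cutoff (default `"H"`).
#' @param erosion_rim voxels of additional VOI erosion before measuring
#'   (default 0: masks are assumed already delineated conservatively).
#' @param alpha significance level.
#' @param min_group_n smallest group tested inferentially.
#' @param use_corrected use Rician-corrected signal in SNR numerators.
#' @return list of class `skin_analysis`: `features` (per-case table, ADC
#'   in 1e-3 mm^2/s), `qc_table`, `excluded`, `group_summary`, `normality`,
#'   `pairwise_tests`, `roc` (list of `roc_result`), `roc_summary`.
#' @export
analyze_cohort <- function(cases, cutoff = 2, exempt_groups = "H",
                           erosion_rim = 0L, alpha = 0.05, min_group_n = 5L,
                           use_corrected = TRUE) {
  if (length(cases) == 0L) stop("no cases to analyze")
  reports <- lapply(cases, function(cs) {
    pair <- select_bvalue_pair(cs$study$b_values)
    compute_snr(cs$study, cs$voi, cs$noise_roi, pair, cutoff = cutoff,
                exempt = isTRUE(cs$study$group %in% exempt_groups),
                use_corrected = use_corrected)
  })
  qc <- snr_qc_filter(do.call(rbind, lapply(reports, snr_report_row)),
                      cutoff = cutoff, exempt_groups = exempt_groups)
  keep <- qc$qc_table$passed
  rows <- list()
  for (i in which(keep)) {
    cs <- cases[[i]]
    voi <- cs$voi
    if (erosion_rim > 0L) voi <- erode_mask(voi, erosion_rim)
    res <- adc_quantify(cs$study, voi)
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = cs$study$case_id, group = cs$study$group %||% NA_character_,
      n_voxels = res$n_voxels_used + res$n_voxels_excluded,
      n_voxels_excluded = res$n_voxels_excluded,
      adc_mean_signal = res$adc_of_mean_signal * 1e3,
      adc_mean = res$summary$mean * 1e3,
      adc_median = res$summary$median * 1e3,
      adc_min = res$summary$min * 1e3,
      adc_max = res$summary$max * 1e3,
      negative_flag = res$flagged_negative,
      snr_low_b = qc$qc_table$snr_low_b[i],
      snr_high_b = qc$qc_table$snr_high_b[i],
      sigma = qc$qc_table$sigma[i],
      exempt = qc$qc_table$exempt[i],
      qc_flag = qc$qc_table$flag[i],
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  feature_cols <- c("adc_mean_signal", "adc_mean", "adc_median",
                    "adc_min", "adc_max")

  normality <- NULL
  for (g in unique(features$group)) for (f in feature_cols) {
    v <- features[[f]][features$group == g]
    if (length(v) >= 4L && sd(v) > 0) {
      normality <- rbind(normality, data.frame(
        group = g, feature = f, n = length(v),
        ks_p = ks_normality(v), stringsAsFactors = FALSE))
    }
  }

  multi <- length(unique(features$group)) >= 2L
  tests <- if (multi)
    pairwise_group_tests(features, feature_cols, min_group_n = min_group_n,
                         alpha = alpha)
  else NULL

  roc_pairs <- list(c("SIBC", "BSI"), c("SIBC", "IBC"), c("IBC", "BSI"))
  roc <- list(); roc_rows <- list()
  for (p in roc_pairs) {
    if (all(p %in% features$group)) {
      r <- roc_analysis(features, "adc_mean_signal", p[1], p[2],
                        orientation = "lower")
      roc[[paste(p, collapse = "_vs_")]] <- r
      roc_rows[[length(roc_rows) + 1L]] <- data.frame(
        positive_group = p[1], negative_group = p[2],
        feature = "adc_mean_signal", auc = r$auc,
        youden_threshold = r$youden_threshold,
        sensitivity = r$sensitivity, specificity = r$specificity,
        stringsAsFactors = FALSE)
    }
  }

  structure(list(features = features, qc_table = qc$qc_table,
                 excluded = qc$excluded,
                 group_summary = summarize_groups(features, feature_cols),
                 normality = normality, pairwise_tests = tests,
                 roc = roc,
                 roc_summary = if (length(roc_rows)) do.call(rbind, roc_rows)),
            class = "skin_analysis")
}

#' @export
print.skin_analysis <- function(x, ...) {
  cat("<skin_analysis> ", nrow(x$features), " cases retained, ",
      nrow(x$excluded), " excluded by SNR QC\n", sep = "")
  if (!is.null(x$roc_summary)) {
    cat("  AUC (adc_mean_signal): ",
        paste(sprintf("%s vs %s = %.3f", x$roc_summary$positive_group,
                      x$roc_summary$negative_group, x$roc_summary$auc),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Simulate a cohort and write all artifacts to disk
#'
#' @param config list (or path to a JSON file) with optional fields:
#'   `seed`, `out` (output directory, required), `n` (named per-group case
#'   counts), `snr_target` (scalar override), plus any `phantom_spec`
#'   argument under `spec` (e.g. `spec = list(grid_shape = c(24, 24, 10))`).
#' @return output directory, invisibly. Writes per-case NIfTI/bval/JSON
#'   files under `out/cases/`, `manifest.csv` and `ground_truth.csv`.
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$out)) stop("config must name an output directory `out`")
  seed <- as.integer(cfg$seed %||% 1L)
  spec_base <- do.call(phantom_spec, as_spec_args(cfg$spec))
  n <- if (!is.null(cfg$n)) unlist(cfg$n)
  cohort <- simulate_cohort(n = n, snr_target = cfg$snr_target, seed = seed,
                            spec_base = spec_base)
  out <- cfg$out
  case_dir <- file.path(out, "cases")
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  for (ph in cohort$phantoms) {
    paths <- write_dwi_study(ph$study, case_dir,
                             extra = list(noise_sigma = ph$spec$noise_sigma,
                                          seed = seed))
    voi_p <- file.path(case_dir, paste0(ph$study$case_id, "_voi.nii.gz"))
    roi_p <- file.path(case_dir, paste0(ph$study$case_id, "_noise.nii.gz"))
    write_mask(ph$voi, voi_p, ph$study$voxel_spacing)
    write_mask(ph$noise_roi, roi_p, ph$study$voxel_spacing)
    man[[length(man) + 1L]] <- data.frame(
      case_id = ph$study$case_id, group = ph$study$group,
      image = rel_path(paths[["image"]], out),
      bval = rel_path(paths[["bval"]], out),
      sidecar = rel_path(paths[["sidecar"]], out),
      voi = rel_path(voi_p, out), noise_roi = rel_path(roi_p, out),
      stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, man), file.path(out, "manifest.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(out, "ground_truth.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n = as.list(table(cohort$truth$group)),
                            tool = "skindwi",
                            version = as.character(packageVersion("skindwi"))),
                       file.path(out, "simulate_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Analyze a cohort from a manifest and write the report
#'
#' @param config list (or JSON path) with fields: `manifest` (path to
#'   `manifest.csv`, required), `out` (report directory, required), and
#'   optional `cutoff`, `exempt_groups`, `erosion_rim`, `alpha`,
#'   `min_group_n`, `use_corrected`.
#' @return the `skin_analysis` object, invisibly. Writes `features.csv`,
#'   `qc_table.csv`, `group_summary.csv`, `normality.csv`,
#'   `pairwise_tests.csv`, `roc_summary.csv` and `run_report.json`.
#' @export
run_analyze <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$manifest) || is.null(cfg$out))
    stop("config must name `manifest` and `out`")
  if (!file.exists(cfg$manifest)) stop("no such manifest: ", cfg$manifest)
  man <- read.csv(cfg$manifest, stringsAsFactors = FALSE)
  root <- dirname(cfg$manifest)
  cases <- lapply(seq_len(nrow(man)), function(i) {
    study <- read_dwi_study(file.path(root, man$image[i]),
                            bval_path = file.path(root, man$bval[i]),
                            case_id = man$case_id[i], group = man$group[i])
    list(study = study,
         voi = read_mask(file.path(root, man$voi[i]), study),
         noise_roi = read_mask(file.path(root, man$noise_roi[i]), study))
  })
  res <- analyze_cohort(cases,
                        cutoff = cfg$cutoff %||% 2,
                        exempt_groups = unlist(cfg$exempt_groups) %||% "H",
                        erosion_rim = cfg$erosion_rim %||% 0L,
                        alpha = cfg$alpha %||% 0.05,
                        min_group_n = cfg$min_group_n %||% 5L,
                        use_corrected = cfg$use_corrected %||% TRUE)
  tables <- list(features = res$features, qc_table = res$qc_table,
                 group_summary = res$group_summary)
  if (!is.null(res$normality)) tables$normality <- res$normality
  if (!is.null(res$pairwise_tests)) tables$pairwise_tests <- res$pairwise_tests
  if (!is.null(res$roc_summary)) tables$roc_summary <- res$roc_summary
  tables$config <- cfg
  tables$version <- as.character(packageVersion("skindwi"))
  tables$n_cases <- nrow(man)
  tables$n_retained <- nrow(res$features)
  tables$exclusions <- lapply(seq_len(nrow(res$excluded)), function(i)
    list(case_id = res$excluded$case_id[i], group = res$excluded$group[i],
         reason = res$excluded$reason[i]))
  write_results(tables, cfg$out)
  invisible(res)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

as_spec_args <- function(spec) {
  if (is.null(spec)) return(list())
  lapply(spec, function(x) if (is.list(x)) unlist(x) else x)
}

# paths are built as file.path(root, ...), so stripping the prefix suffices
rel_path <- function(path, root) {
  root <- sub("/+$", "", root)
  if (startsWith(path, paste0(root, "/"))) substring(path, nchar(root) + 2L)
  else path
}

#' Command-line entry point
#'
#' Usage: `skindwi simulate --out DIR [--seed N] [--config FILE]
#' [--snr-target X]` or `skindwi analyze --manifest FILE --out DIR
#' [--config FILE] [--cutoff X] [--rim N]`. A wrapper script is installed
#' under `inst/cli/skindwi`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return integer exit status: 0 ok, 1 usage error, 2 data/processing
#'   error.
#' @export
skindwi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: skindwi <simulate|analyze> [options]\n",
            "  simulate --out DIR [--seed N] [--config FILE] [--snr-target X]\n",
            "  analyze  --manifest FILE --out DIR [--config FILE]\n",
            "           [--cutoff X] [--rim N] [--alpha A] [--min-group-n N]")
    1L
  }
  if (length(args) == 0L) return(usage())
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  if (is.null(opts)) return(usage())
  cfg <- if (!is.null(opts$config)) load_config(opts$config) else list()
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  tryCatch({
    if (cmd == "simulate") {
      cfg$out <- opts$out %||% cfg$out
      cfg$seed <- num(opts$seed) %||% cfg$seed
      cfg$snr_target <- num(opts[["snr-target"]]) %||% cfg$snr_target
      if (is.null(cfg$out)) return(usage())
      run_simulate(cfg)
      message("cohort written to ", cfg$out)
      0L
    } else if (cmd == "analyze") {
      cfg$manifest <- opts$manifest %||% cfg$manifest
      cfg$out <- opts$out %||% cfg$out
      cfg$cutoff <- num(opts$cutoff) %||% cfg$cutoff
      cfg$erosion_rim <- num(opts$rim) %||% cfg$erosion_rim
      cfg$alpha <- num(opts$alpha) %||% cfg$alpha
      cfg$min_group_n <- num(opts[["min-group-n"]]) %||% cfg$min_group_n
      if (is.null(cfg$manifest) || is.null(cfg$out)) return(usage())
      run_analyze(cfg)
      message("report written to ", cfg$out)
      0L
    } else usage()
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- substring(a, 3L)
    if (i + 1L > length(args)) return(NULL)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
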