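# Noise-floor estimation and SNR quality control.
#
# On a magnitude image, a signal-free background region is Rayleigh
# distributed with mean sigma * sqrt(pi/2); inverting gives the
# single-channel noise-floor estimator sigma = sqrt(2/pi) * mean(S_noise).
# Tissue signal is corrected for the Rician floor by
# S_corrected = sqrt(S^2 - sigma^2), and SNR = S_corrected / sigma.
# Pathology cases with high-b SNR below the cutoff (default 2) are
# excluded; healthy-skin cases are exempt but flagged as biased, because
# their low signal at high b makes the measured ADC systematically low.

#' Estimate the noise sigma from a background ROI
#'
#' @param study a `dwi_study`.
#' @param noise_roi `voi_mask` over a signal-free background region.
#' @param b_value which volume to measure on (default: highest b).
#' @return object of class `noise_estimate`: `s_noise_mean`, `sigma`
#'   (`= sqrt(2/pi) * s_noise_mean`), `roi_voxel_count`, `b_value`.
#' @export
estimate_sigma <- function(study, noise_roi, b_value = max(study$b_values)) {
  noise_roi <- voi_mask(noise_roi, study = study)
  vals <- volume_at_b(study, b_value)[noise_roi]
  if (length(vals) == 0L) stop("empty noise ROI")
  m <- mean(vals)
  structure(list(s_noise_mean = m, sigma = sqrt(2 / pi) * m,
                 roi_voxel_count = length(vals), b_value = b_value),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat("<noise_estimate> sigma = ", signif(x$sigma, 4), " (mean background ",
      signif(x$s_noise_mean, 4), ", ", x$roi_voxel_count, " voxels, b = ",
      x$b_value, ")\n", sep = "")
  invisible(x)
}

#' Rician noise-floor correction of a tissue signal
#'
#' `sqrt(S^2 - sigma^2)` when `S > sigma`; 0 with an underflow flag when
#' `S <= sigma` (the measured signal is at or below the noise floor).
#'
#' @param tissue_signal non-negative numeric (vectorized).
#' @param sigma non-negative scalar.
#' @return corrected signal, same length as `tissue_signal`, with logical
#'   attribute `underflow`.
#' @export
rician_correct <- function(tissue_signal, sigma) {
  if (any(tissue_signal < 0)) stop("tissue_signal must be >= 0")
  if (length(sigma) != 1L || sigma < 0) stop("sigma must be a scalar >= 0")
  under <- tissue_signal <= sigma
  out <- ifelse(under & tissue_signal < sigma, 0,
                sqrt(pmax(tissue_signal^2 - sigma^2, 0)))
  structure(out, underflow = under & sigma > 0)
}

#' Per-case SNR report for a VOI
#'
#' For each b-value of the pair: mean VOI signal, its Rician-corrected
#' value, and SNR = corrected signal / sigma (sigma estimated from the
#' noise ROI on the same b-value volume). Set `use_corrected = FALSE` to
#' use the raw mean signal in the SNR numerator.
#'
#' @param study a `dwi_study`.
#' @param voi measurement `voi_mask`.
#' @param noise_roi background `voi_mask`.
#' @param pair `bvalue_pair`; default [select_bvalue_pair()].
#' @param cutoff SNR inclusion cutoff applied at the high b-value.
#' @param exempt logical: exempt case (healthy skin) — always passes but is
#'   flagged.
#' @param use_corrected use the Rician-corrected signal in the numerator.
#' @return object of class `snr_report` with per-b fields and the QC verdict.
#' @export
compute_snr <- function(study, voi, noise_roi, pair = NULL, cutoff = 2,
                        exempt = FALSE, use_corrected = TRUE) {
  pair <- pair %||% select_bvalue_pair(study$b_values)
  voi <- voi_mask(voi, study = study)
  one_b <- function(b) {
    est <- estimate_sigma(study, noise_roi, b)
    s <- mean(volume_at_b(study, b)[voi])
    corr <- rician_correct(s, est$sigma)
    num <- if (use_corrected) as.numeric(corr) else s
    snr <- if (est$sigma == 0) Inf else num / est$sigma
    list(b = b, sigma = est$sigma, tissue_signal = s,
         corrected_signal = as.numeric(corr),
         underflow = isTRUE(attr(corr, "underflow")), snr = snr)
  }
  low <- one_b(pair$b1)
  high <- one_b(pair$b2)
  structure(list(case_id = study$case_id, group = study$group,
                 low = low, high = high, cutoff = cutoff, exempt = exempt,
                 sigma = high$sigma,
                 passed = exempt || high$snr >= cutoff),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat("<snr_report> ", x$case_id,
      ": SNR(b=", x$low$b, ") = ", signif(x$low$snr, 4),
      ", SNR(b=", x$high$b, ") = ", signif(x$high$snr, 4),
      ", sigma = ", signif(x$sigma, 4), "\n  ",
      if (x$exempt) "exempt (no cutoff applied, values biased at low SNR)"
      else if (x$passed) paste0("PASS (cutoff ", x$cutoff, ")")
      else paste0("FAIL (cutoff ", x$cutoff, ")"), "\n", sep = "")
  invisible(x)
}

snr_report_row <- function(r) {
  data.frame(case_id = r$case_id, group = r$group %||% NA_character_,
             snr_low_b = r$low$snr, snr_high_b = r$high$snr,
             sigma = r$sigma, stringsAsFactors = FALSE)
}

#' Apply the SNR inclusion cutoff across a cohort
#'
#' Pathology cases whose high-b SNR is strictly below the cutoff are
#' excluded (a case exactly at the cutoff is retained). Cases in
#' `exempt_groups` (healthy skin) are always retained but flagged
#' `"biased"`.
#'
#' @param reports list of `snr_report` objects or a data.frame with columns
#'   `case_id`, `group`, `snr_low_b`, `snr_high_b`, `sigma`.
#' @param cutoff SNR cutoff (default 2).
#' @param exempt_groups group labels exempt from the cutoff (default `"H"`).
#' @return list: `included` and `excluded` data.frames, and `qc_table` with
#'   columns passed/exempt/flag/reason.
#' @export
snr_qc_filter <- function(reports, cutoff = 2, exempt_groups = "H") {
  df <- if (is.data.frame(reports)) reports
        else do.call(rbind, lapply(reports, snr_report_row))
  stopifnot(all(c("case_id", "group", "snr_high_b") %in% names(df)))
  df$exempt <- df$group %in% exempt_groups
  df$passed <- df$exempt | df$snr_high_b >= cutoff
  df$flag <- ifelse(df$exempt, "biased", "")
  df$reason <- ifelse(df$passed, "",
                      sprintf("high-b SNR %.3g < cutoff %.3g",
                              df$snr_high_b, cutoff))
  list(included = df[df$passed, , drop = FALSE],
       excluded = df[!df$passed, , drop = FALSE],
       qc_table = df)
}
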