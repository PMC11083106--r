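# Two-point ADC quantification.
#
# ADC = ln(S_b2 / S_b1) / (b1 - b2), evaluated either on the VOI-mean
# signals (method 1) or voxel-wise (method 2) with first-order statistics
# of the resulting map. Only a single low/high b-value pair is used even
# when more b-values are present; multi-b least-squares fitting is out of
# scope. Voxels with nonpositive signal at either b-value cannot enter the
# log and are excluded (not clamped) from map statistics, with counts
# reported, so that noise-bias studies stay honest. Negative ADCs from
# noise are retained and flagged, never floored at zero.

#' Select the low/high b-value pair for ADC computation
#'
#' The low b is the smallest available; the high b must lie in \[700, 900\]
#' s/mm^2, preferring exactly 800, then 750, then the in-range value
#' closest to 800.
#'
#' @param b_values numeric vector with at least two entries.
#' @return object of class `bvalue_pair` with fields `b1` (low), `b2` (high).
#' @export
select_bvalue_pair <- function(b_values) {
  if (length(b_values) < 2L) stop("need at least two b-values")
  b1 <- min(b_values)
  cand <- b_values[b_values >= 700 & b_values <= 900]
  if (length(cand) == 0L)
    stop("no high b-value in [700, 900] s/mm^2; available: ",
         paste(sort(b_values), collapse = ", "))
  b2 <- if (800 %in% cand) 800
        else if (750 %in% cand) 750
        else cand[which.min(abs(cand - 800))]
  structure(list(b1 = b1, b2 = b2), class = "bvalue_pair")
}

#' @export
print.bvalue_pair <- function(x, ...) {
  cat("<bvalue_pair> b1 =", x$b1, ", b2 =", x$b2, "s/mm^2\n")
  invisible(x)
}

#' ADC from the VOI-mean signal (method 1)
#'
#' Computes `ln(mean S_b2 / mean S_b1) / (b1 - b2)` over the mask. A
#' negative result (possible for noise-dominated VOIs where the high-b mean
#' exceeds the low-b mean) is returned and flagged via the
#' `"flagged_negative"` attribute, with a warning.
#'
#' @param study a `dwi_study`.
#' @param mask a `voi_mask`.
#' @param pair a `bvalue_pair`; default chosen by [select_bvalue_pair()].
#' @return numeric scalar ADC in mm^2/s with attributes `s_mean_b1`,
#'   `s_mean_b2`, `flagged_negative`.
#' @export
adc_from_mean_signal <- function(study, mask, pair = NULL) {
  pair <- pair %||% select_bvalue_pair(study$b_values)
  mask <- voi_mask(mask, study = study)
  m1 <- mean(volume_at_b(study, pair$b1)[mask])
  m2 <- mean(volume_at_b(study, pair$b2)[mask])
  if (m1 <= 0 || m2 <= 0)
    stop("nonpositive mean VOI signal (S_b1 = ", signif(m1, 4), ", S_b2 = ",
         signif(m2, 4), "); ADC undefined")
  adc <- log(m2 / m1) / (pair$b1 - pair$b2)
  neg <- adc < 0
  if (neg) warning("negative ADC (", signif(adc, 4),
                   " mm^2/s): high-b mean signal exceeds low-b mean; ",
                   "VOI is likely noise-dominated")
  structure(adc, s_mean_b1 = m1, s_mean_b2 = m2, flagged_negative = neg)
}

#' Voxel-wise ADC map (method 2)
#'
#' Applies the two-point formula per voxel. Voxels with nonpositive signal
#' at either b-value are invalid and stored as `NA`; outside an optional
#' mask the map is `NA` as well.
#'
#' @inheritParams adc_from_mean_signal
#' @param mask optional `voi_mask` restricting computation; default whole
#'   grid.
#' @return 3D numeric array of ADC in mm^2/s (`NA` = invalid/outside mask)
#'   with attribute `n_invalid` (invalid voxels inside the computed region).
#' @export
adc_map <- function(study, pair = NULL, mask = NULL) {
  pair <- pair %||% select_bvalue_pair(study$b_values)
  v1 <- volume_at_b(study, pair$b1)
  v2 <- volume_at_b(study, pair$b2)
  valid <- v1 > 0 & v2 > 0
  out <- array(NA_real_, dim = dim(v1))
  out[valid] <- log(v2[valid] / v1[valid]) / (pair$b1 - pair$b2)
  if (!is.null(mask)) {
    mask <- voi_mask(mask, study = study)
    n_invalid <- sum(mask & !valid)
    out[!mask] <- NA_real_
  } else {
    n_invalid <- sum(!valid)
  }
  attr(out, "n_invalid") <- n_invalid
  out
}

#' First-order statistics of an ADC map over a VOI
#'
#' @param map 3D ADC array (`NA` = invalid), e.g. from [adc_map()].
#' @param mask a `voi_mask`.
#' @return list: `mean`, `median`, `min`, `max` (mm^2/s), `n_voxels_used`,
#'   `n_voxels_excluded`.
#' @export
first_order_stats <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) stop("map and mask shapes differ")
  vals <- map[mask > 0]
  used <- vals[!is.na(vals)]
  if (length(used) == 0L)
    stop("no valid voxels in VOI: all signals nonpositive or masked out")
  list(mean = mean(used), median = median(used),
       min = min(used), max = max(used),
       n_voxels_used = length(used),
       n_voxels_excluded = sum(is.na(vals)))
}

#' Full ADC quantification of one VOI
#'
#' Runs both methods and the first-order summary; the container mirrors
#' what downstream cohort tables consume.
#'
#' @inheritParams adc_from_mean_signal
#' @return object of class `adc_result`: `adc_of_mean_signal`, `adc_map`,
#'   `summary` (first-order stats), `pair`, `n_voxels_used`,
#'   `n_voxels_excluded`, `flagged_negative`.
#' @export
adc_quantify <- function(study, mask, pair = NULL) {
  pair <- pair %||% select_bvalue_pair(study$b_values)
  mask <- voi_mask(mask, study = study)
  scalar <- withCallingHandlers(
    adc_from_mean_signal(study, mask, pair),
    warning = function(w) invokeRestart("muffleWarning"))
  map <- adc_map(study, pair, mask)
  s <- first_order_stats(map, mask)
  structure(list(adc_of_mean_signal = as.numeric(scalar),
                 s_mean_b1 = attr(scalar, "s_mean_b1"),
                 s_mean_b2 = attr(scalar, "s_mean_b2"),
                 flagged_negative = attr(scalar, "flagged_negative"),
                 adc_map = map,
                 summary = s[c("mean", "median", "min", "max")],
                 pair = pair,
                 n_voxels_used = s$n_voxels_used,
                 n_voxels_excluded = s$n_voxels_excluded),
            class = "adc_result")
}

#' @export
print.adc_result <- function(x, ...) {
  f <- function(v) signif(v * 1e3, 4)
  cat("<adc_result> b = (", x$pair$b1, ",", x$pair$b2, ") s/mm^2\n",
      "  ADC of mean signal: ", f(x$adc_of_mean_signal), " 1e-3 mm^2/s",
      if (x$flagged_negative) "  [FLAG: negative]", "\n",
      "  map summary (1e-3 mm^2/s): mean ", f(x$summary$mean),
      ", median ", f(x$summary$median), ", min ", f(x$summary$min),
      ", max ", f(x$summary$max), "\n",
      "  voxels used ", x$n_voxels_used, ", excluded ",
      x$n_voxels_excluded, "\n", sep = "")
  invisible(x)
}

#' Erode a VOI mask by a rim of voxels
#'
#' Morphological erosion with the face-connected (6-neighbour) structuring
#' element, applied `rim_voxels` times — the partial-volume mitigation used
#' when a delineation deliberately keeps a safety rim.
#'
#' @param mask a `voi_mask` or logical 3D array.
#' @param rim_voxels non-negative integer; 0 returns the mask unchanged.
#' @return eroded `voi_mask`.
#' @export
erode_mask <- function(mask, rim_voxels = 1L) {
  if (rim_voxels < 0) stop("rim_voxels must be >= 0")
  m <- array(mask > 0, dim = dim(mask))
  for (i in seq_len(rim_voxels)) {
    d <- dim(m)
    shift <- function(arr, ax, by) {
      out <- array(FALSE, dim = d)
      idx_src <- lapply(d, seq_len)
      idx_dst <- idx_src
      if (by == 1L) { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1L) }
      else { idx_dst[[ax]] <- 1:(d[ax] - 1L); idx_src[[ax]] <- 2:d[ax] }
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out
    }
    m <- m & shift(m, 1L, 1L) & shift(m, 1L, -1L) &
         shift(m, 2L, 1L) & shift(m, 2L, -1L) &
         shift(m, 3L, 1L) & shift(m, 3L, -1L)
    if (!any(m))
      stop("erosion by rim = ", rim_voxels,
           " empties the mask; use a smaller rim (or 0)")
  }
  voi_mask(m)
}
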