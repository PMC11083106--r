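# Group-level generative model: per-group truncated-normal distributions of
# the true VOI diffusivity, and cohort simulation.
#
# The defaults encode the study population this package emulates: five
# groups (Paget's disease PD, inflammatory breast cancer IBC, benign skin
# inflammation BSI, skin-involved breast cancer SIBC, healthy skin H) with
# published per-group mean "ADC of mean signal", dispersion printed as a
# standard error of the mean (SD is reconstructed as SEM * sqrt(n); with
# n = 11 and a printed range of 1.04-2.30, a plain SD of 0.11 would be
# impossible), observed min-max ranges used as truncation bounds, group
# sizes, typical VOI voxel counts, and typical high-b SNR levels.
# The healthy-skin row is the *measured* (noise-biased) distribution — the
# true healthy diffusivity is unknown and stays a free parameter.

#' Define a group-level diffusivity distribution
#'
#' Truncated normal law for the true VOI ADC of one group, in units of
#' 1e-3 mm^2/s.
#'
#' @param group label in `skin_groups()`.
#' @param mean_adc,sd_adc mean and SD of the underlying normal, 1e-3 mm^2/s.
#' @param truncation_range length-2 numeric bounds containing `mean_adc`.
#' @param n_default default number of cases simulated for the group.
#' @param voi_target_voxels typical VOI size in voxels.
#' @param snr_target typical high-b VOI SNR the generator aims for.
#' @param voi_type `"lesion"` or `"skin_slice"`.
#' @return object of class `group_distribution`.
#' @export
group_distribution <- function(group, mean_adc, sd_adc, truncation_range,
                               n_default, voi_target_voxels = 50L,
                               snr_target = 40, voi_type = "lesion") {
  group <- match.arg(group, skin_groups())
  if (sd_adc <= 0) stop("sd_adc must be > 0")
  if (length(truncation_range) != 2L ||
      truncation_range[1] >= truncation_range[2])
    stop("degenerate truncation_range: must be (lo, hi) with lo < hi")
  if (mean_adc < truncation_range[1] || mean_adc > truncation_range[2])
    stop("truncation_range must contain mean_adc")
  if (n_default < 0) stop("n_default must be >= 0")
  structure(list(group = group, mean_adc = mean_adc, sd_adc = sd_adc,
                 truncation_range = as.numeric(truncation_range),
                 n_default = as.integer(n_default),
                 voi_target_voxels = as.integer(voi_target_voxels),
                 snr_target = snr_target, voi_type = voi_type),
            class = "group_distribution")
}

#' Default group distributions of the emulated study population
#'
#' SD is SEM * sqrt(n); truncation bounds are the published group ranges.
#' The H entry reproduces the *measured* healthy-skin values, which are
#' noise-biased by construction; pass a replacement to assert a different
#' true healthy diffusivity.
#'
#' @return named list of `group_distribution` objects (PD, IBC, BSI, SIBC, H).
#' @export
default_group_distributions <- function() {
  list(
    PD = group_distribution("PD", 0.95, 0.23 * sqrt(3), c(0.59, 1.37),
                            n_default = 3, voi_target_voxels = 35,
                            snr_target = 14),
    IBC = group_distribution("IBC", 1.86, 0.17 * sqrt(5), c(1.28, 2.18),
                             n_default = 5, voi_target_voxels = 258,
                             snr_target = 59),
    BSI = group_distribution("BSI", 1.88, 0.11 * sqrt(11), c(1.04, 2.30),
                             n_default = 11, voi_target_voxels = 197,
                             snr_target = 56),
    SIBC = group_distribution("SIBC", 1.38, 0.13 * sqrt(11), c(0.73, 1.98),
                              n_default = 11, voi_target_voxels = 46,
                              snr_target = 37),
    H = group_distribution("H", 0.49, 0.02 * sqrt(58), c(0.23, 0.85),
                           n_default = 58, voi_target_voxels = 29,
                           snr_target = 2.04, voi_type = "skin_slice"))
}

#' Sample true diffusivities for a group
#'
#' Seeded rejection sampling from the group's truncated normal.
#'
#' @param dist a `group_distribution`.
#' @param n number of draws, >= 1.
#' @param seed optional integer seed (local RNG state).
#' @return numeric vector of length `n`, units 1e-3 mm^2/s, all inside the
#'   truncation range.
#' @export
sample_group_diffusivity <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "group_distribution"))
  if (n < 1) stop("n must be >= 1")
  draw <- function() {
    lo <- dist$truncation_range[1]; hi <- dist$truncation_range[2]
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, dist$mean_adc, dist$sd_adc)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a multi-group breast-skin DWI cohort
#'
#' For each case a true VOI diffusivity is drawn from its group
#' distribution, a phantom is synthesized around it, and the noise sigma is
#' set so that the noise-free VOI signal at the high b-value divided by
#' sigma equals the group's `snr_target`. Healthy-skin cases get
#' single-slice VOIs (~29 voxels); pathology VOIs are 3D lesions sized to
#' the group's typical voxel count.
#'
#' @param groups named list of `group_distribution`s (default
#'   [default_group_distributions()]).
#' @param n optional named integer vector overriding per-group case counts;
#'   a group with n = 0 is omitted.
#' @param snr_target optional scalar overriding every group's SNR target.
#' @param seed integer master seed; per-case sub-seeds are derived from it.
#' @param spec_base `phantom_spec` providing grid/geometry/b-value defaults.
#' @return list of class `skin_cohort`: `phantoms` (list of `skin_phantom`),
#'   `truth` (data.frame of ground-truth records), `manifest` (data.frame
#'   case_id/group).
#' @export
simulate_cohort <- function(groups = default_group_distributions(),
                            n = NULL, snr_target = NULL, seed = 1L,
                            spec_base = phantom_spec()) {
  if (!is.null(n)) {
    unknown <- setdiff(names(n), names(groups))
    if (length(unknown))
      stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  }
  # when `n` is given it fully specifies the cohort: unnamed groups get 0
  counts <- vapply(names(groups), function(g) {
    if (is.null(n)) groups[[g]]$n_default
    else if (g %in% names(n)) as.integer(n[[g]])
    else 0L
  }, integer(1))
  names(counts) <- names(groups)
  total <- sum(counts)
  # independent sub-seeds: one per case (noise) + one per group (sampling)
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, total + length(groups)))
  case_seeds <- seeds[seq_len(total)]
  group_seeds <- seeds[total + seq_along(groups)]
  names(group_seeds) <- names(groups)

  b_high <- max(spec_base$b_values)
  phantoms <- vector("list", total)
  k <- 0L
  for (g in names(groups)) {
    if (counts[[g]] == 0L) next
    dist <- groups[[g]]
    d_true <- sample_group_diffusivity(dist, counts[[g]],
                                       seed = group_seeds[[g]])
    tgt <- snr_target %||% dist$snr_target
    # lesion radius depends only on geometry + target: resolve once per group
    lesion_r <- if (dist$voi_type == "lesion")
      choose_lesion_radius(spec_base, dist$voi_target_voxels)
    for (i in seq_len(counts[[g]])) {
      k <- k + 1L
      D <- d_true[i] * 1e-3                  # 1e-3 mm^2/s -> mm^2/s
      spec <- spec_base
      spec$voi_type <- dist$voi_type
      spec$voi_target_voxels <- dist$voi_target_voxels
      if (dist$voi_type == "lesion") {
        spec$true_adc_lesion <- D
        spec$lesion_radius <- lesion_r
      } else {
        spec$true_adc_skin <- D
      }
      spec$noise_sigma <- spec$S0 * exp(-b_high * D) / tgt
      cid <- sprintf("%s_%03d", g, i)
      phantoms[[k]] <- make_skin_phantom(spec, seed = case_seeds[k],
                                         case_id = cid, group = g)
    }
  }
  phantoms <- phantoms[seq_len(k)]
  truth <- do.call(rbind, lapply(phantoms, `[[`, "truth"))
  structure(list(phantoms = phantoms, truth = truth,
                 manifest = truth[, c("case_id", "group")]),
            class = "skin_cohort")
}

#' @export
print.skin_cohort <- function(x, ...) {
  cat("<skin_cohort> ", nrow(x$truth), " cases: ",
      paste(sprintf("%s=%d", names(table(x$truth$group)),
                    as.integer(table(x$truth$group))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
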