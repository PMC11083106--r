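# Digital breast-skin DWI phantom.
#
# Geometry: a cylindrical "body" of breast tissue centred in the grid, whose
# outermost shell is a skin rim; a spherical lesion sits on the rim.  The
# corner of the grid stays signal-free and hosts a 2D background-noise ROI,
# mirroring how noise floors are measured on clinical magnitude images.
# Noise-free voxel signal follows the mono-exponential decay
# S(b) = S0 * exp(-b * D(x)); Rician noise (single-channel magnitude model)
# is applied on top at a controlled sigma.

#' Specify a breast-skin DWI phantom
#'
#' Diffusivities are in mm^2/s (typical soft-tissue values are of order
#' 1e-3), b-values in s/mm^2. Defaults: breast-tissue background 1.85e-3
#' (the conventional normal fibroglandular range is 1.7-2.0e-3), dermis-like
#' skin rim 1.2e-3, lesion 1.5e-3, b = \{50, 800\}.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing voxel edge lengths in mm.
#' @param body_radius radius (voxels) of the cylindrical body in-plane.
#' @param skin_rim_thickness thickness (voxels) of the outer skin shell.
#' @param lesion_center voxel coordinates (1-based) of the lesion sphere;
#'   default sits on the skin rim at the mid slice.
#' @param lesion_radius lesion sphere radius in voxels.
#' @param S0 noise-free signal at b = 0, arbitrary units.
#' @param true_adc_background,true_adc_skin,true_adc_lesion ground-truth
#'   diffusivities, mm^2/s.
#' @param b_values strictly increasing b-values, at least two.
#' @param noise_sigma Rician noise sigma in signal units (0 = noise-free).
#' @param noise_box in-plane edge length (voxels) of the corner noise ROI.
#' @param voi_type `"lesion"` (3D pathology VOI) or `"skin_slice"` (single
#'   axial slice of skin rim, used for healthy-skin cases).
#' @param voi_target_voxels approximate VOI size aimed for; for
#'   `"skin_slice"` the exact number of rim voxels taken on the slice.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 12L),
                         voxel_spacing = c(1.5, 1.5, 3),
                         body_radius = 10,
                         skin_rim_thickness = 2,
                         lesion_center = NULL,
                         lesion_radius = 2.2,
                         S0 = 1000,
                         true_adc_background = 1.85e-3,
                         true_adc_skin = 1.2e-3,
                         true_adc_lesion = 1.5e-3,
                         b_values = c(50, 800),
                         noise_sigma = 0,
                         noise_box = 8L,
                         voi_type = c("lesion", "skin_slice"),
                         voi_target_voxels = NULL) {
  voi_type <- match.arg(voi_type)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("grid_shape must be three integers >= 4")
  if (length(b_values) < 2L || any(diff(b_values) <= 0))
    stop("b_values must be strictly increasing with >= 2 entries")
  if (any(c(true_adc_background, true_adc_skin, true_adc_lesion) <= 0))
    stop("all diffusivities must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (skin_rim_thickness <= 0 || skin_rim_thickness >= body_radius)
    stop("skin_rim_thickness must be in (0, body_radius)")
  if (is.null(lesion_center)) {
    lesion_center <- c(round((grid_shape[1] + 1) / 2 + body_radius - 1),
                       round((grid_shape[2] + 1) / 2),
                       ceiling(grid_shape[3] / 2))
  }
  spec <- structure(
    list(grid_shape = grid_shape, voxel_spacing = as.numeric(voxel_spacing),
         body_radius = body_radius, skin_rim_thickness = skin_rim_thickness,
         lesion_center = as.numeric(lesion_center),
         lesion_radius = lesion_radius, S0 = S0,
         true_adc_background = true_adc_background,
         true_adc_skin = true_adc_skin, true_adc_lesion = true_adc_lesion,
         b_values = as.numeric(b_values), noise_sigma = noise_sigma,
         noise_box = as.integer(noise_box), voi_type = voi_type,
         voi_target_voxels = voi_target_voxels),
    class = "phantom_spec")
  validate_phantom_geometry(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$grid_shape, collapse = "x"),
      ", body r=", x$body_radius, ", rim ", x$skin_rim_thickness,
      ", voi ", x$voi_type, "\n",
      "  D (1e-3 mm^2/s): background ", x$true_adc_background * 1e3,
      ", skin ", x$true_adc_skin * 1e3, ", lesion ", x$true_adc_lesion * 1e3,
      "\n  b = {", paste(x$b_values, collapse = ", "), "} s/mm^2, S0 = ",
      x$S0, ", sigma = ", signif(x$noise_sigma, 4), "\n", sep = "")
  invisible(x)
}

# Deterministic geometry derived from a spec: logical masks for body, rim,
# lesion, noise ROI, plus the in-plane radial distance field.
phantom_geometry <- function(spec) {
  g <- spec$grid_shape
  cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2
  xs <- matrix(rep(seq_len(g[1]) - cx, g[2]), g[1], g[2])
  ys <- matrix(rep(seq_len(g[2]) - cy, each = g[1]), g[1], g[2])
  r2d <- sqrt(xs^2 + ys^2)
  body2d <- r2d <= spec$body_radius
  rim2d <- body2d & r2d > (spec$body_radius - spec$skin_rim_thickness)
  body <- array(body2d, dim = g)
  rim <- array(rim2d, dim = g)

  lc <- spec$lesion_center; lr <- spec$lesion_radius
  if (any(lc - lr < 1) || any(lc + lr > g))
    stop("lesion (center ", paste(lc, collapse = ","), ", radius ", lr,
         ") extends outside the grid")
  ii <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                              z = seq_len(g[3])))
  d2 <- (ii[, 1] - lc[1])^2 + (ii[, 2] - lc[2])^2 + (ii[, 3] - lc[3])^2
  lesion <- array(d2 <= lr^2, dim = g) & body

  nb <- spec$noise_box
  noise_roi <- array(FALSE, dim = g)
  noise_roi[seq_len(nb), seq_len(nb), 1L] <- TRUE   # 2D region, one slice
  if (any(noise_roi & body))
    stop("noise ROI overlaps the body: grid has no signal-free corner ",
         "(enlarge grid_shape or shrink body_radius/noise_box)")
  list(body = body, rim = rim, lesion = lesion, noise_roi = noise_roi,
       r2d = r2d)
}

validate_phantom_geometry <- function(spec) invisible(phantom_geometry(spec))

#' Apply single-channel Rician noise to a signal array
#'
#' Each voxel with noise-free signal s becomes
#' `sqrt((s + n1)^2 + n2^2)` with `n1`, `n2` independent zero-mean Gaussians
#' of standard deviation `sigma` (magnitude of a complex Gaussian channel).
#' At s = 0 this is a Rayleigh background with mean `sigma * sqrt(pi/2)`.
#'
#' @param volume numeric array (any shape).
#' @param sigma noise standard deviation, >= 0; 0 returns the input.
#' @param seed optional integer; when given, draws are made under a local
#'   RNG state so the call is reproducible and side-effect free.
#' @return array of the same shape.
#' @export
add_rician_noise <- function(volume, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  draw <- function() {
    n <- length(volume)
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    array(sqrt((as.vector(volume) + n1)^2 + n2^2), dim = dim(volume))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Lesion radius matching a target VOI voxel count
#'
#' Picks the sphere radius whose lesion mask (sphere intersected with the
#' body) contains the voxel count closest to `target`, for the geometry of
#' `spec`. Used to size group-typical VOIs.
#'
#' @param spec a `phantom_spec`.
#' @param target desired voxel count.
#' @param radii candidate radii scanned (voxels).
#' @return radius in voxels.
#' @export
choose_lesion_radius <- function(spec, target,
                                 radii = seq(1, min(spec$grid_shape) / 2 - 0.5,
                                             by = 0.05)) {
  g <- spec$grid_shape; lc <- spec$lesion_center
  cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2
  ii <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                              z = seq_len(g[3])))
  in_body <- sqrt((ii[, 1] - cx)^2 + (ii[, 2] - cy)^2) <= spec$body_radius
  d <- sqrt((ii[in_body, 1] - lc[1])^2 + (ii[in_body, 2] - lc[2])^2 +
            (ii[in_body, 3] - lc[3])^2)
  r_max <- min(lc - 1, g - lc)               # sphere must stay inside the grid
  radii <- radii[radii <= r_max]
  counts <- vapply(radii, function(r) sum(d <= r), numeric(1))
  keep <- counts >= 1
  if (!any(keep)) stop("no feasible lesion radius for target ", target)
  radii[keep][which.min(abs(counts[keep] - target))]
}

# Single-slice skin VOI of ~n voxels: rim voxels on the mid slice, taken as
# a contiguous arc ordered by azimuth (how a reader delineates skin on one
# representative slice).
skin_slice_voi <- function(spec, n_voxels) {
  geo <- phantom_geometry(spec)
  g <- spec$grid_shape
  z0 <- ceiling(g[3] / 2)
  rim_idx <- which(geo$rim[, , z0], arr.ind = TRUE)
  if (nrow(rim_idx) == 0L) stop("no rim voxels on the mid slice")
  cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2
  ang <- atan2(rim_idx[, 2] - cy, rim_idx[, 1] - cx)
  ord <- order(ang)
  take <- ord[seq_len(min(n_voxels, nrow(rim_idx)))]
  m <- array(FALSE, dim = g)
  m[cbind(rim_idx[take, , drop = FALSE], z0)] <- TRUE
  m
}

#' Generate one synthetic breast-skin DWI study
#'
#' Builds the noise-free mono-exponential stack for every b-value in the
#' spec, applies Rician noise, and returns the study together with its
#' measurement VOI, background-noise ROI, and a ground-truth record.
#' Identical `(spec, seed)` reproduce identical voxel data.
#'
#' @param spec a `phantom_spec`.
#' @param seed integer seed controlling the noise draw.
#' @param case_id,group metadata attached to the study.
#' @return list of class `skin_phantom` with elements `study` (`dwi_study`),
#'   `voi` (`voi_mask`), `noise_roi` (`voi_mask`), and `truth` (one-row
#'   data.frame: case_id, group, true_voi_adc in 1e-3 mm^2/s, noise_sigma,
#'   voi_voxel_count).
#' @export
make_skin_phantom <- function(spec, seed = 1L, case_id = "phantom",
                              group = NULL) {
  geo <- phantom_geometry(spec)
  g <- spec$grid_shape
  D <- array(0, dim = g)
  D[geo$body] <- spec$true_adc_background
  D[geo$rim] <- spec$true_adc_skin
  D[geo$lesion] <- spec$true_adc_lesion
  S0field <- array(0, dim = g)
  S0field[geo$body] <- spec$S0

  nb <- length(spec$b_values)
  vols <- array(0, dim = c(g, nb))
  for (i in seq_len(nb))
    vols[, , , i] <- S0field * exp(-spec$b_values[i] * D)
  if (spec$noise_sigma > 0)
    vols <- add_rician_noise(vols, spec$noise_sigma, seed = seed)

  voi_arr <- switch(spec$voi_type,
    lesion = geo$lesion,
    skin_slice = skin_slice_voi(spec, spec$voi_target_voxels %||% 29L))
  true_voi_adc <- switch(spec$voi_type,
    lesion = spec$true_adc_lesion,
    skin_slice = spec$true_adc_skin)

  study <- dwi_study(vols, spec$b_values, voxel_spacing = spec$voxel_spacing,
                     case_id = case_id, group = group)
  structure(
    list(study = study,
         voi = voi_mask(voi_arr, study = study),
         noise_roi = voi_mask(geo$noise_roi, study = study),
         spec = spec,
         truth = data.frame(case_id = case_id,
                            group = group %||% NA_character_,
                            true_voi_adc = true_voi_adc * 1e3,
                            noise_sigma = spec$noise_sigma,
                            voi_voxel_count = sum(voi_arr),
                            stringsAsFactors = FALSE)),
    class = "skin_phantom")
}

#' @export
print.skin_phantom <- function(x, ...) {
  cat("<skin_phantom> ", x$truth$case_id,
      " (", x$truth$group, "): true VOI ADC ",
      signif(x$truth$true_voi_adc, 4), " 1e-3 mm^2/s, ",
      x$truth$voi_voxel_count, " VOI voxels, sigma ",
      signif(x$truth$noise_sigma, 4), "\n", sep = "")
  invisible(x)
}
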