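# Core in-memory containers: dwi_study (4D stack + b-values) and voi_mask.
# Axis order is (x, y, z, b) at the API boundary; voxel indexing in R is
# 1-based (documented here once; on-disk metadata uses no voxel indices).

#' Construct a DWI study
#'
#' A validated container for one subject's multi-b-value DWI stack.
#'
#' @param volumes 4D numeric array, axes (x, y, z, b); signals must be
#'   non-negative.
#' @param b_values numeric vector of b-values (s/mm^2) aligned with the 4th
#'   axis.
#' @param voxel_spacing voxel edge lengths in mm, length 3.
#' @param case_id character scalar identifier.
#' @param group optional group label, one of `"PD"`, `"IBC"`, `"BSI"`,
#'   `"SIBC"`, `"H"`.
#' @return an object of class `dwi_study`.
#' @export
dwi_study <- function(volumes, b_values, voxel_spacing = c(1, 1, 1),
                      case_id = "case", group = NULL) {
  if (!is.array(volumes) || length(dim(volumes)) != 4L)
    stop("`volumes` must be a 4D array (x, y, z, b)")
  if (any(dim(volumes)[1:3] < 1L)) stop("spatial dimensions must be >= 1")
  if (length(b_values) != dim(volumes)[4])
    stop("b-value count (", length(b_values), ") does not match volume count (",
         dim(volumes)[4], ")")
  if (any(!is.finite(volumes))) stop("non-finite signal values")
  if (any(volumes < 0)) stop("negative signal values are not allowed")
  if (!is.null(group)) group <- match.arg(group, skin_groups())
  structure(
    list(volumes = volumes, b_values = as.numeric(b_values),
         voxel_spacing = as.numeric(voxel_spacing),
         case_id = as.character(case_id), group = group),
    class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  d <- dim(x$volumes)
  cat("<dwi_study> ", x$case_id,
      if (!is.null(x$group)) paste0(" [", x$group, "]"), "\n",
      "  grid ", d[1], "x", d[2], "x", d[3],
      ", voxel ", paste(signif(x$voxel_spacing, 3), collapse = "x"), " mm\n",
      "  b-values (s/mm^2): ", paste(x$b_values, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' The five study group labels
#' @return character vector `c("PD", "IBC", "BSI", "SIBC", "H")`.
#' @export
skin_groups <- function() c("PD", "IBC", "BSI", "SIBC", "H")

#' Construct a binary VOI mask
#'
#' @param mask logical or 0/1 numeric 3D array; values > 0 are foreground.
#' @param study optional `dwi_study` whose spatial grid the mask must match.
#' @param allow_empty keep an all-FALSE mask (used internally); by default an
#'   empty mask is an error.
#' @return logical 3D array of class `voi_mask`.
#' @export
voi_mask <- function(mask, study = NULL, allow_empty = FALSE) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  m <- array(as.vector(mask) > 0, dim = dim(mask))
  if (!allow_empty && !any(m)) stop("empty VOI: mask has no foreground voxels")
  if (!is.null(study)) {
    if (!identical(dim(m), dim(study$volumes)[1:3]))
      stop("mask shape (", paste(dim(m), collapse = "x"),
           ") does not match study grid (",
           paste(dim(study$volumes)[1:3], collapse = "x"), ")")
  }
  class(m) <- c("voi_mask", class(m))
  m
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", sum(x), " voxels on a ",
      paste(dim(x), collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a `voi_mask` or logical array.
#' @return integer count.
#' @export
voxel_count <- function(mask) sum(mask > 0)

volume_at_b <- function(study, b) {
  i <- match(b, study$b_values)
  if (is.na(i)) stop("b-value ", b, " not present in study (available: ",
                     paste(study$b_values, collapse = ", "), ")")
  study$volumes[, , , i, drop = TRUE]
}
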