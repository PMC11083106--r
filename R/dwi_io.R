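# On-disk artifacts: NIfTI volumes, FSL .bval files, JSON sidecars,
# manifest and result tables.

#' Read an FSL-style .bval file
#' @param path whitespace-separated b-values on one or more lines.
#' @return numeric vector.
#' @export
read_bval <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) == 0L) stop("no b-values in ", path)
  vals
}

#' Write an FSL-style .bval file
#' @param b_values numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bval <- function(b_values, path) {
  writeLines(paste(format(b_values, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' Write a DWI study to disk
#'
#' Emits `<case_id>_dwi.nii.gz` (float32), `<case_id>.bval` and a JSON
#' sidecar `<case_id>.json` carrying b-values and any extra metadata.
#'
#' @param study a `dwi_study`.
#' @param dir output directory (created if needed).
#' @param extra named list merged into the sidecar (e.g. noise sigma, seed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_dwi_study <- function(study, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, study$case_id)
  paths <- c(image = paste0(stem, "_dwi.nii.gz"),
             bval = paste0(stem, ".bval"),
             sidecar = paste0(stem, ".json"))
  write_nifti(study$volumes, paths[["image"]],
              voxel_spacing = study$voxel_spacing, datatype = "float32")
  write_bval(study$b_values, paths[["bval"]])
  side <- c(list(case_id = study$case_id, group = study$group,
                 b_values = study$b_values,
                 voxel_spacing = study$voxel_spacing), extra)
  jsonlite::write_json(side, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read a DWI study from disk
#'
#' @param image_path 4D NIfTI (.nii/.nii.gz).
#' @param bval_path FSL .bval file; if `NULL`, b-values are taken from the
#'   JSON sidecar.
#' @param sidecar_path optional JSON sidecar; defaults to `<stem>.json` next
#'   to the image when present.
#' @param case_id,group override metadata (defaults come from the sidecar or
#'   file stem).
#' @return a validated `dwi_study`.
#' @export
read_dwi_study <- function(image_path, bval_path = NULL, sidecar_path = NULL,
                           case_id = NULL, group = NULL) {
  nii <- read_nifti(image_path)
  if (length(nii$dim) != 4L)
    stop("expected a 4D DWI image, got ", length(nii$dim), "D: ", image_path)
  stem <- sub("(_dwi)?\\.nii(\\.gz)?$", "", image_path)
  if (is.null(sidecar_path)) {
    cand <- paste0(stem, ".json")
    if (file.exists(cand)) sidecar_path <- cand
  }
  side <- if (!is.null(sidecar_path)) jsonlite::read_json(sidecar_path) else list()
  b_values <- if (!is.null(bval_path)) read_bval(bval_path)
              else as.numeric(unlist(side$b_values))
  if (length(b_values) == 0L)
    stop("no b-values: provide a .bval file or a JSON sidecar")
  if (length(b_values) != nii$dim[4])
    stop("b-value count (", length(b_values),
         ") does not match volume count (", nii$dim[4], ")")
  dwi_study(nii$data, b_values, voxel_spacing = nii$voxel_spacing,
            case_id = case_id %||% side$case_id %||% basename(stem),
            group = group %||% unlist(side$group))
}

#' Read a VOI or noise-ROI mask and check it against a study
#'
#' Voxels > 0 are foreground (label images with small integer labels are
#' accepted).
#'
#' @param path NIfTI mask path.
#' @param study `dwi_study` whose grid the mask must match.
#' @return a `voi_mask`.
#' @export
read_mask <- function(path, study) {
  nii <- read_nifti(path)
  if (length(nii$dim) != 3L) stop("mask must be 3D: ", path)
  voi_mask(nii$data, study = study)
}

#' Write a mask as uint8 NIfTI
#' @param mask `voi_mask` or logical array.
#' @param path output path.
#' @param voxel_spacing voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_spacing = c(1, 1, 1)) {
  write_nifti(array(as.integer(mask > 0), dim = dim(mask)), path,
              voxel_spacing = voxel_spacing, datatype = "uint8")
}

#' Write analysis result tables and the run report
#'
#' @param tables named list; data.frame entries are written as
#'   `<name>.csv`, everything else into `run_report.json`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  report <- list()
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(x, p, row.names = FALSE)
      written <- c(written, p)
    } else {
      report[[nm]] <- x
    }
  }
  if (length(report)) {
    p <- file.path(out_dir, "run_report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    written <- c(written, p)
  }
  invisible(written)
}
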