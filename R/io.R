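# File-format plumbing: CSI tensors as a NIfTI pair (real/imaginary) with
# a JSON metadata sidecar, fitted maps and masks as NIfTI, tables as CSV.

#' Write a CSI dataset to disk
#'
#' The complex 4D tensor is stored as two 4D NIfTI volumes (`*_real.nii.gz`
#' and `*_imag.nii.gz`, FID dimension last) plus a JSON sidecar
#' (`*_meta.json`) holding the acquisition metadata.
#'
#' @param csi a `dmi_csi` dataset.
#' @param prefix output path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_csi <- function(csi, prefix) {
  stopifnot(inherits(csi, "dmi_csi"))
  x <- aperm(csi$data, c(2, 3, 4, 1)) # spatial first for NIfTI viewers
  RNifti::writeNifti(RNifti::asNifti(Re(x), pixdim = rep(csi$voxel_mm, 3)),
                     paste0(prefix, "_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(x), pixdim = rep(csi$voxel_mm, 3)),
                     paste0(prefix, "_imag.nii.gz"))
  meta <- csi[setdiff(names(csi), "data")]
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a CSI dataset written by [write_csi()]
#'
#' @param prefix path prefix used when writing.
#' @return A `dmi_csi` dataset.
#' @export
read_csi <- function(prefix) {
  re <- as.array(RNifti::readNifti(paste0(prefix, "_real.nii.gz")))
  im <- as.array(RNifti::readNifti(paste0(prefix, "_imag.nii.gz")))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  data <- aperm(re + 1i * im, c(4, 1, 2, 3))
  structure(c(list(data = data), meta), class = "dmi_csi")
}

#' Write fitted metabolite maps as NIfTI volumes
#'
#' One volume per metabolite per quantity (amplitude and phase), plus the
#' glucose linewidth and water-frequency maps.
#'
#' @param fit a [fit_csi()] result.
#' @param prefix output path prefix.
#' @param voxel_mm voxel size recorded in the headers (default 15).
#' @return The written paths, invisibly.
#' @export
write_fit_maps <- function(fit, prefix, voxel_mm = 15) {
  stopifnot(inherits(fit, "dmi_csi_fit"))
  paths <- character(0)
  wr <- function(arr, name) {
    p <- paste0(prefix, "_", name, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(voxel_mm, 3)), p)
    p
  }
  for (i in seq_along(fit$metabolites)) {
    m <- fit$metabolites[i]
    paths <- c(paths, wr(fit$amplitude[, , , i], paste0(m, "_amplitude")),
               wr(fit$phase[, , , i], paste0(m, "_phase")))
  }
  paths <- c(paths, wr(fit$linewidth_glc_hz, "glc_linewidth_hz"),
             wr(fit$f0_hz, "f0_hz"))
  invisible(paths)
}

#' Write a time course as tidy CSV
#'
#' @param tc time-course data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(tc, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of
#' [dmi_default_config()]; everything else keeps its default.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `dmi_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext)
  }
  cfg <- dmi_default_config()
  allowed <- names(cfg)
  bad <- setdiff(names(user), c(allowed, "n_d2", "n_d7", "repeats"))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cohort_over <- intersect(names(user), c("n_d2", "n_d7", "repeats"))
  if (length(cohort_over)) {
    args <- user[cohort_over]
    cfg$cohort <- do.call(cohort_spec, args)
    user <- user[setdiff(names(user), cohort_over)]
  }
  utils::modifyList(cfg, user)
}
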