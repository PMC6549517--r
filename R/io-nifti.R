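#' Write a velocity dataset as a NIfTI triplet with a metadata sidecar
#'
#' Stores one 4D NIfTI volume per velocity direction (`<prefix>_vx.nii.gz`,
#' `_vy`, `_vz`) plus `<prefix>_meta.yaml` holding the voxel spacing, frame
#' times, cycle duration, VENC, origin and the stored velocity units.
#'
#' @param field a [velocity_field()].
#' @param prefix path prefix for the four files.
#' @param units units to store the values in, `"m/s"` or `"cm/s"`.
#' @return the sidecar path, invisibly.
#' @export
write_velocity_dataset <- function(field, prefix, units = c("m/s", "cm/s")) {
  units <- match.arg(units)
  stopifnot(inherits(field, "velocity_field"))
  scale <- if (units == "cm/s") 100 else 1
  comp <- c("vx", "vy", "vz")
  for (i in 1:3) {
    img <- field$values[, , , , i, drop = TRUE] * scale
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = c(field$spacing, 1)),
                       paste0(prefix, "_", comp[i], ".nii.gz"))
  }
  meta <- list(spacing_mm = as.numeric(field$spacing),
               frame_times_s = as.numeric(field$frame_times),
               cycle_s = field$cycle_s,
               venc_cms = field$venc_cms,
               origin_mm = as.numeric(field$origin),
               units = units)
  path <- paste0(prefix, "_meta.yaml")
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Read a velocity dataset
#'
#' Reads the on-disk representation back into a [velocity_field()]. The
#' only dialect implemented is the NIfTI triplet with YAML sidecar written
#' by [write_velocity_dataset()]; values are converted to m/s according to
#' the units declared in the sidecar.
#'
#' @param prefix path prefix (as given to [write_velocity_dataset()]).
#' @param dialect storage dialect; only `"nifti"` is available.
#' @return a [velocity_field()].
#' @export
read_velocity_dataset <- function(prefix, dialect = c("nifti", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5")
    stop("the HDF5 dialect is not available in this build; use the NIfTI triplet",
         call. = FALSE)
  meta_path <- paste0(prefix, "_meta.yaml")
  if (!file.exists(meta_path))
    stop(sprintf("metadata sidecar not found: %s", meta_path), call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  for (fld in c("spacing_mm", "frame_times_s", "venc_cms", "units"))
    if (is.null(meta[[fld]]))
      stop(sprintf("metadata field '%s' missing in %s", fld, meta_path),
           call. = FALSE)
  comp <- c("vx", "vy", "vz")
  vols <- lapply(comp, function(cc) {
    f <- paste0(prefix, "_", cc, ".nii.gz")
    if (!file.exists(f)) stop(sprintf("missing component volume: %s", f),
                              call. = FALSE)
    as.array(RNifti::readNifti(f))
  })
  dims <- lapply(vols, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("dimension mismatch across the three component volumes", call. = FALSE)
  d <- dims[[1]]
  vals <- array(0, c(d, 3))
  for (i in 1:3) vals[, , , , i] <- vols[[i]]
  if (meta$units == "cm/s") vals <- vals / 100
  else if (meta$units != "m/s")
    stop(sprintf("unknown velocity units '%s'", meta$units), call. = FALSE)
  velocity_field(vals, spacing = meta$spacing_mm,
                 frame_times = meta$frame_times_s,
                 venc_cms = meta$venc_cms,
                 cycle_s = meta$cycle_s %||% NULL,
                 origin = meta$origin_mm %||% c(0, 0, 0))
}

#' Write / read a chamber mask as NIfTI with a YAML sidecar
#'
#' @param mask a [chamber_mask()].
#' @param prefix path prefix (`<prefix>.nii.gz` + `<prefix>_meta.yaml`).
#' @return `write_chamber_mask()` the sidecar path invisibly;
#'   `read_chamber_mask()` a [chamber_mask()].
#' @export
write_chamber_mask <- function(mask, prefix) {
  stopifnot(inherits(mask, "chamber_mask"))
  RNifti::writeNifti(RNifti::asNifti(mask$data, pixdim = mask$spacing),
                     paste0(prefix, ".nii.gz"))
  path <- paste0(prefix, "_meta.yaml")
  yaml::write_yaml(list(frame = mask$frame, label = mask$label,
                        spacing_mm = as.numeric(mask$spacing),
                        origin_mm = as.numeric(mask$origin)), path)
  invisible(path)
}

#' @rdname write_chamber_mask
#' @export
read_chamber_mask <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  dat <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  dat <- array(round(as.numeric(dat)), dim(dat))
  chamber_mask(dat, frame = meta$frame, label = meta$label,
               spacing = meta$spacing_mm, origin = meta$origin_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
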