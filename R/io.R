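#' Read and write volumes, masks and displacement fields as NIfTI
#'
#' Thin wrappers around RNifti preserving the grid geometry (anisotropic
#' spacing in the NIfTI pixdim). Masks are stored as uint8 and
#' reproduce bit-exactly; displacement fields are 4D float volumes with
#' the component along the fourth dimension.
#'
#' @param x object to write.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_*` return the corresponding package object; `write_*`
#'   return `path` invisibly.
#' @name irv4d-io
NULL

#' @rdname irv4d-io
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data, reference = NULL)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname irv4d-io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol3d(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname irv4d-io
#' @export
write_mask <- function(x, path) {
  img <- RNifti::asNifti(array(as.integer(x$data), dim(x$data)))
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname irv4d-io
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  mask3d(array(as.integer(img) > 0, dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname irv4d-io
#' @export
write_dvf <- function(x, path) {
  d <- dim(x$ux)
  arr <- array(0, c(d, 3))
  arr[, , , 1] <- x$ux; arr[, , , 2] <- x$uy; arr[, , , 3] <- x$uz
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(x$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname irv4d-io
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  dvf3d(a[, , , 1], a[, , , 2], a[, , , 3], RNifti::pixdim(img)[1:3])
}

#' Write a series manifest describing phases, organs and provenance
#'
#' @param dir output directory containing the written NIfTI files.
#' @param phases,organs,seed,series manifest fields.
#' @param extra optional named list merged into the manifest.
#' @return manifest path invisibly.
#' @export
write_manifest <- function(dir, phases, organs, seed, series = "navigator",
                           extra = list()) {
  man <- c(list(phases = phases, organs = organs, seed = seed,
                series = series, package = "irv4d"), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @param path manifest path.
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a phantom/study configuration from YAML
#'
#' Recognized top-level keys are the arguments of [phantom_config()]
#' (under `phantom:`) and of [study_config()] (everything else).
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)

#' Export a phantom subject to a directory of NIfTI files
#'
#' Writes one intensity volume and one mask per organ per phase, plus a
#' JSON manifest.
#'
#' @param phantom an `"irv_phantom"`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
export_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  organs <- names(phantom$config$organ_geometry)
  for (p in seq_along(phantom$phases)) {
    write_volume(phantom$phases[[p]],
                 file.path(dir, sprintf("phase%02d.nii.gz", p - 1)))
    for (o in organs)
      write_mask(phantom$truth[[p]]$masks[[o]],
                 file.path(dir, sprintf("phase%02d_%s.nii.gz", p - 1, o)))
  }
  write_manifest(dir, phases = length(phantom$phases), organs = organs,
                 seed = phantom$config$seed)
  invisible(dir)
}
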