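#' Save and load acquisitions and reconstructions
#'
#' Serializes simulated acquisitions (`kspace_data`), parameter maps and
#' experiment tables into a single portable RDS container with a format tag
#' and version, so whole experiments can be archived and reloaded.
#'
#' @param object the object to save.
#' @param path file path (conventionally `.rds`).
#' @return `write_container()` returns `path` invisibly; `read_container()`
#'   returns the stored object.
#' @export
write_container <- function(object, path) {
  saveRDS(list(format = "t1rhomap-container", version = 1L,
               class = class(object), object = object),
          path, version = 3L)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "t1rhomap-container"))
    stop("not a t1rhomap container: ", path)
  x$object
}

#' Export parameter maps as NIfTI volumes
#'
#' Writes the S0, T1rho and phase maps of a [parameter_maps()] object as
#' three NIfTI files `<prefix>_s0.nii.gz`, `<prefix>_t1rho.nii.gz`,
#' `<prefix>_phase.nii.gz`.
#'
#' @param maps a [parameter_maps()] object.
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_maps_nifti <- function(maps, prefix) {
  stopifnot(inherits(maps, "parameter_maps"))
  paths <- paste0(prefix, "_", c("s0", "t1rho", "phase"), ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(maps$s0), paths[1L])
  RNifti::writeNifti(RNifti::asNifti(maps$t1rho), paths[2L])
  RNifti::writeNifti(RNifti::asNifti(maps$phase), paths[3L])
  invisible(paths)
}

#' @rdname write_maps_nifti
#' @export
read_maps_nifti <- function(prefix) {
  paths <- paste0(prefix, "_", c("s0", "t1rho", "phase"), ".nii.gz")
  arr <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    matrix(as.numeric(v), dim(v)[1L], dim(v)[2L])
  })
  parameter_maps(s0 = arr[[1L]], t1rho = arr[[2L]], phase = arr[[3L]])
}
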