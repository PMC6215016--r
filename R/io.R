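#' Write a kernel to disk as NIfTI volumes with a JSON sidecar
#'
#' One NIfTI volume per channel (`<name>_dose.nii.gz`,
#' `<name>_fluence.nii.gz`) plus `<name>.json` recording species, energy,
#' Bragg depth, units, grid geometry and seed.
#'
#' @param kernel A `beam_kernel`.
#' @param dir Output directory (created if missing).
#' @param name Basename for the three files; defaults to
#'   `<species>_<energy>`.
#' @return Invisibly, the sidecar path.
#' @export
write_kernel <- function(kernel, dir, name = NULL) {
  stopifnot(inherits(kernel, "beam_kernel"))
  if (is.null(name)) name <- sprintf("%s_%g", kernel$species, kernel$energy)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("dose", "fluence")) {
    img <- RNifti::asNifti(kernel[[ch]])
    RNifti::pixdim(img) <- kernel$grid$voxel
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", name, ch)))
  }
  side <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(species = kernel$species, energy = kernel$energy,
         bragg_depth_mm = kernel$bragg_depth,
         units = list(dose = "Gy/primary", fluence = "n/cm^2/primary"),
         grid = list(extent_mm = kernel$grid$extent[1],
                     voxel_mm = kernel$grid$voxel[1]),
         seed = kernel$meta$seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a kernel written by [write_kernel()]
#'
#' @param dir Directory containing the three files.
#' @param name Basename used at write time.
#' @return A `beam_kernel`.
#' @export
read_kernel <- function(dir, name) {
  side <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  grid <- grid_spec(extent = side$grid$extent_mm, voxel = side$grid$voxel_mm)
  rd <- function(ch) {
    arr <- as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_%s.nii.gz", name, ch))))
    array(as.numeric(arr), dim = dim(arr))
  }
  structure(list(species = side$species, energy = side$energy, grid = grid,
                 dose = rd("dose"), fluence = rd("fluence"),
                 bragg_depth = side$bragg_depth_mm,
                 meta = list(seed = side$seed)),
            class = "beam_kernel")
}
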