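# Shared fixtures. Small grids keep the unit tests fast; the acceptance
# tests use the default 2.5 mm / 250 mm grid via the cache below.

small_grid <- function() grid_spec(extent = 200, voxel = 5)   # 40^3
tiny_grid <- function() grid_spec(extent = 50, voxel = 5)     # 10^3

default_params <- function() beam_model_params()

# hand-built kernel with a prescribed fluence field (for noise calibration)
manual_kernel <- function(grid, fluence, dose = fluence, bragg_depth = NULL,
                          species = "proton", energy = 100) {
  k <- structure(list(species = species, energy = energy, grid = grid,
                      dose = dose, fluence = fluence,
                      bragg_depth = NA_real_,
                      meta = list(noise_enabled = TRUE, seed = 1L)),
                 class = "beam_kernel")
  k$bragg_depth <- if (is.null(bragg_depth)) locate_bragg_peak(k) else bragg_depth
  k
}

# lateral FWHM of a dose slice, measured by linear interpolation of the
# half-maximum crossings along x through the beam axis
measure_fwhm <- function(kernel, zindex) {
  g <- kernel$grid
  prof <- kernel$dose[, ceiling(g$shape[2] / 2), zindex]
  x <- (seq_len(g$shape[1]) - 0.5) * g$voxel[1] - g$extent[1] / 2
  half <- max(prof) / 2
  above <- which(prof >= half)
  i1 <- min(above); i2 <- max(above)
  left <- if (i1 > 1) {
    x[i1 - 1] + (half - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1]) * g$voxel[1]
  } else x[i1]
  right <- if (i2 < length(x)) {
    x[i2] + (prof[i2] - half) / (prof[i2] - prof[i2 + 1]) * g$voxel[1]
  } else x[i2]
  right - left
}

# session-level cache for the expensive default-resolution objects shared by
# the acceptance tests
.cache <- new.env(parent = emptyenv())

cached_library <- function(species) {
  key <- paste0("lib_", species)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- build_kernel_library(species, grid_spec(),
                                          beam_model_params())
  .cache[[key]]
}

cached_plan <- function(species) {
  key <- paste0("plan_", species)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- optimize_plan(cached_library(species),
                                   treatment_volume(c(100, 150)),
                                   D = 1, step = 1)
  .cache[[key]]
}
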