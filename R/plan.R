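#' Treatment volume and spot-grid specification
#'
#' A cubic treatment volume centred on the beam axis: `depth_range` along
#' the beam (50 mm deep by default) and a `lateral` mm square cross
#' section. The pencil beam is stepped across a `rows` x `cols` transverse
#' spot grid with `spacing` mm between spots (defaults 11 x 11 at 5 mm,
#' i.e. spots spanning the 50 mm treatment plane with spacing equal to the
#' beam FWHM).
#'
#' @param depth_range `c(z_min, z_max)` in mm; default `c(100, 150)`, the
#'   shallow study volume (the deep volume is `c(140, 190)`).
#' @param lateral Side of the square cross-section in mm (default 50).
#' @param rows,cols Spot grid dimensions (default 11 each).
#' @param spacing Spot spacing in mm (default 5).
#' @return Object of class `treatment_volume`.
#' @export
treatment_volume <- function(depth_range = c(100, 150), lateral = 50,
                             rows = 11, cols = 11, spacing = 5) {
  stopifnot(length(depth_range) == 2, depth_range[2] > depth_range[1],
            lateral > 0, rows >= 1, cols >= 1, spacing > 0)
  structure(list(depth_range = as.numeric(depth_range), lateral = lateral,
                 rows = as.integer(rows), cols = as.integer(cols),
                 spacing = spacing),
            class = "treatment_volume")
}

#' @export
print.treatment_volume <- function(x, ...) {
  cat(sprintf("<treatment_volume> depth %g-%g mm, %g mm square, %dx%d spots @ %g mm\n",
              x$depth_range[1], x$depth_range[2], x$lateral,
              x$rows, x$cols, x$spacing))
  invisible(x)
}

#' Logical in-volume mask over a grid
#' @param grid A [grid_spec()].
#' @param volume A [treatment_volume()].
#' @return Logical array; voxel centres inside the volume.
#' @export
volume_mask <- function(grid, volume) {
  h <- volume$lateral / 2
  inx <- abs(grid_x(grid)) <= h
  iny <- abs(grid_y(grid)) <= h
  z <- grid_z(grid)
  inz <- z >= volume$depth_range[1] & z <= volume$depth_range[2]
  outer(outer(inx, iny, `&`), inz, `&`)
}

# centred spot offsets in mm for one transverse axis
spot_offsets <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Average a pencil-beam map over the transverse spot grid
#'
#' Returns (1/RC) * sum over all R x C spot translations of the input map,
#' i.e. the per-primary map of a layer delivered with equal weight to every
#' spot. Because the spot positions form a product grid, the average is
#' computed separably: the mean over row offsets along x, then over column
#' offsets along y. Translations use [shift_axis()] (linear resampling for
#' non-integer voxel offsets, zero fill at the faces). Applied identically
#' to BED and fluence channels.
#'
#' @param map 3D numeric array on `grid`.
#' @param volume A [treatment_volume()] providing the spot grid.
#' @param grid The [grid_spec()] of `map`.
#' @return Averaged array of the same shape.
#' @export
lateral_average <- function(map, volume, grid) {
  stopifnot(is.array(map), identical(dim(map), as.integer(grid$shape)))
  offx <- spot_offsets(volume$rows, volume$spacing) / grid$voxel[1]
  offy <- spot_offsets(volume$cols, volume$spacing) / grid$voxel[2]
  if (max(abs(offx)) >= grid$shape[1] / 2 ||
      max(abs(offy)) >= grid$shape[2] / 2)
    stop("spot grid translations push the beam outside the phantom")
  avg1 <- function(a, axis, offs) {
    out <- 0
    for (s in offs) out <- out + shift_axis(a, axis, s)
    out / length(offs)
  }
  avg1(avg1(map, 1, offx), 2, offy)
}

#' Energies whose Bragg peaks fall inside the treatment volume
#'
#' Walks the library energy grid at the requested step and keeps every
#' energy whose interpolated Bragg depth lies within the volume's depth
#' range, i.e. the energy layers that build the SOBP.
#'
#' @param volume A [treatment_volume()].
#' @param library A [build_kernel_library()].
#' @param step Energy step in MeV/u (default 1).
#' @return Increasing vector of energies (MeV/u).
#' @export
select_energies <- function(volume, library, step = 1) {
  e <- library_energies(library, step)
  d <- interp_bragg_depth(e, library$ref_table)
  keep <- d >= volume$depth_range[1] & d <= volume$depth_range[2]
  if (!any(keep)) {
    stop(sprintf(paste0("no library energy has a Bragg depth inside [%g, %g] mm; ",
                        "achievable depths span [%.1f, %.1f] mm"),
                 volume$depth_range[1], volume$depth_range[2], min(d), max(d)))
  }
  e[keep]
}

#' Non-negative least-squares SOBP weights
#'
#' Solves `argmin_N || sum_k N_k BED_k - D ||^2` over the in-volume voxels
#' subject to `N_k >= 0`, using the active-set non-negative least-squares
#' algorithm (Lawson-Hanson, via `pracma::lsqnonneg`). Exact NNLS is used
#' rather than a generic gradient optimiser: the problem is a convex
#' quadratic, so the solution is the same, and the active-set solver is
#' deterministic with no initialisation or seed to document.
#'
#' @param bed_stack Numeric matrix, one column per energy, one row per
#'   in-volume voxel, of per-primary BED (GyE/primary).
#' @param D Target dose in GyE (default 1).
#' @return List with `weights` (primaries per energy, >= 0) and `residual`
#'   (the minimised objective, GyE^2).
#' @export
optimize_weights <- function(bed_stack, D = 1) {
  bed_stack <- as.matrix(bed_stack)
  if (any(bed_stack < 0)) stop("BED stack contains negative entries")
  if (all(bed_stack == 0)) stop("BED stack is all zero inside the volume")
  sol <- pracma::lsqnonneg(bed_stack, rep(D, nrow(bed_stack)))
  w <- as.numeric(sol$x)
  list(weights = pmax(w, 0),
       residual = sum((bed_stack %*% w - D)^2))
}

#' Accumulate total fluence from per-energy maps
#'
#' `phi = sum_k N_k phi_k`, voxelwise.
#'
#' @param weights Primaries per energy.
#' @param maps List of per-primary fluence maps, aligned with `weights`.
#' @return Total fluence map.
#' @export
accumulate_fluence <- function(weights, maps) {
  if (length(weights) != length(maps))
    stop("length mismatch: ", length(weights), " weights vs ",
         length(maps), " maps")
  out <- 0
  for (k in seq_along(maps)) out <- out + weights[k] * maps[[k]]
  out
}

#' Fluence summary statistics inside the treatment volume
#'
#' @param phi Total fluence map (n/cm^2), normalised per GyE of in-volume
#'   mean BED.
#' @param volume A [treatment_volume()].
#' @param grid The [grid_spec()] of `phi`.
#' @return Named vector `c(min, mean, max)` in n/cm^2 per GyE.
#' @export
fluence_stats <- function(phi, volume, grid) {
  m <- volume_mask(grid, volume)
  if (!any(m)) stop("treatment volume contains no voxels on this grid")
  v <- phi[m]
  c(min = min(v), mean = mean(v), max = max(v))
}

#' Optimise a full spread-out Bragg peak treatment plan
#'
#' End-to-end plan construction for one species and treatment volume:
#' select the energy layers whose Bragg peaks fall inside the volume, build
#' each layer's laterally-averaged BED and fluence maps from the kernel
#' library (carbon kernels are RBE-weighted per their position in the
#' SOBP), solve the non-negative least-squares problem for the per-energy
#' primary counts targeting a flat `D` GyE, and accumulate the total BED,
#' physical dose and thermal neutron fluence maps.
#'
#' After optimisation the weights are rescaled so that the in-volume mean
#' BED is exactly `D`; fluence-per-GyE statistics are computed from the
#' rescaled plan, while `mean_bed_raw` records the unrescaled in-volume
#' mean BED actually achieved by the optimiser.
#'
#' @param library A [build_kernel_library()].
#' @param volume A [treatment_volume()].
#' @param D Target biological dose in GyE (default 1).
#' @param step Energy step in MeV/u (default 1; use 6 for the coarse preset).
#' @param rbe An [rbe_params()].
#' @param normalize Rescale weights to an in-volume mean BED of exactly `D`
#'   (default TRUE).
#' @param verbose Print per-layer progress.
#' @return Object of class `plan_result` with fields `species`, `energies`,
#'   `weights`, `weights_raw`, `residual`, `mean_bed_raw`, `bed`, `dose`,
#'   `fluence` (3D maps), `stats` (fluence min/mean/max per GyE), `bed_cv`
#'   (in-volume coefficient of variation of BED), `volume`, `grid`.
#' @export
optimize_plan <- function(library, volume = treatment_volume(), D = 1,
                          step = 1, rbe = rbe_params(), normalize = TRUE,
                          verbose = FALSE) {
  stopifnot(inherits(library, "kernel_library"),
            inherits(volume, "treatment_volume"), D > 0)
  grid <- library$grid
  mask <- volume_mask(grid, volume)
  energies <- select_energies(volume, library, step)
  sobp <- volume$depth_range
  layer <- function(e, bed_only = FALSE) {
    k <- kernel_at(library, e)
    bed <- apply_rbe(k, sobp = sobp, params = rbe)
    out <- list(bed = lateral_average(bed$dose, volume, grid))
    if (!bed_only) {
      out$dose <- lateral_average(k$dose, volume, grid)
      out$fluence <- lateral_average(k$fluence, volume, grid)
    }
    out
  }
  # pass 1: in-volume BED stack only (kept small)
  stack <- matrix(0, sum(mask), length(energies))
  for (j in seq_along(energies)) {
    if (verbose) message("layer ", energies[j], " MeV/u (", j, "/",
                         length(energies), ")")
    stack[, j] <- layer(energies[j], bed_only = TRUE)$bed[mask]
  }
  opt <- optimize_weights(stack, D)
  mean_raw <- mean(stack %*% opt$weights)
  w <- if (normalize) opt$weights * (D / mean_raw) else opt$weights
  # pass 2: accumulate full maps with the final weights
  bed_map <- dose_map <- phi_map <- array(0, grid$shape)
  for (j in seq_along(energies)) {
    L <- layer(energies[j])
    bed_map <- bed_map + w[j] * L$bed
    dose_map <- dose_map + w[j] * L$dose
    phi_map <- phi_map + w[j] * L$fluence
  }
  bed_in <- bed_map[mask]
  structure(list(species = library$species, energies = energies,
                 weights = w, weights_raw = opt$weights,
                 residual = opt$residual, mean_bed_raw = mean_raw,
                 bed = bed_map, dose = dose_map, fluence = phi_map,
                 stats = fluence_stats(phi_map, volume, grid),
                 bed_cv = stats::sd(bed_in) / mean(bed_in),
                 volume = volume, grid = grid),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> %s, %d energy layers (%g-%g MeV/u)\n",
              x$species, length(x$energies), min(x$energies), max(x$energies)))
  cat(sprintf("  in-volume mean BED (raw) %.4f GyE, CV %.2f%%, NNLS residual %.3g\n",
              x$mean_bed_raw, 100 * x$bed_cv, x$residual))
  cat(sprintf("  fluence per GyE: min %.3g / mean %.3g / max %.3g n/cm^2\n",
              x$stats["min"], x$stats["mean"], x$stats["max"]))
  invisible(x)
}
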