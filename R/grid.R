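#' Voxel grid specification for a cubic phantom
#'
#' Defines the scoring grid used for all per-primary kernels: a cube of
#' `extent` mm on each side divided into isotropic voxels of `voxel` mm.
#' The beam travels along the third array axis (z = depth), entering the
#' phantom at z = 0; the x and y axes are centred on the beam axis, so
#' lateral coordinates run from -extent/2 to +extent/2.
#'
#' Voxel values are intensive quantities (dose in Gy, fluence in n/cm^2)
#' sampled at voxel centres: x_i = (i - 1/2) * voxel - extent/2 and
#' z_k = (k - 1/2) * voxel.
#'
#' @param extent Side length of the cubic phantom in mm (default 250,
#'   a desk-scale homogeneous PMMA cube).
#' @param voxel Isotropic voxel size in mm (default 2.5, i.e. 100^3 voxels).
#' @return An object of class `grid_spec` with fields `shape`, `voxel`,
#'   `extent`.
#' @examples
#' g <- grid_spec(extent = 100, voxel = 5)
#' g$shape
#' @export
grid_spec <- function(extent = 250, voxel = 2.5) {
  stopifnot(is.numeric(extent), length(extent) == 1, extent > 0,
            is.numeric(voxel), length(voxel) == 1, voxel > 0)
  n <- extent / voxel
  if (abs(n - round(n)) > 1e-8)
    stop("voxel size (", voxel, " mm) must divide the extent (", extent, " mm)")
  n <- as.integer(round(n))
  structure(list(shape = c(n, n, n), voxel = rep(voxel, 3),
                 extent = rep(extent, 3)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g mm isotropic (%g mm cube)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel[1], x$extent[1]))
  invisible(x)
}

# voxel-centre coordinates; x/y centred on the beam axis, z measured from the
# entry face
grid_x <- function(grid) (seq_len(grid$shape[1]) - 0.5) * grid$voxel[1] - grid$extent[1] / 2
grid_y <- function(grid) (seq_len(grid$shape[2]) - 0.5) * grid$voxel[2] - grid$extent[2] / 2
grid_z <- function(grid) (seq_len(grid$shape[3]) - 0.5) * grid$voxel[3]

# voxel volume in cm^3 (voxel sizes are mm)
grid_voxvol_cm3 <- function(grid) prod(grid$voxel) / 1000

same_grid <- function(a, b) {
  isTRUE(all.equal(a$shape, b$shape)) && isTRUE(all.equal(a$voxel, b$voxel))
}

# Extract a[... idx ...] along one axis, zero-filling indices outside 1..n.
index_take <- function(a, axis, idx) {
  d <- dim(a)
  ok <- idx >= 1L & idx <= d[axis]
  clamped <- pmin.int(pmax.int(idx, 1L), d[axis])
  args <- lapply(d, seq_len)
  args[[axis]] <- clamped
  out <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  if (!all(ok)) {
    zargs <- lapply(d, seq_len)
    zargs[[axis]] <- which(!ok)
    out <- do.call(`[<-`, c(list(out), zargs, list(value = 0)))
  }
  out
}

#' Shift an array along one axis by a (possibly fractional) voxel offset
#'
#' Content moves towards larger indices for positive `s`. Fractional shifts
#' are realised by linear resampling between the two straddling voxels;
#' voxels shifted in from outside the grid are zero-filled. This is the
#' translation primitive used both for Bragg-peak alignment of kernels along
#' depth and for stepping pencil-beam maps across the transverse spot grid.
#'
#' @param a Numeric array.
#' @param axis Axis index (1 = x, 2 = y, 3 = z/depth).
#' @param s Shift in voxels; may be negative or fractional.
#' @return Array of the same shape.
#' @export
shift_axis <- function(a, axis, s) {
  stopifnot(is.array(a), axis %in% seq_along(dim(a)), is.finite(s))
  if (s == 0) return(a)
  m <- floor(s)
  f <- s - m
  n <- dim(a)[axis]
  out <- index_take(a, axis, seq_len(n) - m)
  if (f > 1e-12) {
    out <- (1 - f) * out + f * index_take(a, axis, seq_len(n) - m - 1L)
  }
  out
}
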