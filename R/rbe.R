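#' RBE model parameters
#'
#' Proton biological effective dose (BED) uses a single constant RBE
#' (default 1.1). Carbon uses a per-pencil-beam peak RBE determined by the
#' beam's position within the spread-out Bragg peak (2.5 at the proximal
#' edge, 3.0 at the centre, 3.3 at the distal edge, linearly interpolated
#' and clamped), a plateau value of 1.5 in the entrance/buildup region
#' (where the laterally-integrated dose is below `plateau_threshold` of its
#' maximum), and a linear-in-depth ramp joining the two between the
#' threshold depth and the pencil's Bragg peak. Distal to the peak the RBE
#' is held at the peak value by default (`distal_mode = "hold"`); set
#' `distal_mode = "plateau"` to fall back to 1.5 where the dose drops below
#' the threshold again in the fragmentation tail.
#'
#' @param proton_factor Constant proton RBE (default 1.1).
#' @param carbon_plateau,carbon_proximal,carbon_centre,carbon_distal Carbon
#'   RBE anchors (defaults 1.5 / 2.5 / 3.0 / 3.3).
#' @param plateau_threshold Fraction of the maximum laterally-integrated
#'   dose below which (proximally) the plateau RBE applies (default 0.60).
#' @param distal_mode Behaviour beyond the pencil's Bragg peak.
#' @return Object of class `rbe_params`.
#' @export
rbe_params <- function(proton_factor = 1.1, carbon_plateau = 1.5,
                       carbon_proximal = 2.5, carbon_centre = 3.0,
                       carbon_distal = 3.3, plateau_threshold = 0.60,
                       distal_mode = c("hold", "plateau")) {
  stopifnot(proton_factor > 0,
            carbon_proximal <= carbon_centre, carbon_centre <= carbon_distal,
            plateau_threshold > 0, plateau_threshold < 1)
  structure(list(proton_factor = proton_factor,
                 carbon_plateau = carbon_plateau,
                 carbon_proximal = carbon_proximal,
                 carbon_centre = carbon_centre,
                 carbon_distal = carbon_distal,
                 plateau_threshold = plateau_threshold,
                 distal_mode = match.arg(distal_mode)),
            class = "rbe_params")
}

#' Proton biological effective dose
#'
#' Multiplies a non-negative physical dose grid by the constant proton RBE.
#'
#' @param dose Numeric array or vector of physical dose in Gy.
#' @param params An [rbe_params()].
#' @return BED in GyE, same shape as `dose`.
#' @export
proton_bed <- function(dose, params = rbe_params()) {
  if (any(dose < 0)) stop("negative dose voxel")
  dose * params$proton_factor
}

# peak RBE of a carbon pencil beam from its position within the SOBP
carbon_peak_rbe <- function(pencil_bragg_depth, sobp, params = rbe_params()) {
  stopifnot(length(sobp) == 2)
  if (sobp[2] <= sobp[1]) return(rep(params$carbon_centre,
                                     length(pencil_bragg_depth)))
  # piecewise linear through the proximal / centre / distal anchors,
  # clamped outside the SOBP
  mid <- mean(sobp)
  lo <- params$carbon_proximal +
    (params$carbon_centre - params$carbon_proximal) *
      (pencil_bragg_depth - sobp[1]) / (mid - sobp[1])
  hi <- params$carbon_centre +
    (params$carbon_distal - params$carbon_centre) *
      (pencil_bragg_depth - mid) / (sobp[2] - mid)
  pmin(params$carbon_distal,
       pmax(params$carbon_proximal,
            ifelse(pencil_bragg_depth <= mid, lo, hi)))
}

#' Carbon RBE at a single depth of one pencil beam
#'
#' Point evaluation of the piecewise-linear carbon RBE rule for a pencil
#' beam whose Bragg peak sits at `pencil_bragg_depth` inside an SOBP
#' spanning `sobp = c(proximal, distal)` mm. Voxels in the entrance/buildup
#' region (`local_dose_fraction` below the threshold, proximal to the peak)
#' receive the plateau value; the voxel at the peak receives the beam's
#' peak RBE; between the threshold depth and the peak the RBE ramps
#' linearly in depth (supply `threshold_depth`, the shallowest depth at
#' which the dose reaches the threshold fraction); distal behaviour follows
#' `params$distal_mode`.
#'
#' @param depth Depth of the voxel in mm (vectorised).
#' @param sobp Numeric `c(proximal, distal)` extent of the SOBP in mm. A
#'   degenerate SOBP (proximal == distal) gives every beam the centre RBE.
#' @param pencil_bragg_depth Bragg depth of this pencil beam in mm.
#' @param local_dose_fraction Voxel dose as a fraction of the beam's
#'   maximum, in `[0, 1]` (vectorised).
#' @param threshold_depth Depth at which the dose first reaches the plateau
#'   threshold; required to evaluate the ramp region.
#' @param params An [rbe_params()].
#' @return RBE values.
#' @examples
#' carbon_rbe_at_depth(125, c(100, 150), 125, 1)        # 3.0 at SOBP centre
#' carbon_rbe_at_depth(60, c(100, 150), 125, 0.1)       # 1.5 in the plateau
#' @export
carbon_rbe_at_depth <- function(depth, sobp, pencil_bragg_depth,
                                local_dose_fraction, threshold_depth = NULL,
                                params = rbe_params()) {
  stopifnot(all(local_dose_fraction >= 0), all(local_dose_fraction <= 1))
  peak <- carbon_peak_rbe(pencil_bragg_depth, sobp, params)
  n <- max(length(depth), length(local_dose_fraction))
  depth <- rep_len(depth, n)
  frac <- rep_len(local_dose_fraction, n)
  out <- rep(NA_real_, n)
  proximal <- depth < pencil_bragg_depth
  out[depth >= pencil_bragg_depth] <- peak
  if (params$distal_mode == "plateau") {
    distal_low <- depth > pencil_bragg_depth & frac < params$plateau_threshold
    out[distal_low] <- params$carbon_plateau
  }
  out[proximal & frac < params$plateau_threshold] <- params$carbon_plateau
  ramp <- proximal & frac >= params$plateau_threshold
  if (any(ramp)) {
    if (is.null(threshold_depth))
      stop("threshold_depth is required to evaluate the ramp region ",
           "(voxels proximal to the peak with dose above the threshold)")
    f <- (depth[ramp] - threshold_depth) /
         (pencil_bragg_depth - threshold_depth)
    out[ramp] <- params$carbon_plateau +
      (peak - params$carbon_plateau) * pmin(1, pmax(0, f))
  }
  out
}

#' Carbon RBE depth profile for one pencil beam
#'
#' Builds the per-depth RBE vector applied to every lateral position of a
#' carbon pencil-beam kernel, from its laterally-integrated depth-dose
#' profile. This is the grid form of [carbon_rbe_at_depth()].
#'
#' @param dose_profile Laterally-integrated dose by depth.
#' @param z Depth coordinates (mm) matching `dose_profile`.
#' @param sobp `c(proximal, distal)` of the SOBP in mm.
#' @param pencil_bragg_depth Bragg depth of the beam in mm.
#' @param params An [rbe_params()].
#' @return Numeric RBE vector along depth.
#' @export
carbon_rbe_profile <- function(dose_profile, z, sobp, pencil_bragg_depth,
                               params = rbe_params()) {
  stopifnot(length(dose_profile) == length(z))
  frac <- dose_profile / max(dose_profile)
  thr_idx <- which(frac >= params$plateau_threshold)
  if (!length(thr_idx)) stop("dose profile never reaches the threshold")
  threshold_depth <- z[thr_idx[1]]
  peak <- carbon_peak_rbe(pencil_bragg_depth, sobp, params)
  out <- numeric(length(z))
  out[z < threshold_depth] <- params$carbon_plateau
  ramp <- z >= threshold_depth & z <= pencil_bragg_depth
  denom <- pencil_bragg_depth - threshold_depth
  out[ramp] <- if (denom > 0) {
    params$carbon_plateau + (peak - params$carbon_plateau) *
      (z[ramp] - threshold_depth) / denom
  } else peak
  distal <- z > pencil_bragg_depth
  out[distal] <- if (params$distal_mode == "hold") peak else
    ifelse(frac[distal] >= params$plateau_threshold, peak,
           params$carbon_plateau)
  out
}

#' Convert a per-primary kernel to biological effective dose
#'
#' Protons are scaled uniformly by the proton RBE; carbon kernels are
#' multiplied depth-wise by [carbon_rbe_profile()] computed from the
#' kernel's own laterally-integrated depth-dose curve and its position in
#' the SOBP. The fluence channel is untouched.
#'
#' @param kernel A `beam_kernel`.
#' @param sobp `c(proximal, distal)` of the SOBP in mm (carbon only).
#' @param params An [rbe_params()].
#' @return A `beam_kernel` whose `dose` field holds BED in GyE/primary
#'   (flagged in `meta$bed`).
#' @export
apply_rbe <- function(kernel, sobp = NULL, params = rbe_params()) {
  stopifnot(inherits(kernel, "beam_kernel"))
  if (!kernel$species %in% c("proton", "carbon"))
    stop("unknown species: ", kernel$species)
  if (kernel$species == "proton") {
    kernel$dose <- proton_bed(kernel$dose, params)
  } else {
    if (is.null(sobp)) stop("carbon RBE weighting requires the SOBP extent")
    nz <- kernel$grid$shape[3]
    prof <- colSums(matrix(kernel$dose, ncol = nz))
    rbe <- carbon_rbe_profile(prof, grid_z(kernel$grid), sobp,
                              kernel$bragg_depth, params)
    kernel$dose <- sweep(kernel$dose, 3, rbe, `*`)
  }
  kernel$meta$bed <- TRUE
  kernel
}
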