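#' Neutron capture agent registry
#'
#' Reads the editable registry of neutron capture agents shipped with the
#' package (one row per agent/site pair): the fluence-to-kerma conversion
#' factor `sigma_nca` (Gy per n/cm^2 per ppm of the capture isotope), the
#' compound biological effectiveness in tumour and normal tissue, and the
#' tumour:normal concentration ratio, each with a short provenance string.
#' The `in_default_report` flag marks rows whose normal-tissue arithmetic
#' is fully determined by the registry constants; the BSH-brain row is
#' excluded from default normal-tissue reports because its published
#' tumour:normal ratio is a range rather than a single value.
#'
#' @param path Optional path to an alternative registry CSV.
#' @return data.frame, one row per agent/site.
#' @export
nc_agents <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nc_agents.csv", package = "captureplan")
  agents <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("agent", "site", "isotope", "sigma_nca", "cbe_tumour",
              "cbe_normal", "tn_ratio")
  if (!all(needed %in% names(agents)))
    stop("agent registry is missing columns: ",
         paste(setdiff(needed, names(agents)), collapse = ", "))
  bad <- agents$sigma_nca <= 0 | agents$cbe_tumour <= 0 |
    agents$cbe_normal <= 0 | agents$tn_ratio <= 0
  if (any(bad))
    stop("non-positive constants in registry rows: ",
         paste(agents$agent[bad], collapse = ", "))
  agents
}

#' Look up one agent from the registry
#'
#' @param agent Agent name (e.g. `"BPA"`, `"Gd-cell"`).
#' @param site Target site; needed when the agent appears at several sites.
#' @param registry Registry data.frame (defaults to [nc_agents()]).
#' @return Object of class `nc_agent` (single-row list).
#' @examples
#' nc_agent("BPA", "brain")
#' @export
nc_agent <- function(agent, site = NULL, registry = nc_agents()) {
  hit <- registry[registry$agent == agent, , drop = FALSE]
  if (!is.null(site)) hit <- hit[hit$site == site, , drop = FALSE]
  if (nrow(hit) == 0)
    stop("no registry entry for agent '", agent, "'",
         if (!is.null(site)) paste0(" at site '", site, "'"))
  if (nrow(hit) > 1)
    stop("agent '", agent, "' matches ", nrow(hit),
         " registry rows; specify the site")
  structure(as.list(hit[1, ]), class = "nc_agent")
}

#' @export
print.nc_agent <- function(x, ...) {
  cat(sprintf("<nc_agent> %s (%s, %s): sigma %.3g Gy cm^2/ppm, CBE %g/%g (T/N), T:N %g:1\n",
              x$agent, x$site, x$isotope, x$sigma_nca,
              x$cbe_tumour, x$cbe_normal, x$tn_ratio))
  invisible(x)
}

#' Neutron capture boost dose
#'
#' The biological dose contributed by thermal neutron capture in an agent:
#' `D_B = phi * sigma_NCA * N_NCA * CBE`, with `phi` the thermal neutron
#' fluence (n/cm^2), `N_NCA` the agent concentration in ppm, and the CBE of
#' the requested tissue compartment.
#'
#' @param phi Thermal neutron fluence in n/cm^2 (vectorised).
#' @param agent An [nc_agent()].
#' @param concentration Agent concentration in ppm.
#' @param compartment `"tumour"` (default) or `"normal"`.
#' @return Boost dose in GyE.
#' @export
boost_dose <- function(phi, agent, concentration,
                       compartment = c("tumour", "normal")) {
  stopifnot(inherits(agent, "nc_agent"))
  compartment <- match.arg(compartment)
  if (any(phi < 0) || any(concentration < 0))
    stop("fluence and concentration must be non-negative")
  cbe <- if (compartment == "tumour") agent$cbe_tumour else agent$cbe_normal
  phi * agent$sigma_nca * concentration * cbe
}

#' Tumour concentration required for a stated dose boost
#'
#' Inverts the boost-dose relation for the concentration delivering a
#' fractional boost of the target dose:
#' `N = (boost_fraction * D) / (phi_ref * sigma_NCA * CBE_tumour)`, with
#' `phi_ref` the mean in-volume thermal neutron fluence per GyE.
#'
#' @param phi_ref Mean in-volume fluence in n/cm^2 per GyE (> 0, vectorised).
#' @param agent An [nc_agent()].
#' @param boost_fraction Fractional dose boost (default 0.10).
#' @param D Target dose in GyE (default 1).
#' @return data.frame with `ppm` (unrounded) and `ppm_3sf` (rounded to the
#'   3 significant figures used in reports).
#' @examples
#' required_concentration(7.79e8, nc_agent("BPA", "brain"))  # ~390 ppm
#' @export
required_concentration <- function(phi_ref, agent, boost_fraction = 0.10,
                                   D = 1) {
  stopifnot(inherits(agent, "nc_agent"), boost_fraction > 0, D > 0)
  denom <- phi_ref * agent$sigma_nca * agent$cbe_tumour
  if (any(denom <= 0)) stop("phi_ref * sigma * CBE must be positive")
  ppm <- boost_fraction * D / denom
  data.frame(ppm = ppm, ppm_3sf = signif(ppm, 3))
}

#' Maximum normal-tissue dose increase for a stated tumour boost
#'
#' The normal-tissue concentration implied by the tumour:normal ratio,
#' combined with the normal-tissue CBE and the ratio of the maximum
#' normal-tissue fluence to the in-volume reference fluence, gives the
#' maximum percentage increase in normal-tissue biological dose:
#' `100 * boost_fraction * (CBE_normal / CBE_tumour) * fluence_ratio / tn_ratio`.
#'
#' @param agent An [nc_agent()].
#' @param boost_fraction Fractional tumour boost (default 0.10).
#' @param fluence_ratio Maximum normal-tissue fluence over the in-volume
#'   reference fluence (default 1: the fluence at the treatment-volume
#'   margin is taken equal to the in-volume mean).
#' @return Percentage increase in normal-tissue biological dose.
#' @examples
#' normal_tissue_increase(nc_agent("BPA", "brain"))  # ~0.68 %
#' @export
normal_tissue_increase <- function(agent, boost_fraction = 0.10,
                                   fluence_ratio = 1) {
  stopifnot(inherits(agent, "nc_agent"), fluence_ratio > 0)
  if (agent$tn_ratio <= 0) stop("tumour:normal ratio must be positive")
  100 * boost_fraction * (agent$cbe_normal / agent$cbe_tumour) *
    fluence_ratio / agent$tn_ratio
}
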