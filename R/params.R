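#' Force-field and integrator parameters
#'
#' Returns the full parameter set of the coarse-grained model in reduced
#' units: length in bead diameters (1 lu ~ 5 Angstrom, so the 10-Angstrom
#' pore-clogging threshold is 2 lu), energy in kBT at 300 K, and time in the
#' Langevin unit implied by `dt`/`friction`. Every constant has a config key
#' of the same name (see [load_config()]).
#'
#' @param ... named overrides for any default listed below.
#'
#' @details Key groups and defaults:
#' \describe{
#'   \item{thermodynamics}{`temperature = 1` (kBT), `salt_M = 0.3`,
#'     `dielectric = 72.2`, `temperature_K = 300`. The Debye screening
#'     constant and Bjerrum length are derived from these.}
#'   \item{integrator}{`dt = 0.2`, `friction = 0.843`, `mass = 10` (uniform
#'     reduced bead mass; keeps the stiffest bond well inside BAOAB
#'     stability at this dt).}
#'   \item{local terms}{`k_bond = 100`, `k_angle = 2`, bond rest lengths
#'     `bond_ps`, `bond_sb`.}
#'   \item{hydrogen-bond wells}{`eps_hb = 12`, `sigma_hb = 0.55`,
#'     `r0_hb = 0.85`; capture radius for contact bookkeeping is
#'     `r0_hb + 2*sigma_hb`.}
#'   \item{base pairing}{Morse depths `eps_at = 3`, `eps_gc = 4.5`
#'     (GC > AT), width `alpha_bp = 6`, centre `r0_bp = 0.5`. A pair is
#'     flagged broken beyond `r_break`, the distance at which the well
#'     retains `break_frac = 0.05` of its depth.}
#'   \item{electrostatics}{phosphate charge -0.6 e for intra-DNA pairs and
#'     -1.0 e for protein-DNA pairs; cutoff at `dh_cut_debye = 5` Debye
#'     lengths with energy shift.}
#'   \item{nucleosome}{site well depths `eps_site_inner = 10`,
#'     `eps_site_shl45 = 8`, `eps_site_outer = 4` (graded so outer sites
#'     breathe thermally while SHL(-4.5) and inward stay formed).}
#' }
#'
#' @return an object of class `ff_params` (named list).
#' @export
#' @examples
#' p <- ff_params(eps_gc = 5)
#' p$eps_gc
ff_params <- function(...) {
  p <- list(
    # thermodynamics / electrostatics
    temperature   = 1.0,
    temperature_K = 300,
    salt_M        = 0.3,
    dielectric    = 72.2,
    dh_cut_debye  = 5,
    q_phosphate_intra   = -0.6,
    q_phosphate_protein = -1.0,
    q_loop        = 1.0,
    q_fpc_patch   = 1.0,
    q_fact_tail   = -1.0,
    q_h2ab_patch  = 1.0,
    # integrator
    dt        = 0.1,
    friction  = 0.843,
    mass      = 2.5,
    loop_mass = 1800,
    nlist_every    = 30,
    nlist_skin     = 1.5,
    force_overflow = 16.0,
    # geometry
    rise      = 0.7,
    rise_ds   = 1.1,
    bond_ps   = 0.58,
    bond_sb   = 0.40,
    radius_protein   = 0.5,
    radius_loop      = 0.2,
    radius_phosphate = 0.35,
    radius_sugar     = 0.35,
    radius_base      = 0.30,
    # local terms
    k_bond   = 50,
    k_angle  = 2,
    k_angle_ds = 30,
    # excluded volume
    eps_ev   = 0.2,
    eps_ev_wall = 0.5,
    # protein-DNA hydrogen-bond wells (pore loops)
    eps_hb   = 40,
    hb_ramp_steps = 4000,
    hb_ramp_delay = 4000,
    hb_refract_steps = 2000,
    sigma_hb = 0.5,
    well_break_sigma = 3.0,
    r0_hb    = 0.6,
    # base pairing / stacking
    eps_at     = 8.0,
    eps_gc     = 24.0,
    alpha_bp   = 4,
    r0_bp      = 0.5,
    break_frac = 0.05,
    eps_stack   = 1.0,
    alpha_stack = 2,
    r0_stack    = 0.75,
    # state-stabilising loop restraints (harmonic within native_dcap of the
    # rest length, constant-force beyond: the loop escorts gripped DNA)
    k_native = 40,
    native_dcap = 0.5,
    # nucleosome site wells
    eps_site_inner = 10,
    eps_site_shl45 = 8,
    eps_site_outer = 4,
    sigma_site     = 0.4,
    r0_site        = 1.0,
    # factors
    eps_rpa     = 6,
    sigma_rpa   = 0.6,
    r0_rpa      = 0.9,
    rpa_footprint = 25,
    eps_fact    = 8,
    sigma_fact  = 0.6,
    r0_fact     = 0.8,
    k_tether    = 5,
    k_posres    = 25,
    # analysis thresholds
    clog_threshold = 2.0,
    outcome_threshold = 3,
    # engine defaults
    switch_interval = 12000,
    frames_per_segment = 120,
    relax_minimize_iter = 120,
    relax_steps = 1200
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown ff_params key(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$eps_gc > p$eps_at, p$eps_at > 0,
            p$k_bond > 0, p$k_angle > 0,
            p$sigma_hb > 0, p$sigma_hb < p$r0_hb)
  class(p) <- "ff_params"
  p
}

#' Derived electrostatic constants
#'
#' Bjerrum length and Debye screening constant in reduced length units,
#' computed from salt molarity, dielectric constant and temperature
#' (lu = 5 Angstrom).
#'
#' @param params an [ff_params()] object.
#' @return list with `lB`, `kappa`, `r_cut` (all in lu).
#' @export
dh_constants <- function(params) {
  lu_A <- 5.0
  lB_A <- 167100.9 / (params$dielectric * params$temperature_K)
  # kappa^2 = 8 pi lB n, n = number density of a 1:1 salt in A^-3
  n_A3 <- params$salt_M * 6.02214076e-4
  kappa_A <- sqrt(8 * pi * lB_A * n_A3)
  lB <- lB_A / lu_A
  kappa <- kappa_A * lu_A
  list(lB = lB, kappa = kappa, r_cut = params$dh_cut_debye / kappa)
}

#' Base-pair break distance
#'
#' Distance at which a Morse pair well retains `break_frac` of its depth;
#' pairs beyond it are flagged broken.
#'
#' @param params an [ff_params()] object.
#' @return numeric distance (lu).
#' @export
bp_break_distance <- function(params) {
  x <- 1 - sqrt(1 - params$break_frac)
  params$r0_bp + log(1 / x) / params$alpha_bp
}

#' Hydrogen-bond capture radius
#'
#' `r0_hb + 2 sigma_hb`; used for contact bookkeeping (anchor identity,
#' lagging-strand capture, contact probabilities).
#'
#' @param params an [ff_params()] object.
#' @return numeric distance (lu).
#' @export
hb_capture_radius <- function(params) params$r0_hb + 2 * params$sigma_hb
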