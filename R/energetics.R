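# Assembles the always-on terms (bonded, excluded volume, Debye-Hueckel,
# base pairing, stacking, nucleosome/factor site wells, position restraints)
# and the state-dependent terms (switchable loop-phosphate hydrogen-bond
# wells and loop native restraints) into the form consumed by the C++ core.

as_cpp_topology <- function(asm) {
  params <- asm$params
  dh <- dh_constants(params)
  b <- asm$beads
  im <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0)
      return(matrix(integer(0), 0, length(cols)))
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "integer"
    m - 1L
  }
  nm <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0)
      return(matrix(numeric(0), 0, length(cols)))
    as.matrix(df[, cols, drop = FALSE])
  }
  # nonbonded exclusions: 1-2, 1-3, paired bases, stacked bases, and the
  # near-bonded base/phosphate pairs within each nucleotide
  excl <- rbind(im(asm$bonds, c("i", "j")),
                im(asm$angles, c("i", "k_")),
                im(asm$pairs, c("i", "j")),
                im(asm$stacks, c("i", "j")))
  for (st in asm$dna$strands) {
    n <- st$n
    if (n > 1) {
      excl <- rbind(excl,
        cbind(st$ids_P, st$ids_B) - 1L,
        cbind(st$ids_B[-n], st$ids_P[-1]) - 1L)
    }
  }
  # a pore loop protrudes from its own subunit wall: no self-repulsion.
  # Loops also pass freely over base beads (they engage the backbone); the
  # phosphate/sugar excluded volume still bars them from crossing a strand.
  if (!is.null(asm$ring)) {
    base_ids <- which(b$kind == "base")
    for (s in names(asm$ring$loop_bead)) {
      body <- asm$ring$body_beads[[s]]
      lb <- asm$ring$loop_bead[[s]]
      excl <- rbind(excl,
                    cbind(rep(lb, length(body)), body) - 1L,
                    cbind(rep(lb, length(base_ids)), base_ids) - 1L)
    }
  }
  ev <- rep(params$eps_ev, nrow(b))
  if (!is.null(asm$ring))
    ev[c(unlist(asm$ring$body_beads))] <- params$eps_ev_wall
  if (!is.null(asm$nucleosome))
    ev[asm$nucleosome$core_beads] <- params$eps_ev_wall
  list(
    radius = b$radius,
    mass = b$mass,
    ev_eps = ev,
    charge_dna = b$charge_dna,
    charge_pro = b$charge_pro,
    is_dna = as.integer(b$kind != "protein"),
    mobile = as.integer(b$mobile),
    bonds_ij = im(asm$bonds, c("i", "j")),
    bonds_par = nm(asm$bonds, c("r0", "k")),
    angles_ijk = im(asm$angles, c("i", "j", "k_")),
    angles_par = nm(asm$angles, c("theta0", "kang")),
    morse_ij = im(asm$pairs, c("i", "j")),
    morse_par = nm(asm$pairs, c("eps", "alpha", "r0")),
    stack_ij = im(asm$stacks, c("i", "j")),
    stack_par = nm(asm$stacks, c("eps", "alpha", "r0")),
    site_ij = im(asm$sites, c("i", "j")),
    site_par = nm(asm$sites, c("eps", "sigma", "r0")),
    posres_i = if (is.null(asm$posres) || nrow(asm$posres) == 0) integer(0)
               else as.integer(asm$posres$i - 1L),
    posres_par = nm(asm$posres, c("x", "y", "z", "k")),
    excl_ij = excl,
    eps_ev = params$eps_ev,
    lB = dh$lB, kappa = dh$kappa, r_cut_dh = dh$r_cut)
}

#' Assemble the active potential set for a motor state
#'
#' The always-on terms never change across switches; the state-dependent
#' terms are the hydrogen-bond contact wells of the state's engaged
#' subunits (each loop to its nearest tracked-strand phosphate) and the
#' loop native restraints realising the state's loop staircase.
#'
#' @param assembly a `cg_assembly`.
#' @param state_id conformational state (1-4) driving the loop targets, or
#'   `NULL` for assemblies without a ring (free nucleosome).
#' @param contact_state_id state whose hydrogen-bond wells are active;
#'   defaults to `state_id`. A conformation-only control passes the retained
#'   contact state here.
#' @return an `active_potentials` list with `$topo` (always-on) and
#'   `$state_terms` (switchable) components.
#' @export
make_active_potentials <- function(assembly, state_id,
                                   contact_state_id = state_id,
                                   topo = NULL) {
  params <- assembly$params
  if (is.null(topo)) topo <- as_cpp_topology(assembly)
  if (is.null(state_id) || is.null(assembly$states)) {
    st <- list(well_loop = integer(0),
               well_mate = integer(0),
               well_par = matrix(numeric(0), 0, 4),
               eligible = as.integer(assembly$dna$tracked_phos - 1L),
               native_ij = matrix(integer(0), 0, 2),
               native_par = matrix(numeric(0), 0, 2),
               native_dcap = params$native_dcap,
               well_ramp = params$hb_ramp_steps,
               well_delay = params$hb_ramp_delay,
               well_refract = params$hb_refract_steps,
               loop_pr_i = integer(0),
               loop_pr_par = matrix(numeric(0), 0, 4))
    return(structure(list(topo = topo, state_terms = st,
                          state_id = NULL, contact_state_id = NULL,
                          params = params),
                     class = "active_potentials"))
  }
  if (!state_id %in% 1:4 || !contact_state_id %in% 1:4)
    stop("unknown state id")
  conf <- assembly$states[[state_id]]
  cont <- assembly$states[[contact_state_id]]
  engaged <- cont$engaged_set
  loops <- unname(assembly$ring$loop_bead[as.character(engaged)])
  # two wells per engaged loop (the ~2-nt grip), mate-exclusive binding
  loops2 <- rep(loops, each = 2)
  nw <- length(loops2)
  mate <- as.integer(seq_len(nw) - 1L + c(1L, -1L))
  st <- list(
    well_loop = as.integer(loops2 - 1L),
    well_mate = mate,
    well_par = matrix(rep(c(params$eps_hb, params$sigma_hb, params$r0_hb,
                            params$well_break_sigma),
                          each = nw), ncol = 4),
    eligible = as.integer(assembly$dna$tracked_phos - 1L),
    native_ij = matrix(integer(0), 0, 2),
    native_par = matrix(numeric(0), 0, 2),
    native_dcap = params$native_dcap,
    well_ramp = params$hb_ramp_steps,
    well_delay = params$hb_ramp_delay,
    well_refract = params$hb_refract_steps,
    loop_pr_i = as.integer(unname(
      assembly$ring$loop_bead[rownames(conf$loop_axial_targets)]) - 1L),
    loop_pr_par = cbind(conf$loop_axial_targets,
                        params$k_native))
  structure(list(topo = topo, state_terms = st,
                 state_id = state_id, contact_state_id = contact_state_id,
                 params = params),
            class = "active_potentials")
}

eval_energy <- function(coords, active) {
  if (!all(is.finite(coords))) stop("non-finite coordinate")
  .cg_energy_cpp(coords, active$topo, active$state_terms)
}

#' Total energy and components
#' @param assembly a `cg_assembly`.
#' @param active an `active_potentials`; defaults to State 1.
#' @param coords coordinate matrix; defaults to the assembly coordinates.
#' @return named list of energy components (`bond`, `angle`, `morse`,
#'   `stack`, `site`, `posres`, `ev`, `dh`, `well`, `native`, `total`).
#' @export
total_energy <- function(assembly, active = NULL, coords = NULL) {
  if (is.null(active))
    active <- make_active_potentials(assembly,
                                     if (is.null(assembly$states)) NULL else 1L)
  if (is.null(coords)) coords <- assembly$coords
  e <- eval_energy(coords, active)
  e[setdiff(names(e), c("forces", "well_partner"))]
}

#' Analytic forces of the active potential set
#' @inheritParams total_energy
#' @return an n x 3 matrix of per-bead forces (frozen beads report zero).
#' @export
total_force <- function(assembly, active = NULL, coords = NULL) {
  if (is.null(active))
    active <- make_active_potentials(assembly,
                                     if (is.null(assembly$states)) NULL else 1L)
  if (is.null(coords)) coords <- assembly$coords
  eval_energy(coords, active)$forces
}

#' Bonded (harmonic bond + angle) energy
#' @inheritParams total_energy
#' @export
bonded_energy <- function(assembly, coords = NULL) {
  e <- total_energy(assembly, coords = coords)
  e$bond + e$angle
}

#' Switchable hydrogen-bond well energy
#' @param active an `active_potentials` from [make_active_potentials()].
#' @inheritParams total_energy
#' @export
hbond_energy <- function(assembly, active, coords = NULL) {
  total_energy(assembly, active, coords)$well
}

#' Base-pair energy and formed/broken flags
#'
#' A pair is flagged broken when the base-base distance exceeds the break
#' distance at which the Morse well retains 5% of its depth.
#'
#' @inheritParams total_energy
#' @return list with `energy`, logical `formed`, and the pair table.
#' @export
basepair_energy <- function(assembly, coords = NULL) {
  if (is.null(coords)) coords <- assembly$coords
  e <- total_energy(assembly, coords = coords)
  pr <- assembly$pairs
  if (is.null(pr) || nrow(pr) == 0)
    return(list(energy = 0, formed = logical(0), pairs = pr))
  d <- sqrt(rowSums((coords[pr$i, , drop = FALSE] -
                     coords[pr$j, , drop = FALSE])^2))
  list(energy = e$morse, formed = d <= bp_break_distance(assembly$params),
       pairs = pr, distance = d)
}

#' Screened (Debye-Hueckel) electrostatic energy
#' @inheritParams total_energy
#' @export
electrostatic_energy <- function(assembly, coords = NULL) {
  total_energy(assembly, coords = coords)$dh
}

#' Excluded-volume energy
#' @inheritParams total_energy
#' @export
excluded_volume_energy <- function(assembly, coords = NULL) {
  total_energy(assembly, coords = coords)$ev
}

#' Nucleosome site-well energy and per-site flags
#'
#' @inheritParams total_energy
#' @return list with `energy` (site wells of the nucleosome only) and a
#'   per-site `formed` flag (distance within 6 sigma of the well centre).
#' @export
nucleosome_site_energy <- function(assembly, coords = NULL) {
  if (is.null(assembly$nucleosome)) stop("assembly has no nucleosome")
  if (is.null(coords)) coords <- assembly$coords
  cs <- assembly$nucleosome$contact_sites
  p <- assembly$params
  d <- sqrt(rowSums((coords[cs$anchor_bead, , drop = FALSE] -
                     coords[cs$phosphate_bead, , drop = FALSE])^2))
  u <- -cs$eps_site * exp(-(d - p$r0_site)^2 / (2 * p$sigma_site^2))
  list(energy = sum(u),
       formed = d < p$r0_site + 6 * p$sigma_site,
       shl = cs$shl, distance = d)
}
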