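# Toy hexameric ring: six rigid subunit bodies lining a central channel, one
# mobile pore-loop bead per subunit, and the four DNA-binding reference states.

# Ring adjacency order (standard CMG architecture). Only adjacency matters.
RING_ORDER <- c(5L, 3L, 7L, 4L, 6L, 2L)

# Per-state base grip ranks: subunit s engaged in a state grips nucleotide
# ranks (delta + b, delta + b + 1) of the current registry. The tables are
# one consistent solution to the printed per-transition step sizes: every
# step equals the rank change of the subunit that stays anchored across the
# switch, so shared subunits agree on +1 (1->2), +6 (2->3), +2 (3->4) and
# +3 (4->1), while the 3-state shortcut 3->1 leaves subunit 6 demanding +5
# and subunit 3 demanding -7 -- the stochastic anchor conflict.
STATE_RANKS <- list(
  `1` = c(`6` = 0, `2` = 2, `5` = 4, `3` = 6),
  `2` = c(`2` = 1, `5` = 3, `3` = 5, `7` = 7),
  `3` = c(`3` = -1, `7` = 1, `4` = 3, `6` = 5),
  `4` = c(`7` = -1, `4` = 1, `6` = 3, `2` = 5)
)

# Registry offsets (nt) accumulated along the forward cycle 1->2->3->4->1.
STATE_DELTA <- c(`1` = 0, `2` = 1, `3` = 7, `4` = 9)

subunit_azimuth <- function() {
  az <- (seq_along(RING_ORDER) - 1) * pi / 3
  names(az) <- as.character(RING_ORDER)
  az
}

#' Build the toy hexameric ring motor
#'
#' Places six subunits at 60-degree azimuthal spacing around a channel along
#' +z. Each subunit contributes a column of frozen pore-lining beads, a few
#' frozen outer body beads, and one mobile pore-loop bead (the DNA-binding
#' loop proxy). The channel spans the axial range swept by the loop targets
#' of all four DNA-binding states.
#'
#' @param beads_per_subunit number of body beads per subunit (>= 4).
#' @param pore_radius radial position of the pore-lining bead centres (lu).
#'   Must admit ssDNA but exclude duplex DNA.
#' @param loop_rise_per_nt axial rise per nucleotide rank (lu).
#' @param params an [ff_params()] object.
#' @return a `ring_topology` list: bead table, coordinates, per-subunit loop
#'   beads, body beads, restraint anchors, and the pore bead set.
#' @export
build_ring <- function(beads_per_subunit = 20, pore_radius = 1.2,
                       loop_rise_per_nt = 1.0, params = ff_params()) {
  if (beads_per_subunit < 4)
    stop("beads_per_subunit must be >= 4")
  ss_clear <- 0.5 + params$radius_phosphate   # pore bead + ssDNA bead contact
  if (pore_radius <= ss_clear)
    stop("assembly error: pore too small to pass ssDNA beads (pore_radius <= ",
         round(ss_clear, 2), ")")
  duplex_half_width <- 0.6
  if (pore_radius - duplex_half_width >= ss_clear)
    stop("assembly error: pore admits duplex DNA (pore_radius too large)")
  az <- subunit_azimuth()
  a <- loop_rise_per_nt
  z_lo <- -1.5 * a; z_hi <- 12.5 * a
  n_pore <- max(3L, ceiling(0.7 * beads_per_subunit))
  n_outer <- beads_per_subunit - n_pore
  kind <- chain <- character(0); resi <- integer(0)
  xyz <- NULL
  body_beads <- list(); loop_bead <- integer(0); pore_set <- integer(0)
  idx <- 0L
  for (s in RING_ORDER) {
    th <- az[[as.character(s)]]
    zcol <- seq(z_lo, z_hi, length.out = n_pore)
    pcol <- cbind(pore_radius * cos(th), pore_radius * sin(th), zcol)
    outer <- NULL
    if (n_outer > 0) {
      zo <- seq(z_lo + a, z_hi - a, length.out = n_outer)
      outer <- cbind(2.6 * cos(th), 2.6 * sin(th), zo)
    }
    sub_xyz <- rbind(pcol, outer)
    ids <- idx + seq_len(nrow(sub_xyz))
    body_beads[[as.character(s)]] <- ids
    pore_set <- c(pore_set, idx + seq_len(n_pore))
    idx <- idx + nrow(sub_xyz)
    xyz <- rbind(xyz, sub_xyz)
    kind <- c(kind, rep("protein", nrow(sub_xyz)))
    chain <- c(chain, rep(paste0("M", s), nrow(sub_xyz)))
    resi <- c(resi, seq_len(nrow(sub_xyz)))
  }
  # one mobile loop bead per subunit, initialised at its State-1 target
  # (engaged) or parked position (disengaged)
  for (s in RING_ORDER) {
    idx <- idx + 1L
    loop_bead[[as.character(s)]] <- idx
    tgt <- loop_target_point(s, 1L, az, a, params)
    xyz <- rbind(xyz, tgt)
    kind <- c(kind, "protein")
    chain <- c(chain, paste0("M", s))
    resi <- c(resi, 0L)
  }
  beads <- data.frame(
    bead_id = seq_len(nrow(xyz)), kind = kind, chain_id = chain,
    residue_index = resi,
    mass = ifelse(seq_len(nrow(xyz)) %in% loop_bead,
                  params$loop_mass, params$mass),
    radius = ifelse(seq_len(nrow(xyz)) %in% loop_bead,
                    params$radius_loop, 0.5),
    charge_dna = 0,
    charge_pro = ifelse(seq_len(nrow(xyz)) %in% loop_bead, params$q_loop, 0),
    mobile = seq_len(nrow(xyz)) %in% loop_bead,
    stringsAsFactors = FALSE)
  # restraint anchors: two own-subunit pore beads (channel ends) plus one
  # mid-channel pore bead from each ring neighbour -- non-collinear, so the
  # native restraints pin each loop at a unique point
  anchors <- list()
  ord <- as.character(RING_ORDER)
  for (i in seq_along(ord)) {
    s <- ord[i]
    own <- body_beads[[s]][c(1L, n_pore)]
    left <- ord[if (i == 1) length(ord) else i - 1]
    right <- ord[if (i == length(ord)) 1 else i + 1]
    mid <- ceiling(n_pore / 2)
    anchors[[s]] <- c(own, body_beads[[left]][mid], body_beads[[right]][mid])
  }
  structure(list(
    beads = beads, coords = unname(xyz),
    subunit_order = RING_ORDER, azimuth = az,
    loop_bead = loop_bead, body_beads = body_beads, anchors = anchors,
    pore_bead_set = pore_set,
    channel_axis = c(0, 0, 1), rise = a, pore_radius = pore_radius,
    loop_radial = 0.6, park = c(radial = 2.2, z = 5.5 * a),
    n_pore_per_subunit = n_pore
  ), class = "ring_topology")
}

# state target (engaged) or parked point for a subunit's loop bead
loop_target_point <- function(subunit, state_id, az, a, params) {
  th <- az[[as.character(subunit)]]
  rk <- STATE_RANKS[[as.character(state_id)]]
  b <- rk[as.character(subunit)]
  if (!is.na(b)) {
    c(0.6 * cos(th), 0.6 * sin(th), (b + 0.5) * a)
  } else {
    c(2.2 * cos(th), 2.2 * sin(th), 5.5 * a)
  }
}

#' Build the four DNA-binding reference states
#'
#' Each state engages four of the six subunits; an engaged subunit grips two
#' consecutive nucleotide ranks of the current registry and its loop bead is
#' restrained to the corresponding axial target. Registry offsets accumulate
#' 0, 1, 7, 9 nt along the forward cycle (printed step sizes 1, 6, 2, 3 nt),
#' closing at 12 nt per full cycle.
#'
#' @param ring a `ring_topology` from [build_ring()].
#' @param params an [ff_params()] object.
#' @return list of four `reference_state` objects with fields `state_id`,
#'   `engaged_set`, `registry_offset`, `per_subunit_registry`,
#'   `loop_axial_targets` (per-subunit target points, parked loops included)
#'   and `native_pairs` (loop-to-body restraints realising the targets).
#' @export
build_reference_states <- function(ring, params = ff_params()) {
  az <- ring$azimuth; a <- ring$rise
  lapply(1:4, function(st) {
    rk <- STATE_RANKS[[as.character(st)]]
    engaged <- sort(as.integer(names(rk)))
    reg <- lapply(names(rk), function(s) STATE_DELTA[[as.character(st)]] + rk[[s]] + c(0, 1))
    names(reg) <- names(rk)
    targets <- t(vapply(as.character(ring$subunit_order), function(s)
      loop_target_point(s, st, az, a, params), numeric(3)))
    rownames(targets) <- as.character(ring$subunit_order)
    # native restraints: loop bead to its 4 anchor body beads, rest length
    # measured from the target point
    nat <- do.call(rbind, lapply(as.character(ring$subunit_order), function(s) {
      tgt <- targets[s, ]
      anc <- ring$anchors[[s]]
      data.frame(i = ring$loop_bead[[s]], j = anc,
                 r0 = sqrt(colSums((t(ring$coords[anc, , drop = FALSE]) - tgt)^2)),
                 k = params$k_native)
    }))
    structure(list(
      state_id = st,
      engaged_set = engaged,
      registry_offset = STATE_DELTA[[as.character(st)]],
      base_rank = rk,
      per_subunit_registry = reg,
      loop_axial_targets = targets,
      native_pairs = nat
    ), class = "reference_state")
  })
}
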