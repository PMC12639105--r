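# Builders for the three study geometries: ssDNA translocation, Y-fork
# unwinding, and nucleosome navigation.

#' Build the ssDNA translocation scenario
#'
#' Threads a single strand through the ring pore along the channel axis,
#' with the motor's State-1 contacts formable at assembly. The tracked
#' nucleotide is the one nearest the subunit-3 loop's State-1 home site.
#'
#' @param n_nt strand length (nt).
#' @param ring_position_nt nucleotide index (from the 3' end, increasing
#'   toward 5') initially at the subunit-3 loop site.
#' @param seed integer seed (sequence + initial velocities).
#' @param sequence_mode one of `"random"`, `"polyAT"`, `"polyGC"`.
#' @param params an [ff_params()] object.
#' @param beads_per_subunit,pore_radius passed to [build_ring()].
#' @return a `cg_assembly`.
#' @export
#' @examples
#' asm <- build_ssdna_scenario(60, 30, seed = 1)
#' nrow(asm$beads)
build_ssdna_scenario <- function(n_nt = 60, ring_position_nt = 30, seed = 1,
                                 sequence_mode = "random",
                                 params = ff_params(),
                                 beads_per_subunit = 20, pore_radius = 1.2) {
  if (ring_position_nt < 7 || ring_position_nt >= n_nt - 12)
    stop("ring position too close to a strand end (need 7 <= pos < n_nt - 12)")
  ring <- build_ring(beads_per_subunit, pore_radius, params$rise, params)
  n_base <- ring_position_nt - 6L
  seqs <- with_seed(seed, make_sequence(n_nt, sequence_mode))
  nidx <- seq_len(n_nt)
  path <- cbind(0, 0, (nidx - n_base) * params$rise)
  az <- (nidx * 30) * pi / 180
  base_dir <- cbind(cos(az), sin(az), 0)
  strand <- build_strand("LEAD", seqs, path, base_dir, params)
  acc <- new_acc()
  ring_off <- acc_add_beads(acc, ring$beads, ring$coords, "ring")
  off <- acc_add_beads(acc, strand$beads, strand$coords, "dna")
  acc_add_term(acc, "bonds", strand$bonds, off)
  acc_add_term(acc, "angles", strand$angles, off, c("i", "j", "k_"))
  acc_add_term(acc, "stacks", strand$stacks, off)
  dna <- list(
    strands = list(LEAD = list(seq = seqs, n = n_nt,
                               ids_P = strand$ids_P + off,
                               ids_S = strand$ids_S + off,
                               ids_B = strand$ids_B + off)),
    tracked = "LEAD",
    tracked_phos = strand$ids_P + off,
    n_base = n_base,
    fork_junction_index = NA_integer_)
  scenario <- list(name = "ssdna", n_nt = n_nt,
                   ring_position_nt = ring_position_nt,
                   sequence_mode = sequence_mode, seed = seed)
  asm <- finish_assembly(acc, ring_off, ring, dna, scenario, params,
                         seed = seed)
  asm$ring_position_nt <- ring_position_nt
  asm
}

# shared fork construction; returns pieces so the nucleosome builder can
# extend the parental arm onto a wrapped core
fork_geometry <- function(parental_path_fn, parental_bp, lagging_bp,
                          leading_bp, lagging_ss_nt, leading_ss_nt,
                          sequence_mode, seed, params,
                          beads_per_subunit, pore_radius) {
  if (leading_ss_nt < 14)
    stop("infeasible threading: leading ssDNA must be >= 14 nt to span the pore")
  ring <- build_ring(beads_per_subunit, pore_radius, params$rise, params)
  a <- params$rise
  Ld <- leading_bp; Lss <- leading_ss_nt; P <- parental_bp
  Nt <- Ld + Lss + P
  j <- Ld + Lss + 1L                      # junction: first paired parental nt
  n_base <- j - 13L
  seq_tracked <- with_seed(seed, make_sequence(Nt, sequence_mode))
  seq_arm <- with_seed(seed + 1L, make_sequence(lagging_ss_nt + lagging_bp,
                                                sequence_mode))
  nidx <- seq_len(Nt)
  # tracked strand: vertical through the pore; duplex regions offset -x
  w <- offset_ramp(nidx, list(c(1, Ld), c(j, Nt)))
  ds_t <- nidx <= Ld | nidx >= j
  # piecewise rise: single-stranded gaps at the channel rise, duplex gaps
  # at the B-form rise (strain-free for the stiff straight duplex)
  gap <- ifelse(ds_t[-Nt] & ds_t[-1], params$rise_ds, a)
  zc <- c(0, cumsum(gap))
  z <- zc - zc[n_base]
  path_t <- cbind(-0.6 * w, 0, z)
  bd_t <- cbind(w, 0, 0)
  ssn <- w < 1
  az <- (nidx * 30) * pi / 180
  bd_t[ssn, ] <- cbind(cos(az[ssn]), sin(az[ssn]), 0) * (1 - w[ssn]) +
    bd_t[ssn, ] * w[ssn]
  # parental region beyond the junction may follow a caller-supplied path
  # (nucleosome wrap); t = 0 at the junction bp
  if (!is.null(parental_path_fn)) {
    pp <- parental_path_fn(seq_len(P) - 1)
    path_t[j:Nt, ] <- pp$tracked
    bd_t[j:Nt, ] <- pp$base_dir_tracked
  }
  tracked <- build_strand("LEAD", seq_tracked, path_t, bd_t, params,
                          ds_mask = ds_t)
  # lagging template: parental complement (index 1 = its 3' end, at the
  # distal parental terminus) then the single-stranded arm and arm duplex
  L_lag <- P + lagging_ss_nt + lagging_bp
  seq_lag <- c(rev(unname(COMPLEMENT[seq_tracked[j:Nt]])), seq_arm)
  path_l <- matrix(0, L_lag, 3)
  bd_l <- matrix(0, L_lag, 3)
  if (!is.null(parental_path_fn)) {
    pp <- parental_path_fn(seq_len(P) - 1)
    path_l[seq_len(P), ] <- pp$lagging[P:1, , drop = FALSE]
    bd_l[seq_len(P), ] <- pp$base_dir_lagging[P:1, , drop = FALSE]
  } else {
    path_l[seq_len(P), ] <- path_t[j + P - seq_len(P), ] +
      matrix(c(1.2, 0, 0), P, 3, byrow = TRUE)
    bd_l[seq_len(P), ] <- matrix(c(-1, 0, 0), P, 3, byrow = TRUE)
  }
  arm_n <- lagging_ss_nt + lagging_bp
  d_arm <- c(0, 0.866, 0.5)
  n_perp <- c(0, -0.5, 0.866)
  arm_origin <- path_l[P, ]
  arm_is_ds <- c(rep(FALSE, lagging_ss_nt), rep(TRUE, lagging_bp))
  arm_gap <- ifelse(arm_is_ds, params$rise_ds, a)
  arm_s <- cumsum(arm_gap)
  for (t in seq_len(arm_n))
    path_l[P + t, ] <- arm_origin + arm_s[t] * d_arm
  for (t in seq_len(arm_n))
    bd_l[P + t, ] <- if (arm_is_ds[t]) n_perp else
      c(cos(t * 0.52), sin(t * 0.52) * 0.2, 0.8)
  ds_l <- c(rep(TRUE, P), arm_is_ds)
  lagging <- build_strand("LAGG", seq_lag, path_l, bd_l, params,
                          ds_mask = ds_l)
  # complements closing the two arm duplexes
  leadC <- lagC <- NULL
  if (Ld > 0) {
    seq_leadC <- rev(unname(COMPLEMENT[seq_tracked[seq_len(Ld)]]))
    pathC <- path_t[Ld:1, ] + matrix(c(1.2, 0, 0), Ld, 3, byrow = TRUE)
    leadC <- build_strand("LEDC", seq_leadC, pathC,
                          matrix(c(-1, 0, 0), Ld, 3, byrow = TRUE), params,
                          ds_mask = rep(TRUE, Ld))
  }
  if (lagging_bp > 0) {
    idx_ds <- P + lagging_ss_nt + seq_len(lagging_bp)
    seq_lagC <- rev(unname(COMPLEMENT[seq_lag[idx_ds]]))
    pathC2 <- path_l[rev(idx_ds), ] +
      matrix(1.2 * n_perp, lagging_bp, 3, byrow = TRUE)
    lagC <- build_strand("LGGC", seq_lagC, pathC2,
                         matrix(-n_perp, lagging_bp, 3, byrow = TRUE),
                         params, ds_mask = rep(TRUE, lagging_bp))
  }
  list(ring = ring, tracked = tracked, lagging = lagging,
       leadC = leadC, lagC = lagC,
       seq_tracked = seq_tracked, seq_lag = seq_lag,
       Nt = Nt, L_lag = L_lag, j = j, n_base = n_base,
       P = P, Ld = Ld, lagging_ss_nt = lagging_ss_nt,
       lagging_bp = lagging_bp)
}

make_pairs <- function(ids_B1, nt1, seq1, ids_B2, nt2, seq2, region, params) {
  cls <- pair_class(seq1, seq2)
  data.frame(i = ids_B1, j = ids_B2,
             eps = ifelse(cls == "AT", params$eps_at, params$eps_gc),
             alpha = params$alpha_bp, r0 = params$r0_bp,
             class = cls, region = region,
             nt_i = nt1, nt_j = nt2, stringsAsFactors = FALSE)
}

assemble_fork <- function(fg, scenario, params, seed,
                          nucleosome_parts = NULL) {
  acc <- new_acc()
  ring_off <- acc_add_beads(acc, fg$ring$beads, fg$ring$coords, "ring")
  offs <- list()
  for (nm in c("tracked", "lagging", "leadC", "lagC")) {
    st <- fg[[nm]]
    if (is.null(st)) next
    off <- acc_add_beads(acc, st$beads, st$coords, "dna")
    acc_add_term(acc, "bonds", st$bonds, off)
    acc_add_term(acc, "angles", st$angles, off, c("i", "j", "k_"))
    acc_add_term(acc, "stacks", st$stacks, off)
    offs[[nm]] <- off
  }
  # pairing tables
  prs <- list()
  m <- seq_len(fg$P)
  prs$parental <- make_pairs(
    fg$tracked$ids_B[fg$j + fg$P - m] + offs$tracked,
    fg$j + fg$P - m, fg$seq_tracked[fg$j + fg$P - m],
    fg$lagging$ids_B[m] + offs$lagging, m, fg$seq_lag[m],
    "parental", params)
  if (!is.null(fg$leadC)) {
    n <- seq_len(fg$Ld)
    prs$leading <- make_pairs(
      fg$tracked$ids_B[n] + offs$tracked, n, fg$seq_tracked[n],
      fg$leadC$ids_B[fg$Ld + 1 - n] + offs$leadC, fg$Ld + 1 - n,
      unname(COMPLEMENT[fg$seq_tracked[n]]),
      "leading", params)
  }
  if (!is.null(fg$lagC)) {
    kk <- seq_len(fg$lagging_bp)
    idx_ds <- fg$P + fg$lagging_ss_nt + kk
    prs$lagging_arm <- make_pairs(
      fg$lagging$ids_B[idx_ds] + offs$lagging, idx_ds, fg$seq_lag[idx_ds],
      fg$lagC$ids_B[fg$lagging_bp + 1 - kk] + offs$lagC,
      fg$lagging_bp + 1 - kk,
      unname(COMPLEMENT[fg$seq_lag[idx_ds]]),
      "lagging_arm", params)
  }
  acc_add_term(acc, "pairs", do.call(rbind, prs), 0L)
  # weak positional anchor on the distal parental terminus
  tp <- c(fg$tracked$ids_P[fg$Nt], fg$tracked$ids_S[fg$Nt]) + offs$tracked
  lp <- c(fg$lagging$ids_P[1], fg$lagging$ids_S[1]) + offs$lagging
  term <- c(tp, lp)
  posres_xyz <- rbind(fg$tracked$coords[c(fg$Nt * 3 - 2, fg$Nt * 3 - 1), ],
                      fg$lagging$coords[c(1, 2), ])
  acc_add_term(acc, "posres",
               data.frame(i = term, x = posres_xyz[, 1], y = posres_xyz[, 2],
                          z = posres_xyz[, 3], k = params$k_posres),
               0L, cols = "i")
  nucle <- NULL
  if (!is.null(nucleosome_parts)) {
    nuc_off <- acc_add_beads(acc, nucleosome_parts$beads,
                             nucleosome_parts$coords, "nucleosome")
    sites <- nucleosome_parts$sites
    sites$i <- sites$i + nuc_off                       # anchor bead
    sites$j <- fg$tracked$ids_P[sites$nt_index] + offs$tracked
    acc_add_term(acc, "sites",
                 sites[, c("i", "j", "eps", "sigma", "r0")], 0L)
    nucle <- list(
      core_beads = nucleosome_parts$core_ids + nuc_off,
      contact_sites = data.frame(
        shl = sites$shl, anchor_bead = sites$i,
        nt_index = sites$nt_index, eps_site = sites$eps,
        phosphate_bead = sites$j),
      dyad_index = nucleosome_parts$dyad_index,
      h2ab_patch = nucleosome_parts$patch_ids + nuc_off,
      exposure_rule = nucleosome_parts$exposure_rule,
      shl_start = nucleosome_parts$shl_start)
  }
  dna <- list(
    strands = list(
      LEAD = list(seq = fg$seq_tracked, n = fg$Nt,
                  ids_P = fg$tracked$ids_P + offs$tracked,
                  ids_S = fg$tracked$ids_S + offs$tracked,
                  ids_B = fg$tracked$ids_B + offs$tracked),
      LAGG = list(seq = fg$seq_lag, n = fg$L_lag,
                  ids_P = fg$lagging$ids_P + offs$lagging,
                  ids_S = fg$lagging$ids_S + offs$lagging,
                  ids_B = fg$lagging$ids_B + offs$lagging)),
    tracked = "LEAD",
    tracked_phos = fg$tracked$ids_P + offs$tracked,
    n_base = fg$n_base,
    fork_junction_index = fg$j,
    parental_len = fg$P,
    lagging_arm_start = fg$P + 1L,
    lagging_ss_nt = fg$lagging_ss_nt)
  asm <- finish_assembly(acc, ring_off, fg$ring, dna, scenario, params,
                         nucleosome = nucle, seed = seed)
  asm$ring_position_nt <- fg$j - 7L
  asm
}

#' Build the Y-fork unwinding scenario
#'
#' Assembles a Y-forked substrate: parental duplex ahead of the ring,
#' leading-strand template threaded through the pore (subunit-3 loop 7 nt
#' from the junction), a lagging arm (ssDNA then duplex) excluded from the
#' pore, and an already-formed leading duplex behind the motor.
#'
#' @param parental_bp,lagging_bp,leading_bp duplex lengths (bp).
#' @param lagging_ss_nt,leading_ss_nt single-stranded lengths (nt).
#' @param sequence_mode `"random"`, `"polyAT"` or `"polyGC"`.
#' @param seed integer seed.
#' @param lagging_mode `"ssDNA"` (default) or `"duplex-occluded"`, which
#'   replaces the lagging single-stranded region with duplex.
#' @param params an [ff_params()] object.
#' @param beads_per_subunit,pore_radius passed to [build_ring()].
#' @return a `cg_assembly`.
#' @export
build_fork_scenario <- function(parental_bp = 16, lagging_bp = 8,
                                leading_bp = 8, lagging_ss_nt = 12,
                                leading_ss_nt = 18,
                                sequence_mode = "random", seed = 1,
                                lagging_mode = c("ssDNA", "duplex-occluded"),
                                params = ff_params(),
                                beads_per_subunit = 20, pore_radius = 1.2) {
  lagging_mode <- match.arg(lagging_mode)
  if (lagging_mode == "duplex-occluded") {
    lagging_bp <- lagging_bp + lagging_ss_nt
    lagging_ss_nt <- 0L
  }
  stopifnot(parental_bp >= 1, lagging_bp >= 0, leading_bp >= 0,
            lagging_ss_nt >= 0)
  fg <- fork_geometry(NULL, parental_bp, lagging_bp, leading_bp,
                      lagging_ss_nt, leading_ss_nt, sequence_mode, seed,
                      params, beads_per_subunit, pore_radius)
  scenario <- list(name = "fork", parental_bp = parental_bp,
                   lagging_bp = lagging_bp, leading_bp = leading_bp,
                   lagging_ss_nt = lagging_ss_nt,
                   leading_ss_nt = leading_ss_nt,
                   sequence_mode = sequence_mode,
                   lagging_mode = lagging_mode, seed = seed)
  assemble_fork(fg, scenario, params, seed)
}
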