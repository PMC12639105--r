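# Toy nucleosome: a frozen core disc with 14 half-integer-SHL contact sites
# (Gaussian wells to the wrapped DNA, graded so outer sites breathe
# thermally), an H2A/H2B surface-patch proxy occluded by the wrapped DNA,
# and wrap geometry that peels entry-side DNA when the motor starts deeper
# in the nucleosome.

NUC_WRAP_BP <- 140L           # full wrap spanning SHL -6.5 .. +6.5
NUC_SHL_BP <- 10L             # bp per superhelical location unit

nuc_wrap_radius <- function(a = 1) NUC_WRAP_BP * a / (1.8 * 2 * pi)

shl_site_bp <- function() 5 + NUC_SHL_BP * (0:13)   # full-wrap bp of each site
shl_labels <- function() -6.5 + (0:13)

site_depth <- function(shl, params) {
  a <- abs(shl)
  ifelse(a >= 5.5, params$eps_site_outer,
         ifelse(a >= 4.5, params$eps_site_shl45, params$eps_site_inner))
}

# spine position of full-wrap bp b (can be negative = peeled), given the
# peel count t0 and the attachment height z_attach; circle in the xz-plane,
# entry tangent +z at the attach point
nuc_spine <- function(b, t0, z_attach, a = 1) {
  Rw <- nuc_wrap_radius(a)
  cc <- c(-Rw, 0, z_attach)
  phi <- (b - t0) * a / Rw
  cbind(cc[1] + Rw * cos(phi), 0, cc[3] + Rw * sin(phi))
}

nuc_inward <- function(b, t0, a = 1) {
  Rw <- nuc_wrap_radius(a)
  phi <- (b - t0) * a / Rw
  cbind(-cos(phi), 0, -sin(phi))
}

# frozen core + anchors + patch for a wrap peeled by t0 bp; nt_index of each
# site refers to the tracked strand and is filled by the caller offset
make_nucleosome_parts <- function(t0, z_attach, nt_of_full_bp, params) {
  a <- params$rise_ds
  Rw <- nuc_wrap_radius(a)
  Rc <- Rw - 2.2
  phi_range <- c(0 - t0, NUC_WRAP_BP - 1 - t0) * a / Rw
  phis <- seq(phi_range[1], phi_range[2], by = 0.12)
  cc <- c(-Rw, 0, z_attach)
  core <- cbind(cc[1] + Rc * cos(phis), 0, cc[3] + Rc * sin(phis))
  bps <- shl_site_bp()
  anc <- sweep(nuc_spine(bps, t0, z_attach, a), 2, c(0, -0.6, 0), "+") +
    1.0 * nuc_inward(bps, t0, a)
  patch_bp <- c(26, 28, 30, 32, 34)
  patch <- sweep(nuc_spine(patch_bp, t0, z_attach, a), 2,
                 c(0, 0.7, 0), "+") +
    1.0 * nuc_inward(patch_bp, t0, a)
  xyz <- rbind(core, anc, patch)
  n <- nrow(xyz)
  beads <- data.frame(
    bead_id = seq_len(n), kind = "protein", chain_id = "CORE",
    residue_index = seq_len(n), mass = params$mass,
    radius = c(rep(1.2, nrow(core)), rep(0.5, nrow(anc)),
               rep(0.5, nrow(patch))),
    charge_dna = 0,
    charge_pro = c(rep(0, nrow(core) + nrow(anc)),
                   rep(params$q_h2ab_patch, nrow(patch))),
    mobile = FALSE, stringsAsFactors = FALSE)
  sites <- data.frame(
    i = nrow(core) + seq_along(bps),       # anchor bead (local id)
    shl = shl_labels(),
    nt_index = nt_of_full_bp(bps),
    eps = site_depth(shl_labels(), params),
    sigma = params$sigma_site, r0 = params$r0_site)
  list(beads = beads, coords = xyz,
       core_ids = seq_len(nrow(core)),
       patch_ids = nrow(core) + length(bps) + seq_along(patch_bp),
       sites = sites,
       exposure_rule = shl_labels()[shl_labels() <= -3.5],
       dyad_index = nt_of_full_bp(70),
       shl_start = NULL)
}

#' Build the nucleosome-collision scenario
#'
#' A Y-fork whose parental arm runs through a 22-bp linker onto a nucleosome
#' wrapped at half-integer superhelical locations SHL(-6.5)..(+6.5). The
#' fork junction sits 22 bp upstream of `shl_start`; wrap outward of
#' `shl_start` is peeled by construction (that DNA has already been passed
#' by the advancing fork). Factor bodies are added with [place_factors()].
#'
#' @param shl_start one of -7, -5, -4, -3.
#' @param factors a [factor_set()]; applied after assembly.
#' @param seed integer seed.
#' @param sequence_mode,params,beads_per_subunit,pore_radius as in
#'   [build_fork_scenario()].
#' @param max_retries placement retries (jittered) before giving up.
#' @return a `cg_assembly` with a `$nucleosome` component.
#' @export
build_nucleosome_scenario <- function(shl_start = -7,
                                      factors = factor_set(),
                                      seed = 1,
                                      sequence_mode = "random",
                                      params = ff_params(),
                                      beads_per_subunit = 20,
                                      pore_radius = 1.2,
                                      max_retries = 20) {
  if (!shl_start %in% c(-7, -5, -4, -3))
    stop("shl_start must be one of -7, -5, -4, -3")
  t0 <- as.integer((shl_start + 7) * NUC_SHL_BP)
  linker <- 22L
  stub <- 6L
  wrap_here <- NUC_WRAP_BP - t0
  P <- linker + wrap_here + stub
  a <- params$rise
  ad <- params$rise_ds
  z_j <- 13 * a                           # junction height
  z_attach <- z_j + linker * ad
  Rw <- nuc_wrap_radius(ad)
  spine_of_t <- function(tvec) {
    # t = parental bp offset from the junction
    out <- matrix(0, length(tvec), 3)
    lin <- tvec < linker
    out[lin, ] <- cbind(0, 0, z_j + tvec[lin] * ad)
    wr <- tvec >= linker & tvec < linker + wrap_here
    out[wr, ] <- nuc_spine(tvec[wr] - linker + t0, t0, z_attach, ad)
    st <- tvec >= linker + wrap_here
    if (any(st)) {
      phi_end <- (wrap_here - 1) * ad / Rw
      pend <- nuc_spine(wrap_here - 1 + t0, t0, z_attach, ad)
      tang <- cbind(-sin(phi_end), 0, cos(phi_end))
      k <- (tvec[st] - (linker + wrap_here - 1)) * ad
      out[st, ] <- matrix(pend, sum(st), 3, byrow = TRUE) +
        k * matrix(tang, sum(st), 3, byrow = TRUE)
    }
    out
  }
  ppf <- function(tvec) {
    sp <- spine_of_t(tvec)
    list(tracked = sp + matrix(c(0, -0.6, 0), length(tvec), 3, byrow = TRUE),
         lagging = sp + matrix(c(0, 0.6, 0), length(tvec), 3, byrow = TRUE),
         base_dir_tracked = matrix(c(0, 1, 0), length(tvec), 3, byrow = TRUE),
         base_dir_lagging = matrix(c(0, -1, 0), length(tvec), 3, byrow = TRUE))
  }
  attempt <- function(try_seed) {
    fg <- fork_geometry(ppf, P, 10L, 10L, 12L, 20L, sequence_mode,
                        try_seed, params, beads_per_subunit, pore_radius)
    nt_of_full_bp <- function(b) fg$j + linker + (b - t0)
    parts <- make_nucleosome_parts(t0, z_attach, nt_of_full_bp, params)
    parts$shl_start <- shl_start
    scenario <- list(name = "nucleosome", shl_start = shl_start,
                     sequence_mode = sequence_mode, seed = seed,
                     factors = factors)
    assemble_fork(fg, scenario, params, seed, nucleosome_parts = parts)
  }
  asm <- NULL
  for (r in seq_len(max_retries)) {
    asm <- tryCatch(attempt(seed + (r - 1L) * 1000003L),
                    error = function(e) e)
    if (!inherits(asm, "error")) break
  }
  if (inherits(asm, "error"))
    stop("no clash-free nucleosome configuration within the retry budget: ",
         conditionMessage(asm))
  place_factors(asm, factors)
}

#' Build a free nucleosome (no motor) for thermal calibration
#'
#' The fully wrapped 140-bp toy nucleosome alone: used to verify that the
#' graded site wells let entry/exit sites breathe at temperature while
#' SHL(-4.5) and inward stay formed.
#'
#' @param seed integer seed.
#' @param sequence_mode,params as elsewhere.
#' @return a list with `$assembly`-like fields usable by the engine (a
#'   `cg_assembly` without ring or states).
#' @export
build_free_nucleosome <- function(seed = 1, sequence_mode = "random",
                                  params = ff_params()) {
  n <- NUC_WRAP_BP
  z_attach <- 0
  seqs <- with_seed(seed, make_sequence(n, sequence_mode))
  sp <- nuc_spine(0:(n - 1), 0L, z_attach, params$rise_ds)
  s1 <- build_strand("NCP1", seqs, sweep(sp, 2, c(0, -0.6, 0), "+"),
                     matrix(c(0, 1, 0), n, 3, byrow = TRUE), params,
                     ds_mask = rep(TRUE, n))
  s2 <- build_strand("NCP2", rev(unname(COMPLEMENT[seqs])),
                     sweep(sp[n:1, ], 2, c(0, 0.6, 0), "+"),
                     matrix(c(0, -1, 0), n, 3, byrow = TRUE), params,
                     ds_mask = rep(TRUE, n))
  parts <- make_nucleosome_parts(0L, z_attach, function(b) b + 1L, params)
  acc <- new_acc()
  o1 <- acc_add_beads(acc, s1$beads, s1$coords, "dna")
  acc_add_term(acc, "bonds", s1$bonds, o1)
  acc_add_term(acc, "angles", s1$angles, o1, c("i", "j", "k_"))
  acc_add_term(acc, "stacks", s1$stacks, o1)
  o2 <- acc_add_beads(acc, s2$beads, s2$coords, "dna")
  acc_add_term(acc, "bonds", s2$bonds, o2)
  acc_add_term(acc, "angles", s2$angles, o2, c("i", "j", "k_"))
  acc_add_term(acc, "stacks", s2$stacks, o2)
  prs <- make_pairs(s1$ids_B + o1, seq_len(n), seqs,
                    s2$ids_B[n:1] + o2, n:1,
                    unname(COMPLEMENT[seqs]), "wrap", params)
  acc_add_term(acc, "pairs", prs, 0L)
  no <- acc_add_beads(acc, parts$beads, parts$coords, "nucleosome")
  sites <- parts$sites
  sites$i <- sites$i + no
  sites$j <- (s1$ids_P + o1)[sites$nt_index]
  acc_add_term(acc, "sites", sites[, c("i", "j", "eps", "sigma", "r0")], 0L)
  p <- acc_finish(acc)
  vels <- matrix(0, nrow(p$coords), 3)
  mob <- p$beads$mobile
  vels[mob, ] <- with_seed(seed + 7L,
    matrix(rnorm(3 * sum(mob)), ncol = 3) *
      sqrt(params$temperature / p$beads$mass[mob]))
  structure(list(
    beads = p$beads, coords = unname(p$coords), vels = vels,
    molecule = p$molecule, bonds = p$bonds, angles = p$angles,
    stacks = p$stacks, pairs = p$pairs, sites = p$sites, posres = p$posres,
    ring = NULL, states = NULL,
    dna = list(strands = list(
      NCP1 = list(seq = seqs, n = n, ids_P = s1$ids_P + o1,
                  ids_S = s1$ids_S + o1, ids_B = s1$ids_B + o1),
      NCP2 = list(seq = rev(unname(COMPLEMENT[seqs])), n = n,
                  ids_P = s2$ids_P + o2, ids_S = s2$ids_S + o2,
                  ids_B = s2$ids_B + o2)),
      tracked = "NCP1", tracked_phos = s1$ids_P + o1, n_base = 1L,
      fork_junction_index = NA_integer_),
    nucleosome = list(
      core_beads = parts$core_ids + no,
      contact_sites = data.frame(
        shl = sites$shl, anchor_bead = sites$i, nt_index = sites$nt_index,
        eps_site = sites$eps, phosphate_bead = sites$j),
      dyad_index = parts$dyad_index,
      h2ab_patch = parts$patch_ids + no,
      exposure_rule = parts$exposure_rule,
      shl_start = -7),
    factors = list(),
    scenario = list(name = "free_nucleosome", seed = seed,
                    sequence_mode = sequence_mode),
    params = params, ref_site = c(0, 0, 0)
  ), class = "cg_assembly")
}
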