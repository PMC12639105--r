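# Accessory factor bodies: RPA tiling the lagging single strand, the fork
# protection complex (positive patch gripping the parental duplex,
# electrostatics switchable), inert Ctf4/Mrc1 placeholders, and FACT (a
# tethered domain with an acidic tail that occupies the exposed H2A/H2B
# surface patch).

#' Specify which accessory factors to place
#'
#' @param rpa,fpc,ctf4,mrc1,fact logicals.
#' @param fpc_electrostatics_on if `FALSE`, the FPC positive-patch charges
#'   are zeroed (all else equal).
#' @param rpa_footprint nt footprint per RPA body; `NULL` uses the
#'   [ff_params()] default.
#' @return a `factor_set` list.
#' @export
factor_set <- function(rpa = FALSE, fpc = FALSE, ctf4 = FALSE, mrc1 = FALSE,
                       fact = FALSE, fpc_electrostatics_on = TRUE,
                       rpa_footprint = NULL) {
  structure(list(rpa = rpa, fpc = fpc, ctf4 = ctf4, mrc1 = mrc1,
                 fact = fact,
                 fpc_electrostatics_on = fpc_electrostatics_on,
                 rpa_footprint = rpa_footprint), class = "factor_set")
}

append_body <- function(asm, coords, molecule, chain, radius, q_pro = 0,
                        mobile = TRUE) {
  n <- nrow(coords)
  off <- nrow(asm$beads)
  params <- asm$params
  beads <- data.frame(
    bead_id = off + seq_len(n), kind = "protein", chain_id = chain,
    residue_index = seq_len(n), mass = params$mass,
    radius = radius, charge_dna = 0, charge_pro = q_pro,
    mobile = mobile, stringsAsFactors = FALSE)
  asm$beads <- rbind(asm$beads, beads)
  asm$coords <- rbind(asm$coords, coords)
  vnew <- matrix(0, n, 3)
  if (mobile)
    vnew <- matrix(rnorm(3 * n, 0, sqrt(params$temperature / params$mass)),
                   ncol = 3)  # factor beads all carry the default mass
  asm$vels <- rbind(asm$vels, vnew)
  asm$molecule <- c(asm$molecule, rep(molecule, n))
  list(asm = asm, ids = off + seq_len(n))
}

add_bonds <- function(asm, i, j, r0, k) {
  asm$bonds <- rbind(asm$bonds, data.frame(i = i, j = j, r0 = r0, k = k))
  asm
}

nearest_bead <- function(asm, point, candidates) {
  d2 <- colSums((t(asm$coords[candidates, , drop = FALSE]) - point)^2)
  candidates[which.min(d2)]
}

#' Place accessory factor bodies on an assembly
#'
#' RPA bodies tile the lagging single strand with the configured footprint;
#' the FPC is tethered at the ring front flanking the parental duplex with
#' its positive patch within electrostatic range; Ctf4/Mrc1 are
#' excluded-volume placeholders; FACT is positioned at the nucleosome dyad
#' with its tail reaching toward the H2A/H2B patch. Placement is seeded and
#' clash-checked, with jittered retries.
#'
#' @param assembly a `cg_assembly` (fork or nucleosome scenario).
#' @param factors a [factor_set()].
#' @param max_retries jittered placement retries.
#' @return the modified `cg_assembly` (unchanged if no factor requested).
#' @export
place_factors <- function(assembly, factors = factor_set(),
                          max_retries = 20) {
  if (!inherits(factors, "factor_set")) stop("factors must be a factor_set")
  if (!any(unlist(factors[c("rpa", "fpc", "ctf4", "mrc1", "fact")])))
    return(assembly)
  seed <- assembly$scenario$seed %||% 1L
  for (r in seq_len(max_retries)) {
    out <- tryCatch(
      with_seed(seed + 31L * r,
                place_factors_once(assembly, factors,
                                   jitter = 0.3 * (r - 1))),
      error = function(e) e)
    if (!inherits(out, "error")) return(out)
  }
  stop("factor placement failed after ", max_retries, " retries: ",
       conditionMessage(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

place_factors_once <- function(asm, factors, jitter = 0) {
  params <- asm$params
  jig <- function() runif(3, -jitter, jitter)
  placed <- list(flags = list(
    fpc_electrostatics_on = factors$fpc_electrostatics_on))
  if (isTRUE(factors$rpa)) {
    fp <- factors$rpa_footprint %||% params$rpa_footprint
    lss <- asm$dna$lagging_ss_nt %||% 0L
    nb <- if (fp > 0) floor(lss / fp) else 0L
    rpa_bodies <- list()
    lag <- asm$dna$strands$LAGG
    arm0 <- asm$dna$lagging_arm_start - 1L
    for (b in seq_len(nb)) {
      nts <- arm0 + ((b - 1L) * fp + 1L):(b * fp)
      ppos <- asm$coords[lag$ids_P[nts], , drop = FALSE]
      tsel <- unique(pmax(1, round(seq(0.15, 0.85, length.out = 4) * fp)))
      bpos <- ppos[tsel, , drop = FALSE] +
        matrix(c(0.9, 0, 0), length(tsel), 3, byrow = TRUE) +
        matrix(jig(), length(tsel), 3, byrow = TRUE)
      res <- append_body(asm, bpos, paste0("rpa", b), paste0("RPA", b),
                         radius = 0.45)
      asm <- res$asm
      ids <- res$ids
      asm <- add_bonds(asm, ids[-length(ids)], ids[-1],
                       r0 = sqrt(rowSums((bpos[-1, , drop = FALSE] -
                                          bpos[-length(tsel), , drop = FALSE])^2)),
                       k = 20)
      wells <- data.frame(
        i = vapply(nts, function(nt)
          nearest_bead(asm, asm$coords[lag$ids_P[nt], ], ids), integer(1)),
        j = lag$ids_P[nts],
        eps = params$eps_rpa, sigma = params$sigma_rpa, r0 = params$r0_rpa)
      asm$sites <- rbind(asm$sites, wells)
      rpa_bodies[[b]] <- list(ids = ids, footprint = range(nts))
    }
    placed$rpa <- rpa_bodies
  }
  if (isTRUE(factors$fpc) || isTRUE(factors$ctf4) || isTRUE(factors$mrc1)) {
    j <- asm$dna$fork_junction_index
    if (is.na(j)) stop("FPC/Ctf4/Mrc1 need a fork scenario")
    tr <- asm$dna$strands$LEAD; lg <- asm$dna$strands$LAGG
    pj <- asm$coords[tr$ids_P[j], ]
    pj4 <- asm$coords[tr$ids_P[j + 4L], ]
    partner <- asm$dna$parental_len  # lag index pairing tracked j is parental_len
    ps <- asm$coords[lg$ids_P[partner], ]
    vax <- pj4 - pj; vax <- vax / sqrt(sum(vax^2))
    ssep <- ps - pj; ssep <- ssep / sqrt(sum(ssep^2))
    u <- c(vax[2] * ssep[3] - vax[3] * ssep[2],
           vax[3] * ssep[1] - vax[1] * ssep[3],
           vax[1] * ssep[2] - vax[2] * ssep[1])
    u <- u / sqrt(sum(u^2))
    mid <- (pj + ps) / 2
    if (isTRUE(factors$fpc)) {
      patch <- rbind(mid + 1.9 * u + 1.2 * vax, mid + 1.9 * u + 3.0 * vax,
                     mid - 1.9 * u + 1.2 * vax, mid - 1.9 * u + 3.0 * vax)
      body <- rbind(mid + 3.4 * u + 1.8 * vax, mid + 3.4 * u + 3.2 * vax,
                    mid - 3.4 * u + 1.8 * vax, mid - 3.4 * u + 3.2 * vax)
      xyz <- rbind(patch, body) + matrix(jig(), 8, 3, byrow = TRUE)
      qp <- c(rep(if (factors$fpc_electrostatics_on)
        params$q_fpc_patch else 0, 4), rep(0, 4))
      res <- append_body(asm, xyz, "fpc", "FPC", radius = 0.5, q_pro = qp)
      asm <- res$asm; ids <- res$ids
      # near-rigid internal frame + tethers to the frozen ring top
      cmb <- combn(ids, 2)
      d <- sqrt(rowSums((asm$coords[cmb[1, ], ] - asm$coords[cmb[2, ], ])^2))
      keep <- d < 4
      asm <- add_bonds(asm, cmb[1, keep], cmb[2, keep], d[keep], 20)
      for (b in ids[5:8]) {
        anchor <- nearest_bead(asm, asm$coords[b, ],
                               unlist(asm$ring$body_beads))
        asm <- add_bonds(asm, b, anchor,
                         sqrt(sum((asm$coords[b, ] - asm$coords[anchor, ])^2)),
                         params$k_tether)
      }
      placed$fpc <- list(ids = ids, patch = ids[1:4])
    }
    for (nm in c("ctf4", "mrc1")) {
      if (!isTRUE(factors[[nm]])) next
      side <- if (nm == "ctf4") 1 else -1
      base <- mid + side * 5.0 * u - 1.5 * vax
      xyz <- rbind(base, base + c(1, 0, 0), base + c(0, 1, 0)) +
        matrix(jig(), 3, 3, byrow = TRUE)
      res <- append_body(asm, xyz, nm, toupper(nm), radius = 0.6)
      asm <- res$asm; ids <- res$ids
      asm <- add_bonds(asm, ids[c(1, 1, 2)], ids[c(2, 3, 3)], 1.0, 20)
      anchor <- nearest_bead(asm, base, unlist(asm$ring$body_beads))
      asm <- add_bonds(asm, ids[1], anchor,
                       sqrt(sum((asm$coords[ids[1], ] -
                                 asm$coords[anchor, ])^2)),
                       params$k_tether)
      placed[[nm]] <- list(ids = ids)
    }
  }
  if (isTRUE(factors$fact)) {
    nuc <- asm$nucleosome
    if (is.null(nuc)) stop("FACT needs a nucleosome scenario")
    core_c <- colMeans(asm$coords[nuc$core_beads, , drop = FALSE])
    dyad_p <- asm$coords[asm$dna$tracked_phos[nuc$dyad_index], ]
    dir <- dyad_p - core_c; dir <- dir / sqrt(sum(dir^2))
    # dyad exterior on the exposed (+y) face, clear of the fork linker
    dom0 <- dyad_p + 2.5 * dir + c(0, 2.6, 0)
    grid <- as.matrix(expand.grid(x = c(0, 1.2), y = c(-0.6, 0.6),
                                  z = c(0, 1.2)))[1:6, ]
    dom <- matrix(dom0, 6, 3, byrow = TRUE) + grid +
      matrix(jig(), 6, 3, byrow = TRUE)
    res <- append_body(asm, dom, "fact", "FCTD", radius = 0.6)
    asm <- res$asm; dom_ids <- res$ids
    cmb <- combn(dom_ids, 2)
    d <- sqrt(rowSums((asm$coords[cmb[1, ], ] - asm$coords[cmb[2, ], ])^2))
    keep <- d < 2.5
    asm <- add_bonds(asm, cmb[1, keep], cmb[2, keep], d[keep], 20)
    asm$posres <- rbind(asm$posres,
      data.frame(i = dom_ids, x = asm$coords[dom_ids, 1],
                 y = asm$coords[dom_ids, 2], z = asm$coords[dom_ids, 3],
                 k = 2))
    patch_c <- colMeans(asm$coords[nuc$h2ab_patch, , drop = FALSE])
    # route the tail on the exposed (+y) face of the core, clear of the
    # wrapped DNA; its wells pull it onto the patch during dynamics
    tgt <- patch_c + c(0, 2.2, 0)
    tdir <- tgt - dom0; tdir <- tdir / sqrt(sum(tdir^2))
    tail <- matrix(dom0, 8, 3, byrow = TRUE) +
      outer(1.0 + 0.8 * (1:8), tdir)
    res <- append_body(asm, tail, "fact", "FCTL", radius = 0.4,
                       q_pro = asm$params$q_fact_tail)
    asm <- res$asm; tail_ids <- res$ids
    asm <- add_bonds(asm, c(dom_ids[1], tail_ids[-8]),
                     c(tail_ids[1], tail_ids[-1]), 0.8, 20)
    wells <- data.frame(
      i = tail_ids,
      j = vapply(tail_ids, function(b)
        nearest_bead(asm, asm$coords[b, ], nuc$h2ab_patch), integer(1)),
      eps = asm$params$eps_fact, sigma = asm$params$sigma_fact,
      r0 = asm$params$r0_fact)
    asm$sites <- rbind(asm$sites, wells)
    placed$fact <- list(domain = dom_ids, tail = tail_ids)
  }
  clash <- assembly_clash(asm$beads, asm$coords, asm$molecule)
  if (!is.null(clash))
    stop("factor placement clash: beads ", clash[1], "/", clash[2],
         " (", asm$molecule[clash[1]], " vs ", asm$molecule[clash[2]], ")")
  asm$factors <- placed
  asm
}
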