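# Scenario assemblies: ring + DNA (+ nucleosome, + factors) composed into a
# single `cg_assembly` with global bead ids, bonded terms, pairing table,
# always-on site wells and seeded initial velocities.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

new_acc <- function() {
  env <- new.env(parent = emptyenv())
  env$beads <- list(); env$coords <- list(); env$molecule <- list()
  env$bonds <- list(); env$angles <- list(); env$stacks <- list()
  env$pairs <- list(); env$sites <- list(); env$posres <- list()
  env$n <- 0L
  env
}

acc_add_beads <- function(acc, beads, coords, molecule) {
  off <- acc$n
  beads$bead_id <- beads$bead_id + off
  acc$beads[[length(acc$beads) + 1L]] <- beads
  acc$coords[[length(acc$coords) + 1L]] <- coords
  acc$molecule[[length(acc$molecule) + 1L]] <- rep(molecule, nrow(beads))
  acc$n <- acc$n + nrow(beads)
  off
}

acc_add_term <- function(acc, slot, df, off, cols = c("i", "j")) {
  if (is.null(df) || nrow(df) == 0) return(invisible())
  for (cl in cols) df[[cl]] <- df[[cl]] + off
  acc[[slot]][[length(acc[[slot]]) + 1L]] <- df
  invisible()
}

acc_finish <- function(acc) {
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  list(beads = bind(acc$beads),
       coords = do.call(rbind, acc$coords),
       molecule = unlist(acc$molecule),
       bonds = bind(acc$bonds), angles = bind(acc$angles),
       stacks = bind(acc$stacks), pairs = bind(acc$pairs),
       sites = bind(acc$sites), posres = bind(acc$posres))
}

# minimum-distance clash check between distinct bodies; pore-loop beads
# are exempt against DNA bases (they engage the backbone and their mutual
# excluded volume is disabled)
assembly_clash <- function(beads, coords, molecule, factor = 0.8) {
  n <- nrow(coords)
  if (n > 4000) stop("clash check: assembly unexpectedly large")
  rad <- beads$radius
  loopish <- beads$kind == "protein" & beads$residue_index == 0
  basish <- beads$kind == "base"
  worst <- NULL
  mols <- unique(molecule)
  for (a in seq_along(mols)) for (b in seq_len(a - 1L)) {
    ia <- which(molecule == mols[a]); ib <- which(molecule == mols[b])
    d2 <- outer(rowSums(coords[ia, , drop = FALSE]^2),
                rowSums(coords[ib, , drop = FALSE]^2), "+") -
      2 * coords[ia, , drop = FALSE] %*% t(coords[ib, , drop = FALSE])
    lim <- factor * outer(rad[ia], rad[ib], "+")
    bad <- d2 < lim^2
    bad <- bad & !outer(loopish[ia], basish[ib], "&") &
      !outer(basish[ia], loopish[ib], "&")
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      worst <- c(ia[w[1]], ib[w[2]])
      return(worst)
    }
  }
  NULL
}

finish_assembly <- function(acc, ring_off, ring, dna, scenario, params,
                            nucleosome = NULL, seed = 1) {
  parts <- acc_finish(acc)
  clash <- assembly_clash(parts$beads, parts$coords, parts$molecule)
  if (!is.null(clash))
    stop("assembly error: steric clash between beads ",
         clash[1], " and ", clash[2], " (molecules ",
         parts$molecule[clash[1]], "/", parts$molecule[clash[2]], ")")
  ring$loop_bead <- ring$loop_bead + ring_off
  ring$pore_bead_set <- ring$pore_bead_set + ring_off
  ring$body_beads <- lapply(ring$body_beads, function(v) v + ring_off)
  ring$anchors <- lapply(ring$anchors, function(v) v + ring_off)
  ring_global <- ring
  ring_global$coords <- parts$coords   # anchors are global ids
  states <- build_reference_states(ring_global, params)
  vels <- matrix(0, nrow(parts$coords), 3)
  mob <- parts$beads$mobile
  vels[mob, ] <- with_seed(seed + 7L,
    matrix(rnorm(3 * sum(mob)), ncol = 3) *
      sqrt(params$temperature / parts$beads$mass[mob]))
  ref_site <- states[[1]]$loop_axial_targets["3", ]
  asm <- structure(list(
    beads = parts$beads, coords = unname(parts$coords), vels = vels,
    molecule = parts$molecule,
    bonds = parts$bonds, angles = parts$angles, stacks = parts$stacks,
    pairs = parts$pairs, sites = parts$sites, posres = parts$posres,
    ring = ring, states = states, dna = dna,
    nucleosome = nucleosome, factors = list(),
    scenario = scenario, params = params,
    ref_site = unname(ref_site)
  ), class = "cg_assembly")
  asm
}

#' @export
print.cg_assembly <- function(x, ...) {
  cat("cg_assembly:", x$scenario$name, "\n")
  cat("  beads:", nrow(x$beads), "(", sum(x$beads$mobile), "mobile )\n")
  if (!is.null(x$pairs)) cat("  base pairs:", nrow(x$pairs), "\n")
  if (!is.null(x$nucleosome)) cat("  nucleosome contact sites:",
                                  nrow(x$nucleosome$contact_sites), "\n")
  invisible(x)
}
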