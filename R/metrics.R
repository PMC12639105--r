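# Trajectory metrics: tracked displacement, per-transition step sizes,
# outcome classification, anchor identity, unwinding/reannealing counts,
# pore clogging, nucleosome unwrapping extent, lagging-strand capture,
# contact probabilities, occupancy densities, and condition comparisons.

frame_count <- function(traj) dim(traj$frames)[3]

# squared distances of a bead set to a fixed point, per frame: (nb x F)
d2_to_point <- function(traj, ids, point) {
  (traj$frames[1, ids, , drop = FALSE] - point[1])^2 +
  (traj$frames[2, ids, , drop = FALSE] - point[2])^2 +
  (traj$frames[3, ids, , drop = FALSE] - point[3])^2
}

#' Tracked-nucleotide displacement series
#'
#' Motor displacement along the tracked strand, in nucleotides: the index of
#' the nucleotide whose phosphate currently occupies the subunit-3 loop's
#' State-1 home site (a fixed point in the ring frame), minus the index
#' there at the first frame. Positive values are 3'->5' (toward the 5' end).
#' Nearest-phosphate selection is hysteretic (the previous index is kept
#' unless a competitor is closer by `hysteresis`); if no phosphate is within
#' `max_gap` the previous value is carried forward and flagged.
#'
#' @param traj a `cg_trajectory`.
#' @param hysteresis switching margin (lu).
#' @param max_gap disengagement distance (lu).
#' @return integer vector (per frame) with attribute `flagged`.
#' @export
tracked_displacement <- function(traj, hysteresis = 0.3, max_gap = 3.0) {
  asm <- traj$assembly
  phos <- asm$dna$tracked_phos
  d2 <- matrix(d2_to_point(traj, phos, asm$ref_site),
               nrow = length(phos))
  nf <- ncol(d2)
  idx <- integer(nf)
  flagged <- logical(nf)
  prev <- asm$ring_position_nt %||% which.min(d2[, 1])
  for (f in seq_len(nf)) {
    best <- which.min(d2[, f])
    db <- sqrt(d2[best, f]); dp <- sqrt(d2[prev, f])
    if (db > max_gap) {
      idx[f] <- prev; flagged[f] <- TRUE
    } else {
      if (db + hysteresis < dp) prev <- best
      idx[f] <- prev
    }
  }
  out <- idx - idx[1]
  attr(out, "flagged") <- flagged
  attr(out, "index") <- idx
  out
}

segment_tail_means <- function(traj, disp, tail_frac) {
  segs <- sort(unique(traj$frame_segment))
  vapply(segs, function(k) {
    w <- which(traj$frame_segment == k)
    if (length(w) < 2) stop("too few frames per segment for step analysis")
    nt <- max(1L, ceiling(tail_frac * length(w)))
    mean(disp[tail(w, nt)])
  }, numeric(1))
}

#' Per-transition step sizes
#'
#' The step of transition k is the mean tracked displacement over the last
#' `tail_frac` of segment k+1 minus the same tail mean of segment k
#' (suppressing post-switch relaxation transients). Steps telescope exactly
#' to the net displacement.
#'
#' @param traj a `cg_trajectory`.
#' @param tail_frac tail fraction of each segment used for the means.
#' @return a `step_table`: data frame of transitions plus attributes
#'   `net_displacement` and `outcome`.
#' @export
per_transition_steps <- function(traj, tail_frac = 0.1) {
  disp <- tracked_displacement(traj)
  tm <- segment_tail_means(traj, disp, tail_frac)
  segs <- traj$segments
  if (length(segs) < 2) {
    tab <- data.frame(from_state = integer(0), to_state = integer(0),
                      step_size = numeric(0), anchor_subunit = integer(0))
    net <- mean(tail(disp, max(1, ceiling(tail_frac * length(disp)))))
  } else {
    tab <- data.frame(
      from_state = segs[-length(segs)],
      to_state = segs[-1],
      step_size = diff(tm))
    tab$anchor_subunit <- vapply(seq_len(nrow(tab)), function(k)
      anchor_identity(traj, k), integer(1))
    net <- tm[length(tm)] - tm[1]
  }
  structure(tab, class = c("step_table", "data.frame"),
            net_displacement = net,
            outcome = classify_outcome(net))
}

#' Classify a net displacement
#'
#' Forward if the net displacement exceeds +3 nt, backward below -3 nt,
#' idling within \[-3, +3\].
#'
#' @param net_displacement numeric (nt); vectorised.
#' @return character vector in `c("forward", "idling", "backward")`.
#' @export
classify_outcome <- function(net_displacement) {
  stopifnot(all(is.finite(net_displacement)))
  ifelse(net_displacement > 3, "forward",
         ifelse(net_displacement < -3, "backward", "idling"))
}

#' Anchor subunit of a transition
#'
#' Among the subunits engaged in both states of a transition, the one whose
#' loop-phosphate contact persisted longest after the switch (contact =
#' distance below the hydrogen-bond capture radius to the same phosphate it
#' held at the switch instant).
#'
#' @param traj a `cg_trajectory`.
#' @param transition switch index (1-based).
#' @return subunit label (integer) or `NA` if no contact persisted.
#' @export
anchor_identity <- function(traj, transition) {
  asm <- traj$assembly
  if (is.null(asm$states)) return(NA_integer_)
  segs <- traj$segments
  from <- segs[transition]; to <- segs[transition + 1]
  shared <- intersect(asm$states[[from]]$engaged_set,
                      asm$states[[to]]$engaged_set)
  if (length(shared) == 0) return(NA_integer_)
  cap <- hb_capture_radius(asm$params)
  w_from <- which(traj$frame_segment == transition)
  w_to <- which(traj$frame_segment == transition + 1)
  f0 <- tail(w_from, 1)
  phos <- asm$dna$tracked_phos
  persist <- vapply(shared, function(s) {
    loop <- asm$ring$loop_bead[[as.character(s)]]
    p0 <- traj$frames[, loop, f0]
    d0 <- sqrt(colSums((traj$frames[, phos, f0] - p0)^2))
    g <- which.min(d0)
    if (d0[g] > cap) return(0L)
    cnt <- 0L
    for (f in w_to) {
      d <- sqrt(sum((traj$frames[, loop, f] - traj$frames[, phos[g], f])^2))
      if (d < cap) cnt <- cnt + 1L else break
    }
    cnt
  }, integer(1))
  if (all(persist == 0)) return(NA_integer_)
  shared[which.max(persist)]
}

pair_distance_series <- function(traj, pairs) {
  (traj$frames[1, pairs$i, , drop = FALSE] -
     traj$frames[1, pairs$j, , drop = FALSE])^2 +
  (traj$frames[2, pairs$i, , drop = FALSE] -
     traj$frames[2, pairs$j, , drop = FALSE])^2 +
  (traj$frames[3, pairs$i, , drop = FALSE] -
     traj$frames[3, pairs$j, , drop = FALSE])^2
}

#' Unwound base-pair count and reannealing events
#'
#' Number of initially-formed parental (junction-side) base pairs currently
#' flagged broken, per frame. A reannealing event is a formed -> broken ->
#' formed sequence on the same pair.
#'
#' @param traj a fork-scenario `cg_trajectory`.
#' @return list with `series`, `final`, `reannealing_events`.
#' @export
count_unwound_bp <- function(traj) {
  asm <- traj$assembly
  pr <- asm$pairs
  pr <- pr[pr$region == "parental", , drop = FALSE]
  if (nrow(pr) == 0) stop("not a fork scenario (no parental pairs)")
  rb2 <- bp_break_distance(asm$params)^2
  d2 <- matrix(pair_distance_series(traj, pr), nrow = nrow(pr))
  broken <- d2 > rb2
  # every junction-side pair is formed at assembly by construction; the
  # count is therefore over all parental pairs currently flagged broken
  init_formed <- rep(TRUE, nrow(pr))
  series <- colSums(broken[init_formed, , drop = FALSE])
  reanneal <- sum(apply(broken, 1, function(b) {
    r <- rle(b)$values
    sum(r[-1] == FALSE & r[-length(r)] == TRUE)
  }))
  list(series = series, final = series[length(series)],
       reannealing_events = reanneal)
}

#' Lagging-strand pore clogging statistics
#'
#' Per-frame minimum distance between lagging-strand beads (the
#' single-stranded arm plus any parental lagging nucleotides whose base
#' pair is currently broken) and the pore lining; clogged fraction is the
#' fraction of frames below the threshold (10 Angstrom equivalent).
#'
#' @param traj a fork-scenario `cg_trajectory`.
#' @param threshold clogging distance (lu); default from `ff_params`.
#' @return list with `min_dist` series, `clogged_fraction`, `threshold`.
#' @export
clogging_stats <- function(traj, threshold = NULL) {
  asm <- traj$assembly
  if (is.null(threshold)) threshold <- asm$params$clog_threshold
  pore <- asm$ring$pore_bead_set
  # intrusion is measured against the channel interior, below the mouth
  # where the fork junction necessarily sits
  zp <- asm$coords[pore, 3]
  pore <- pore[zp < max(zp) - 2 * asm$params$rise]
  lag <- asm$dna$strands$LAGG
  if (is.null(lag)) stop("not a fork scenario")
  arm_nts <- seq(asm$dna$lagging_arm_start, lag$n)
  arm_beads <- lag$ids_P[arm_nts]    # backbone distance defines intrusion
  pr <- asm$pairs
  ppr <- pr[pr$region == "parental", , drop = FALSE]
  d2p <- matrix(pair_distance_series(traj, ppr), nrow = nrow(ppr))
  rb2 <- bp_break_distance(asm$params)^2
  pore_xyz <- t(traj$frames[, pore, 1])     # frozen
  nf <- frame_count(traj)
  md <- numeric(nf)
  for (f in seq_len(nf)) {
    open_nts <- ppr$nt_j[d2p[, f] > rb2]
    ids <- arm_beads
    if (length(open_nts)) ids <- c(ids, lag$ids_P[open_nts])
    lx <- t(traj$frames[, ids, f])
    d2 <- outer(rowSums(lx^2), rowSums(pore_xyz^2), "+") -
      2 * lx %*% t(pore_xyz)
    md[f] <- sqrt(max(0, min(d2)))
  }
  list(min_dist = md, clogged_fraction = mean(md < threshold),
       threshold = threshold)
}

nucleosome_site_broken <- function(traj) {
  asm <- traj$assembly
  cs <- asm$nucleosome$contact_sites
  p <- asm$params
  prs <- data.frame(i = cs$anchor_bead, j = cs$phosphate_bead)
  d2 <- matrix(pair_distance_series(traj, prs), nrow = nrow(prs))
  lim2 <- (p$r0_site + 6 * p$sigma_site)^2
  list(broken = d2 > lim2, shl = cs$shl)
}

#' Nucleosome unwrapping extent series
#'
#' The SHL label of the innermost entry-side contact site in the maximal
#' contiguous detached run starting from SHL(-6.5); a fully wrapped
#' nucleosome reports the sentinel value -7 ("< -6.5"). Inner transient
#' bubbles that are not connected to the entry end are not counted.
#'
#' @param traj a nucleosome-scenario `cg_trajectory`.
#' @return numeric vector (per frame) of SHL values, -7 when fully wrapped.
#' @export
unwrap_extent <- function(traj) {
  sb <- nucleosome_site_broken(traj)
  entry <- order(sb$shl)
  entry <- entry[sb$shl[entry] < 0]
  ebrk <- sb$broken[entry, , drop = FALSE]
  shls <- sb$shl[entry]
  apply(ebrk, 2, function(b) {
    if (!b[1]) return(-7)
    k <- which(!b)[1]
    if (is.na(k)) shls[length(shls)] else shls[k - 1]
  })
}

#' Lagging-strand capture by the exposed histone surface
#'
#' TRUE when (i) every entry-side site of the exposure rule is detached and
#' (ii) a lagging-strand bead is within the capture cutoff of the H2A/H2B
#' patch, sustained for at least `persistence` consecutive frames.
#'
#' @param traj a nucleosome-scenario `cg_trajectory`.
#' @param persistence consecutive frames required.
#' @param cutoff capture distance; defaults to the hydrogen-bond capture
#'   radius.
#' @return list with `captured` (logical) and `first_frame` (NA if never).
#' @export
lagging_capture <- function(traj, persistence = 5, cutoff = NULL) {
  asm <- traj$assembly
  nuc <- asm$nucleosome
  if (is.null(nuc)) stop("not a nucleosome scenario")
  if (is.null(cutoff)) cutoff <- hb_capture_radius(asm$params)
  sb <- nucleosome_site_broken(traj)
  rule <- nuc$exposure_rule
  sel <- match(rule, sb$shl)
  exposed <- colSums(!sb$broken[sel, , drop = FALSE]) == 0
  lag <- asm$dna$strands$LAGG
  arm_nts <- seq(asm$dna$lagging_arm_start, lag$n)
  ids <- c(lag$ids_P[arm_nts], lag$ids_B[arm_nts])
  patch_xyz <- t(traj$frames[, nuc$h2ab_patch, 1])
  nf <- frame_count(traj)
  contact <- logical(nf)
  for (f in seq_len(nf)) {
    lx <- t(traj$frames[, ids, f])
    d2 <- outer(rowSums(lx^2), rowSums(patch_xyz^2), "+") -
      2 * lx %*% t(patch_xyz)
    contact[f] <- min(d2) < cutoff^2
  }
  ok <- exposed & contact
  r <- rle(ok)
  runs <- which(r$values & r$lengths >= persistence)
  if (length(runs) == 0)
    return(list(captured = FALSE, first_frame = NA_integer_))
  first <- sum(r$lengths[seq_len(runs[1] - 1)]) + 1L
  list(captured = TRUE, first_frame = first)
}

#' Per-bead contact probability
#'
#' For each query bead, the fraction of frames in which its minimum
#' distance to the target set is below the cutoff.
#'
#' @param traj a `cg_trajectory`.
#' @param query_beads,target_beads bead id vectors (nonempty).
#' @param cutoff contact distance; defaults to the hydrogen-bond capture
#'   radius.
#' @return numeric vector, one probability per query bead.
#' @export
contact_probability <- function(traj, query_beads, target_beads,
                                cutoff = NULL) {
  stopifnot(length(query_beads) > 0, length(target_beads) > 0)
  if (is.null(cutoff)) cutoff <- hb_capture_radius(traj$assembly$params)
  nf <- frame_count(traj)
  hits <- matrix(FALSE, length(query_beads), nf)
  for (f in seq_len(nf)) {
    qx <- t(traj$frames[, query_beads, f])
    tx <- t(traj$frames[, target_beads, f])
    d2 <- outer(rowSums(qx^2), rowSums(tx^2), "+") - 2 * qx %*% t(tx)
    hits[, f] <- apply(d2, 1, min) < cutoff^2
  }
  rowMeans(hits)
}

#' Spatial occupancy density on a regular grid
#'
#' Normalised histogram of bead positions over all frames (the frozen
#' nucleosome core defines the reference frame); integrates to 1.
#'
#' @param traj a `cg_trajectory`.
#' @param bead_set bead ids (nonempty).
#' @param grid_spacing voxel edge (lu).
#' @return list with `density` (3-d array), `origin`, `spacing`.
#' @export
occupancy_density <- function(traj, bead_set, grid_spacing = 1) {
  if (length(bead_set) == 0) stop("empty bead set")
  xs <- matrix(aperm(traj$frames[, bead_set, , drop = FALSE], c(2, 3, 1)),
               ncol = 3)
  origin <- floor(apply(xs, 2, min) / grid_spacing) * grid_spacing
  ijk <- floor(sweep(xs, 2, origin) / grid_spacing) + 1L
  dims <- apply(ijk, 2, max)
  dens <- array(0, dims)
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1L) +
    dims[1] * dims[2] * (ijk[, 3] - 1L)
  tb <- tabulate(lin, nbins = prod(dims))
  dens[] <- tb / (sum(tb) * grid_spacing^3)
  list(density = dens, origin = origin, spacing = grid_spacing)
}

#' Displacement/unwinding coupling across runs
#'
#' Pearson correlation between per-run net displacement and final unwound
#' base-pair count.
#'
#' @param run_summaries list of `run_summary` objects (>= 3).
#' @return correlation coefficient; NA with attribute `flagged` when a
#'   variable has zero variance.
#' @export
coupling_correlation <- function(run_summaries) {
  stopifnot(length(run_summaries) >= 3)
  x <- vapply(run_summaries, function(r) r$net_displacement, numeric(1))
  y <- vapply(run_summaries, function(r) r$unwound_final, numeric(1))
  if (sd(x) == 0 || sd(y) == 0) {
    out <- NA_real_
    attr(out, "flagged") <- "zero variance"
    warning("coupling correlation undefined: zero variance")
    return(out)
  }
  cor(x, y)
}

#' One-tailed Wilcoxon-Mann-Whitney comparison with Cohen's d
#'
#' Exact permutation test when both groups have at most 10 observations
#' (complete enumeration of group assignments), normal approximation with
#' tie correction and continuity correction otherwise. The alternative is
#' that `a` is stochastically greater than `b`.
#'
#' @param a,b numeric vectors (>= 3 each).
#' @return list with `p_value`, `cohens_d`, `method`, `flagged`.
#' @export
compare_conditions <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 3 || nb < 3) stop("need at least 3 observations per group")
  pooled_sd <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                      (na + nb - 2))
  if (pooled_sd == 0) {
    return(list(p_value = 0.5, cohens_d = 0,
                method = "degenerate (all tied)", flagged = TRUE))
  }
  d <- (mean(a) - mean(b)) / pooled_sd
  z <- c(a, b)
  rk <- rank(z)
  W <- sum(rk[seq_len(na)])
  if (na <= 10 && nb <= 10) {
    idx <- combn(na + nb, na)
    Ws <- colSums(matrix(rk[idx], nrow = na))
    p <- mean(Ws >= W - 1e-9)
    method <- "exact permutation"
  } else {
    U <- W - na * (na + 1) / 2
    mu <- na * nb / 2
    ties <- table(z)
    n <- na + nb
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- pnorm((U - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
    method <- "normal approximation with tie correction"
  }
  list(p_value = p, cohens_d = d, method = method, flagged = FALSE)
}
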