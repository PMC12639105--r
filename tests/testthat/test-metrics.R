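# Trajectory metrics against constructed-input oracles.

test_that("tracked displacement reads rigid shifts with the right sign", {
  asm <- tiny_ss()
  # static trajectory -> all zeros
  d0 <- tracked_displacement(fake_traj(asm, rep(0, 10)))
  expect_equal(as.integer(d0), rep(0L, 10))
  # DNA rigidly shifted down by k nt = motor advanced k nt toward 5'
  for (k in c(2, 5)) {
    dk <- tracked_displacement(fake_traj(asm, c(0, rep(k, 9))))
    expect_equal(as.integer(dk[10]), k)
  }
  # backward shift is negative
  db <- tracked_displacement(fake_traj(asm, c(0, rep(-3, 9))))
  expect_equal(as.integer(db[10]), -3)
})

test_that("per-transition steps reproduce constructed registries and telescope", {
  asm <- tiny_ss()
  # piecewise-constant displacement 0,1,7,12 across segments -> steps 1,6,5
  shifts <- rep(c(0, 1, 7, 12), each = 25)
  segs <- rep(1:4, each = 25)
  tr <- fake_traj(asm, shifts, segments = segs, seg_states = c(1, 2, 3, 1))
  st <- per_transition_steps(tr)
  expect_equal(st$step_size, c(1, 6, 5))
  expect_equal(st$from_state, c(1, 2, 3))
  expect_equal(st$to_state, c(2, 3, 1))
  expect_equal(attr(st, "net_displacement"), 12)
  expect_equal(attr(st, "outcome"), "forward")
  expect_equal(sum(st$step_size), attr(st, "net_displacement"))
  # no switches: empty table, net = final displacement
  st0 <- per_transition_steps(fake_traj(asm, rep(4, 20)))
  expect_equal(nrow(st0), 0)
  expect_equal(attr(st0, "net_displacement"), 0)  # constant from frame 1
})

test_that("telescoping holds for arbitrary random segment patterns", {
  asm <- tiny_ss()
  set.seed(42)
  for (rep in 1:5) {
    nseg <- sample(3:5, 1)
    shifts <- unlist(lapply(cumsum(sample(-3:6, nseg, TRUE)),
                            function(v) rep(v, 20)))
    segs <- rep(seq_len(nseg), each = 20)
    tr <- fake_traj(asm, shifts, segments = segs,
                    seg_states = rep_len(c(1, 2, 3, 4), nseg))
    st <- per_transition_steps(tr)
    expect_equal(sum(st$step_size), attr(st, "net_displacement"),
                 tolerance = 1e-12)
  }
})

test_that("outcome classification partitions the integers at the +/-3 bounds", {
  expect_equal(classify_outcome(4), "forward")
  expect_equal(classify_outcome(0), "idling")
  expect_equal(classify_outcome(-4), "backward")
  expect_equal(classify_outcome(3), "idling")
  expect_equal(classify_outcome(-3), "idling")
  nets <- -15:15
  cls <- classify_outcome(nets)
  expect_true(all(cls %in% c("forward", "idling", "backward")))
  expect_equal(sum(cls == "idling"), 7)
  expect_error(classify_outcome(NaN))
})

test_that("anchor identity returns a shared engaged subunit or none", {
  asm <- tiny_ss()
  shifts <- rep(c(0, 1), each = 30)
  tr <- fake_traj(asm, shifts, segments = rep(1:2, each = 30),
                  seg_states = c(1, 2))
  a <- anchor_identity(tr, 1)
  shared <- intersect(asm$states[[1]]$engaged_set,
                      asm$states[[2]]$engaged_set)
  expect_true(is.na(a) || a %in% shared)
})

test_that("unwound base pairs count a synthetic melt and reannealing", {
  fk <- tiny_fork()
  nf <- 12
  n <- nrow(fk$coords)
  frames <- array(rep(t(fk$coords), nf), dim = c(3, n, nf))
  tr <- fake_traj(fk, rep(0, nf))
  # assembly frame: zero unwound
  uw0 <- count_unwound_bp(tr)
  expect_equal(unname(uw0$series), rep(0, nf))
  # melt 5 junction-side pairs in later frames, refreeze one (reannealing)
  pr <- fk$pairs[fk$pairs$region == "parental", ]
  pr <- pr[order(pr$nt_i), ]     # junction side first
  melt <- pr$i[1:5]
  tr2 <- tr
  for (f in 5:nf) tr2$frames[1, melt, f] <- tr2$frames[1, melt, f] + 30
  tr2$frames[1, melt[1], 9:nf] <- tr2$frames[1, melt[1], 9:nf] - 30
  uw <- count_unwound_bp(tr2)
  expect_equal(unname(uw$series[4]), 0)
  expect_equal(unname(uw$series[6]), 5)
  expect_equal(unname(uw$final), 4)
  expect_equal(uw$reannealing_events, 1)
})

test_that("clogging statistics flag planted pore intrusions", {
  fk <- tiny_fork()
  tr <- fake_traj(fk, rep(0, 6))
  cl0 <- clogging_stats(tr)
  # plant a lagging arm bead inside the pore (1 lu from a pore bead)
  lag <- fk$dna$strands$LAGG
  arm_bead <- lag$ids_P[fk$dna$lagging_arm_start + 2]
  pore1 <- fk$ring$pore_bead_set[1]
  tr2 <- tr
  tr2$frames[, arm_bead, 3] <- tr2$frames[, pore1, 3] + c(1, 0, 0)
  cl <- clogging_stats(tr2)
  expect_lt(cl$min_dist[3], 2.0)
  expect_equal(cl$clogged_fraction, 1 / 6)
  expect_true(all(cl$min_dist[-3] >= cl$min_dist[3]))
})

test_that("unwrap extent follows the contiguous-from-entry definition", {
  nuc <- fixture("free_nuc", function() build_free_nucleosome(seed = 1))
  tr <- fake_traj(nuc, rep(0, 4))
  # fully wrapped reference: sentinel -7
  expect_equal(unwrap_extent(tr), rep(-7, 4))
  cs <- nuc$nucleosome$contact_sites
  off <- function(tr, shls, f) {
    k <- match(shls, cs$shl)
    tr$frames[1, cs$phosphate_bead[k], f] <-
      tr$frames[1, cs$phosphate_bead[k], f] + 50
    tr
  }
  # -6.5, -5.5, -4.5 broken, -3.5 formed -> extent -4.5
  tr2 <- off(tr, c(-6.5, -5.5, -4.5), 2)
  # non-contiguous inner island is ignored -> fully wrapped
  tr2 <- off(tr2, c(-4.5), 3)
  e <- unwrap_extent(tr2)
  expect_equal(e[1], -7)
  expect_equal(e[2], -4.5)
  expect_equal(e[3], -7)
})

test_that("lagging capture needs exposure and sustained patch contact", {
  skip_if(is.null(tryCatch(build_nucleosome_scenario(-4, seed = 1),
                           error = function(e) NULL)),
          "nucleosome scenario unavailable")
  asm <- fixture("nuc4", function() build_nucleosome_scenario(-4, seed = 1))
  tr <- fake_traj(asm, rep(0, 12))
  # patch occluded at assembly: no capture
  expect_false(lagging_capture(tr)$captured)
  # construct exposure (break all exposure-rule sites) + plant contact
  cs <- asm$nucleosome$contact_sites
  k <- match(asm$nucleosome$exposure_rule, cs$shl)
  tr2 <- tr
  for (f in 4:12)
    tr2$frames[2, cs$phosphate_bead[k], f] <-
      tr2$frames[2, cs$phosphate_bead[k], f] - 60
  lagb <- asm$dna$strands$LAGG$ids_P[asm$dna$lagging_arm_start + 1]
  patch1 <- asm$nucleosome$h2ab_patch[1]
  for (f in 4:12)
    tr2$frames[, lagb, f] <- tr2$frames[, patch1, f] + c(0.8, 0, 0)
  lc <- lagging_capture(tr2, persistence = 5)
  expect_true(lc$captured)
  expect_equal(lc$first_frame, 4L)
})

test_that("contact probabilities and densities match hand computations", {
  asm <- tiny_ss()
  tr <- fake_traj(asm, rep(0, 10))
  # static disjoint groups beyond cutoff -> all zeros
  q <- asm$dna$tracked_phos[1:3]
  t1 <- asm$ring$pore_bead_set[1:5]
  p0 <- contact_probability(tr, q, t1, cutoff = 0.01)
  expect_equal(p0, rep(0, 3))
  # permanent contact -> probability 1
  p1 <- contact_probability(tr, q, q, cutoff = 0.5)
  expect_equal(p1, rep(1, 3))
  expect_error(contact_probability(tr, integer(0), t1), "length")
  # occupancy: single static bead puts all mass in one voxel
  d1 <- occupancy_density(tr, asm$dna$tracked_phos[1], grid_spacing = 1)
  expect_equal(sum(d1$density > 0), 1)
  expect_equal(sum(d1$density) * 1^3, 1, tolerance = 1e-6)
  # two-frame constructed histogram
  tr2 <- fake_traj(asm, c(0, 0))
  b <- asm$dna$tracked_phos[1]
  tr2$frames[, b, 2] <- tr2$frames[, b, 1] + c(3, 0, 0)
  d2 <- occupancy_density(tr2, b, grid_spacing = 1)
  expect_equal(sort(d2$density[d2$density > 0]), c(0.5, 0.5))
  expect_error(occupancy_density(tr, integer(0)), "empty")
})

test_that("coupling correlation matches closed forms and flags degeneracy", {
  mk <- function(net, uw) structure(list(net_displacement = net,
                                         unwound_final = uw),
                                    class = "run_summary")
  perfect <- Map(mk, 1:5, 1:5)
  expect_equal(coupling_correlation(perfect), 1)
  anti <- Map(mk, 1:5, 5:1)
  expect_equal(coupling_correlation(anti), -1)
  # hand-checkable 4-point set against the textbook formula
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 6)
  four <- Map(mk, x, y)
  expect_equal(coupling_correlation(four),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_warning(r <- coupling_correlation(Map(mk, c(1, 1, 1), 1:3)),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("Wilcoxon-Mann-Whitney comparison matches brute-force enumeration", {
  # disjoint-support 5 vs 5: exact one-tailed p = 1/252
  a <- c(10, 11, 12, 13, 14); b <- c(1, 2, 3, 4, 5)
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$p_value, 1 / choose(10, 5))
  expect_equal(cmp$method, "exact permutation")
  # independent brute-force oracle over all assignments, random data
  set.seed(7)
  x <- rnorm(5); y <- rnorm(5) - 0.5
  cmp2 <- compare_conditions(x, y)
  z <- c(x, y); rk <- rank(z)
  W <- sum(rk[1:5])
  idx <- combn(10, 5)
  Ws <- colSums(matrix(rk[idx], nrow = 5))
  expect_equal(cmp2$p_value, mean(Ws >= W - 1e-9))
  # identical groups: d = 0
  expect_equal(compare_conditions(c(1, 2, 3), c(1, 2, 3))$cohens_d, 0)
  # all tied: p = 0.5 convention, flagged
  tied <- compare_conditions(rep(1, 5), rep(1, 5))
  expect_true(tied$flagged)
  expect_equal(tied$p_value, 0.5)
  expect_equal(tied$cohens_d, 0)
  # constant shift by one pooled SD: d = 1
  b2 <- rep(c(0, 2), 5)
  a2 <- b2 + sd(b2)
  expect_equal(compare_conditions(a2, b2)$cohens_d, 1)
  expect_error(compare_conditions(1:2, 1:5), "at least 3")
  # large-sample branch uses the tie-corrected normal approximation
  set.seed(8)
  big <- compare_conditions(rnorm(15) + 1, rnorm(15))
  expect_equal(big$method, "normal approximation with tie correction")
  expect_lt(big$p_value, 0.5)
})
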