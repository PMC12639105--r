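# Structure generators: ring geometry, reference states, scenario
# assemblies, clash-freedom and seeded determinism.

test_that("ring construction counts beads and validates the pore", {
  ring <- build_ring(beads_per_subunit = 20)
  body <- sum(!ring$beads$bead_id %in% ring$loop_bead)
  expect_equal(body, 120)
  expect_equal(length(ring$loop_bead), 6)
  expect_true(length(ring$pore_bead_set) > 0)
  expect_error(build_ring(pore_radius = 0.3), "pore too small")
  expect_error(build_ring(pore_radius = 3.0), "admits duplex")
  expect_error(build_ring(beads_per_subunit = 3), ">= 4")
})

test_that("reference states carry the printed engaged sets and registry", {
  ring <- build_ring()
  states <- build_reference_states(structure(
    c(ring, list(coords = ring$coords)), class = "ring_topology"))
  expect_equal(states[[1]]$engaged_set, c(2, 3, 5, 6))
  expect_equal(states[[2]]$engaged_set, c(2, 3, 5, 7))
  expect_equal(states[[3]]$engaged_set, c(3, 4, 6, 7))
  expect_equal(sort(states[[4]]$engaged_set), c(2, 4, 6, 7))
  d <- vapply(states, function(s) s$registry_offset, numeric(1))
  expect_equal(d, c(0, 1, 7, 9))
  # printed step size of the 2->3 transition
  expect_equal(d[3] - d[2], 6)
  # cycle closure: per-transition registry differences sum to 12 nt
  expect_equal((d[2] - d[1]) + (d[3] - d[2]) + (d[4] - d[3]) +
                 ((d[1] + 12) - d[4]), 12)
  # forward 3-state branch: 3->1 difference is 5 nt
  expect_equal((d[1] + 12) - d[3], 5)
  for (s in states) {
    reg <- s$per_subunit_registry
    # two consecutive nt ranks per engaged subunit, disjoint across them
    expect_true(all(vapply(reg, function(r) diff(r) == 1, logical(1))))
    expect_equal(anyDuplicated(unlist(reg)), 0)
    expect_equal(length(s$engaged_set), 4)
  }
  # anchor ambiguity of the 3-state cycle: subunits 3 and 6 engaged in both
  expect_true(all(c(3, 6) %in% intersect(states[[3]]$engaged_set,
                                         states[[1]]$engaged_set)))
  # consecutive 4-state cycle states share at least one engaged subunit
  for (k in 1:4) {
    nxt <- if (k == 4) 1 else k + 1
    expect_gte(length(intersect(states[[k]]$engaged_set,
                                states[[nxt]]$engaged_set)), 1)
  }
})

test_that("ssDNA scenario validates ring position and forms contacts", {
  asm <- build_ssdna_scenario(60, 30, seed = 1)
  expect_s3_class(asm, "cg_assembly")
  expect_equal(sum(asm$beads$kind != "protein"), 3 * 60)
  # State-1 contacts formable: loop-to-nearest-phosphate within well range
  act <- make_active_potentials(asm, 1L)
  e <- ringmotor:::eval_energy(asm$coords, act)
  expect_lt(e$well, 0)
  expect_error(build_ssdna_scenario(60, 2), "too close")
  # full-scale geometry remains constructible
  full <- build_ssdna_scenario(495, 157, seed = 1)
  expect_equal(full$ring_position_nt, 157)
})

test_that("fork scenario encodes sequence classes and occlusion variants", {
  gc <- build_fork_scenario(12, 6, 6, 8, 16, sequence_mode = "polyGC",
                            seed = 1)
  expect_true(all(gc$pairs$class == "GC"))
  at <- build_fork_scenario(12, 6, 6, 8, 16, sequence_mode = "polyAT",
                            seed = 1)
  expect_true(all(at$pairs$class == "AT"))
  expect_true(all(at$pairs$eps < gc$pairs$eps))
  # paper-scale fork remains constructible
  paper <- build_fork_scenario(168, 113, 285, 29, 42, seed = 1)
  expect_equal(paper$dna$parental_len, 168)
  # subunit-3 loop is 7 nt from the junction
  expect_equal(paper$dna$fork_junction_index - paper$ring_position_nt, 7)
  # duplex-occluded lagging arm: no unpaired lagging nt at assembly
  occ <- build_fork_scenario(12, 6, 6, 8, 16, seed = 1,
                             lagging_mode = "duplex-occluded")
  expect_equal(occ$dna$lagging_ss_nt, 0)
  expect_error(build_fork_scenario(12, 6, 6, 8, 6), "threading")
})

test_that("assemblies are clash-free and bead tables well-formed", {
  for (asm in list(tiny_ss(), tiny_fork())) {
    expect_null(ringmotor:::assembly_clash(asm$beads, asm$coords,
                                           asm$molecule))
    b <- asm$beads
    expect_equal(b$bead_id, seq_len(nrow(b)))
    expect_true(all(b$radius > 0))
    nt <- table(b$kind[b$kind != "protein"])
    expect_true(all(nt == nt[1]))  # one P, S, B bead per nucleotide
  }
})

test_that("identical scenario spec and seed give identical coordinates", {
  a1 <- build_fork_scenario(12, 6, 6, 8, 16, seed = 9)
  a2 <- build_fork_scenario(12, 6, 6, 8, 16, seed = 9)
  expect_identical(a1$coords, a2$coords)
  expect_identical(a1$vels, a2$vels)
  a3 <- build_fork_scenario(12, 6, 6, 8, 16, seed = 10)
  expect_false(identical(a3$coords, a1$coords) &&
                 identical(a3$vels, a1$vels))
})

test_that("factor placement tiles RPA and respects the identity case", {
  fk <- tiny_fork()
  expect_identical(place_factors(fk, factor_set()), fk)
  withrpa <- place_factors(fk, factor_set(rpa = TRUE, rpa_footprint = 8))
  expect_equal(length(withrpa$factors$rpa), 1)  # floor(8/8) = 1 body
  none <- place_factors(fk, factor_set(rpa = TRUE, rpa_footprint = 25))
  expect_equal(length(none$factors$rpa), 0)     # floor(8/25) = 0 bodies
  wfpc <- place_factors(fk, factor_set(fpc = TRUE, ctf4 = TRUE))
  expect_true(!is.null(wfpc$factors$fpc))
  # FPC positive patch within electrostatic range of parental phosphates
  dh <- dh_constants(fk$params)
  patch <- wfpc$factors$fpc$patch
  j <- wfpc$dna$fork_junction_index
  pids <- wfpc$dna$strands$LEAD$ids_P[j:(j + 4)]
  dmin <- min(as.matrix(dist(rbind(wfpc$coords[patch, ],
                                   wfpc$coords[pids, ])))[
    seq_along(patch), length(patch) + seq_along(pids)])
  expect_lt(dmin, dh$r_cut)
  # electrostatics-off variant zeroes the patch charges, all else equal
  off <- place_factors(fk, factor_set(fpc = TRUE,
                                      fpc_electrostatics_on = FALSE))
  expect_equal(off$beads$charge_pro[off$factors$fpc$patch], rep(0, 4))
})
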