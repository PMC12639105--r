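# Potential terms: closed forms, brute-force oracles, force-energy
# consistency, switch invariance of always-on terms.

test_that("bonded terms vanish at reference and follow the closed form", {
  asm <- tiny_ss()
  # single stretched bond: displace one terminal phosphate along the bond
  b1 <- asm$bonds[1, ]
  x <- asm$coords
  dvec <- x[b1$i, ] - x[b1$j, ]
  r <- sqrt(sum(dvec^2))
  delta <- 0.1
  x2 <- x
  x2[b1$i, ] <- x[b1$j, ] + dvec / r * (b1$r0 + delta)
  e_ref <- total_energy(asm)
  e_str <- total_energy(asm, coords = x2)
  expect_equal(e_str$bond - e_ref$bond,
               0.5 * b1$k * delta^2 - 0.5 * b1$k * (r - b1$r0)^2,
               tolerance = 1e-8)
  # brute-force term-by-term oracle on a perturbed configuration
  set.seed(4)
  xp <- asm$coords + matrix(rnorm(length(asm$coords), 0, 0.01), ncol = 3)
  manual <- sum(apply(asm$bonds, 1, function(row) {
    d <- sqrt(sum((xp[row["i"], ] - xp[row["j"], ])^2))
    0.5 * row["k"] * (d - row["r0"])^2
  }))
  ang <- apply(asm$angles, 1, function(row) {
    v1 <- xp[row["i"], ] - xp[row["j"], ]
    v2 <- xp[row["k_"], ] - xp[row["j"], ]
    cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    row["kang"] * (1 + cs)   # cosine bending form
  })
  e <- total_energy(asm, coords = xp)
  expect_equal(e$bond, manual, tolerance = 1e-10)
  expect_equal(e$angle, sum(ang), tolerance = 1e-10)
})

test_that("hydrogen-bond wells bind the nearer eligible phosphate", {
  asm <- tiny_ss()
  p <- asm$params
  act <- make_active_potentials(asm, 1L)
  # place one loop exactly at r0 from its nearest phosphate: -eps each for
  # the two wells of that loop is the lower bound of its contribution
  e <- ringmotor:::eval_energy(asm$coords, act)
  expect_gte(e$well, -8 * p$eps_hb)   # 4 engaged loops x 2 wells
  expect_lt(e$well, 0)
  # far tail: pull the whole DNA 6 sigma + r0 away radially
  x2 <- asm$coords
  dna <- asm$beads$kind != "protein"
  x2[dna, 1] <- x2[dna, 1] + (p$r0_hb + 8 * p$sigma_hb)
  e2 <- ringmotor:::eval_energy(x2, act)
  expect_lt(abs(e2$well), 1e-4 * p$eps_hb)
  # nearest selection matches an explicit minimum over the eligible set
  loops <- asm$ring$loop_bead[as.character(asm$states[[1]]$engaged_set)]
  wp <- e$well_partner + 1L
  for (k in seq_along(loops)) {
    d <- sqrt(colSums((t(asm$coords[asm$dna$tracked_phos, ]) -
                         asm$coords[loops[[k]], ])^2))
    expect_equal(wp[2 * k - 1], asm$dna$tracked_phos[which.min(d)])
  }
})

test_that("base pairing is deeper for GC, flags breakage, resists pulling", {
  gc <- build_fork_scenario(12, 6, 6, 8, 16, sequence_mode = "polyGC",
                            seed = 3)
  at <- build_fork_scenario(12, 6, 6, 8, 16, sequence_mode = "polyAT",
                            seed = 3)
  bg <- basepair_energy(gc)
  ba <- basepair_energy(at)
  expect_true(all(bg$formed))
  expect_true(all(ba$formed))
  expect_lt(bg$energy, ba$energy)  # GC pairs are more stable
  # separate one pair beyond the break distance -> flagged broken, ~0 energy
  p <- at$params
  x <- at$coords
  pr <- at$pairs[at$pairs$region == "parental", ][1, ]
  x[pr$i, ] <- x[pr$i, ] + c(0, 0, 40)   # move the base far away
  b2 <- basepair_energy(at, coords = x)
  k <- which(at$pairs$i == pr$i)
  expect_false(b2$formed[k])
  # quasi-static pulling oracle: the maximum restoring force of an AT well
  # is below that of a GC well, so AT melts first at matched geometry
  morse_force <- function(eps, alpha, r0, r)
    2 * eps * alpha * exp(-alpha * (r - r0)) * (1 - exp(-alpha * (r - r0)))
  rr <- seq(p$r0_bp, p$r0_bp + 2, by = 0.01)
  expect_lt(max(morse_force(p$eps_at, p$alpha_bp, p$r0_bp, rr)),
            max(morse_force(p$eps_gc, p$alpha_bp, p$r0_bp, rr)))
})

test_that("screened electrostatics follow Debye-Hueckel with charge rules", {
  asm <- tiny_ss()
  dh <- dh_constants(asm$params)
  # two unit charges at one Debye length: closed-form screened Coulomb
  r <- 1 / dh$kappa
  u_expect <- dh$lB * exp(-1) / r - dh$lB * exp(-dh$kappa * dh$r_cut) / dh$r_cut
  # construct a two-bead system through the public topology path
  topo <- ringmotor:::as_cpp_topology(asm)
  topo$radius <- c(0.1, 0.1); topo$mass <- c(1, 1); topo$ev_eps <- c(0, 0)
  topo$charge_dna <- c(0, 0); topo$charge_pro <- c(1, 1)
  topo$is_dna <- c(0L, 0L); topo$mobile <- c(1L, 1L)
  for (nm in c("bonds_ij", "angles_ijk", "morse_ij", "stack_ij", "site_ij",
               "excl_ij"))
    topo[[nm]] <- topo[[nm]][0, , drop = FALSE]
  for (nm in c("bonds_par", "angles_par", "morse_par", "stack_par",
               "site_par", "posres_par"))
    topo[[nm]] <- topo[[nm]][0, , drop = FALSE]
  topo$posres_i <- integer(0)
  st0 <- make_active_potentials(asm, NULL)$state_terms
  st0$eligible <- integer(0)
  e <- ringmotor:::.cg_energy_cpp(rbind(c(0, 0, 0), c(r, 0, 0)), topo, st0)
  expect_equal(e$dh, u_expect, tolerance = 1e-6)
  # zero-charge pair contributes nothing
  topo$charge_pro <- c(0, 1)
  e0 <- ringmotor:::.cg_energy_cpp(rbind(c(0, 0, 0), c(r, 0, 0)), topo, st0)
  expect_equal(e0$dh, 0)
  # intra-DNA vs protein-DNA classing: energies in the 0.36 : 0.6 ratio
  topo$is_dna <- c(1L, 1L)
  topo$charge_dna <- c(-0.6, -0.6); topo$charge_pro <- c(-1, -1)
  e_dd <- ringmotor:::.cg_energy_cpp(rbind(c(0, 0, 0), c(r, 0, 0)), topo, st0)
  topo$is_dna <- c(1L, 0L)
  topo$charge_pro <- c(-1, 0.6)
  e_pd <- ringmotor:::.cg_energy_cpp(rbind(c(0, 0, 0), c(r, 0, 0)), topo, st0)
  expect_equal(e_dd$dh / e_pd$dh, (-0.6 * -0.6) / (-1.0 * 0.6),
               tolerance = 1e-6)
})

test_that("excluded volume is repulsive, truncated, and matches brute force", {
  asm <- tiny_ss()
  e <- total_energy(asm)
  expect_gte(e$ev, 0)
  # brute-force pair loop oracle on the assembly configuration
  x <- asm$coords; rad <- asm$beads$radius
  topo <- ringmotor:::as_cpp_topology(asm)
  evs <- topo$ev_eps
  excl <- paste(topo$excl_ij[, 1], topo$excl_ij[, 2])
  excl <- c(excl, paste(topo$excl_ij[, 2], topo$excl_ij[, 1]))
  ev_manual <- 0
  mob <- asm$beads$mobile
  for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
    if (!mob[i] && !mob[j]) next
    if (paste(i - 1, j - 1) %in% excl) next
    sig <- rad[i] + rad[j]
    eps_ij <- sqrt(evs[i] * evs[j])
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (r >= 1.5 * sig) next
    shift <- (1 / 1.5)^12
    if (r >= 0.85 * sig) {
      ev_manual <- ev_manual + eps_ij * ((sig / r)^12 - shift)
    } else {
      s12m <- (1 / 0.85)^12
      f0 <- 12 * eps_ij * s12m / (0.85 * sig)
      ev_manual <- ev_manual + eps_ij * (s12m - shift) +
        f0 * (0.85 * sig - r)
    }
  }
  expect_equal(e$ev, ev_manual, tolerance = 1e-8)
  # monotone in overlap for an isolated pair
  u_of <- function(r) {
    topo2 <- topo
    topo2$radius <- c(0.5, 0.5); topo2$mass <- c(1, 1)
    topo2$ev_eps <- c(asm$params$eps_ev, asm$params$eps_ev)
    topo2$charge_dna <- topo2$charge_pro <- c(0, 0)
    topo2$is_dna <- c(0L, 0L); topo2$mobile <- c(1L, 1L)
    for (nm in c("bonds_ij", "angles_ijk", "morse_ij", "stack_ij",
                 "site_ij", "excl_ij"))
      topo2[[nm]] <- topo2[[nm]][0, , drop = FALSE]
    for (nm in c("bonds_par", "angles_par", "morse_par", "stack_par",
                 "site_par", "posres_par"))
      topo2[[nm]] <- topo2[[nm]][0, , drop = FALSE]
    topo2$posres_i <- integer(0)
    st0 <- make_active_potentials(asm, NULL)$state_terms
    st0$eligible <- integer(0)
    ringmotor:::.cg_energy_cpp(rbind(c(0, 0, 0), c(r, 0, 0)), topo2, st0)$ev
  }
  rs <- seq(0.2, 1.6, by = 0.1)
  us <- vapply(rs, u_of, numeric(1))
  expect_true(all(diff(us) <= 1e-12))
  expect_equal(us[rs >= 1.5], rep(0, sum(rs >= 1.5)))
})

test_that("forces are the analytic gradient of the energy", {
  asm <- tiny_ss_relaxed()
  act <- make_active_potentials(asm, 1L)
  set.seed(11)
  x <- asm$coords
  mob <- which(asm$beads$mobile)
  x[mob, ] <- x[mob, ] + matrix(rnorm(3 * length(mob), 0, 0.02), ncol = 3)
  e <- ringmotor:::eval_energy(x, act)
  h <- 1e-5
  errs <- c()
  for (b in sample(mob, 10)) for (d in 1:3) {
    xp <- x; xp[b, d] <- xp[b, d] + h
    xm <- x; xm[b, d] <- xm[b, d] - h
    num <- -(ringmotor:::eval_energy(xp, act)$total -
               ringmotor:::eval_energy(xm, act)$total) / (2 * h)
    errs <- c(errs, abs(num - e$forces[b, d]) / max(1, abs(num)))
  }
  expect_lt(max(errs), 1e-4)
  expect_error(total_force(asm, coords = x * NA), "non-finite")
})

test_that("doubling the well depth doubles the well energy exactly", {
  asm <- tiny_ss()
  a1 <- make_active_potentials(asm, 1L)
  a2 <- a1
  a2$state_terms$well_par[, 1] <- 2 * a2$state_terms$well_par[, 1]
  e1 <- ringmotor:::eval_energy(asm$coords, a1)
  e2 <- ringmotor:::eval_energy(asm$coords, a2)
  expect_equal(e2$well, 2 * e1$well, tolerance = 1e-12)
})

test_that("always-on terms are invariant across a state switch", {
  asm <- tiny_ss_relaxed()
  for (st in 2:4) {
    e1 <- total_energy(asm, make_active_potentials(asm, 1L))
    e2 <- total_energy(asm, make_active_potentials(asm, st))
    for (term in c("bond", "angle", "morse", "stack", "site", "ev", "dh",
                   "posres"))
      expect_identical(e1[[term]], e2[[term]])
    # state-dependent terms do change
    expect_false(isTRUE(all.equal(e1$native, e2$native)))
  }
  # conformation-only: contact set retained from the previous state
  act <- make_active_potentials(asm, 2L, contact_state_id = 1L)
  act1 <- make_active_potentials(asm, 1L)
  expect_identical(act$state_terms$well_loop, act1$state_terms$well_loop)
  expect_error(make_active_potentials(asm, 7L), "unknown state")
})

test_that("active potentials restrict wells to the engaged subunits", {
  asm <- tiny_ss()
  act1 <- make_active_potentials(asm, 1L)
  loops1 <- asm$ring$loop_bead[as.character(c(2, 3, 5, 6))]
  expect_setequal(unique(act1$state_terms$well_loop + 1L), unlist(loops1))
  act2 <- make_active_potentials(asm, 2L)
  loops2 <- asm$ring$loop_bead[as.character(c(2, 3, 5, 7))]
  expect_setequal(unique(act2$state_terms$well_loop + 1L), unlist(loops2))
})
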