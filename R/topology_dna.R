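# DNA strand construction: three beads per nucleotide (phosphate, sugar,
# base), harmonic backbone, weak angle terms, stacking, and Morse base
# pairing with AT/GC-graded depths. Residue indices increase toward the
# 5' end of every strand, so forward (3'->5') motor translocation along the
# tracked strand is positive.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# seeded sequence generation; complementarity is enforced by construction
make_sequence <- function(n, mode = c("random", "polyAT", "polyGC")) {
  mode <- match.arg(mode)
  if (n == 0) return(character(0))
  switch(mode,
    random = sample(BASES, n, replace = TRUE),
    polyAT = rep_len(c("A", "T"), n),
    polyGC = rep_len(c("G", "C"), n))
}

pair_class <- function(b1, b2) {
  ok <- COMPLEMENT[b1] == b2
  if (!all(ok)) stop("pairing table is not complementary")
  ifelse(b1 %in% c("A", "T"), "AT", "GC")
}

# Build one strand along a path. `path` is an (n x 3) matrix of per-nt
# backbone reference points (the phosphate positions); sugars sit halfway to
# the next nt, bases offset along `base_dir` (n x 3). Returns bead table,
# coords, bonded terms, and per-nt bead-id lookups.
build_strand <- function(chain_id, seq, path, base_dir, params,
                         ds_mask = NULL) {
  n <- length(seq)
  stopifnot(nrow(path) == n)
  if (is.null(ds_mask)) ds_mask <- rep(FALSE, n)
  step <- rbind(path[-1, , drop = FALSE] - path[-n, , drop = FALSE], c(0, 0, 0))
  if (n > 1) step[n, ] <- step[n - 1, ]
  sugar <- path + 0.5 * step
  base <- sugar + 0.4 * base_dir
  ids_P <- seq_len(n) * 3L - 2L
  ids_S <- ids_P + 1L
  ids_B <- ids_P + 2L
  coords <- matrix(0, 3 * n, 3)
  coords[ids_P, ] <- path
  coords[ids_S, ] <- sugar
  coords[ids_B, ] <- base
  beads <- data.frame(
    bead_id = seq_len(3 * n),
    kind = rep(c("phosphate", "sugar", "base"), n),
    chain_id = chain_id,
    residue_index = rep(seq_len(n), each = 3),
    mass = params$mass,
    radius = rep(c(params$radius_phosphate, params$radius_sugar,
                   params$radius_base), n),
    charge_dna = rep(c(params$q_phosphate_intra, 0, 0), n),
    charge_pro = rep(c(params$q_phosphate_protein, 0, 0), n),
    mobile = TRUE,
    stringsAsFactors = FALSE)
  bonds <- rbind(
    data.frame(i = ids_P, j = ids_S, r0 = params$bond_ps, k = params$k_bond),
    data.frame(i = ids_S, j = ids_B, r0 = params$bond_sb, k = params$k_bond),
    if (n > 1)
      data.frame(i = ids_S[-n], j = ids_P[-1], r0 = params$bond_ps,
                 k = params$k_bond))
  angles <- NULL
  if (n > 1) {
    # duplex regions carry B-form bending rigidity; ssDNA stays flexible
    k1 <- ifelse(ds_mask[-n], params$k_angle_ds, params$k_angle)
    k2 <- ifelse(ds_mask[-n] & ds_mask[-1], params$k_angle_ds,
                 params$k_angle)
    angles <- rbind(
      # P(n) - S(n) - P(n+1)
      data.frame(i = ids_P[-n], j = ids_S[-n], k_ = ids_P[-1],
                 theta0 = pi, kang = k1),
      # S(n) - P(n+1) - S(n+1)
      data.frame(i = ids_S[-n], j = ids_P[-1], k_ = ids_S[-1],
                 theta0 = pi, kang = k2))
  }
  stacks <- NULL
  if (n > 1) {
    r0s <- ifelse(ds_mask[-n] & ds_mask[-1], params$rise_ds,
                  params$r0_stack)
    stacks <- data.frame(i = ids_B[-n], j = ids_B[-1],
                         eps = params$eps_stack, alpha = params$alpha_stack,
                         r0 = r0s)
  }
  list(beads = beads, coords = coords, bonds = bonds, angles = angles,
       stacks = stacks, seq = seq,
       ids_P = ids_P, ids_S = ids_S, ids_B = ids_B)
}

# linear ramp used to blend lateral offsets at duplex/ss boundaries
offset_ramp <- function(n_idx, on_ranges, width = 2) {
  w <- numeric(length(n_idx))
  for (rg in on_ranges) {
    lo <- rg[1]; hi <- rg[2]
    w <- pmax(w, pmin(1, pmin((n_idx - lo + width) / width,
                              (hi - n_idx + width) / width)))
  }
  pmin(1, pmax(0, w))
}
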