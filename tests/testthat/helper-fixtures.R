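# Shared fixtures, built once per session. All fixtures are generated in
# code; sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_ss <- function() fixture("tiny_ss", function()
  build_ssdna_scenario(40, 20, seed = 1))

tiny_ss_relaxed <- function() fixture("tiny_ss_relaxed", function()
  relax(build_ssdna_scenario(40, 20, seed = 1), n_steps = 500, seed = 1))

tiny_fork <- function() fixture("tiny_fork", function()
  build_fork_scenario(parental_bp = 12, lagging_bp = 6, leading_bp = 6,
                      lagging_ss_nt = 8, leading_ss_nt = 16, seed = 2))

# a synthetic trajectory: the DNA of `asm` rigidly shifted along -z by
# `shift_nt[k]` nucleotides in frame k (ring frame fixed), optionally with
# explicit segment ids; used as the constructed input for metric oracles
fake_traj <- function(asm, shift_nt, segments = NULL,
                      seg_states = NULL) {
  nf <- length(shift_nt)
  n <- nrow(asm$coords)
  dna <- asm$beads$kind != "protein"
  frames <- array(0, dim = c(3, n, nf))
  a <- asm$params$rise
  for (f in seq_len(nf)) {
    x <- asm$coords
    # constant 0.3-nt offset avoids the degenerate half-integer alignment
    # of the reference site with the assembly lattice
    x[dna, 3] <- x[dna, 3] - (shift_nt[f] - 0.3) * a
    frames[, , f] <- t(x)
  }
  if (is.null(segments)) segments <- rep(1L, nf)
  if (is.null(seg_states)) seg_states <- unique(segments) * 0L + 1L
  ev <- NULL
  bounds <- which(diff(segments) != 0)
  if (length(bounds))
    ev <- data.frame(step = bounds * 10L,
                     from_state = seg_states[segments[bounds]],
                     to_state = seg_states[segments[bounds + 1L]])
  structure(list(
    frames = frames, frame_step = seq_len(nf) * 10L,
    frame_state = seg_states[segments], frame_segment = segments,
    switch_events = ev, segments = seg_states,
    protocol = switch_protocol(seg_states, 10),
    interval = 10, seed = 0, assembly = asm
  ), class = "cg_trajectory")
}
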