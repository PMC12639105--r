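# Langevin engine: BAOAB integration in the C++ core, steepest-descent
# relaxation, the state-switching scheduler, and the trajectory container.

#' Define a switching protocol
#'
#' @param sequence ordered state ids (cyclic); e.g. `c(1, 2, 3)` for the
#'   3-state scheme, `c(1, 2, 3, 4)` for the 4-state scheme, `c(1, 3, 2)`
#'   for the reversed control.
#' @param interval steps between switches.
#' @param mode `"full"` (wells + conformation switch together),
#'   `"conformation_only"` (loop targets switch, wells held at the initial
#'   state's contact set), or `"frozen"` (no switching).
#' @param n_cycles number of times the sequence is traversed.
#' @return a `switch_protocol` list.
#' @export
switch_protocol <- function(sequence, interval = NULL,
                            mode = c("full", "conformation_only", "frozen"),
                            n_cycles = 1) {
  mode <- match.arg(mode)
  stopifnot(length(sequence) >= 1, all(sequence %in% 1:4), n_cycles >= 1)
  if (!is.null(interval)) stopifnot(interval > 0)
  structure(list(sequence = as.integer(sequence), interval = interval,
                 mode = mode, n_cycles = n_cycles),
            class = "switch_protocol")
}

seg_seed <- function(seed, k) ((seed %% 65011) * 32003 + 977 * k) %% 2147483629

run_opts <- function(params, n_steps, seed, subsample,
                     well_partner = integer(0), well_age = numeric(0),
                     well_refract = numeric(0)) {
  list(n_steps = as.integer(n_steps), dt = params$dt,
       gamma = params$friction, temperature = params$temperature,
       mass = params$mass,
       subsample_every = as.integer(max(1, floor(n_steps / subsample))),
       seed = as.double(seed),
       nlist_every = as.integer(params$nlist_every),
       nlist_skin = params$nlist_skin,
       force_overflow = params$force_overflow,
       well_partner = as.integer(well_partner),
       well_age = as.numeric(well_age),
       well_refract = as.numeric(well_refract))
}

# carry dynamic-bond partners across a switch: wells are listed in the
# order of the contact state's engaged subunits
map_partners <- function(assembly, old_contact, old_partner, new_contact) {
  old_sub <- assembly$states[[old_contact]]$engaged_set
  new_sub <- assembly$states[[new_contact]]$engaged_set
  out <- rep(-1L, 2L * length(new_sub))
  m <- match(new_sub, old_sub)
  for (i in seq_along(new_sub)) {
    if (!is.na(m[i])) {
      out[2L * i - 1L] <- old_partner[2L * m[i] - 1L]
      out[2L * i] <- old_partner[2L * m[i]]
    }
  }
  out
}

# retained wells stay mature; freshly engaged wells ramp up from zero age
map_ages <- function(assembly, old_contact, old_age, new_contact) {
  old_sub <- assembly$states[[old_contact]]$engaged_set
  new_sub <- assembly$states[[new_contact]]$engaged_set
  out <- rep(0, 2L * length(new_sub))
  m <- match(new_sub, old_sub)
  for (i in seq_along(new_sub)) {
    if (!is.na(m[i])) {
      out[2L * i - 1L] <- old_age[2L * m[i] - 1L]
      out[2L * i] <- old_age[2L * m[i]]
    }
  }
  out
}

#' Advance an assembly by Langevin dynamics
#'
#' One or more BAOAB updates under the given active potentials;
#' deterministic for a given seed.
#'
#' @param assembly a `cg_assembly` (its `$coords`/`$vels` are the state).
#' @param active an `active_potentials`; defaults to State 1.
#' @param n_steps number of steps.
#' @param seed integer seed for the thermal noise.
#' @param subsample number of frames to retain.
#' @return the assembly with updated coordinates and velocities; the
#'   retained frames are in `attr(, "segment")`.
#' @export
langevin_step <- function(assembly, active = NULL, n_steps = 1, seed = 1,
                          subsample = 1) {
  if (is.null(active))
    active <- make_active_potentials(assembly,
                                     if (is.null(assembly$states)) NULL else 1L)
  p <- assembly$params
  stopifnot(p$dt > 0, p$friction > 0, p$temperature >= 0)
  out <- .cg_run_segment_cpp(assembly$coords, assembly$vels, active$topo,
                             active$state_terms,
                             run_opts(p, n_steps, seed, subsample,
                                      attr(assembly, "well_partner") %||%
                                        integer(0)))
  assembly$coords <- out$coords
  assembly$vels <- out$vels
  attr(assembly, "well_partner") <- out$well_partner
  attr(assembly, "segment") <- out
  assembly
}

#' Relax an assembly
#'
#' Steepest-descent energy minimisation followed by a short thermal
#' equilibration, as applied to every freshly built scenario before a
#' switching run. The final potential energy never exceeds the initial one
#' after minimisation.
#'
#' @param assembly a `cg_assembly`.
#' @param n_steps thermal equilibration steps (default from `ff_params`).
#' @param seed integer seed.
#' @return the relaxed assembly; `attr(, "relax")` records the energy
#'   before/after minimisation and the equilibration energy series.
#' @export
relax <- function(assembly, n_steps = NULL, seed = 1) {
  p <- assembly$params
  if (is.null(n_steps)) n_steps <- p$relax_steps
  active <- make_active_potentials(assembly,
                                   if (is.null(assembly$states)) NULL else 1L)
  e0 <- eval_energy(assembly$coords, active)$total
  mn <- .cg_minimize_cpp(assembly$coords, active$topo, active$state_terms,
                         as.integer(p$relax_minimize_iter), 0.02, 1e-4)
  if (!is.finite(mn$energy) || mn$energy > e0 + 1e-6)
    stop("relaxation diverged")
  assembly$coords <- mn$coords
  if (n_steps > 0) {
    assembly <- langevin_step(assembly, active, n_steps,
                              seed = seg_seed(seed, 0L),
                              subsample = min(50, n_steps))
    seg <- attr(assembly, "segment")
    attr(assembly, "relax") <- list(e_initial = e0, e_minimized = mn$energy,
                                    e_series = seg$frame_energy,
                                    dt_reductions = seg$dt_reductions)
    attr(assembly, "segment") <- NULL
  } else {
    attr(assembly, "relax") <- list(e_initial = e0, e_minimized = mn$energy,
                                    e_series = numeric(0), dt_reductions = 0)
  }
  assembly
}

#' Switch the active potentials to another motor state
#'
#' Coordinates and velocities are untouched at the switch instant; only the
#' potential set changes. In `"full"` mode both the contact wells and the
#' loop conformation targets move to the next state; in
#' `"conformation_only"` mode the wells are retained; `"frozen"` returns
#' the input unchanged.
#'
#' @param assembly a `cg_assembly`.
#' @param active the current `active_potentials`.
#' @param next_state target state id (1-4).
#' @param mode switching mode.
#' @return a new `active_potentials`.
#' @export
apply_switch <- function(assembly, active, next_state,
                         mode = c("full", "conformation_only", "frozen")) {
  mode <- match.arg(mode)
  if (!next_state %in% 1:4) stop("unknown state id")
  switch(mode,
    full = make_active_potentials(assembly, next_state,
                                  topo = active$topo),
    conformation_only = make_active_potentials(assembly, next_state,
                                               active$contact_state_id,
                                               topo = active$topo),
    frozen = active)
}

#' Run a state-switching protocol
#'
#' Alternates Langevin segments of `interval` steps with potential switches
#' following the protocol sequence, recording subsampled frames and switch
#' events. The run starts in the first state of the sequence and, for
#' multi-state sequences, closes with a segment back in that state so the
#' final transition of the cycle is sampled.
#'
#' @param assembly a relaxed `cg_assembly`.
#' @param protocol a [switch_protocol()].
#' @param seed integer seed.
#' @param subsample frames retained per segment.
#' @return a `cg_trajectory`: frame array, per-frame step/state, switch
#'   events, and the generating assembly.
#' @export
run_protocol <- function(assembly, protocol, seed = 1, subsample = NULL) {
  p <- assembly$params
  interval <- protocol$interval %||% p$switch_interval
  if (is.null(subsample)) subsample <- p$frames_per_segment
  segs <- rep(protocol$sequence, protocol$n_cycles)
  if (length(protocol$sequence) > 1) segs <- c(segs, protocol$sequence[1])
  if (protocol$mode == "frozen") segs <- rep(segs[1], length(segs))
  active <- make_active_potentials(assembly, segs[1])
  partners <- rep(-1L, length(active$state_terms$well_loop))
  ages <- rep(1e12, length(partners))   # assembly-state contacts are mature
  refract <- rep(0, length(partners))
  frames <- vector("list", length(segs))
  fpart <- vector("list", length(segs))
  fstep <- fstate <- fseg <- vector("list", length(segs))
  events <- NULL
  step0 <- 0L
  dtred <- 0L
  for (k in seq_along(segs)) {
    if (k > 1) {
      events <- rbind(events,
                      data.frame(step = step0, from_state = segs[k - 1],
                                 to_state = segs[k]))
      old_contact <- active$contact_state_id
      active <- apply_switch(assembly, active, segs[k], protocol$mode)
      partners <- map_partners(assembly, old_contact, partners,
                               active$contact_state_id)
      ages <- map_ages(assembly, old_contact, ages,
                       active$contact_state_id)
      refract <- map_ages(assembly, old_contact, refract,
                          active$contact_state_id)
    }
    out <- .cg_run_segment_cpp(assembly$coords, assembly$vels, active$topo,
                               active$state_terms,
                               run_opts(p, interval, seg_seed(seed, k),
                                        subsample, partners, ages, refract))
    partners <- out$well_partner
    ages <- out$well_age
    refract <- out$well_refract
    assembly$coords <- out$coords
    assembly$vels <- out$vels
    frames[[k]] <- out$frames
    fpart[[k]] <- out$frame_partner
    fstep[[k]] <- step0 + out$frame_step
    fstate[[k]] <- rep(segs[k], length(out$frame_step))
    fseg[[k]] <- rep(k, length(out$frame_step))
    dtred <- dtred + out$dt_reductions
    step0 <- step0 + as.integer(interval)
  }
  n <- nrow(assembly$coords)
  nf <- sum(vapply(fstep, length, integer(1)))
  arr <- array(unlist(frames), dim = c(3, n, nf))
  structure(list(
    frames = arr,
    frame_step = unlist(fstep),
    frame_state = unlist(fstate),
    frame_segment = unlist(fseg),
    switch_events = events,
    frame_partner = fpart,
    segments = segs,
    protocol = protocol,
    interval = interval,
    seed = seed,
    dt_reductions = dtred,
    assembly = assembly
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", dim(x$frames)[3], "frames,",
      length(x$segments), "segments, protocol [",
      paste(x$protocol$sequence, collapse = ","), "] mode",
      x$protocol$mode, "\n")
  invisible(x)
}
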