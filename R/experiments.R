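# Named, seeded experiment registry reproducing each computational
# experiment at toy scale, with replicate aggregation and condition
# comparisons.

#' Summarise one trajectory
#'
#' Computes every metric applicable to the scenario: step table, net
#' displacement and outcome, anchor identities, unwound base pairs and
#' reannealing events (fork), clogging statistics (fork), unwrapping
#' extent and lagging-strand capture (nucleosome).
#'
#' @param traj a `cg_trajectory`.
#' @return a `run_summary` list.
#' @export
summarize_run <- function(traj) {
  st <- per_transition_steps(traj)
  out <- list(
    steps = as.data.frame(st),
    net_displacement = attr(st, "net_displacement"),
    outcome = attr(st, "outcome"),
    seed = traj$seed)
  asm <- traj$assembly
  if (!is.null(asm$dna$fork_junction_index) &&
      !is.na(asm$dna$fork_junction_index)) {
    uw <- count_unwound_bp(traj)
    cl <- clogging_stats(traj)
    # tail mean suppresses breathing flicker, as for the step sizes
    nt <- max(1, ceiling(0.1 * length(uw$series)))
    out$unwound_final <- mean(tail(uw$series, nt))
    out$reannealing_events <- uw$reannealing_events
    out$clogged_fraction <- cl$clogged_fraction
    out$min_pore_dist <- min(cl$min_dist)
  }
  if (!is.null(asm$nucleosome)) {
    ue <- unwrap_extent(traj)
    lc <- lagging_capture(traj)
    nt <- max(1, ceiling(0.1 * length(ue)))
    out$unwrap_final <- mean(tail(ue, nt))
    out$unwrap_max <- max(ue)
    out$lagging_capture <- lc$captured
  }
  structure(out, class = "run_summary")
}

toy_protocols <- function(interval) list(
  p3 = switch_protocol(c(1, 2, 3), interval),
  p4 = switch_protocol(c(1, 2, 3, 4), interval),
  rev = switch_protocol(c(1, 3, 2), interval),
  conf = switch_protocol(c(1, 2, 3), interval, mode = "conformation_only"))

two_state_pairs <- function() {
  cmb <- combn(4, 2)
  lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
}

#' The experiment registry
#'
#' Named, seeded specifications for every computational experiment at toy
#' scale: ssDNA switching schemes (3-state, 4-state, reversed,
#' conformation-only control, all six two-state schemes), Y-fork unwinding
#' across sequence composition and accessory-factor conditions, the
#' lagging-duplex occlusion variant, and nucleosome collisions from
#' SHL(-7)/(-5)/(-4)/(-3) with and without FACT.
#'
#' @param scale `"toy"` (default) or `"full"` (paper-scale geometry; very
#'   slow, excluded from routine testing).
#' @param interval switching interval override (steps).
#' @return named list of `experiment_spec` objects.
#' @export
experiment_registry <- function(scale = c("toy", "full"), interval = NULL) {
  scale <- match.arg(scale)
  params <- ff_params()
  if (is.null(interval)) interval <- params$switch_interval
  full <- scale == "full"
  ss_args <- if (full) list(n_nt = 495, ring_position_nt = 157)
             else list(n_nt = 60, ring_position_nt = 30)
  fork_args <- function(mode, ...) {
    base <- if (full)
      list(parental_bp = 168, lagging_bp = 113, leading_bp = 285,
           lagging_ss_nt = 29, leading_ss_nt = 42, sequence_mode = mode)
    else
      list(parental_bp = 16, lagging_bp = 8, leading_bp = 8,
           lagging_ss_nt = 12, leading_ss_nt = 18, sequence_mode = mode)
    modifyList(base, list(...))
  }
  rpa_fp <- if (full) 25 else 10
  pr <- toy_protocols(interval)
  specs <- list()
  k <- 0L
  add <- function(name, builder, builder_args, protocol,
                  factors = factor_set()) {
    k <<- k + 1L
    specs[[name]] <<- structure(list(
      name = name, builder = builder, builder_args = builder_args,
      protocol = protocol, factors = factors,
      n_replicates = 20L, seed0 = 1000L * k, scale = scale),
      class = "experiment_spec")
  }
  add("ss_3state", "build_ssdna_scenario", ss_args, pr$p3)
  add("ss_4state", "build_ssdna_scenario", ss_args, pr$p4)
  add("ss_reversed", "build_ssdna_scenario", ss_args, pr$rev)
  add("ss_control_conformation_only", "build_ssdna_scenario", ss_args,
      pr$conf)
  for (tp in two_state_pairs())
    add(paste0("ss_two_state_", tp[1], tp[2]), "build_ssdna_scenario",
        ss_args, switch_protocol(tp, interval))
  for (m in c("random", "polyAT", "polyGC"))
    add(paste0("fork_", sub("poly", "poly", m)), "build_fork_scenario",
        fork_args(m), pr$p4)
  for (m in c("polyAT", "polyGC")) {
    add(paste0("fork_", m, "_rpa"), "build_fork_scenario", fork_args(m),
        pr$p4, factor_set(rpa = TRUE, rpa_footprint = rpa_fp))
    add(paste0("fork_", m, "_fpc_ctf4"), "build_fork_scenario",
        fork_args(m), pr$p4,
        factor_set(fpc = TRUE, ctf4 = TRUE, mrc1 = TRUE))
    add(paste0("fork_", m, "_rpa_fpc_ctf4"), "build_fork_scenario",
        fork_args(m), pr$p4,
        factor_set(rpa = TRUE, fpc = TRUE, ctf4 = TRUE, mrc1 = TRUE,
                   rpa_footprint = rpa_fp))
  }
  add("fork_polyGC_rpa_fpc_ctf4_noelec", "build_fork_scenario",
      fork_args("polyGC"), pr$p4,
      factor_set(rpa = TRUE, fpc = TRUE, ctf4 = TRUE, mrc1 = TRUE,
                 rpa_footprint = rpa_fp, fpc_electrostatics_on = FALSE))
  add("fork_polyGC_lagging_duplex", "build_fork_scenario",
      fork_args("polyGC", lagging_mode = "duplex-occluded"), pr$p4)
  for (shl in c(7, 5, 4, 3)) {
    add(paste0("nuc_shl", shl, "_fpc_rpa"), "build_nucleosome_scenario",
        list(shl_start = -shl), pr$p4,
        factor_set(rpa = TRUE, fpc = TRUE, ctf4 = TRUE, mrc1 = TRUE,
                   rpa_footprint = rpa_fp))
    add(paste0("nuc_shl", shl, "_fact"), "build_nucleosome_scenario",
        list(shl_start = -shl), pr$p4,
        factor_set(rpa = TRUE, fpc = TRUE, ctf4 = TRUE, mrc1 = TRUE,
                   fact = TRUE, rpa_footprint = rpa_fp))
  }
  add("nuc_shl7_noelec", "build_nucleosome_scenario",
      list(shl_start = -7), pr$p4,
      factor_set(rpa = TRUE, fpc = TRUE, ctf4 = TRUE, mrc1 = TRUE,
                 rpa_footprint = rpa_fp, fpc_electrostatics_on = FALSE))
  # convenience handle for the two-state scan as a whole
  specs[["ss_two_state_scan"]] <- structure(list(
    name = "ss_two_state_scan",
    members = paste0("ss_two_state_",
                     vapply(two_state_pairs(), function(p)
                       paste0(p[1], p[2]), character(1))),
    pairs = two_state_pairs()), class = "experiment_scan")
  specs
}

run_one_replicate <- function(spec, seed, keep_trajectory = FALSE) {
  args <- c(spec$builder_args, list(seed = seed))
  if (identical(spec$builder, "build_nucleosome_scenario")) {
    args$factors <- spec$factors
    asm <- do.call(spec$builder, args)
  } else {
    asm <- do.call(spec$builder, args)
    asm <- place_factors(asm, spec$factors)
  }
  asm <- relax(asm, seed = seed)
  traj <- run_protocol(asm, spec$protocol, seed = seed)
  s <- summarize_run(traj)
  if (keep_trajectory) s$trajectory <- traj
  s
}

#' Run a registry experiment
#'
#' Replicate i uses `seed0 + i - 1`. Failures of individual replicates are
#' recorded and do not abort the experiment; the result is flagged
#' incomplete in that case.
#'
#' @param spec an `experiment_spec` from [experiment_registry()].
#' @param n_replicates override of the replicate count.
#' @param seed0 override of the base seed.
#' @param keep_trajectories retain full trajectories (memory-heavy).
#' @return an `experiment_result`: `$runs` (list of `run_summary`),
#'   `$aggregate` (one-row data frame), `$failures`.
#' @export
run_experiment <- function(spec, n_replicates = NULL, seed0 = NULL,
                           keep_trajectories = FALSE) {
  if (inherits(spec, "experiment_scan")) {
    reg <- experiment_registry()
    res <- lapply(spec$members, function(m)
      run_experiment(reg[[m]], n_replicates, seed0, keep_trajectories))
    names(res) <- spec$members
    return(structure(list(name = spec$name, members = res),
                     class = "experiment_scan_result"))
  }
  n <- n_replicates %||% spec$n_replicates
  s0 <- seed0 %||% spec$seed0
  runs <- vector("list", n)
  failures <- list()
  for (i in seq_len(n)) {
    r <- tryCatch(run_one_replicate(spec, s0 + i - 1L, keep_trajectories),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failures[[length(failures) + 1L]] <-
        list(replicate = i, message = conditionMessage(r))
      runs[i] <- list(NULL)
    } else runs[[i]] <- r
  }
  ok <- !vapply(runs, is.null, logical(1))
  structure(list(
    name = spec$name, spec = spec, runs = runs[ok],
    failures = failures, incomplete = length(failures) > 0,
    seeds = s0 + seq_len(n) - 1L,
    aggregate = aggregate_runs(runs[ok])
  ), class = "experiment_result")
}

aggregate_runs <- function(runs) {
  if (length(runs) == 0) return(NULL)
  net <- vapply(runs, function(r) r$net_displacement, numeric(1))
  outc <- vapply(runs, function(r) r$outcome, character(1))
  agg <- data.frame(
    n = length(runs),
    net_mean = mean(net), net_sd = sd(net),
    n_forward = sum(outc == "forward"),
    n_idling = sum(outc == "idling"),
    n_backward = sum(outc == "backward"))
  steps <- do.call(rbind, lapply(runs, function(r) r$steps))
  if (!is.null(steps) && nrow(steps)) {
    key <- paste0(steps$from_state, "->", steps$to_state)
    sm <- tapply(steps$step_size, key, mean)
    for (nm in names(sm)) agg[[paste0("step_", nm)]] <- unname(sm[nm])
  }
  for (fld in c("unwound_final", "clogged_fraction", "unwrap_final")) {
    v <- vapply(runs, function(r) r[[fld]] %||% NA_real_, numeric(1))
    if (!all(is.na(v))) agg[[paste0(fld, "_mean")]] <- mean(v, na.rm = TRUE)
  }
  cap <- vapply(runs, function(r) isTRUE(r$lagging_capture), logical(1))
  if (any(vapply(runs, function(r) !is.null(r$lagging_capture), logical(1))))
    agg$n_lagging_capture <- sum(cap)
  agg
}

#' Per-replicate values of a metric
#' @param result an `experiment_result`.
#' @param metric_key field of the run summaries (e.g.
#'   `"net_displacement"`, `"unwound_final"`, `"clogged_fraction"`).
#' @return numeric vector.
#' @export
replicate_values <- function(result, metric_key = "net_displacement") {
  v <- vapply(result$runs, function(r) {
    x <- r[[metric_key]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }, numeric(1))
  if (all(is.na(v))) stop("metric '", metric_key, "' undefined for ",
                          result$name)
  v
}

#' Compare two experiments on a metric
#'
#' One-tailed Wilcoxon-Mann-Whitney (alternative: `result_a` greater) with
#' Cohen's d, on per-replicate values.
#'
#' @param result_a,result_b `experiment_result` objects.
#' @param metric_key run-summary field to compare.
#' @return list with the test output plus the direction of the observed
#'   mean difference.
#' @export
compare_experiments <- function(result_a, result_b,
                                metric_key = "net_displacement") {
  va <- replicate_values(result_a, metric_key)
  vb <- replicate_values(result_b, metric_key)
  if (length(va) != length(vb))
    warning("unequal replicate counts: ", length(va), " vs ", length(vb))
  cmp <- compare_conditions(va, vb)
  cmp$direction <- if (mean(va) > mean(vb)) "a > b"
                   else if (mean(va) < mean(vb)) "a < b" else "equal"
  cmp$metric <- metric_key
  cmp$experiments <- c(result_a$name, result_b$name)
  cmp
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", x$name, "(", length(x$runs), "replicates",
      if (x$incomplete) ", INCOMPLETE" else "", ")\n")
  print(x$aggregate)
  invisible(x)
}
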