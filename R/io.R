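# Configuration (plain-text YAML-compatible key-value), trajectory and
# table serialization, density grid writers, and run manifests.

config_defaults <- function() {
  list(
    params = unclass(ff_params()),
    scenario = list(
      kind = "ssdna", n_nt = 60, ring_position_nt = 30,
      sequence_mode = "random",
      parental_bp = 16, lagging_bp = 8, leading_bp = 8,
      lagging_ss_nt = 12, leading_ss_nt = 18,
      lagging_mode = "ssDNA", shl_start = -7),
    protocol = list(sequence = c(1, 2, 3, 4), interval = 12000,
                    mode = "full", n_cycles = 1),
    factors = list(rpa = FALSE, fpc = FALSE, ctf4 = FALSE, mrc1 = FALSE,
                   fact = FALSE, fpc_electrostatics_on = TRUE,
                   rpa_footprint = 25),
    experiment = list(name = "", n_replicates = 20, seed0 = 1000),
    output = list(outdir = "ringmotor_out", subsample = 120,
                  write_pdb = FALSE, log_level = "info")
  )
}

validate_against <- function(x, ref, path = "") {
  errs <- character(0)
  for (nm in names(x)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(ref)) {
      errs <- c(errs, paste0("unknown key '", here, "'"))
    } else if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (is.list(x[[nm]]))
        errs <- c(errs, validate_against(x[[nm]], ref[[nm]], here))
      else errs <- c(errs, paste0("key '", here, "' must be a section"))
    }
  }
  errs
}

#' Load a configuration file
#'
#' Plain-text YAML key-value document with sections `params`, `scenario`,
#' `protocol`, `factors`, `experiment`, `output`. Missing keys take the
#' documented defaults; unknown keys are rejected with an exhaustive list.
#' An empty file yields the full default configuration.
#'
#' @param path file path.
#' @return a `ringmotor_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  errs <- validate_against(raw, defs)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  cfg <- modifyList(defs, raw)
  structure(cfg, class = "ringmotor_config")
}

#' Write a configuration file
#' @param config a `ringmotor_config` (or plain list with the same shape).
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Normalise a configuration (defaults filled in)
#' @param config partial configuration list.
#' @return complete `ringmotor_config`.
#' @export
normalize_config <- function(config = list()) {
  structure(modifyList(config_defaults(), unclass(config)),
            class = "ringmotor_config")
}

#' Short content hash of a configuration (FNV-1a over its YAML text)
#' @param config a configuration list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

ATOM_NAME <- c(protein = "CA", phosphate = "P", sugar = "C4", base = "N1")

chain_letters <- function(chains) {
  u <- unique(chains)
  lets <- c(LETTERS, letters, 0:9)
  setNames(lets[(seq_along(u) - 1) %% length(lets) + 1], u)
}

write_pdb_model <- function(con, beads, xyz, model, chmap) {
  cat(sprintf("MODEL     %4d\n", model), file = con)
  recs <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    beads$bead_id %% 100000,
    ATOM_NAME[beads$kind],
    substr(beads$chain_id, 1, 3),
    chmap[beads$chain_id],
    beads$residue_index %% 10000,
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(recs, con)
  cat("ENDMDL\n", file = con)
}

#' Write an assembly as a PDB file
#'
#' One bead per ATOM record (atom names encode bead kind: CA protein, P
#' phosphate, C4 sugar, N1 base), one chain letter per molecule chain.
#' Coordinates are in reduced length units.
#'
#' @param assembly a `cg_assembly`.
#' @param path output file.
#' @export
write_assembly_pdb <- function(assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  chmap <- chain_letters(assembly$beads$chain_id)
  write_pdb_model(con, assembly$beads, assembly$coords, 1L, chmap)
  cat("END\n", file = con)
  invisible(path)
}

#' Write a trajectory
#'
#' `pdb_models`: multi-model PDB, one MODEL per frame. `csv_coords`: CSV
#' with columns (frame, bead_id, x, y, z) at full precision, bit-exact on
#' re-reading. A JSON sidecar (`<path>.events.json`) carries the switch
#' events, seed and per-frame state ids; a `<path>.summary.csv` carries the
#' per-frame step index, state and tracked displacement.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file path.
#' @param format `"pdb_models"` or `"csv_coords"`.
#' @return invisibly, the main file path.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb_models", "csv_coords")) {
  format <- match.arg(format)
  nf <- dim(traj$frames)[3]
  if (nf == 0) stop("empty trajectory")
  beads <- traj$assembly$beads
  if (format == "pdb_models") {
    con <- file(path, "w")
    chmap <- chain_letters(beads$chain_id)
    for (f in seq_len(nf))
      write_pdb_model(con, beads, t(traj$frames[, , f]), f, chmap)
    cat("END\n", file = con)
    close(con)
  } else {
    n <- nrow(beads)
    df <- data.frame(
      frame = rep(seq_len(nf), each = n),
      bead_id = rep(beads$bead_id, nf),
      x = sprintf("%.17g", as.vector(traj$frames[1, , ])),
      y = sprintf("%.17g", as.vector(traj$frames[2, , ])),
      z = sprintf("%.17g", as.vector(traj$frames[3, , ])))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  disp <- tracked_displacement(traj)
  write.csv(data.frame(frame = seq_len(nf), step = traj$frame_step,
                       state_id = traj$frame_state,
                       segment = traj$frame_segment,
                       displacement_nt = as.integer(disp)),
            paste0(path, ".summary.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = traj$seed, interval = traj$interval,
         mode = traj$protocol$mode,
         sequence = traj$protocol$sequence,
         switch_events = traj$switch_events),
    paste0(path, ".events.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trajectory coordinates written by [write_trajectory()]
#' @param path the csv_coords file.
#' @return 3 x n x frames array (bit-exact round trip).
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, colClasses = c("integer", "integer", "character",
                                      "character", "character"))
  nf <- max(df$frame)
  n <- nrow(df) / nf
  arr <- array(0, dim = c(3, n, nf))
  arr[1, , ] <- as.numeric(df$x)
  arr[2, , ] <- as.numeric(df$y)
  arr[3, , ] <- as.numeric(df$z)
  arr
}

#' Export the assembly topology as a plain-text table file
#'
#' Sections (bead table, bonds, angles, base pairs, site wells) in TSV with
#' documented headers, separated by `## section` markers.
#'
#' @param assembly a `cg_assembly`.
#' @param path output file.
#' @export
export_topology <- function(assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sect <- function(name, df) {
    cat("## ", name, "\n", sep = "", file = con)
    if (!is.null(df) && nrow(df))
      suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                                   quote = FALSE))
  }
  beads <- assembly$beads
  beads$x <- assembly$coords[, 1]
  beads$y <- assembly$coords[, 2]
  beads$z <- assembly$coords[, 3]
  beads$molecule <- assembly$molecule
  sect("beads", beads)
  sect("bonds", assembly$bonds)
  sect("angles", assembly$angles)
  sect("basepairs", assembly$pairs)
  sect("sites", assembly$sites)
  invisible(path)
}

#' Write an occupancy density grid
#'
#' `voxels`: simple text format (header + one `i j k density` row per
#' occupied voxel). `dx`: OpenDX-compatible scalar field for visualisation.
#'
#' @param density output of [occupancy_density()].
#' @param path output file.
#' @param format `"voxels"` or `"dx"`.
#' @export
write_density <- function(density, path, format = c("voxels", "dx")) {
  format <- match.arg(format)
  d <- density$density
  dm <- dim(d)
  if (format == "voxels") {
    con <- file(path, "w")
    on.exit(close(con))
    cat("# origin", density$origin, "\n# spacing", density$spacing,
        "\n# dim", dm, "\n", file = con)
    occ <- which(d > 0, arr.ind = TRUE)
    writeLines(sprintf("%d %d %d %.8g", occ[, 1], occ[, 2], occ[, 3],
                       d[occ]), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    cat(sprintf("object 1 class gridpositions counts %d %d %d\n",
                dm[1], dm[2], dm[3]), file = con)
    cat(sprintf("origin %g %g %g\n", density$origin[1], density$origin[2],
                density$origin[3]), file = con)
    cat(sprintf("delta %g 0 0\ndelta 0 %g 0\ndelta 0 0 %g\n",
                density$spacing, density$spacing, density$spacing),
        file = con)
    cat(sprintf("object 2 class gridconnections counts %d %d %d\n",
                dm[1], dm[2], dm[3]), file = con)
    cat(sprintf(
      "object 3 class array type double rank 0 items %d data follows\n",
      prod(dm)), file = con)
    vals <- as.vector(aperm(d, c(3, 2, 1)))
    for (i in seq(1, length(vals), 3))
      cat(paste(sprintf("%.8g", vals[i:min(i + 2, length(vals))]),
                collapse = " "), "\n", file = con)
    cat("attribute \"dep\" string \"positions\"\n", file = con)
  }
  invisible(path)
}

#' Write an experiment manifest
#'
#' JSON with the experiment name, seeds, configuration hash and package
#' version; re-running with the same manifest reproduces results bitwise.
#'
#' @param result an `experiment_result`.
#' @param config the configuration used.
#' @param path output file.
#' @export
write_manifest <- function(result, config, path) {
  jsonlite::write_json(list(
    experiment = result$name,
    seeds = result$seeds,
    incomplete = result$incomplete,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("ringmotor"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
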