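#' Run configuration
#'
#' Everything needed to reproduce a run: the system composition, the
#' integrator settings, the analysis cutoffs, the replicate count and seed
#' policy (one master seed, per-replicate streams \code{seed + 1000 *
#' replicate}), and a scale preset.  The \code{"desk"} preset defaults are
#' small systems (a few short RNA chains at elevated concentration, at
#' least \eqn{10^5} production steps); \code{"production"} encodes the
#' full-scale grid (8 chains of 100 nucleotides in a \eqn{(200\sigma)^3}
#' box, \eqn{2\times 10^8} steps) for cluster use.
#'
#' @param n_rna,l_rna,n_pei,l_pei,box_edge composition, see
#'   \code{\link{system_spec}}.
#' @param dt,thermostat_tau integrator settings.
#' @param equil_steps,production_steps,trajectory_stride run lengths.
#' @param np_cutoff clustering/attachment cutoff, \eqn{\sigma}.
#' @param coulomb_realspace_cutoff,coulomb_accuracy Ewald settings.
#' @param replicates number of replicate runs.
#' @param seed master seed.
#' @param out_dir output directory.
#' @param scale \code{"desk"} or \code{"production"} preset label.
#' @return an object of class \code{run_config} (a named list).
#' @export
run_config <- function(n_rna = 2, l_rna = 30, n_pei = 6, l_pei = 10,
                       box_edge = 40, dt = 0.005, thermostat_tau = 0.5,
                       equil_steps = 20000L, production_steps = 100000L,
                       trajectory_stride = 500L, np_cutoff = 3.5,
                       coulomb_realspace_cutoff = 10,
                       coulomb_accuracy = 5e-4,
                       replicates = 1L, seed = 1L, out_dir = "run",
                       scale = c("desk", "production")) {
  scale <- match.arg(scale)
  cfg <- list(n_rna = n_rna, l_rna = l_rna, n_pei = n_pei, l_pei = l_pei,
              box_edge = box_edge, dt = dt, thermostat_tau = thermostat_tau,
              equil_steps = as.integer(equil_steps),
              production_steps = as.integer(production_steps),
              trajectory_stride = as.integer(trajectory_stride),
              np_cutoff = np_cutoff,
              coulomb_realspace_cutoff = coulomb_realspace_cutoff,
              coulomb_accuracy = coulomb_accuracy,
              replicates = as.integer(replicates), seed = as.integer(seed),
              out_dir = out_dir, scale = scale)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / parse a run configuration (YAML)
#'
#' Round-trip safe: \code{parse_config(serialize_config(cfg))} recovers
#' the configuration exactly.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param path file path; for \code{serialize_config}, where to write.
#' @return \code{serialize_config} returns \code{path} invisibly;
#'   \code{parse_config} returns a \code{run_config}.
#' @export
serialize_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname serialize_config
#' @export
parse_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Write / read an extended-XYZ frame
#'
#' Plain-text frame format: a count line, a comment line carrying the box
#' edge, step, dt and stride, then one line per bead with species, x, y,
#' z, charge and chain id columns.
#'
#' @param state a \code{\link{system_state}}.
#' @param path file path.
#' @param dt,stride metadata written into the comment line.
#' @return \code{write_xyz} returns \code{path} invisibly;
#'   \code{read_xyz} returns a \code{system_state} (velocities zero,
#'   bonds reconstructed from consecutive beads sharing a chain id).
#' @export
write_xyz <- function(state, path, dt = NA, stride = NA) {
  n <- nrow(state$positions)
  hdr <- sprintf(
    'Lattice="%g 0 0 0 %g 0 0 0 %g" step=%d dt=%g stride=%g Properties=species:S:1:pos:R:3:charge:R:1:chain:I:1',
    state$box_edge, state$box_edge, state$box_edge, state$step, dt, stride)
  lines <- sprintf("%s %.10g %.10g %.10g %g %d", state$species,
                   state$positions[, 1], state$positions[, 2],
                   state$positions[, 3], state$charge, state$chain_id)
  writeLines(c(as.character(n), hdr, lines), path)
  invisible(path)
}

#' @rdname write_xyz
#' @param traj a \code{cg_trajectory}; all frames are appended to one file.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$positions)[1]
  for (i in seq_len(n_frames(traj))) {
    hdr <- sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" step=%d dt=%g stride=%g Properties=species:S:1:pos:R:3:charge:R:1:chain:I:1',
      traj$box_edge, traj$box_edge, traj$box_edge, traj$steps[i],
      traj$dt, traj$stride)
    p <- traj$positions[, , i]
    writeLines(c(as.character(n), hdr,
                 sprintf("%s %.10g %.10g %.10g %g %d", traj$species,
                         p[, 1], p[, 2], p[, 3], traj$charge,
                         traj$chain_id)), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  hdr <- lines[2]
  L <- as.numeric(sub('.*Lattice="([0-9.eE+-]+) .*', "\\1", hdr))
  step <- as.integer(sub(".*step=([0-9]+).*", "\\1", hdr))
  parts <- strsplit(lines[3:(2 + n)], " +")
  species <- vapply(parts, `[`, character(1), 1)
  num <- t(vapply(parts, function(p) as.numeric(p[2:6]), numeric(5)))
  chain_id <- as.integer(num[, 5])
  bonds <- which(chain_id[-n] == chain_id[-1] & chain_id[-n] > 0)
  bonds <- cbind(bonds, bonds + 1L)
  system_state(num[, 1:3], NULL, num[, 4], species, chain_id, bonds, L,
               step = step)
}

#' Run the full pipeline for one configuration
#'
#' Stages: build (random insertion), equilibrate (soft-core relaxation,
#' minimisation, thermostatted equilibration), produce (production MD),
#' analyze (per-frame NP detection and observables), summarize (order
#' parameter and condition summary).  Every stage writes its outputs under
#' \code{cfg$out_dir} and is skipped on re-run if they already exist
#' (idempotent, resumable); a manifest logs seeds and any cutoff
#' reductions.  Identical config + seeds give identical tables.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param units a \code{\link{reduced_units}}.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the per-NP metrics table, the order
#'   parameter series and the summary table; all also on disk.
#' @export
run_pipeline <- function(cfg, units = reduced_units(), verbose = TRUE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(cfg$out_dir, 2) != 0)
    stop("run_pipeline: output directory is not writable: ", cfg$out_dir)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  params <- forcefield_params(
    coulomb_realspace_cutoff = cfg$coulomb_realspace_cutoff,
    coulomb_accuracy = cfg$coulomb_accuracy)
  rc_eff <- resolve_cutoff(params, cfg$box_edge)
  manifest <- file.path(cfg$out_dir, "manifest.txt")
  cat(sprintf("polyplexmd pipeline\nmaster_seed: %d\nreplicates: %d\n",
              cfg$seed, cfg$replicates),
      sprintf("realspace_cutoff: requested %g, effective %g\n",
              cfg$coulomb_realspace_cutoff, rc_eff),
      file = manifest)
  serialize_config(cfg, file.path(cfg$out_dir, "config.yaml"))

  all_metrics <- list(); all_series <- list()
  for (rep_i in seq_len(cfg$replicates)) {
    rseed <- cfg$seed + 1000L * (rep_i - 1L)
    tag <- sprintf("rep%02d", rep_i)
    eq_file <- file.path(cfg$out_dir, paste0(tag, "_equilibrated.xyz"))
    met_file <- file.path(cfg$out_dir, paste0(tag, "_np_metrics.csv"))
    ser_file <- file.path(cfg$out_dir, paste0(tag, "_n_nps_star.csv"))
    spec <- system_spec(cfg$n_rna, cfg$l_rna, cfg$n_pei, cfg$l_pei,
                        cfg$box_edge, seed = rseed)
    ip <- integrator_params(dt = cfg$dt, thermostat_tau = cfg$thermostat_tau,
                            n_steps = cfg$production_steps,
                            trajectory_stride = cfg$trajectory_stride,
                            seed = rseed)
    if (file.exists(met_file) && file.exists(ser_file)) {
      say(tag, ": analysis present, skipping")
      all_metrics[[rep_i]] <- utils::read.csv(met_file)
      all_series[[rep_i]] <- utils::read.csv(ser_file)
      next
    }
    if (file.exists(eq_file)) {
      say(tag, ": reusing equilibrated state")
      st <- read_xyz(eq_file)
      set.seed(rseed)
      st$velocities <- draw_velocities(nrow(st$positions))
    } else {
      say(tag, ": build + equilibrate")
      st <- build_random_system(spec)
      st <- relax_and_equilibrate(st, params, units, ip,
                                  equil_steps = cfg$equil_steps)
      write_xyz(st, eq_file, dt = cfg$dt, stride = cfg$trajectory_stride)
    }
    say(tag, ": production (", cfg$production_steps, " steps)")
    traj <- integrate_md(st, ip, params, units)
    write_xyz(traj$final_state,
              file.path(cfg$out_dir, paste0(tag, "_final.xyz")),
              dt = cfg$dt, stride = cfg$trajectory_stride)
    say(tag, ": analysis")
    met <- np_metrics_table(traj, cutoff = cfg$np_cutoff, units = units,
                            replicate = rep_i)
    ser <- n_nps_star_series(met, cfg$n_rna, replicate = rep_i,
                             alpha_np = alpha_np(spec))
    utils::write.csv(met, met_file, row.names = FALSE)
    utils::write.csv(ser, ser_file, row.names = FALSE)
    all_metrics[[rep_i]] <- met
    all_series[[rep_i]] <- ser
  }
  metrics <- do.call(rbind, all_metrics)
  series <- do.call(rbind, all_series)
  spec1 <- system_spec(cfg$n_rna, cfg$l_rna, cfg$n_pei, cfg$l_pei,
                       cfg$box_edge)
  merged <- merge(metrics, series[, c("replicate", "frame", "n_nps_star")],
                  by = c("replicate", "frame"))
  merged$condition <- sprintf("alphaNP=%g", alpha_np(spec1))
  summary_tab <- sweep_summary(merged)
  utils::write.csv(summary_tab, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(list(metrics = metrics, series = series, summary = summary_tab))
}
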