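#' Integrator parameters
#'
#' Canonical-ensemble leapfrog integration with the stochastic
#' velocity-rescaling (v-rescale) thermostat.  The time step default is
#' \eqn{0.005\,\tau}; the thermostat coupling time defaults to
#' \eqn{100\,dt = 0.5\,\tau}, weak enough not to distort diffusive
#' dynamics.  A Langevin thermostat is deliberately not offered: its
#' uncorrelated random forces suppress the diffusion of large aggregates.
#'
#' @param dt time step, \eqn{\tau}.
#' @param thermostat_target temperature in \eqn{\epsilon/k_B}.
#' @param thermostat_tau coupling time, \eqn{\tau}; must exceed \code{dt}.
#' @param n_steps number of integration steps.
#' @param trajectory_stride steps between stored frames.
#' @param seed integer seed (thermostat noise and nothing else).
#' @return an object of class \code{integrator_params}.
#' @export
integrator_params <- function(dt = 0.005, thermostat_target = 1,
                              thermostat_tau = 100 * dt,
                              n_steps = 10000L, trajectory_stride = 100L,
                              seed = 1L) {
  stopifnot(dt > 0, trajectory_stride >= 1, thermostat_tau > dt)
  p <- list(dt = dt, thermostat_target = thermostat_target,
            thermostat_tau = thermostat_tau,
            n_steps = as.integer(n_steps),
            trajectory_stride = as.integer(trajectory_stride),
            seed = as.integer(seed))
  class(p) <- "integrator_params"
  p
}

#' Integrate the equations of motion
#'
#' Leapfrog updates with the v-rescale thermostat (total momentum is
#' preserved: the rescaling is uniform and the initial centre-of-mass
#' momentum is zero by construction).  With \code{thermostat = FALSE} the
#' integrator is symplectic and conserves energy.  Periodic wrapping is
#' maintained; unwrapped displacements are accumulated in a separate
#' coordinate channel for diffusion analysis.
#'
#' @param state a \code{\link{system_state}} with finite energy.
#' @param ip an \code{\link{integrator_params}}.
#' @param params a \code{\link{forcefield_params}}.
#' @param units a \code{\link{reduced_units}}.
#' @param thermostat logical; \code{FALSE} runs NVE.
#' @param force_cap positive value caps per-bead force norms (soft-core
#'   relaxation); \code{NULL} for the untouched force field.
#' @return an object of class \code{cg_trajectory}: frame arrays
#'   (\code{positions}, \code{unwrapped}, each N x 3 x frames), per-frame
#'   \code{pe}/\code{ke}/\code{steps}, metadata (\code{dt},
#'   \code{stride}), \code{final_state}, and the running
#'   \code{max_bond_dev}.
#' @export
integrate_md <- function(state, ip = integrator_params(),
                         params = forcefield_params(),
                         units = reduced_units(), thermostat = TRUE,
                         force_cap = NULL) {
  rc <- resolve_cutoff(params, state$box_edge)
  ew <- ewald_setup(state$box_edge, rc, params$coulomb_accuracy)
  if (any(state$charge != 0) && !is_neutral(state))
    stop("integrate_md: charged system must be neutral")
  set.seed(ip$seed)
  res <- run_md_cpp(state$positions, state$velocities, state$charge,
                    bonds0(state), state$box_edge, units$bjerrum_length,
                    rc, ew$alpha, ew$nmax, params$k_bond,
                    params$equilibrium_bond_length, params$wca_shift,
                    ip$dt, ip$n_steps, ip$trajectory_stride,
                    ip$thermostat_target,
                    if (thermostat) ip$thermostat_tau else -1,
                    if (is.null(force_cap)) -1 else force_cap,
                    0.4, state$step)
  final <- state
  final$positions <- res$final_pos
  final$velocities <- res$final_vel
  final$step <- state$step + ip$n_steps
  traj <- list(positions = res$positions, unwrapped = res$unwrapped,
               pe = res$pe, ke = res$ke, steps = res$steps,
               dt = ip$dt, stride = ip$trajectory_stride,
               species = state$species, charge = state$charge,
               chain_id = state$chain_id, bonds = state$bonds,
               box_edge = state$box_edge, seed = ip$seed,
               final_state = final, max_bond_dev = res$max_bond_dev)
  class(traj) <- "cg_trajectory"
  traj
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", dim(x$positions)[3], "frames of",
      dim(x$positions)[1], "beads; dt =", x$dt, "tau, stride =", x$stride,
      "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{cg_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' Extract one frame as a system_state
#' @param traj a \code{cg_trajectory}.
#' @param i frame index.
#' @return a \code{\link{system_state}}.
#' @export
trajectory_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  system_state(traj$positions[, , i], NULL, traj$charge, traj$species,
               traj$chain_id, traj$bonds, traj$box_edge,
               step = traj$steps[i])
}

#' Instantaneous kinetic temperature per frame
#'
#' \eqn{T = 2K/(N_{df} k_B)} with \eqn{N_{df} = 3N - 3} (centre-of-mass
#' momentum removed).
#'
#' @param traj a \code{cg_trajectory}.
#' @return numeric vector of temperatures, \eqn{\epsilon/k_B}.
#' @export
kinetic_temperature <- function(traj) {
  n <- dim(traj$positions)[1]
  2 * traj$ke / (3 * n - 3)
}

#' Mean-square displacement with multiple time origins
#'
#' Averages \eqn{|r(t+\tau) - r(t)|^2} over all beads matching the species
#' filter and over all usable time origins, from the unwrapped coordinate
#' channel.  At long lag in a thermally agitated system this grows
#' linearly (diffusive regime); for free flight it is quadratic.
#'
#' @param traj a \code{cg_trajectory}.
#' @param species species filter (default RNA beads); \code{NULL} for all.
#' @param lags integer frame lags; default all up to half the trajectory.
#' @return data.frame with lag time \code{tau} (\eqn{\tau} units) and
#'   \code{msd} (\eqn{\sigma^2}).
#' @export
msd <- function(traj, species = "RNA", lags = NULL) {
  sel <- if (is.null(species)) rep(TRUE, length(traj$species))
         else traj$species %in% species
  if (!any(sel)) stop("msd: no beads match the species filter")
  u <- traj$unwrapped[sel, , , drop = FALSE]
  nf <- dim(u)[3]
  if (is.null(lags)) lags <- seq_len(max(1, nf %/% 2))
  if (any(lags >= nf)) stop("msd: lag exceeds trajectory length")
  out <- vapply(lags, function(l) {
    orig <- seq_len(nf - l)
    d <- u[, , orig + l, drop = FALSE] - u[, , orig, drop = FALSE]
    mean(apply(d^2, c(1, 3), sum))
  }, numeric(1))
  data.frame(tau = lags * traj$stride * traj$dt, msd = out)
}

#' Total momentum of a state
#' @param state a \code{\link{system_state}}.
#' @return length-3 momentum vector (mass = 1).
#' @export
total_momentum <- function(state) colSums(state$velocities)
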