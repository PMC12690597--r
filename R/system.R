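#' Bead table and periodic system state
#'
#' A \code{system_state} bundles everything the integrator needs: bead
#' positions and velocities (\eqn{\sigma}, \eqn{\sigma/\tau}), integer
#' charges in e, a species label per bead (\code{"RNA"}, \code{"PEI"},
#' \code{"COUNTERION"}, \code{"COION"}), a chain id (\code{-1} for free
#' ions), the bond list (consecutive beads within a chain), and the cubic
#' periodic box edge.  RNA beads carry \eqn{-e} (one bead per nucleotide),
#' PEI beads \eqn{+e} (one bead per two monomers, i.e. 50\% protonation),
#' counterions \eqn{+e} and co-ions \eqn{-e}; a valid system is neutral.
#'
#' @param positions N x 3 matrix, \eqn{\sigma} units.
#' @param velocities N x 3 matrix, \eqn{\sigma/\tau} units.
#' @param charge integer vector in \{-1, 0, +1\}, units e.
#' @param species character vector of species labels.
#' @param chain_id integer vector; -1 marks free ions.
#' @param bonds M x 2 integer matrix of 1-based bead indices.
#' @param box_edge cubic box edge, \eqn{\sigma} units.
#' @param step integer MD step counter.
#' @param rng_seed integer seed recorded for provenance.
#' @return an object of class \code{system_state}.
#' @export
system_state <- function(positions, velocities = NULL, charge, species,
                         chain_id, bonds, box_edge, step = 0L,
                         rng_seed = NA_integer_) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  stopifnot(ncol(positions) == 3, nrow(velocities) == n,
            length(charge) == n, length(species) == n,
            length(chain_id) == n, box_edge > 0)
  if (length(bonds) == 0) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    same <- chain_id[bonds[, 1]] == chain_id[bonds[, 2]]
    if (!all(same)) stop("bonds must connect beads of the same chain")
    if (any(chain_id[bonds[, 1]] < 0)) stop("free ions cannot be bonded")
  }
  st <- list(positions = wrap_positions(positions, box_edge),
             velocities = velocities,
             charge = as.numeric(charge),
             species = as.character(species),
             chain_id = as.integer(chain_id),
             bonds = bonds,
             box_edge = box_edge,
             step = as.integer(step),
             rng_seed = rng_seed)
  class(st) <- "system_state"
  st
}

#' @export
print.system_state <- function(x, ...) {
  tab <- table(x$species)
  cat("system_state:", nrow(x$positions), "beads in a (", x$box_edge,
      "sigma)^3 box\n")
  cat("  ", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  cat("  net charge:", sum(x$charge), "e;", nrow(x$bonds), "bonds; step",
      x$step, "\n")
  invisible(x)
}

wrap_positions <- function(pos, L) {
  pos - L * floor(pos / L)
}

#' @rdname system_state
#' @param state a \code{system_state}.
#' @export
is_neutral <- function(state) {
  isTRUE(all.equal(sum(state$charge), 0))
}

#' WCA excluded-volume pair energy
#'
#' Purely repulsive truncated Lennard-Jones interaction: for
#' \eqn{r < 2^{1/6}\sigma}, \eqn{4\epsilon[(\sigma/r)^{12} -
#' (\sigma/r)^6]} (plus \eqn{+\epsilon} when shifted so the energy is
#' continuous at the cutoff), and 0 beyond.  The shift does not change
#' forces.
#'
#' @param r distance(s), \eqn{\sigma} units; must be positive.
#' @param params a \code{\link{forcefield_params}}.
#' @param shifted override of \code{params$wca_shift}.
#' @return energy in \eqn{\epsilon}.
#' @export
wca_energy <- function(r, params = forcefield_params(),
                       shifted = params$wca_shift) {
  if (any(r <= 0)) stop("wca_energy: distance must be positive")
  inside <- r < params$wca_cutoff
  e <- numeric(length(r))
  ri <- r[inside]
  e[inside] <- 4 * (ri^-12 - ri^-6) + if (shifted) 1 else 0
  e
}

#' Harmonic bond energy
#'
#' \eqn{U(r) = \tfrac12 k_{bond} (r - \sigma)^2}.
#'
#' @inheritParams wca_energy
#' @return energy in \eqn{\epsilon}.
#' @export
bond_energy <- function(r, params = forcefield_params()) {
  if (any(r < 0)) stop("bond_energy: distance must be non-negative")
  0.5 * params$k_bond * (r - params$equilibrium_bond_length)^2
}

#' Coulomb pair energy in reduced units
#'
#' \eqn{U(r) = k_B T\, l_b\, q_i q_j / r} with \eqn{k_B T = \epsilon}; the
#' dielectric constant of the medium is absorbed into the Bjerrum length.
#'
#' @param r distance(s), \eqn{\sigma}; must be positive.
#' @param q_i,q_j charges in e.
#' @param units a \code{\link{reduced_units}}.
#' @return energy in \eqn{\epsilon}.
#' @export
coulomb_pair_energy <- function(r, q_i, q_j, units = reduced_units()) {
  if (any(r <= 0)) stop("coulomb_pair_energy: distance must be positive")
  units$bjerrum_length * q_i * q_j / r
}

#' Total potential energy and forces of a periodic state
#'
#' Sums WCA excluded volume, harmonic bonds and full periodic
#' electrostatics (classical Ewald summation: real-space part under the
#' minimum-image cutoff, reciprocal sum, self term).  Forces are the exact
#' analytic negative gradients of the returned energy; the Ewald splitting
#' parameters are tuned from \code{coulomb_accuracy}.  The system must be
#' charge-neutral (an Ewald-class solver requires it).
#'
#' @param state a \code{\link{system_state}}.
#' @param params a \code{\link{forcefield_params}}.
#' @param units a \code{\link{reduced_units}}.
#' @return list with \code{energy}, components (\code{wca}, \code{bond},
#'   \code{coulomb}) and an N x 3 \code{forces} matrix (\eqn{\epsilon/\sigma}).
#' @export
total_energy_forces <- function(state, params = forcefield_params(),
                                units = reduced_units()) {
  if (!is_neutral(state))
    stop("total_energy_forces: system must be charge-neutral")
  rc <- resolve_cutoff(params, state$box_edge)
  ew <- ewald_setup(state$box_edge, rc, params$coulomb_accuracy)
  energy_forces_cpp(state$positions, state$charge,
                    bonds0(state), state$box_edge,
                    units$bjerrum_length, rc, ew$alpha, ew$nmax,
                    params$k_bond, params$equilibrium_bond_length,
                    params$wca_shift)
}

# 0-based bond matrix for the C++ layer
bonds0 <- function(state) {
  if (nrow(state$bonds) == 0) return(matrix(integer(0), 0, 2))
  state$bonds - 1L
}
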