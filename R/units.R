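#' Reduced Lennard-Jones unit system
#'
#' The simulations work in reduced units: the bead diameter \eqn{\sigma} is
#' the length unit, \eqn{\epsilon} the energy unit, the bead mass \eqn{m}
#' the mass unit, and \eqn{\tau = \sqrt{m\sigma^2/\epsilon}} the time unit.
#' The thermal energy is fixed at \eqn{k_B T = 1\,\epsilon}; the solvent
#' dielectric enters only through the Bjerrum length \eqn{l_b}, expressed in
#' \eqn{\sigma}.  Mapping to physical units uses \code{sigma_nm}, the
#' average phosphate-phosphate distance along an RNA backbone.
#'
#' @param sigma_nm physical length of one bead diameter, in nm.
#' @param epsilon energy unit (reduced; kept for bookkeeping, always 1).
#' @param mass bead mass (reduced; always 1, all beads identical).
#' @param bjerrum_length Bjerrum length in units of \eqn{\sigma}; 1.168
#'   reproduces water (\eqn{l_b \approx 0.7} nm) at room temperature.
#' @return an object of class \code{reduced_units}.
#' @examples
#' u <- reduced_units()
#' physical_bjerrum_nm(u)   # ~0.7 nm, water at room temperature
#' @export
reduced_units <- function(sigma_nm = 0.6, epsilon = 1, mass = 1,
                          bjerrum_length = 1.168) {
  stopifnot(sigma_nm > 0, epsilon > 0, mass > 0, bjerrum_length > 0)
  u <- list(sigma_nm = sigma_nm, epsilon = epsilon, mass = mass,
            tau = sqrt(mass * 1^2 / epsilon), bjerrum_length = bjerrum_length)
  class(u) <- "reduced_units"
  u
}

#' @export
print.reduced_units <- function(x, ...) {
  cat("Reduced LJ units: sigma =", x$sigma_nm, "nm, epsilon =", x$epsilon,
      ", m =", x$mass, ", tau =", x$tau, "\n")
  cat("Bjerrum length: ", x$bjerrum_length, " sigma (",
      format(physical_bjerrum_nm(x), digits = 3), " nm)\n", sep = "")
  invisible(x)
}

#' Physical Bjerrum length implied by a unit system
#'
#' @param units a \code{\link{reduced_units}} object.
#' @return Bjerrum length in nm.
#' @export
physical_bjerrum_nm <- function(units) {
  units$bjerrum_length * units$sigma_nm
}

# CODATA 2018 constants used for unit conversions
.kB_J_per_K <- 1.380649e-23
.NA_per_mol <- 6.02214076e23
.e_C <- 1.602176634e-19
.eps0_F_per_m <- 8.8541878128e-12

#' Reference temperature for a given energy unit
#'
#' Temperature at which \eqn{k_B T} equals the energy unit \eqn{\epsilon},
#' when \eqn{\epsilon} is expressed in kJ/mol.  With \eqn{\epsilon = 1}
#' kJ/mol this is 120.27 K, the thermostat reference temperature that makes
#' the reduced temperature \eqn{T = \epsilon/k_B} correspond to the model's
#' working point.
#'
#' @param epsilon_kJ_per_mol energy unit in kJ/mol.
#' @return temperature in K.
#' @export
reference_temperature_K <- function(epsilon_kJ_per_mol = 1) {
  epsilon_kJ_per_mol * 1000 / (.kB_J_per_K * .NA_per_mol)
}

#' Coulomb prefactor in molar simulation units
#'
#' The electric conversion factor \eqn{f = 1/(4\pi\epsilon_0)} expressed in
#' kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}, computed from CODATA constants
#' (138.935...).  Used to map the reduced Coulomb interaction
#' \eqn{U = k_BT\, l_b q_i q_j / r} onto an engine working in molar units.
#'
#' @return the prefactor, a scalar.
#' @export
coulomb_prefactor_kJ_mol_nm <- function() {
  .e_C^2 / (4 * pi * .eps0_F_per_m) * 1e9 * .NA_per_mol / 1000
}

#' Effective relative dielectric constant for a molar-unit engine
#'
#' Absorbs the Bjerrum length into a dielectric constant
#' \eqn{\epsilon_r = f / (l_b/\sigma)} (with \eqn{f} in kJ/mol nm e^-2 and
#' lengths in bead diameters), so that a molar-unit Coulomb term reproduces
#' the reduced-unit interaction without a separate dielectric parameter.
#'
#' @param units a \code{\link{reduced_units}} object.
#' @return effective \eqn{\epsilon_r}, a scalar.
#' @export
effective_dielectric <- function(units) {
  coulomb_prefactor_kJ_mol_nm() / units$bjerrum_length
}

#' Force-field parameters of the bead-spring model
#'
#' Houses the interaction constants: harmonic bond stiffness
#' \code{k_bond} (default \eqn{5000\,\epsilon\sigma^{-2}}, stiff enough to
#' keep bond-length fluctuations within 10\% and prevent chain crossing),
#' the WCA cutoff \eqn{2^{1/6}\sigma}, the real-space Coulomb cutoff
#' (default \eqn{10\sigma}) and the relative accuracy of the Ewald
#' long-range solver.
#'
#' @param k_bond harmonic bond constant, \eqn{\epsilon\sigma^{-2}}.
#' @param coulomb_realspace_cutoff real-space cutoff for the Ewald split,
#'   in \eqn{\sigma}.  Must not exceed half the box edge of any state it is
#'   applied to; \code{\link{resolve_cutoff}} shrinks it automatically.
#' @param coulomb_accuracy target relative force error of the Ewald solver.
#' @param equilibrium_bond_length rest length of the bonds, \eqn{\sigma}.
#' @param wca_shift logical; if \code{TRUE} (default) the WCA energy is
#'   shifted by \eqn{+\epsilon} inside the cutoff so it is continuous at
#'   \eqn{2^{1/6}\sigma}.  Forces are identical either way; the unshifted
#'   piecewise form is kept as an option.
#' @return an object of class \code{forcefield_params}.
#' @export
forcefield_params <- function(k_bond = 5000, coulomb_realspace_cutoff = 10,
                              coulomb_accuracy = 1e-4,
                              equilibrium_bond_length = 1,
                              wca_shift = TRUE) {
  stopifnot(k_bond >= 0, coulomb_realspace_cutoff > 0,
            coulomb_accuracy > 0, coulomb_accuracy < 1,
            equilibrium_bond_length > 0)
  p <- list(k_bond = k_bond,
            wca_cutoff = 2^(1 / 6),
            coulomb_realspace_cutoff = coulomb_realspace_cutoff,
            coulomb_accuracy = coulomb_accuracy,
            equilibrium_bond_length = equilibrium_bond_length,
            wca_shift = wca_shift)
  class(p) <- "forcefield_params"
  p
}

# Ewald splitting from cutoff + accuracy: alpha = s/rc with s = sqrt(-log(acc))
# puts the real-space truncation error at ~acc; the reciprocal cutoff
# k_cut = 2 alpha s matches it, giving nmax = ceil(k_cut L / (2 pi)).
ewald_setup <- function(box_edge, cutoff, accuracy) {
  s <- sqrt(-log(accuracy))
  alpha <- s / cutoff
  kcut <- 2 * alpha * s
  nmax <- max(1L, as.integer(ceiling(kcut * box_edge / (2 * pi))))
  list(alpha = alpha, nmax = nmax)
}

# Shrink the real-space cutoff below box_edge/2 when the box is small; the
# Ewald split is retuned so the physics is unchanged.
resolve_cutoff <- function(params, box_edge) {
  rc <- min(params$coulomb_realspace_cutoff, 0.49 * box_edge)
  rc
}
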