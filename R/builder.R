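#' System specification
#'
#' Composition of a polyplex simulation: \code{n_rna} RNA chains of
#' \code{l_rna} beads (one bead per nucleotide, charge \eqn{-e}),
#' \code{n_pei} polycation chains of \code{l_pei} beads (one bead per two
#' monomers, charge \eqn{+e}), in a cubic box of edge \code{box_edge}
#' (\eqn{\sigma}).  One counterion (+e) is implied per RNA bead and one
#' co-ion (-e) per PEI bead, so every built system is neutral.
#'
#' @param n_rna,l_rna number and length of RNA chains.
#' @param n_pei,l_pei number and length of polycation chains.
#' @param box_edge cubic box edge in \eqn{\sigma}.
#' @param seed integer master seed for building.
#' @return an object of class \code{system_spec}.
#' @examples
#' sp <- system_spec(n_rna = 8, l_rna = 100, n_pei = 3000, l_pei = 10,
#'                   box_edge = 200)
#' alpha_np(sp)    # 37.5, the top of the studied charge-ratio range
#' @export
system_spec <- function(n_rna, l_rna, n_pei, l_pei, box_edge, seed = 1L) {
  stopifnot(n_rna >= 0, n_pei >= 0, l_rna >= 1, l_pei >= 1, box_edge > 0)
  sp <- list(n_rna = as.integer(n_rna), l_rna = as.integer(l_rna),
             n_pei = as.integer(n_pei), l_pei = as.integer(l_pei),
             box_edge = box_edge, seed = as.integer(seed))
  class(sp) <- "system_spec"
  sp
}

#' Charge ratio of a composition
#'
#' \eqn{\alpha N/P = N_{PEI} l_{PEI} / (N_{RNA} l_{RNA})}: the ratio of
#' polycation to RNA charges.  With the 50\% protonation convention (one
#' charged bead per two PEI monomers) this equals \eqn{\alpha} times the
#' chemists' N/P ratio, and \eqn{\alpha N/P = 1} is the isoelectric point.
#'
#' @param spec a \code{\link{system_spec}}.
#' @return dimensionless charge ratio.
#' @export
alpha_np <- function(spec) {
  np <- spec$n_rna * spec$l_rna
  if (np <= 0) stop("alpha_np: undefined for a system with no RNA beads")
  (spec$n_pei * spec$l_pei) / np
}

# mol/L per (beads/nm^3): 1 L = 1e24 nm^3
.molar_per_nm3 <- function() 1e24 / .NA_per_mol

#' Monomer concentrations and derived composition descriptors
#'
#' Bead (repeat-unit) concentrations \eqn{c = N l / V_{box}} for both
#' polyelectrolytes, in beads/\eqn{\sigma^3} and in mM (via the
#' \eqn{\sigma \to} nm mapping and Avogadro's number), plus the excess
#' polycation concentration \eqn{c^*_{PEI} = c_{PEI} - c_{RNA}}.
#'
#' @param spec a \code{\link{system_spec}}.
#' @param units a \code{\link{reduced_units}}.
#' @return list of class \code{composition_descriptor} with fields
#'   \code{alpha_np}, \code{c_rna}, \code{c_pei}, \code{c_pei_excess}
#'   (each in \code{sigma3} and \code{mM}).
#' @export
concentrations <- function(spec, units = reduced_units()) {
  V <- spec$box_edge^3
  c_rna <- spec$n_rna * spec$l_rna / V
  c_pei <- spec$n_pei * spec$l_pei / V
  to_mM <- function(c_sigma3)
    c_sigma3 / units$sigma_nm^3 * .molar_per_nm3() * 1000
  out <- list(
    alpha_np = if (c_rna > 0) c_pei / c_rna else NA_real_,
    c_rna = list(sigma3 = c_rna, mM = to_mM(c_rna)),
    c_pei = list(sigma3 = c_pei, mM = to_mM(c_pei)),
    c_pei_excess = list(sigma3 = c_pei - c_rna, mM = to_mM(c_pei - c_rna)))
  class(out) <- "composition_descriptor"
  out
}

# one random unit vector
runit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Grow one chain as a self-avoiding random walk with bond length 1,
# rejecting beads closer than `thresh` to anything already placed.
grow_chain <- function(len, placed, L, thresh, max_dir = 60L,
                       max_restart = 200L) {
  for (restart in seq_len(max_restart)) {
    chain <- matrix(NA_real_, len, 3)
    chain[1, ] <- stats::runif(3, 0, L)
    if (nrow(placed) > 0 &&
        min_dist_to_set_cpp(chain[1, , drop = FALSE], placed, L) < thresh)
      next
    ok <- TRUE
    for (b in seq_len(len - 1)) {
      grown <- FALSE
      for (try in seq_len(max_dir)) {
        cand <- chain[b, ] + runit3()
        cand <- cand - L * floor(cand / L)
        prev <- chain[seq_len(max(1, b - 1)), , drop = FALSE]
        dmin <- min_dist_to_set_cpp(matrix(cand, 1, 3), prev, L)
        if (nrow(placed) > 0)
          dmin <- min(dmin, min_dist_to_set_cpp(matrix(cand, 1, 3), placed, L))
        if (dmin >= thresh) {
          chain[b + 1, ] <- cand
          grown <- TRUE
          break
        }
      }
      if (!grown) { ok <- FALSE; break }
    }
    if (ok) return(chain)
  }
  stop("grow_chain: could not insert a chain without overlap; box too dense")
}

place_ions <- function(n, placed, L, thresh, max_try = 5000L) {
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(max_try)) {
      cand <- stats::runif(3, 0, L)
      if (nrow(placed) == 0 ||
          min_dist_to_set_cpp(matrix(cand, 1, 3), placed, L) >= thresh) {
        out[i, ] <- cand
        placed <- rbind(placed, cand)
        done <- TRUE
        break
      }
    }
    if (!done) stop("place_ions: insertion failed; box too dense")
  }
  out
}

#' Maxwell-Boltzmann velocities with zero total momentum
#'
#' @param n number of beads.
#' @param kT temperature in \eqn{\epsilon}.
#' @return n x 3 matrix of velocities, centre-of-mass motion removed.
#' @export
draw_velocities <- function(n, kT = 1) {
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kT)), n, 3)
  if (n > 1) v <- sweep(v, 2, colMeans(v))
  v
}

#' Build a random non-overlapping initial configuration
#'
#' Chains are inserted as self-avoiding random walks with fixed bond length
#' \eqn{\sigma} (overlap threshold \code{overlap_thresh}); one neutralizing
#' counterion per RNA bead and one co-ion per PEI bead are inserted at
#' random non-overlapping positions; velocities are drawn from the
#' equilibrium distribution at \eqn{T = \epsilon/k_B}.  Deterministic under
#' the seed carried by \code{spec}.
#'
#' @param spec a \code{\link{system_spec}}.
#' @param overlap_thresh minimum allowed inter-bead distance, \eqn{\sigma}.
#' @param kT temperature for the velocity draw.
#' @return a neutral \code{\link{system_state}}.
#' @export
build_random_system <- function(spec, overlap_thresh = 0.9, kT = 1) {
  set.seed(spec$seed)
  L <- spec$box_edge
  placed <- matrix(numeric(0), 0, 3)
  pos_list <- list(); chain_id <- integer(0); species <- character(0)
  charge <- numeric(0); bonds <- list()
  cid <- 0L; offset <- 0L
  add_chain <- function(len, sp, q) {
    ch <- grow_chain(len, placed, L, overlap_thresh)
    placed <<- rbind(placed, ch)
    pos_list[[length(pos_list) + 1L]] <<- ch
    cid <<- cid + 1L
    chain_id <<- c(chain_id, rep(cid, len))
    species <<- c(species, rep(sp, len))
    charge <<- c(charge, rep(q, len))
    if (len > 1)
      bonds[[length(bonds) + 1L]] <<-
        cbind(offset + seq_len(len - 1), offset + seq_len(len - 1) + 1L)
    offset <<- offset + len
  }
  for (i in seq_len(spec$n_rna)) add_chain(spec$l_rna, "RNA", -1)
  for (i in seq_len(spec$n_pei)) add_chain(spec$l_pei, "PEI", +1)
  n_counter <- spec$n_rna * spec$l_rna
  n_co <- spec$n_pei * spec$l_pei
  if (n_counter > 0) {
    ci <- place_ions(n_counter, placed, L, overlap_thresh)
    placed <- rbind(placed, ci)
    pos_list[[length(pos_list) + 1L]] <- ci
    chain_id <- c(chain_id, rep(-1L, n_counter))
    species <- c(species, rep("COUNTERION", n_counter))
    charge <- c(charge, rep(+1, n_counter))
    offset <- offset + n_counter
  }
  if (n_co > 0) {
    co <- place_ions(n_co, placed, L, overlap_thresh)
    pos_list[[length(pos_list) + 1L]] <- co
    chain_id <- c(chain_id, rep(-1L, n_co))
    species <- c(species, rep("COION", n_co))
    charge <- c(charge, rep(-1, n_co))
  }
  pos <- do.call(rbind, pos_list)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  system_state(pos, draw_velocities(nrow(pos), kT), charge, species,
               chain_id, bonds, L, step = 0L, rng_seed = spec$seed)
}

#' Relax and equilibrate a freshly built state
#'
#' Three stages, mirroring the preparation protocol: (1) 100 MD steps with
#' a soft-core (force-capped) repulsion to remove residual overlaps, (2)
#' steepest-descent energy minimisation, (3) thermostatted equilibration
#' for \code{equil_steps} steps.  Errors name the failing stage if energies
#' go non-finite.
#'
#' @param state a \code{\link{system_state}}.
#' @param params a \code{\link{forcefield_params}}.
#' @param units a \code{\link{reduced_units}}.
#' @param ip an \code{\link{integrator_params}} (thermostat settings, dt).
#' @param softcore_steps MD steps with capped forces.
#' @param softcore_fmax force cap, \eqn{\epsilon/\sigma}.
#' @param minimize_iter maximum minimiser iterations.
#' @param equil_steps thermostatted equilibration steps.
#' @return the equilibrated \code{\link{system_state}}.
#' @export
relax_and_equilibrate <- function(state, params = forcefield_params(),
                                  units = reduced_units(),
                                  ip = integrator_params(),
                                  softcore_steps = 100L,
                                  softcore_fmax = 100,
                                  minimize_iter = 500L,
                                  equil_steps = 20000L) {
  stage <- "soft-core relaxation"
  res <- tryCatch({
    if (softcore_steps > 0) {
      ip_sc <- ip
      ip_sc$n_steps <- as.integer(softcore_steps)
      ip_sc$trajectory_stride <- as.integer(softcore_steps)
      state <- integrate_md(state, ip_sc, params, units,
                            force_cap = softcore_fmax)$final_state
    }
    stage <- "minimisation"
    rc <- resolve_cutoff(params, state$box_edge)
    ew <- ewald_setup(state$box_edge, rc, params$coulomb_accuracy)
    mn <- minimize_cpp(state$positions, state$charge, bonds0(state),
                       state$box_edge, units$bjerrum_length, rc, ew$alpha,
                       ew$nmax, params$k_bond,
                       params$equilibrium_bond_length, params$wca_shift,
                       as.integer(minimize_iter), 1e-3)
    if (!is.finite(mn$energy)) stop("non-finite energy")
    state$positions <- mn$positions
    stage <- "equilibration"
    if (equil_steps > 0) {
      ip_eq <- ip
      ip_eq$n_steps <- as.integer(equil_steps)
      ip_eq$trajectory_stride <- as.integer(max(1, equil_steps %/% 10))
      state <- integrate_md(state, ip_eq, params, units)$final_state
    }
    state
  }, error = function(e) {
    stop("relax_and_equilibrate failed during ", stage, ": ",
         conditionMessage(e))
  })
  res
}

#' Build, relax and mix a system the way production runs start
#'
#' Polycations with their co-ions and RNA with its counterions are prepared
#' in two separate boxes of the final edge, each relaxed and equilibrated,
#' then merged into one box and relaxed and equilibrated again.
#'
#' @inheritParams relax_and_equilibrate
#' @param spec a \code{\link{system_spec}}.
#' @param equil_steps equilibration steps used for each stage.
#' @return an equilibrated mixed \code{\link{system_state}}.
#' @export
build_equilibrated_system <- function(spec, params = forcefield_params(),
                                      units = reduced_units(),
                                      ip = integrator_params(),
                                      equil_steps = 20000L) {
  rna_spec <- system_spec(spec$n_rna, spec$l_rna, 0L, 1L, spec$box_edge,
                          seed = spec$seed)
  pei_spec <- system_spec(0L, 1L, spec$n_pei, spec$l_pei, spec$box_edge,
                          seed = spec$seed + 1L)
  sub <- list()
  if (spec$n_rna > 0)
    sub$rna <- relax_and_equilibrate(build_random_system(rna_spec),
                                     params, units, ip,
                                     equil_steps = equil_steps)
  if (spec$n_pei > 0)
    sub$pei <- relax_and_equilibrate(build_random_system(pei_spec),
                                     params, units, ip,
                                     equil_steps = equil_steps)
  if (length(sub) == 1) return(sub[[1]])
  merged <- merge_states(sub$rna, sub$pei)
  set.seed(spec$seed + 2L)
  merged$velocities <- draw_velocities(nrow(merged$positions),
                                       ip$thermostat_target)
  relax_and_equilibrate(merged, params, units, ip,
                        equil_steps = equil_steps)
}

# Union of two states sharing a box edge; chain ids and bonds re-indexed.
merge_states <- function(a, b) {
  stopifnot(a$box_edge == b$box_edge)
  na <- nrow(a$positions)
  cid_b <- b$chain_id
  cid_b[cid_b > 0] <- cid_b[cid_b > 0] + max(0L, a$chain_id)
  bonds_b <- if (nrow(b$bonds)) b$bonds + na else b$bonds
  system_state(rbind(a$positions, b$positions),
               rbind(a$velocities, b$velocities),
               c(a$charge, b$charge), c(a$species, b$species),
               c(a$chain_id, cid_b), rbind(a$bonds, bonds_b),
               a$box_edge, step = 0L, rng_seed = a$rng_seed)
}

#' Start state with all RNA pre-aggregated in one nanoparticle
#'
#' Takes a converged isoelectric (\eqn{\alpha N/P = 1}) final frame, in
#' which all chains sit in a single aggregate, and adds polycation chains
#' plus matching co-ions at random non-overlapping positions until the
#' target charge ratio is reached; the aggregate's internal coordinates are
#' preserved.  Velocities are re-drawn.  Only defined for targets at or
#' above the isoelectric point.
#'
#' @param isoelectric_final a converged \code{\link{system_state}} at
#'   \eqn{\alpha N/P = 1}.
#' @param target_alpha_np target charge ratio, \eqn{\ge 1}.
#' @param l_pei length of the added polycation chains.
#' @param seed integer seed.
#' @param overlap_thresh minimum insertion distance, \eqn{\sigma}.
#' @param kT temperature for the velocity draw.
#' @return a neutral \code{\link{system_state}} at the target ratio.
#' @export
build_aggregated_start <- function(isoelectric_final, target_alpha_np,
                                   l_pei = NULL, seed = 1L,
                                   overlap_thresh = 0.9, kT = 1) {
  st <- isoelectric_final
  if (target_alpha_np < 1)
    stop("build_aggregated_start: target alpha N/P must be >= 1 ",
         "(the protocol only adds polycations)")
  n_rna_beads <- sum(st$species == "RNA")
  n_pei_beads <- sum(st$species == "PEI")
  if (is.null(l_pei)) {
    pei_chains <- unique(st$chain_id[st$species == "PEI"])
    if (length(pei_chains) == 0)
      stop("build_aggregated_start: l_pei must be given for a PEI-free state")
    l_pei <- sum(st$chain_id == pei_chains[1])
  }
  target_beads <- target_alpha_np * n_rna_beads
  add_beads <- target_beads - n_pei_beads
  if (add_beads < -1e-9)
    stop("build_aggregated_start: target below the state's current ratio")
  n_add <- as.integer(round(add_beads / l_pei))
  set.seed(seed)
  if (n_add == 0) {
    st$velocities <- draw_velocities(nrow(st$positions), kT)
    st$rng_seed <- as.integer(seed)
    return(st)
  }
  add_spec <- system_spec(0L, 1L, n_add, l_pei, st$box_edge, seed = seed)
  L <- st$box_edge
  placed <- st$positions
  pos_list <- list(); bonds <- list()
  cid0 <- max(st$chain_id, 0L)
  chain_id <- integer(0)
  offset <- nrow(st$positions)
  for (i in seq_len(n_add)) {
    ch <- grow_chain(l_pei, placed, L, overlap_thresh)
    placed <- rbind(placed, ch)
    pos_list[[length(pos_list) + 1L]] <- ch
    chain_id <- c(chain_id, rep(cid0 + i, l_pei))
    if (l_pei > 1)
      bonds[[length(bonds) + 1L]] <-
        cbind(offset + seq_len(l_pei - 1), offset + seq_len(l_pei - 1) + 1L)
    offset <- offset + l_pei
  }
  n_co <- n_add * l_pei
  co <- place_ions(n_co, placed, L, overlap_thresh)
  new_pos <- rbind(do.call(rbind, pos_list), co)
  new_species <- c(rep("PEI", n_add * l_pei), rep("COION", n_co))
  new_charge <- c(rep(+1, n_add * l_pei), rep(-1, n_co))
  new_chain <- c(chain_id, rep(-1L, n_co))
  new_bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  pos <- rbind(st$positions, new_pos)
  out <- system_state(pos, draw_velocities(nrow(pos), kT),
                      c(st$charge, new_charge), c(st$species, new_species),
                      c(st$chain_id, new_chain), rbind(st$bonds, new_bonds),
                      L, step = 0L, rng_seed = as.integer(seed))
  out
}

#' Minimum inter-bead distance of a state
#'
#' Smallest minimum-image pair distance; construction invariant of built
#' systems (at or above the overlap threshold).
#'
#' @param state a \code{\link{system_state}}.
#' @return scalar distance, \eqn{\sigma}.
#' @export
min_pair_distance <- function(state) {
  n <- nrow(state$positions)
  g <- seq_len(n) - 1L
  m <- group_min_dist_cpp(state$positions, g, n, state$box_edge)
  min(m[upper.tri(m)])
}
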