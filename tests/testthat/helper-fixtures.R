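# Small deterministic fixtures, built in code.

# a state holding free beads at given positions (no bonds)
free_bead_state <- function(pos, charge = rep(0, nrow(pos)), box_edge = 50,
                            species = NULL) {
  pos <- as.matrix(pos)
  if (is.null(species))
    species <- ifelse(charge > 0, "COUNTERION",
                      ifelse(charge < 0, "COION", "COUNTERION"))
  system_state(pos, NULL, charge, species, rep(-1L, nrow(pos)),
               matrix(integer(0), 0, 2), box_edge)
}

# a single linear chain along +x starting at `origin`
chain_state <- function(len, origin = c(5, 5, 5), spacing = 1,
                        species = "RNA", charge = -1, box_edge = 50,
                        velocities = NULL) {
  pos <- cbind(origin[1] + spacing * (seq_len(len) - 1), origin[2], origin[3])
  bonds <- if (len > 1) cbind(seq_len(len - 1), seq_len(len - 1) + 1L)
           else matrix(integer(0), 0, 2)
  system_state(pos, velocities, rep(charge, len), rep(species, len),
               rep(1L, len), bonds, box_edge)
}

# several chains at given origins; returns a combined neutral-or-not state
multi_chain_state <- function(origins, len = 4, spacing = 1, box_edge = 50,
                              species = "RNA", charge = 0) {
  n <- nrow(origins)
  pos <- NULL; chain_id <- integer(0); bonds <- NULL; off <- 0L
  for (k in seq_len(n)) {
    p <- cbind(origins[k, 1] + spacing * (seq_len(len) - 1),
               origins[k, 2], origins[k, 3])
    pos <- rbind(pos, p)
    chain_id <- c(chain_id, rep(k, len))
    if (len > 1)
      bonds <- rbind(bonds, cbind(off + seq_len(len - 1),
                                  off + seq_len(len - 1) + 1L))
    off <- off + len
  }
  system_state(pos, NULL, rep(charge, nrow(pos)),
               rep(species, nrow(pos)), chain_id,
               if (is.null(bonds)) matrix(integer(0), 0, 2) else bonds,
               box_edge)
}

# rock-salt arrangement: 8 alternating unit charges on a cubic lattice,
# box edge twice the lattice constant (periodic NaCl crystal)
rocksalt_state <- function(a = 1) {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * a
  q <- (-1)^rowSums(g / a)
  free_bead_state(g, q, box_edge = 2 * a)
}

# finite-difference gradient of the total energy
fd_forces <- function(state, params, units, h = 1e-6, beads = NULL) {
  if (is.null(beads)) beads <- seq_len(nrow(state$positions))
  out <- matrix(NA_real_, length(beads), 3)
  for (bi in seq_along(beads)) {
    for (d in 1:3) {
      s1 <- state; s1$positions[beads[bi], d] <- s1$positions[beads[bi], d] + h
      s2 <- state; s2$positions[beads[bi], d] <- s2$positions[beads[bi], d] - h
      e1 <- total_energy_forces(s1, params, units)$energy
      e2 <- total_energy_forces(s2, params, units)$energy
      out[bi, d] <- -(e1 - e2) / (2 * h)
    }
  }
  out
}

# single-nanoparticle wrapper for metric functions on a plain bead set
as_np <- function(state, bead_indices = NULL, ion_indices = integer(0)) {
  if (is.null(bead_indices)) bead_indices <- which(state$chain_id > 0)
  np <- list(member_chain_ids = unique(state$chain_id[bead_indices]),
             member_bead_indices = bead_indices,
             attached_ion_indices = ion_indices,
             n_rna_chains = length(unique(
               state$chain_id[bead_indices][state$species[bead_indices] == "RNA"])),
             n_pei_chains = length(unique(
               state$chain_id[bead_indices][state$species[bead_indices] == "PEI"])))
  class(np) <- "nanoparticle"
  np
}
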