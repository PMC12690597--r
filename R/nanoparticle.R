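#' Identify nanoparticles in a frame
#'
#' A nanoparticle (NP) is the connected set of polymer chains in which two
#' chains are linked whenever any inter-bead minimum-image distance is
#' below the cutoff (default \eqn{3.5\sigma}); the assignment is the
#' transitive closure of that relation, so it is iterative by nature.
#' Chains, not beads, are the clustering unit; an isolated chain is a
#' single-chain NP.  Ions within the cutoff of any member polymer bead are
#' attached to the NP afterwards (each ion to the NP of its nearest
#' polymer bead).
#'
#' @param frame a \code{\link{system_state}}.
#' @param cutoff linking/attachment distance, \eqn{\sigma}.
#' @return list of \code{nanoparticle} objects, each with
#'   \code{member_chain_ids}, \code{member_bead_indices},
#'   \code{attached_ion_indices}, \code{n_rna_chains}, \code{n_pei_chains}.
#' @export
find_nanoparticles <- function(frame, cutoff = 3.5) {
  poly <- frame$chain_id > 0
  if (!any(poly)) return(list())
  chains <- sort(unique(frame$chain_id[poly]))
  nch <- length(chains)
  gidx <- match(frame$chain_id[poly], chains) - 1L
  dmat <- group_min_dist_cpp(frame$positions[poly, , drop = FALSE],
                             gidx, nch, frame$box_edge)
  adj <- dmat < cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ions <- which(frame$chain_id < 0)
  ion_np <- integer(0)
  if (length(ions) > 0) {
    # nearest member polymer bead decides attachment
    pp <- frame$positions[poly, , drop = FALSE]
    nn <- nearest_in_set_cpp(frame$positions[ions, , drop = FALSE], pp,
                             frame$box_edge)
    ion_np <- ifelse(nn$dist < cutoff, comp[gidx[nn$index] + 1L],
                     NA_integer_)
  }
  poly_idx <- which(poly)
  lapply(seq_len(max(comp)), function(cc) {
    member_chains <- chains[comp == cc]
    beads <- poly_idx[frame$chain_id[poly_idx] %in% member_chains]
    att <- if (length(ions)) ions[!is.na(ion_np) & ion_np == cc] else integer(0)
    np <- list(member_chain_ids = member_chains,
               member_bead_indices = beads,
               attached_ion_indices = att,
               n_rna_chains = length(unique(
                 frame$chain_id[beads][frame$species[beads] == "RNA"])),
               n_pei_chains = length(unique(
                 frame$chain_id[beads][frame$species[beads] == "PEI"])))
    class(np) <- "nanoparticle"
    np
  })
}

# Unwrap a cluster across periodic boundaries: each chain is unwrapped
# along its bonds, then chains are placed breadth-first, shifting each new
# chain so its closest contact sits at the minimum image of an already
# placed bead.  Attached ions are placed at the minimum image relative to
# their nearest member bead.  Valid while the cluster diameter is below
# half the box diagonal.
unwrap_cluster <- function(np, frame) {
  L <- frame$box_edge
  mi <- function(d) d - L * round(d / L)
  chains <- np$member_chain_ids
  chain_beads <- lapply(chains, function(cid)
    np$member_bead_indices[frame$chain_id[np$member_bead_indices] == cid])
  unwrap_one <- function(idx) {
    p <- frame$positions[idx, , drop = FALSE]
    if (nrow(p) > 1)
      for (b in 2:nrow(p))
        p[b, ] <- p[b - 1, ] + mi(p[b, ] - p[b - 1, ])
    p
  }
  coords <- lapply(chain_beads, unwrap_one)
  placed <- rep(FALSE, length(chains))
  placed[1] <- TRUE
  while (!all(placed)) {
    progressed <- FALSE
    done <- do.call(rbind, coords[placed])
    done_wrapped <- wrap_positions(done, L)
    for (k in which(!placed)) {
      # closest approach between chain k and the placed set
      dk <- min_dist_to_set_cpp(wrap_positions(coords[[k]], L),
                                done_wrapped, L)
      b <- which.min(dk)
      if (dk[b] >= frame$box_edge) next
      # anchor: nearest placed bead to bead b of chain k
      da <- min_dist_to_set_cpp(done_wrapped,
                                wrap_positions(coords[[k]][b, , drop = FALSE], L),
                                L)
      a <- which.min(da)
      target <- done[a, ] + mi(wrap_positions(coords[[k]][b, , drop = FALSE], L) -
                               done_wrapped[a, , drop = FALSE])
      shift <- as.numeric(target) - coords[[k]][b, ]
      coords[[k]] <- sweep(coords[[k]], 2, -shift)
      placed[k] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) { placed[] <- TRUE }  # disconnected remainder: leave as is
  }
  beads <- unlist(chain_beads)
  pos <- do.call(rbind, coords)
  ion_pos <- NULL
  if (length(np$attached_ion_indices) > 0) {
    pw <- wrap_positions(pos, L)
    ion_pos <- t(vapply(np$attached_ion_indices, function(i) {
      d <- min_dist_to_set_cpp(pw, frame$positions[i, , drop = FALSE], L)
      a <- which.min(d)
      pos[a, ] + mi(frame$positions[i, ] - pw[a, ])
    }, numeric(3)))
  }
  list(bead_indices = beads, bead_pos = pos,
       ion_indices = np$attached_ion_indices, ion_pos = ion_pos)
}

#' Gyration tensor metrics of a nanoparticle
#'
#' Builds the 3x3 gyration tensor over the polymer beads of the NP
#' (coordinates unwrapped within the cluster; ions excluded by
#' convention), diagonalises it into eigenvalues \eqn{\lambda_1^2 \ge
#' \lambda_2^2 \ge \lambda_3^2}, and returns the radius of gyration
#' \eqn{R_g = \sqrt{\lambda_1^2 + \lambda_2^2 + \lambda_3^2}} and the
#' relative shape anisotropy
#' \eqn{\kappa^2 = \tfrac32 \frac{\lambda_1^4 + \lambda_2^4 +
#' \lambda_3^4}{(\lambda_1^2+\lambda_2^2+\lambda_3^2)^2} - \tfrac12},
#' which is 0 for full degeneracy (e.g. cube vertices) and 1 for collinear
#' beads.
#'
#' @param np a \code{nanoparticle} (or any list with
#'   \code{member_bead_indices}).
#' @param frame a \code{\link{system_state}}.
#' @return list with \code{eigvals} (descending, \eqn{\sigma^2}),
#'   \code{r_g} (\eqn{\sigma}) and \code{kappa2}; for a single bead
#'   \code{r_g = 0} and \code{kappa2 = NA} (undefined, flagged).
#' @export
gyration_metrics <- function(np, frame) {
  uw <- unwrap_cluster(np, frame)
  p <- uw$bead_pos
  if (nrow(p) == 1)
    return(list(eigvals = c(0, 0, 0), r_g = 0, kappa2 = NA_real_))
  com <- colMeans(p)
  d <- sweep(p, 2, com)
  S <- crossprod(d) / nrow(p)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  tr <- sum(ev)
  k2 <- if (tr > 0) 1.5 * sum(ev^2) / tr^2 - 0.5 else NA_real_
  list(eigvals = ev, r_g = sqrt(tr), kappa2 = k2)
}

#' Radius of gyration directly from pair/centre distances
#'
#' The direct-sum route \eqn{R_g^2 = \frac1N \sum_i |r_i - r_{com}|^2};
#' numerically identical to the gyration-tensor eigenvalue route.
#'
#' @inheritParams gyration_metrics
#' @return \eqn{R_g} in \eqn{\sigma}.
#' @export
radius_of_gyration_direct <- function(np, frame) {
  uw <- unwrap_cluster(np, frame)
  p <- uw$bead_pos
  com <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, com)^2)))
}

#' Kirkwood hydrodynamic radius
#'
#' Radius of the Stokes sphere with the same diffusion coefficient,
#' from the Kirkwood double sum
#' \eqn{1/R_h = \frac{1}{N(N-1)} \sum_{i \ne j} 1/r_{ij}} over the NP's
#' polymer beads and its attached ions (minimum-image distances).
#'
#' @inheritParams gyration_metrics
#' @return \eqn{R_h} in \eqn{\sigma}; \code{NA} (flagged) for fewer than
#'   two items.
#' @export
hydrodynamic_radius <- function(np, frame) {
  idx <- c(np$member_bead_indices, np$attached_ion_indices)
  n <- length(idx)
  if (n < 2) return(NA_real_)
  s <- inv_dist_sum_cpp(frame$positions[idx, , drop = FALSE],
                        frame$box_edge)
  (n * (n - 1)) / s
}

#' Charge of a nanoparticle, decomposed by species
#'
#' Sum of the polymer charges plus the charges of attached ions, with the
#' decomposition into polymer (PEI+RNA), co-ion and counterion
#' contributions.
#'
#' @inheritParams gyration_metrics
#' @return list with \code{total} (e) and \code{parts} (named numeric:
#'   \code{polymer}, \code{coion}, \code{counterion}).
#' @export
np_charge <- function(np, frame) {
  qb <- sum(frame$charge[np$member_bead_indices])
  qi <- frame$charge[np$attached_ion_indices]
  si <- frame$species[np$attached_ion_indices]
  parts <- c(polymer = qb,
             coion = sum(qi[si == "COION"]),
             counterion = sum(qi[si == "COUNTERION"]))
  list(total = sum(parts), parts = parts)
}

#' Zeta-potential of a nanoparticle from the radial charge profile
#'
#' Assuming spherical symmetry (a good approximation near and above the
#' isoelectric point), the potential at the shear plane \eqn{R_h} is
#' \deqn{\zeta = \int_{R_h}^{r_{max}} \frac{Q(r)}{4\pi\epsilon_0\epsilon_r
#' r^2}\,dr = l_b \frac{\epsilon}{e^2}\int_{R_h}^{r_{max}}
#' \frac{Q(r)}{r^2}\,dr}
#' where \eqn{Q(r)} is the cumulative charge of all beads (polymers and
#' ions, the whole frame) within minimum-image distance \eqn{r} of the
#' NP's centre of mass, and the integration is cut at \eqn{50\sigma}
#' where \eqn{Q(r)/r^2 \approx 0}.  \eqn{Q(r)} is a step function over the
#' exact sorted distances and the integral is evaluated in closed form
#' over each step.
#'
#' @inheritParams gyration_metrics
#' @param units a \code{\link{reduced_units}}.
#' @param r_max integration cutoff, \eqn{\sigma}.
#' @param r_h optional precomputed hydrodynamic radius.
#' @return \eqn{\zeta} in \eqn{\epsilon/e}.
#' @export
zeta_potential <- function(np, frame, units = reduced_units(),
                           r_max = 50, r_h = NULL) {
  if (is.null(r_h)) r_h <- hydrodynamic_radius(np, frame)
  if (!is.finite(r_h)) return(NA_real_)
  if (r_h >= r_max)
    stop("zeta_potential: hydrodynamic radius exceeds the integration cutoff")
  uw <- unwrap_cluster(np, frame)
  com <- colMeans(uw$bead_pos)
  com_w <- wrap_positions(matrix(com, 1, 3), frame$box_edge)
  d <- min_dist_to_set_cpp(frame$positions, com_w, frame$box_edge)
  q <- frame$charge
  keep <- q != 0
  ord <- order(d[keep])
  r <- d[keep][ord]
  Q <- cumsum(q[keep][ord])
  # closed-form integral of the step function Q(r)/r^2 from r_h to r_max
  edges <- c(r, Inf)
  lo <- pmax(edges[-length(edges)], r_h)
  hi <- pmin(edges[-1], r_max)
  ok <- hi > lo
  # charge already inside r_h contributes from r_h outward
  units$bjerrum_length * sum(Q[ok] * (1 / lo[ok] - 1 / hi[ok]))
}

#' Manning counterion-condensation fraction
#'
#' Fraction of the polyelectrolyte charge neutralized by condensed
#' counterions: the number of counterions within the binding cutoff of any
#' RNA bead, divided by the number of RNA beads.  For a lone flexible
#' polyelectrolyte this estimates the Manning fraction
#' \eqn{\phi = 1 - \sigma/l_b} (\eqn{\approx 0.144} at
#' \eqn{l_b = 1.168\sigma}).  Meaningful in polycation-free systems.
#'
#' The default condensation distance is the Bjerrum association
#' criterion, \eqn{2 l_b}: an ion closer than that to a backbone charge
#' has an attraction deeper than \eqn{k_BT/2} and is counted as bound.
#' The looser NP ion-shell cutoff (\eqn{3.5\sigma}) also sweeps up
#' diffuse-layer ions and overestimates the condensed fraction.
#'
#' @param frame a \code{\link{system_state}}.
#' @param binding_cutoff condensation distance, \eqn{\sigma}.
#' @param units a \code{\link{reduced_units}} (sets the default cutoff).
#' @return \eqn{\phi \ge 0} (0 when no counterion is bound).
#' @export
manning_fraction <- function(frame, binding_cutoff = NULL,
                             units = reduced_units()) {
  if (is.null(binding_cutoff)) binding_cutoff <- 2 * units$bjerrum_length
  rna <- frame$species == "RNA"
  ci <- frame$species == "COUNTERION"
  if (!any(rna)) stop("manning_fraction: no RNA beads in the frame")
  if (!any(ci)) return(0)
  d <- min_dist_to_set_cpp(frame$positions[ci, , drop = FALSE],
                           frame$positions[rna, , drop = FALSE],
                           frame$box_edge)
  sum(d < binding_cutoff) / sum(rna)
}

#' Theoretical Manning fraction
#' @param units a \code{\link{reduced_units}}.
#' @return \eqn{1 - \sigma/l_b}.
#' @export
manning_theory <- function(units = reduced_units()) {
  1 - 1 / units$bjerrum_length
}

#' Per-frame, per-NP observable table
#'
#' Runs NP identification and the full observable suite on every frame of
#' a trajectory; one row per NP per frame, CSV-ready.
#'
#' @param traj a \code{cg_trajectory}.
#' @param cutoff clustering/attachment cutoff, \eqn{\sigma}.
#' @param units a \code{\link{reduced_units}}.
#' @param zeta logical, compute the zeta-potential (the slowest metric).
#' @param frames frame indices to analyse (default all).
#' @param replicate replicate id recorded in the table.
#' @return data.frame with columns \code{replicate}, \code{frame},
#'   \code{step}, \code{np_id}, \code{n_rna_chains}, \code{n_pei_chains},
#'   \code{n_beads}, \code{n_ions}, \code{r_g}, \code{kappa2}, \code{r_h},
#'   \code{charge}, \code{charge_polymer}, \code{charge_coion},
#'   \code{charge_counterion}, \code{zeta}.
#' @export
np_metrics_table <- function(traj, cutoff = 3.5, units = reduced_units(),
                             zeta = FALSE, frames = NULL, replicate = 1L) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  rows <- lapply(frames, function(fi) {
    fr <- trajectory_frame(traj, fi)
    nps <- find_nanoparticles(fr, cutoff)
    if (length(nps) == 0) return(NULL)
    do.call(rbind, lapply(seq_along(nps), function(k) {
      np <- nps[[k]]
      gm <- gyration_metrics(np, fr)
      rh <- hydrodynamic_radius(np, fr)
      qc <- np_charge(np, fr)
      z <- if (zeta && is.finite(rh))
        zeta_potential(np, fr, units, r_h = rh) else NA_real_
      data.frame(replicate = replicate, frame = fi, step = fr$step,
                 np_id = k, n_rna_chains = np$n_rna_chains,
                 n_pei_chains = np$n_pei_chains,
                 n_beads = length(np$member_bead_indices),
                 n_ions = length(np$attached_ion_indices),
                 r_g = gm$r_g, kappa2 = gm$kappa2, r_h = rh,
                 charge = qc$total,
                 charge_polymer = qc$parts[["polymer"]],
                 charge_coion = qc$parts[["coion"]],
                 charge_counterion = qc$parts[["counterion"]],
                 zeta = z)
    }))
  })
  do.call(rbind, rows)
}
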