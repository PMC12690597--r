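---
title: "A coarse-grained model of polyplex self-assembly: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of polyplex self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`polyplexmd` simulates the electrostatic self-assembly of RNA with linear
polycations (called PEI throughout, although nothing in the model is
specific to polyethylenimine) as flexible bead-spring polyelectrolytes in
implicit solvent.

Every particle is a bead of diameter $\sigma$ and mass $m = 1$.  An RNA
bead represents one nucleotide and carries charge $-e$; a PEI bead
represents two monomers and carries $+e$, which encodes a 50% protonation
ratio.  For every RNA bead one counterion ($+e$) and for every PEI bead
one co-ion ($-e$) is present, so each system is exactly neutral.  Three
interactions act between beads:

* **Excluded volume** — the purely repulsive WCA potential,
  $4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ for $r < 2^{1/6}\sigma$,
  zero beyond.  By default the energy is shifted by $+\epsilon$ inside
  the cutoff so it is continuous there; the unshifted piecewise form is
  available (`wca_shift = FALSE`).  Both give identical forces, so the
  dynamics do not depend on the choice; the shifted form makes
  energy-conservation checks cleaner.
* **Connectivity** — harmonic bonds
  $\tfrac12 k_{bond}(r-\sigma)^2$ with $k_{bond} =
  5000\,\epsilon\sigma^{-2}$.  This stiffness keeps bond-length
  fluctuations within 10% of $\sigma$ (harmonic estimate
  $\sqrt{k_BT/k_{bond}} \approx 1.4\%$) and prevents chain crossing.
  Bonded pairs also keep their WCA and Coulomb interactions (the common
  bead-spring polyelectrolyte convention); with this $k_{bond}$ the WCA
  push shifts the bond minimum by only $\sim 0.005\,\sigma$.
* **Electrostatics** — the Coulomb potential in thermal units,
  $U(r) = k_BT\, l_b\, q_i q_j / r$ with $k_BT = 1\,\epsilon$.  The
  solvent dielectric is absorbed into the Bjerrum length,
  $l_b = 1.168\,\sigma$, which with $\sigma = 0.6$ nm reproduces water at
  room temperature ($l_b \approx 0.7$ nm).  No separate dielectric
  parameter is exposed.  For engines that work in molar units the
  equivalent settings are a reference temperature of 120.27236 K per
  kJ/mol of $\epsilon$ and an effective dielectric
  $\epsilon_r = 138.935458 / (l_b/\sigma)$; `reference_temperature_K()`
  and `effective_dielectric()` compute both from CODATA constants.

### Periodic electrostatics

Long-range electrostatics are evaluated with classical Ewald summation:
a real-space sum of $\mathrm{erfc}(\alpha r)/r$ terms under a
minimum-image cutoff, a reciprocal-space sum over plane waves, and the
self term.  The splitting parameter and the reciprocal cutoff are tuned
from a single relative-accuracy parameter (`coulomb_accuracy`, default
$10^{-4}$): $\alpha = s/r_c$ and $k_{cut} = 2\alpha s$ with
$s = \sqrt{-\log(\mathrm{acc})}$.  Because the split is exact, the
real-space cutoff $r_c$ (default $10\,\sigma$) is a performance knob,
not a physical one; it is automatically reduced below half the box edge
for small boxes, and analyses of dilute systems may raise it so that the
reciprocal sum stays small.  The implementation is validated in the test
suite against the rock-salt Madelung constant, against a direct
lattice-sum oracle (with the dipole surface term accounting for the
tinfoil boundary of Ewald), and against central-difference gradients of
its own energy.  During time integration the real-space kernel is
linearly interpolated from a dense table in $r^2$ (16k points); the
single-point `total_energy_forces()` path is always exact.

### Integration and temperature control

Leapfrog integration with $dt = 0.005\,\tau$
($\tau = \sqrt{m\sigma^2/\epsilon}$) and the stochastic
velocity-rescaling (v-rescale) thermostat at $T = 1\,\epsilon/k_B$.  The
coupling time is a free choice of this implementation; the default is $100\,dt = 0.5\,\tau$, weak enough not to distort
diffusive dynamics, and recorded in every run configuration.  The
thermostat rescales all velocities by a common factor, so the total
momentum (zero by construction at initialization) is conserved; a
Langevin thermostat is deliberately not offered because its uncorrelated
random forces suppress the diffusion of large aggregates.  With the
thermostat disabled the integrator is symplectic; the test suite bounds
the energy drift of a WCA fluid over $10^4$ steps at 1% of the mean
kinetic energy.

## Building and equilibrating systems

`build_random_system()` inserts chains as self-avoiding random walks
with fixed bond length $\sigma$ and a $0.9\,\sigma$ overlap threshold
(bounded retries, then an explicit density error), adds the neutralizing
ions at random non-overlapping positions, and draws Maxwell–Boltzmann
velocities with the centre-of-mass motion removed.  A fixed seed gives a
bitwise-identical state.

`relax_and_equilibrate()` follows the preparation protocol: 100 MD steps
with a soft-core repulsion, implemented as a per-bead force cap (any
bounded-force relaxation serves the same purpose), then steepest-descent minimisation (which never accepts an uphill move),
then thermostatted equilibration.  `build_equilibrated_system()` applies
the full mixing protocol: polycations with co-ions and RNA with
counterions are prepared and equilibrated in two separate boxes of the
final edge, merged, and relaxed and equilibrated again.
`build_aggregated_start()` produces the complementary start state: it
takes a converged isoelectric frame, in which all chains form one
aggregate, and adds polycations and co-ions around it to reach a target
charge ratio $\ge 1$.

## Nanoparticle observables

A nanoparticle is the transitive closure of the chain-chain contact
relation: two chains are linked when any inter-bead minimum-image
distance is below $3.5\,\sigma$.  Chains, not beads, are the clustering
unit, and an isolated chain is a single-chain NP.  Ions within
$3.5\,\sigma$ of a member polymer bead belong to the NP's ion shell.
The observable conventions are deliberately mixed — each observable uses
the particle set its physics calls for:

* gyration tensor, $R_g$ and $\kappa^2$ over **polymer beads only**;
* Kirkwood hydrodynamic radius
  $1/R_h = \frac{1}{N(N-1)}\sum_{i\neq j} 1/r_{ij}$ and the NP charge
  over **polymer beads plus the attached ion shell**;
* the $\zeta$-potential over **all charges in the frame**, through the
  radial cumulative charge profile $Q(r)$ about the NP's centre of mass:
  $\zeta = l_b \int_{R_h}^{50\sigma} Q(r)/r^2\,dr$ in units of
  $\epsilon/e$.  $Q(r)$ is a step function over the exact sorted
  distances and the integral is evaluated in closed form over each step
  — an exact quadrature of the profile, preferred here over a numerical
  one.

Gyration metrics require coordinates unwrapped within the cluster:
chains are unwrapped along their bonds, then placed breadth-first,
shifting each chain so its closest contact sits at the minimum image of
an already-placed bead; attached ions follow their nearest member bead.
This is valid while the cluster diameter stays below half the box
diagonal, which holds at the scales simulated here; a percolating
aggregate would need a different reconstruction.

### Counterion condensation

`manning_fraction()` measures the fraction of backbone charge
neutralized by condensed counterions — the number of counterions within
a binding cutoff of any RNA bead over the number of RNA beads — to be
compared with the Manning value $\phi = 1 - \sigma/l_b \approx 0.144$.
The condensation cutoff is a genuine modelling choice: the NP ion-shell
cutoff ($3.5\,\sigma \approx 3\,l_b$) also sweeps up diffuse-layer ions
and overestimates the condensed fraction by half or more, so the default
is the Bjerrum association criterion $2\,l_b \approx 2.34\,\sigma$, the
distance below which an ion pair is bound by more than $k_BT/2$.  Note
the estimator counts **ions**, not beads-with-an-ion-nearby: one contact
ion lies within a few $\sigma$ of several consecutive backbone beads, so
a bead-fraction estimator saturates far above $\phi$.

## Ensemble statistics

The state of the system is summarized by $n^*_{NPs}$: the number of
RNA-containing NPs divided by the number of RNA chains.  Free polycation
clusters are excluded — the order parameter saturates at 1 in polycation
excess, which forces this reading — and at $\alpha N/P = 0$ each bare
RNA chain counts as one NP.  `free_energy_profile()` histograms the
series in bins of width $1/N_{RNA}$, converts to
$F = -k_BT\ln\hat P$, and fits a quadratic over the bins within
$2\,k_BT$ of the minimum (a window chosen to weight the well around the
minimum).  The reported minimum
is the parabola's vertex.

`np_star_transform()` implements the excess charge-ratio rescaling
$\alpha N/P^* = (\alpha N/P - 1)\,c_{RNA}/c_{ref} + 1$ and its N/P
analogue with $N/P_{iso} = 1/\alpha$ (2 at 50% protonation; 1.7 is the
experimental value from the sign change of the $\zeta$-potential).
Above the isoelectric point the system is governed by the excess
polycation concentration, so curves recorded at different RNA
concentrations collapse on the starred axis; the identity is exact
algebra and is tested property-style.

`sweep_summary()` averages per-NP metrics over the equilibrated window —
the second half of the frames — per replicate first, then across replicates (mean ± sd).  Averages are
unweighted per NP by default; RNA-mass weighting is available and
recorded in the output.

## Desk-scale study conditions

The production scale of the model (up to $3000$ polycation chains,
$(200\,\sigma)^3$ boxes, $2\times10^8$ steps, several replicates) is
encoded in the `"production"` preset of `run_config()` but is not what
the tests run.  The test suite uses desk-scale conditions chosen once (the
analysis drivers under `analysis/` sweep a similar small grid at
$l_{RNA} = 30$ so a whole charge-ratio scan stays affordable):

* 2 RNA chains of 50 beads with $l_{PEI} = 10$, keeping the chain-length
  hierarchy $l_{RNA} \gg l_{PEI}$ of production-scale systems at reduced
  size.  This hierarchy matters: each RNA must bind several polycations
  for bridging to drive aggregation.  With $l_{RNA} = l_{PEI}$ the
  isoelectric state is a set of inert 1:1 neutral pairs and no
  system-wide aggregation occurs, and at $l_{RNA}/l_{PEI} = 3$ the
  two-chain aggregate is only marginally stable — both observed in
  scoping runs, consistent with the known requirement of a minimum polycation length
  for aggregation.
* box edge $22\,\sigma$ for assembly runs — an elevated concentration
  ($\sim 100\times$ the production bead density) so that chain
  encounters fit in $10^5$-step runs; the dissolution scan in polycation
  excess uses the production density
  ($c_{RNA} = 10^{-4}\,\sigma^{-3}$, box edge $58.5\,\sigma$ for 20
  nucleotides), where transient NP-NP contacts are rare.
* $10^4$-step equilibration, $0.5$–$2\times10^5$-step production, and a
  single replicate per condition, with one fixed master seed per run.
* a dilute single-chain box (50 nucleotides, box edge $70\,\sigma$) for
  the condensation measurement.

What the generator emulates: random well-mixed initial conditions,
exact ion bookkeeping, the equilibrium fluctuations of small clusters.
What it does not: the slow coarsening of many-chain systems, finite-size
scaling of the aggregation peak, replicate-to-replicate spread (tests
run one replicate), or any sequence-, stiffness- or pH-dependence of real
RNA and real polycations.  A passing suite therefore demonstrates the
mechanism — condensation below the isoelectric point, aggregation at it,
dissolution into single-RNA particles in excess — not quantitative
agreement with any particular experiment.

## Numerical choices and degenerate inputs

* Ewald accuracy $5\times10^{-4}$ for production dynamics, $10^{-7}$ for
  oracle checks; the interpolation table adds an error well below the
  splitting error.
* Neighbour handling: a Verlet pair list with $0.4\,\sigma$ skin,
  rebuilt when the largest displacement exceeds half the skin.
* Minimisation: steepest descent with an adaptive step, stopping at a
  force norm of $10^{-3}$ or when the step underflows.
* Single-bead NPs report $R_g = 0$ and flag $\kappa^2$ as undefined
  (`NA`); $R_h$ is flagged below two items; the $\zeta$ integration
  errors out if $R_h$ reaches the $50\,\sigma$ cutoff.
* Empty free-energy bins carry no value; a single occupied bin reports
  the bin as the minimum with no fit.
* The order parameter and clustering are independent of chain
  enumeration order and rigid translations (tested).

## Known limitations

* No hydrodynamic interactions: diffusion arises from ion collisions
  only, so time scales map to experiment only qualitatively.
* Fixed protonation: no constant-pH response, no titration.
* Linear chains only; no branched polycations.
* The cluster unwrapping assumes non-percolating aggregates.
* Desk-scale free-energy profiles resolve only a few $n^*_{NPs}$ bins;
  curvatures from the quadratic fits are meaningful at production scale,
  not at 2 RNA chains.
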