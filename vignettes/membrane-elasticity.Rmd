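---
title: "Measuring membrane elastic constants by Monte Carlo simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring membrane elastic constants by Monte Carlo simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(memelast)
```

## The model

`memelast` simulates a coarse-grained single-tail lipid: one head bead
followed by six tail beads, with a head/tail size ratio of 1.1/1.  All
quantities are in reduced units -- energies in $\epsilon$, lengths in
$\sigma_{LJ}$ (the tail-bead diameter), $k_B = 1$, so temperature is in
$\epsilon/k_B$ and pressure in $\epsilon/\sigma_{LJ}^3$.

Three potentials define the force field (`forcefield_params()`):

* **FENE bonds** between adjacent beads of a chain,
  $V_{FENE}(r) = -\tfrac{\nu_{FENE}}{2}\,\Delta r_m^2
  \ln\!\big[1 - ((r - r_0)/\Delta r_m)^2\big]$,
  with $\nu_{FENE} = 100$, $r_0 = 0.7$, $\Delta r_m = 0.2$.  The bond is
  finitely extensible: the energy diverges as $|r - r_0| \to \Delta r_m$,
  and any trial move that would leave this domain is rejected outright.
* **Bond-angle stiffness** for each triple of adjacent beads,
  $V_{ba}(\theta) = \nu_{ba}(1 - \cos\theta)$ with $\nu_{ba} = 4.7$ and
  $\theta = 0$ for a straight chain.
* **Shifted soft-core pairs** between all non-bonded beads,
  $V_{sc}(r) = [V_{LJ}(r) - V_{LJ}(r_c)]\,\theta(r_c - r)$ with
  $V_{LJ}(r) = \epsilon[(\sigma/r)^{12} - 2(\sigma/r)^6]$.  Tail--tail
  pairs attract ($\sigma = 1$, $r_c = 2\sigma$); head--tail
  ($\sigma = 1.05$) and all head--head / solvent--lipid pairs
  ($\sigma = 1.1$) are cut at $r_c = \sigma$ and hence purely repulsive.
  The solvent is *phantom*: solvent--solvent pairs do not interact at
  all, so the solvent exerts pressure on the membrane without any liquid
  structure of its own.

Two conventions are fixed for reproducibility rather than physics: the
Heaviside factor uses $\theta(0) = 0$ (the interaction vanishes exactly
*at* the cutoff -- the potential is continuous there, so the choice is
inconsequential but bit-stable), and directly bonded beads are excluded
from the soft-core sum (the FENE term replaces it) while second and
further neighbours along a chain do interact.  The exclusion is a
constructor flag (`exclude_bonded`) should a user want the other
convention.

## Phases and initial construction

Three state points are preset (`phase_point()`): gel ($P = 2$,
$T = 1.08$), fluid ($P = 1$, $T = 1.3$) and interdigitated ($P = 0.5$,
$T = 1.16$), each with a slightly raised annealing temperature (1.2,
1.4, 1.3) used only in the rescaling protocol.

`build_bilayer()` places straight-chain lipids on a square lattice in
two leaflets, heads outward, all bonds at $r_0$ and all angles zero, and
fills two solvent slabs above and below the membrane.  The initial area
per lipid defaults to the phase's equilibrium value, which shortens
equilibration; the solvent density defaults to the ideal-gas value $P/T$
of the phase so the starting box is already near pressure balance.  For
the interdigitated phase the two leaflets are offset by half a lattice
vector and overlapped by four bond lengths so opposing tails
interpenetrate; this construction is a reasonable ansatz, not a claim
about how such a state forms spontaneously.  The builder guarantees no
active pair starts below $0.8\,\sigma_{pair}$ and refuses infeasible
packings.

Periodic boundaries are applied on **all three axes**.  Laterally they
are required; in $z$ the choice is ours: the NPT box moves need a
defined, fluctuating $z$ extent, and a periodic phantom-solvent slab is
the simplest consistent option.  A confined (walled) $z$ boundary would
be equally defensible; nothing downstream depends on the difference as
long as the solvent slab is thick enough that the membrane never
interacts with its own image.

## The Monte Carlo engine

`run_mc()` samples the isothermal--isobaric (NPT) ensemble.  One
*sweep* attempts one displacement per bead (uniform in a cube of
half-width `displacement_max`) followed by one box move per non-fixed
axis.  Box moves step uniformly in $\ln L$ and rescale all coordinates
affinely along that axis; they are accepted with
$\min\{1, \exp[-(\Delta U + P\Delta V - N T \ln(V'/V))/T]\}$, which for
a logarithmic proposal makes the phantom gas satisfy
$\langle V\rangle = N T/P$ exactly -- the analytic oracle used in the
tests.  Displacements use plain Metropolis acceptance.  We interpret a
"Monte Carlo step" as one sweep; all protocol step counts are exposed as
configuration values.

Step-size adaptation (towards 40 % displacement acceptance) exists but
is off by default and must only ever be used during equilibration:
adapting proposal widths on the fly breaks detailed balance, so the
production and relaxation runs freeze all step sizes.

Energies are tracked incrementally (local recomputation around a moved
bead, full recomputation for box moves) over cell lists with cell edge
at least the largest cutoff ($2\,\sigma_{LJ}$); small boxes fall back to
brute force.  The running energy is validated against from-scratch
recomputation to $10^{-6}\,\epsilon$ in the test suite, and the whole
trajectory is a deterministic function of one seed.

## Measuring the Poisson's ratio

The Poisson's ratio $\nu_{ij} = -\Delta L_i / (\eta_j L_i)$ is measured
by `measure_poisson()` in four steps:

1. a baseline run fixes the pre-strain equilibrium lengths $L_i(0)$ as
   the mean over its last quarter (an instantaneous baseline would
   inject box-fluctuation noise directly into the strain denominator);
2. all inter-particle distances and the box along the strained axis are
   rescaled so the strained length is exactly $(1 + \eta)L_{axis}(0)$;
3. the system relaxes with the strained axis *fixed*, first for 400
   sweeps at the phase's annealing temperature (the bump restores
   mobility right after the affine deformation), then at the phase
   temperature;
4. the transverse traces $-(L_i(t) - L_i(0))/(\eta L_i(0))$ are averaged
   over the plateau after a 5000-sweep burn-in, with block-averaged
   standard errors and a linear-slope convergence flag
   ($|\mathrm{slope}|$ must stay below stderr/window).

Strain is never applied along $z$: laterally, a rescale opens free
volume *between* molecules, but along the membrane normal it would
stretch the bonds *inside* each lipid and break them.  The transverse
$z$ response is reported twice -- from the box length $L_z$ and, when
descriptor sampling is enabled, from the membrane thickness -- because
the box height is dominated by solvent and the two need not agree; the
discrepancy is surfaced, not averaged away.

The default strain is $\eta = 0.05$.  The estimate must be independent
of $\eta$ inside a working range (too small: no free volume opens; too
large: the membrane is damaged); `scan_eta()` automates that check, and
the acceptance tests verify $\eta$-independence on the spring-lattice
oracle at $\eta = 0.05$ versus $0.10$.  With $\eta = 0$ the protocol
degenerates into a control run whose "traces" are raw relative length
changes; their plateau average must be consistent with zero.

### The analytic oracle

A periodic 2D triangular lattice of identical central-force harmonic
springs (`make_triangular_network()`) has a continuum Poisson's ratio of
exactly $1/3$.  The protocol is run on it unchanged -- springs simply
replace the FENE bonds, there are no angles and no pair interactions --
which both validates the machinery end-to-end and demonstrates that the
method is agnostic to what the surface is made of.  At finite strain the
lattice softens ($\nu \approx 1/3 - 0.22\,\eta$ from static
minimisation), so MC estimates a hair below $1/3$ are expected, not a
bug.  The static minimisation oracle lives in the test helpers and is
entirely independent of the engine.

## Bending rigidity from the undulation spectrum

For small fluctuations the Helfrich free energy in Monge gauge,
$H = \int dx\,dy\,[\tfrac{k_c}{2}(\nabla^2 h)^2 +
\tfrac{\sigma}{2}(\nabla h)^2]$, predicts the mode powers
$\langle|\hat h(q)|^2\rangle = k_B T L^2 / (k_c q^4 + \sigma q^2)$.

`height_field()` grids the lateral plane at a 2 $\sigma_{LJ}$ target
spacing, takes the mean head-bead height of each leaflet per cell, and
defines the local height as the leaflet midplane with the grid average
subtracted.  Cells empty in one leaflet are filled by iterating the
average of their non-empty periodic 4-neighbourhood (with an error above
10 % empty -- a ruptured membrane is not an analysable one).

`power_spectrum()` fixes the discrete-transform normalisation by
contract rather than convention:
$\hat h(q) = A_{cell}\sum_{ij} h_{ij} e^{-i q\cdot r_{ij}}$, chosen so
Parseval's identity
$\sum_q |\hat h(q)|^2/(L_xL_y) = A_{cell}\sum_{ij}h_{ij}^2$ holds
exactly (asserted to $10^{-10}$) and the Helfrich prediction applies
with no hidden cell-area factor.  The round trip through the synthetic
sampler (below) validates the convention independently.

`fit_helfrich()` inverts the spectrum:
$y(q) = k_BT L^2/(\langle|\hat h|^2\rangle q^2) = k_c q^2 + \sigma$ is
linear in $q^2$, fitted by least squares over $0.5 \le q^2 \le 1$ --
below that window finite-size effects distort the modes, above it the
bead discreteness does.  Modes are radially binned (bin width
$2\pi/\max(L_x, L_y)$) and the bins weighted by the number of modes they
average, which is what calibrates the intercept's standard error.  A fit
with $k_c \le 0$ is flagged as failed; a single-frame fit is flagged
undersampled.

`make_helfrich_ensemble()` draws i.i.d. frames whose modes follow the
Helfrich distribution exactly (complex Gaussian amplitudes,
Hermitian-symmetrised so fields are real to $10^{-12}$).  It is
simultaneously the fit's sampling oracle -- the fitted $k_c$ must
recover the generator's $k_c$, verified at 5.2, 7.6 and 10.56 $\epsilon$
within 10 % per run and 3 % in the mean over 20 repetitions -- and a
fixture generator for everything downstream of `height_field()`.

## The Young's modulus

For a thin isotropic plate, $k_c = E d^3/[12(1 - \nu^2)]$;
`young_modulus()` inverts this.  With the measured fluid-phase constants
($k_c = 5.2\,\epsilon$, $\nu = 0.50$, $d = 5.48\,\sigma_{LJ}$) it gives
$E = 0.28\,\epsilon/\sigma_{LJ}^3$, and for the interdigitated phase
($k_c = 7.6$, $\nu \approx 0.40$, $d = 4.86$) $E = 0.67$.  Where the two
in-plane ratios of the interdigitated phase differ in the last digit
(0.40 vs 0.39) their mean enters the relation; both round to the same
modulus.  `phase_report()` assembles the per-phase summary and applies
an isotropy gate: the relation is meaningless for an anisotropic
membrane, so E is withheld whenever $|\nu_{xy} - \nu_{yx}|$ exceeds
twice the combined standard error -- which is exactly what happens in
the gel phase, where the tilted chains make the two directions
inequivalent.  The thickness entering the relation is the spectrum run's
mean thickness, not the tabulated equilibrium value, so that all three
ingredients share a lineage.

## Membrane descriptors

No universal formulas exist for the tabulated structural observables, so
`membrane_descriptors()` fixes the standard definitions: area per lipid
$A = L_xL_y/N_{leaflet}$; thickness $d$ as the distance between mean
head heights of the leaflets; mean chain length as the head-to-terminal
tail distance; and the chain order parameter
$S_z = \langle (3\cos^2\alpha - 1)/2 \rangle$ over tail--tail bonds,
$\alpha$ measured against $z$.  Leaflets are re-identified at every
measurement from the sign of the head height relative to the
instantaneous midplane, so flip-flopped lipids are handled; the
identification errors out if the head-height distribution is not
bimodal, which doubles as a rupture detector.

## Problem sizes and what the tests do (and do not) show

Production-scale runs of this model ($64\times 64$ lipids per leaflet,
$2\times 10^6$ sweeps, 17000--72000 solvent beads) are supported by
configuration but are cluster work.  The package's own test suite runs
desk-scale versions chosen to keep the full suite under a few minutes of
compute per module: $8\times 8$ bilayers over $2\times 10^4$ sweeps for
membrane integrity, a 144-node spring lattice over $1.5\times 10^4$
sweeps for the protocol oracle, 200 phantom beads for the barostat, and
$64\times 64$-grid synthetic ensembles of 500 frames for the spectrum.

At that reduced scale the fluid bilayer's area per lipid, thickness and
chain length land close to the production-scale reference values
($A \approx 1.6\!-\!1.7$, $d \approx 5.5\!-\!5.7$,
$\bar l \approx 3.3$), while the chain order parameter settles lower
($S_z \approx 0.25\!-\!0.3$ versus 0.42): a $10\,\sigma_{LJ}$ patch
started from a fully ordered state and run for $10^4$-sweep stretches
probes a different point of the finite-size, finite-time crossover than
a $2\times 10^6$-sweep production run.  Passing desk-scale tests
therefore demonstrates the *machinery* -- correct ensemble, correct
estimators, correct fits against analytic oracles -- not quantitative
phase-diagram reproduction, which needs the production sizes.

The synthetic Helfrich ensemble deliberately omits features of real
membrane data: protrusion and thickness-fluctuation modes, frame-to-frame
correlation, and leaflet asymmetry.  Conclusions about the fit apply to
real trajectories only at sampling strides long enough that frames
decorrelate (the default stride is 100 sweeps).

## Known limitations

* The gel phase's in-plane anisotropy depends on the tilt direction
  relative to the box axes; the package measures whatever tilt the
  equilibrated configuration has and does not steer it.
* The $\nu_{z*}$ estimates from the box height are solvent-dominated;
  prefer the thickness-based trace for membrane physics.
* No electrostatics, double-tail lipids, interacting solvent, shear
  deformations or finite-strain elasticity: the scope is the linear
  response of this model family.
* The midplane-based leaflet assignment assumes the membrane does not
  drift across the periodic $z$ boundary during an analysis run.
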