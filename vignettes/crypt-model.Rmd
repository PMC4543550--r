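---
title: "A subcellular-element model of the intestinal crypt niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A subcellular-element model of the intestinal crypt niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryptsem)
```

# The model

`cryptsem` simulates the epithelium of a single small-intestinal crypt as a
hybrid stochastic system with three coupled layers:

1. **Cell mechanics** (subcellular element method). Each cell is a cluster
   of N = 20 point elements. Elements of the same cell attract through a
   harmonic spring potential V = mu (r - r0)^2 / 2 (mu = 2.5, r0 = 1.5 um,
   no cutoff), which makes an isolated cell round up into a compact,
   roughly spherical blob. Elements of different cells interact through a
   Lennard-Jones potential V = eps ((sigma/r)^12 - (sigma/r)^6)
   (eps = 0.05, sigma = 4.5 um, hard cutoff at 10 um): short-range
   repulsion gives cells volume exclusion, the medium-range attraction
   mimics cadherin adhesion. The crypt wall is a rigid "test tube" — a
   hemisphere of radius 30 um continued by a cylinder up to the 160 um
   rim — to which elements adhere with a force eps_external * r (toward
   the nearest wall point, within half a cell diameter) and along which
   near-wall elements feel a vertical drag that rescales their provisional
   z-velocity by (1 + b_z) = 0.7. Paneth cells additionally migrate toward
   the crypt base at a fixed speed along the downhill wall tangent, the
   model's account of Eph/ephrin-driven sorting; all other cells ride the
   proliferative conveyor passively upward.

2. **A diffusible, Paneth-derived Wnt field.** Every element of a Paneth
   cell secretes Wnt at a fixed rate. The field obeys
   dc/dt = div(D grad c) + S - d c on a regular grid masked to the
   epithelial shell (between the wall and a lumen surface one cell
   diameter inward): the basement membrane and the lumen are impermeable,
   which is implemented by zero diffusivity outside the shell rather than
   by boundary conditions on a curved surface. Cells themselves obstruct
   diffusion: the local diffusivity falls linearly with the local element
   density, saturating to zero at three times the nominal in-cell density
   (the packed epithelium compresses cells below their nominal diameter,
   so its mean density already exceeds the nominal in-cell value; a lower
   saturation would seal the shell entirely, while the chosen value
   roughly halves transport through tissue and blocks it only in genuine
   pile-ups). Sources are
   spread to the eight surrounding nodes by cloud-in-cell weighting;
   cells read the field back by trilinear interpolation, averaged evenly
   over their elements.

3. **Lineage rules.** Each cell carries a Wnt exposure I_wnt (local field
   plus a mesenchymal gradient 1 - z/H, non-dimensionalized to [0,1]), a
   Notch activity I_notch (the sum of ligand weights over contacting
   neighbors: 0.35 per Paneth, 1.0 per Goblet contact; two cells are in
   contact when any pair of their elements lies within 6 um, just beyond
   the inter-cell equilibrium separation of 5.05 um, so relaxed touching
   neighbors count), and a BMP exposure from an opposing gradient z/H. Fate follows the lineage map:
   a stem cell with I_wnt >= 0.85 stays stem if Notch-activated
   (>= th_notch) and terminally differentiates into a Paneth cell
   otherwise; a stem cell below the Wnt threshold differentiates into an
   absorptive enterocyte (Notch-active) or a secretory Goblet cell.
   Paneth identity is terminal. Differentiated cells transition only
   reversibly between the Goblet and enterocyte fates with Notch — both
   stem re-entry and direct differentiated-to-Paneth conversion are off by
   default (a configuration flag restores the raw threshold table; with it
   on, near-threshold Goblet cells next to the niche convert to Paneth and
   seed a self-propagating ectopic Paneth wave up the wall, which is why
   the lineage restriction is the default). Only stem cells divide (cycle ~ truncated Normal(24, 4) h on
   [20, 28]), and only while their BMP exposure is below 0.15. Cells are
   removed at the rim, on detachment from the wall (anoikis, after one
   update of grace), and Paneth cells at the end of a truncated
   Normal(8, 2)-week lifetime.

This combination produces the known organization: a stem/Paneth
checkerboard at the base maintained by Notch lateral inhibition, a
differentiated upper crypt, and a niche boundary where the global Wnt
gradient crosses threshold — z = 24 um, about 4.1 cell diameters of wall
arc. The scientific point of the model is the interplay of expansion and
repression: Paneth-derived Wnt is a positive feedback (stem cells make
Paneth cells, whose Wnt sustains more stem cells) that, if strong enough,
expands the niche without bound; BMP inhibition of proliferation and the
active downward migration of Paneth cells are the negative regulators that
hold it in check.

# Units, mobility, and integration

All lengths are micrometres; the printed mechanical constants (r0 = 1.5,
sigma = 4.5, cutoffs 10 and 5) are coherent with the 10 um cell diameter
on this scale. Time is carried in hours internally (one mechanical step
dt_mech = 3.6 s = 1e-3 h; each chemistry substep is 0.0036 s, 1000 per
mechanical step, giving the explicit-stability ratio
D dt / h^2 = 0.036 at 1 um spacing).

The equation of motion is overdamped: velocity proportional to force. The
proportionality (mobility) is an explicit parameter, default 60 um/h per
unit force, i.e. the potential gradients are read as velocities in um per
*minute*. The choice is a timescale argument: cell rearrangement in an
epithelium should be fast compared to the cell cycle, so that the tissue
stays a packed monolayer and renewal is limited by division, not by
friction. At mobility 60 the spring relaxation time is a few minutes, the
forward-Euler stability factor is 2 mu mobility dt = 0.3 < 1 (smooth,
monotone relaxation), and the emergent conveyor speed up the crypt wall
(set by stem-cell production, not by the mobility) renews the epithelium
over days. A much smaller mobility makes the model qualitatively wrong,
not just slow: division then outruns relaxation, the base piles into
multilayers and sheds cells by anoikis instead of feeding the conveyor.

Two numerical guards keep the cheap explicit integrator robust. The
Lennard-Jones repulsion is capped below r = 0.5 sigma (overlapping
elements appear whenever a cell divides), and each element's per-step
displacement is clamped at 0.5 um, so freshly divided cells separate
steadily instead of exploding. The rigid wall is impenetrable: an element
pushed through it is projected back onto the surface. Pair interactions
use a Verlet list (skin 3 um) over a spatial hash, rebuilt when the two
largest element displacements since the last build sum past the skin; a
brute-force all-pairs oracle in the test suite checks exact agreement,
including the exact zero beyond both cutoffs.

# The Wnt field: calibration and solvers

The diffusion constants are D = 1e-7 cm^2/s = 10 um^2/s and
d = 1e-3 /s, giving a decay length sqrt(D/d) = 100 um. Concentration is
dimensionless (the same scale as the [0,1] gradients); the secretion rate
is therefore fixed by a functional criterion rather than by units. In one
dimension the steady state of a point source with flux P at the origin is
W_ss(x) = P/sqrt(dD) exp(-sqrt(d/D) x), so the *base* (100%) production
is the P with W_ss(12.5 um) = 0.85: a source just strong enough to hold a
neighbor 1.25 cell diameters away at the differentiation threshold
(`calibrate_base_production`; the closed form is cross-checked against a
ghost-node finite-difference solve, and the threshold crossing of the
numerical profile is the package's principal calibration check).

Inside the simulated crypt the calibration is anchored to the same
functional meaning rather than to the 1D profile, which does not transfer
to a three-dimensional masked field (a planar source is far stronger at
equal flux, and with a 45–100 um decay length the fields of all the
niche's Paneth cells superpose, so no single-source criterion fixes the
biologically meaningful scale). `calibrate_local_rate` therefore
calibrates against the assembled niche: it solves the quasi-steady field
of the initial state's actual Paneth cells at unit rate — on the run's
own grid, with the run's density-reduced diffusivity — computes every
stem cell's element-averaged exposure exactly as the lifecycle does, and
fixes the per-element rate so the *median* stem exposure is th_wnt/1.25.
The margin of 1.25 is the one by which the 12.5 um calibration distance
exceeds one cell diameter: at the base (100%) rate the niche's own Wnt
leaves its typical stem cell 25% short of threshold, so removing the
exogenous gradient collapses the niche, while at 150–200% the local
source alone holds the median stem above threshold and the two Wnt
sources are redundant. The field is linear in the rate, so one sparse
solve fixes the scale; `wnt_production_pct` (the experiments' 0–400%
axis) multiplies it.

Two solvers share one discretization (7-point stencil, harmonic-mean face
diffusivities, so a zero-diffusivity node seals its faces and mass cannot
leak into the lumen or through the membrane; concentrations are clamped
at zero, where coarse grids can undershoot near sharp sources). The
explicit forward-Euler stepper is the reference and refuses to run outside
its stability bound. The quasi-steady mode solves
div(D grad c) - d c + S = 0 directly with a sparse Cholesky factorization;
it is the practical engine mode because the field relaxes in minutes
(1/d ~ 17 min) while lineage decisions unfold over hours. The test suite
holds the two within 3% of each other on a single-source configuration.

# Initialization

A crypt is generated, not loaded: two identity-free cells are seeded at
the base pole and run under mechanics, growth and division alone until
their descendants cover the wall up to the rim. Two construction devices
keep this phase honest and affordable: a shortened division interval
(half an hour; nothing measured depends on the construction timescale) and a
confluence gate — a packing cell divides only if fewer than six cell
centroids lie within one cell diameter, which concentrates divisions at
the advancing front and fills the tube as a monolayer. Identities are
then assigned canonically: below the height where the deterministic
global gradient crosses threshold, a greedy maximal independent set of
the contact graph becomes Paneth with the rest stem (every stem cell
touches a Paneth cell — the checkerboard); above, the same construction
with Goblet/enterocyte. Cycle timers start at uniformly random fractions
of freshly drawn cycle lengths, Paneth ages at uniform fractions of their
lifetimes, and the initial chemical field at its quasi-steady state.

# Scenarios, metrics, classification

`run_scenario` wires the experiment switches: `local_wnt_sweep` (no BMP,
production 0–400%), `bmp_sweep` (BMP on), `global_wnt_removal` (run to a
detected steady state — trailing 12 h niche-height slope below 0.05 cell
diameters/h — then set the gradient to zero and continue),
`no_paneth_migration_1..4` (migration off against the four signaling
backgrounds), `drag_variant`, `fast_cycle` (cycle shortened 3 h),
`diffusivity_reduction`, and `noise_sweep` (multiplicative, spatially and
temporally uncorrelated Gaussian noise on both gradients, redrawn per cell
per lifecycle update; amplitudes 0–0.4). `run_ensemble` runs replicates
on consecutive seeds and reports per-time mean and standard deviation.

Niche height is the 95th percentile of stem-cell wall-arc coordinates in
cell diameters — a robust boundary estimate that a single dividing
outlier cannot move, measured along the wall because that reproduces the
"about four cells" extent of the default-threshold compartment.
`classify_stability` labels a trajectory `dies` (no stem cells at the
end), `unstable` (niche height reaches 90% of the wall arc, or trailing
24 h slope above 0.1 cd/h), else `stable`; both thresholds are exposed in
the configuration because the boundary between "slow growth" and
"expansion" is a reporting convention, not physics.

# Design decisions on open points

* **th_notch** is not part of the published parameter set; 0.3 is chosen
  so a single Paneth contact (0.35) activates Notch while no contact does
  not, which is exactly what the checkerboard requires. It is exposed in
  the configuration.
* **Contact** for Notch means any element pair within 6 um, just beyond
  the inter-cell equilibrium separation 2^(1/6) sigma = 5.05 um at which
  relaxed neighbors sit (a threshold below that separation detects almost
  no contacts in an uncompressed epithelium and collapses the
  checkerboard); exposed as `contact_distance`.
* **Paneth migration speed** (2 um/h) is set from a flux argument: the
  upward conveyor at homeostasis moves about 0.5 um/h (stem production
  over ring circumference), so 2 um/h lets Paneth cells hold station and
  sort downward; `calibrate_paneth_bias` re-derives it by bisection.
* **Element-wise secretion**: production is per Paneth *element* (the
  more specific of the two published statements), so a growing Paneth
  cell's output scales with its volume.
* **BMP gating** is evaluated at division time (not continuously), the
  natural reading of an inhibition of proliferation.
* **Growth schedule**: a cell below N elements adds one every
  cycle_length/(N/2) hours, so a daughter regains full size within one
  cycle; division additionally waits for full size, which keeps volumes
  bounded.
* **Detachment grace**: removal requires two consecutive updates out of
  wall contact, so a division transient cannot kill a cell spuriously.

# Problem sizes and what the tests show

The default parameters above are the simulator's study conditions. The
test suite exercises them at sizes chosen for a desk machine: unit and
property tests run on hand-built states and a reduced test tube; the
baseline-homeostasis check runs the full 160 x 60 um geometry for two
simulated days from a fresh initialization (one seed, quasi-steady
chemistry on a 2.5 um grid, lifecycle updates every 100 mechanical steps
= 6 simulated minutes); the regime contrasts (niche expansion without
BMP, BMP capping, gradient removal, migration deletion) run on a reduced
50 x 32 um tube for about one simulated day per arm from one shared
initial condition and seed, a paired design in which arms differ only by their
signaling switches. At these scales the takeover endpoint of the
unstable regimes (which the published ensembles reach over ten simulated
days) is not reachable; the tests assert the directional contrasts the
mechanisms produce — the stem front climbing without BMP, height
insensitivity to production under BMP, niche death versus survival after
gradient removal, and stem confinement with the redundancy precondition
of the catastrophic migration-deletion model. These scales demonstrate the
mechanisms — threshold geometry, positive feedback, BMP capping,
migration-dependent confinement — not the published ensemble statistics,
which were measured on ten-replicate, ten-day ensembles at 1 um grid
spacing on GPU hardware.

The synthetic initial condition emulates a healthy adult crypt at
homeostasis: full coverage, canonical checkerboard, desynchronized
cycles. It does not emulate villus architecture above the rim, crypt
fission or budding, +4 quiescent stem cells, transit-amplifying
divisions, cell polarity, a deformable basement membrane, or
density-dependent inhibition of proliferation outside the packing phase —
so passing tests say nothing about those phenomena.

# Known limitations

* The fate table is deterministic and instantaneous given the exposures;
  there is no transcriptional delay or hysteresis, so cells at a
  threshold boundary can flicker between fates on the lifecycle cadence.
* The quasi-steady chemistry assumes the field equilibrates between
  refreshes; with very fast perturbations of the source configuration the
  explicit mode is the reference.
* The rigid wall cannot deform, so phenomena that change crypt shape are
  outside the model by construction.
* The dynamics is deterministic and overdamped, with no mechanical
  fluctuations, so a confluent monolayer is effectively jammed: the
  Paneth migration bias reliably biases rearrangements where division
  churn opens space, but it cannot re-sort an already packed epithelium
  on its own. Migration-deletion experiments therefore express themselves
  at short horizons through confinement and signaling, not through large
  shifts of the Paneth position distribution.
* Mechanical parameters are phenomenological; only their ratios and the
  mobility timescale are constrained by the behaviors above.
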