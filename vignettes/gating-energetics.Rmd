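---
title: "Membrane-tension gating of curved-TMD mechanosensitive channels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-tension gating: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechgate)
```

# The model

MscK-family mechanosensitive channels carry a transmembrane domain (TMD)
that is curved in the closed, resting state: the arrangement of the TM
helices deflects the membrane midplane into a cone with bending angle
$\theta_c$ around the protein. Opening flattens and expands the TMD
($\theta_o < \theta_c$, in-plane radius $R_o > R_c$), so lateral membrane
tension $\sigma$ biases the channel open. Treating the channel as a
two-state system, the free-energy difference between the open and closed
conformations is

$$\Delta G(\sigma) = \Delta G_{\sigma=0}
  + \pi\left(\theta_c^2 R_c - \theta_o^2 R_o\right)\sqrt{\sigma K_b}
  - \sigma\,\Delta A,$$

where the middle term is the difference in midplane-bending energy of the
membrane deformation footprints, $K_b$ is the bilayer bending modulus, and
$\Delta A$ is the in-plane area expansion. Units are chosen so that no
$k_BT$ factor ever appears explicitly: energies in $k_BT$, tensions in
$k_BT/\mathrm{nm}^2$, lengths in nm, angles in radians. A single reporting
helper converts tensions to mN/m ($1\,k_BT/\mathrm{nm}^2 \approx 4.114$ mN/m
at 298 K).

With $\Delta G_{\sigma=0} = 0$ (the convention for midpoint estimates, kept
as an explicit argument everywhere else), the midpoint tension — open
probability 0.5 — solves
$\pi X \sqrt{\sigma K_b} = \sigma \Delta A$ with
$X = \theta_c^2 R_c - \theta_o^2 R_o$, giving the closed form

$$\sigma_{1/2} = \frac{X^2 K_b}{4 R_c^2 \Delta R^2}$$

when the expansion is annular, $\Delta A = 2\pi R_c \Delta R$. The package
implements both the closed form and an independent bracketing root finder
(`midpoint_tension()` / `midpoint_tension_root()`); their agreement to
$10^{-8}$ relative over randomized parameter sets is part of the test suite.
The full dose-response uses the minimal two-state Boltzmann completion
$P_\mathrm{open}(\sigma) = 1/(1 + e^{\Delta G(\sigma)})$.

Two properties of the model as written deserve flagging rather than
"correction". First, the bending term *opposes* opening at all tensions
(it is positive whenever $X > 0$ and grows as $\sqrt{\sigma}$), so
$\Delta G(\sigma)$ rises from zero before the $-\sigma\Delta A$ term wins:
$\Delta G$ is non-monotonic with exactly one positive zero. Second, because
the bending term vanishes at $\sigma = 0$, $P_\mathrm{open}(0) = 0.5$ when
$\Delta G_{\sigma=0} = 0$; a realistic resting closed probability requires a
positive intrinsic $\Delta G_{\sigma=0}$, which the midpoint analysis
deliberately omits. When $X \le 0$ there is no positive midpoint and the
parameter set is flagged ill-posed instead of silently returning a number.

## Canonical parameter set

`msck_parameters()` ships the MscK values deduced from the closed and open
structures: $\theta_c = \pi/6$, $\theta_o = \pi/12$ (30° → 15°),
$\Delta A = 54\ \mathrm{nm}^2$, $K_b = 20\ k_BT$. The published in-plane
expansion of 22 Å is read as a *diameter* change, so $\Delta R = 1.1$ nm and
$R_c = \Delta A/(2\pi\Delta R) \approx 7.81$ nm. This is the only reading
consistent with the printed midpoint: it reproduces
$\sigma_{1/2} = 0.159 \to 0.16\ k_BT/\mathrm{nm}^2$, an order of magnitude
below the MscL literature midpoint of $2.5\ k_BT/\mathrm{nm}^2$. Two
contributions are deliberately excluded, matching the scope of the estimate:
hydrophobic-mismatch energetics (MscK gating is near-isometric in membrane
thickness) and the intrinsic $\Delta G_{\sigma=0}$ (including the cost of
expanding the periplasmic ring, which would push the true midpoint higher).

```{r}
gp <- msck_parameters()
glance(gp)
```

# Measurement conventions

The published "~" values do not pin down operational definitions, so the
geometry module fixes one convention per quantity and exposes the knobs:

* **Midplane bending angle.** TM helices are represented by one point per
  membrane crossing: atoms inside the slab are split per chain into
  contiguous residue runs, and each run contributes its centroid. The angle
  is $\arctan|dz/dr|$ of the least-squares fit of centroid $z$ on radial
  distance $r$, pooled over subunits — a single robust number for the
  cone-like midplane deflection. The slab should span the full TMD
  z-extent; synthetic generators suggest one alongside their ground truth.
* **In-plane area and radius.** Area of the 2D convex hull of atom
  projections within a 6 Å band around the slab midplane;
  $R = \sqrt{A/\pi}$. Side chains are included by default.
* **TMD height.** The 2.5th–97.5th percentile z-span of slab atoms — robust
  to single-atom outliers, and ~5% below the literal extreme span on
  uniform columns (documented, tested).
* **Ring diameter.** Twice the maximal radial atom-center distance of the
  selection (outer diameter). Whether published ring dimensions include
  side chains is unstated, so the selection is an argument, not a constant.
* **Membrane slab.** Explicit bounds by default (32 Å hydrophobic
  thickness, user-overridable); a hydrophobic-belt mode slides a window
  along z and maximises the hydrophobic atom fraction. The published
  figures do not tabulate membrane boundaries, so no fixed value is baked
  in.

Closed→open deltas convert degrees to radians and Å to nm once, in
`compare_states()`; `params_from_states()` refuses silently inconsistent
input by flagging $|\Delta A - 2\pi R_c \Delta R|/\Delta A > 0.15$.

# Pore profiling

The sphere-probe profile is the classic pore-radius construction: at each
axial position the reported radius is the largest sphere, centred within a
bounded wander of the axis, that overlaps no atom. Unlike stochastic
implementations, the centre optimisation is a deterministic grid search at
half the axial step (defaults: step 0.5 Å, wander 5 Å), which makes profiles
reproducible and lets the test suite verify them against a brute-force
dense-grid oracle on random atom clouds. Radii are capped (default 15 Å)
where the pore opens into bulk; diameters are reported as twice the probe
radius with no solvent offset. vdW radii follow the Bondi set with
hydrogens ignored (deposited models of this family lack them); a
backbone-only mode exists but side chains are included by default since
bulky side chains (e.g. the W914 indole ring) define the gates.

Gates are local minima of the moving-average-smoothed profile with radial
prominence above a threshold (default 0.5 Å); boundary minima are judged on
their one existing side, so a monotone funnel yields its narrow end. Lining
residues are those within 1.0 Å of touching the probe sphere.

# Electrophysiology

Recordings are uniform time series of current (pA) and pipette pressure
(mmHg, suction negative) at constant holding voltage. The analysis chain
follows standard single-channel practice:

* **Filtering.** Zero-phase 4th-order Butterworth lowpass at 500 Hz
  (`filtfilt`), the package's equivalent of the Bessel filtering used on
  acquisition hardware.
* **Unitary conductance.** Baseline and first open level are the two
  lowest-magnitude dominant modes of the kernel-density amplitude
  histogram (ties resolve toward the lower level as baseline), refined by
  the median of slope-stable samples near each mode so filter ringing and
  overshoot do not bias the levels. $g = |i_\mathrm{open} -
  i_\mathrm{baseline}|/|V|$; the standard error comes from per-event
  amplitudes after half-amplitude idealization. With two stacked openings
  the unitary level is still the first conductance step.
* **First activation.** Current steps are detected as boxcar-mean jumps on
  the filtered trace (threshold at half the class band's lower edge); the
  first step whose amplitude falls in the class band gives the activation
  pressure. Amplitude classes derive from the expected $g|V|$ of each
  population bracketed by ±3 noise SD and must not overlap. A channel
  already conducting in-band at the trace start activates at the first
  sample.
* **Sensitivity ratio.** $P_\mathrm{calibrator}/P_\mathrm{test}$ of
  first-activation pressures on the same ramp — the in-patch calibration
  against a high-threshold channel (MscL) that removes patch-geometry
  unknowns. Pressures are reported as suction magnitudes; converting
  pipette pressure to absolute membrane tension would require patch
  geometry and is out of scope, as are dwell-time kinetics.

# Synthetic data: what it does and does not emulate

The generators provide analytic ground truth rather than realism.

**Structures** are pseudo-atom CA traces: per subunit, a few idealized
helices (small helical wind, uniform carbon radii) whose midpoints lie on a
cone of the requested angle; pore-lining atoms placed at exactly
(constriction radius + atom radius) from the axis so the on-axis probe
radius is exact by construction; a polar marker ring above the membrane for
orientation and ring-diameter tests; seeded Gaussian jitter applied after
ground truth is recorded. Residue names and numbers mimic the MscK gates
(TRP 914, VAL 921, PHE 925) so attribution logic is exercised end-to-end.
The default closed/open pair emulates the published gating transition: cone
30° → 15°, outer radius 78 → 89 Å, gate radii 2.5/4 Å → 10 Å, marker ring
154 → 178 Å. What these bundles do *not* have: real secondary structure,
side-chain geometry, loops crossing the slab boundary, or heterogeneity —
so passing recovery tests demonstrates correctness of the measurement
conventions, not robustness to real-structure pathologies.

**Recordings** ramp suction at 4 mmHg/s and open each channel copy sharply
at its threshold. Because a latched-open step carries no repeated openings,
channels may optionally flicker after activation (exponential open/closed
dwells, default 30 ms) — that is what gives the conductance estimator its
hundreds of events per trace. Multi-population traces use the sharp default;
a step detector working on ~10 ms windows can otherwise mis-measure the
single calibrator step when an independent flicker transition lands inside
the window, which is a real confound of amplitude-based idealization, not an
artifact of the simulation. No open-channel noise, drift, or missed-event
kinetics are modelled.

All randomness flows through one seed per artifact; identical seeds give
bit-identical output, and every artifact carries its generation ground
truth.

# Numerical choices and problem sizes

* Symmetry detection scans orders 2–12 over candidate axes (subunit-centroid
  plane normal plus principal axes), scoring each by atomwise RMSD under
  rotation by $2\pi/n$ with subunits matched by azimuth; among orders within
  noise of the best score the highest wins, so a C7 channel is not reported
  as a lower divisor. Alignment is rigid by construction (pairwise
  distances preserved to numerical precision), with the azimuth fixed by
  placing the first subunit centroid on +x.
* The midpoint root finder brackets by doubling, bisects to $10^{-12}$
  relative, then Newton-polishes, so closed-form agreement and
  $P_\mathrm{open}(\sigma_{1/2}) = 0.5$ hold to machine precision.
* Default validation sizes keep everything desk-scale: bundles of ~550
  pseudo-atoms, pore oracles on ≤500-atom clouds, 1000-set parameter scans,
  and 100×30 s simulated patches at 2 kHz.

```{r}
curve <- energetics_curve(msck_parameters())
autoplot(curve)
```

# Known limitations

* The deposited-structure route (closed 7UW5 / open 7UX1) shares every code
  path with the synthetic route but published "~" values and unspecified
  measurement conventions warrant a ±20% tolerance on those comparisons;
  cryo-EM map statistics are out of scope entirely.
* The hydrophobic-belt slab mode assumes a single contiguous belt; it will
  be misled by proteins with multiple hydrophobic bands.
* The pore profiler's bounded wander follows a straight axis; strongly
  curved conduction paths would need path-following, which MscS-family
  pores do not.
* The energetics model is two-state with a sharp annular footprint; no
  continuum membrane-footprint mechanics, no intermediate states beyond
  reporting their geometry deltas.
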