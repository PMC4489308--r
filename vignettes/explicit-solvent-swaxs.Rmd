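---
title: "Explicit-solvent SWAXS prediction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explicit-solvent SWAXS prediction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`solvaxs` predicts the buffer-subtracted SWAXS intensity of a solute from
two coordinate ensembles: the solute in explicit water, and a matched
pure-water box. Because both the hydration layer and the displaced solvent
are represented by explicit water configurations, no solvent-related
quantity is ever fitted; the only parameters ever adjusted against an
experiment are an overall scale $f$ and a constant offset $c$.

The calculation proceeds in four steps.

**1. Envelope.** A star-shaped closed surface is built around the solute
from an icosphere (regular icosahedron, each triangular face recursively
subdivided into four; depth 4 — 2562 vertices — by default). Each vertex is
displaced radially from the envelope center until it lies at least a
distance $d$ (7 Å by default) from every solute atom in every frame, by
maximizing, over atoms, the exit point of the ray from the union of
atom-centered spheres of radius $d$. The same envelope is reused for the
entire calculation. Only the electron density *inside* the envelope
contributes to the net intensity, which is what makes a finite simulation
box sufficient.

**2. Amplitudes.** For the atoms inside the envelope of each frame,
$\tilde A(\mathbf q) = \sum_j f_j(q)\, e^{-i \mathbf q \cdot \mathbf r_j}$
with Cromer–Mann form factors
$f_j(q) = \sum_{k=1}^4 a_k e^{-b_k (q/4\pi)^2} + c$. The analogous
$\tilde B$ uses the envelope contents of the pure-water system, overlaid in
the same coordinate frame.

**3. Net intensity.** Writing $\langle\cdot\rangle$ for the frame average at
fixed solute orientation,

$$D(\mathbf q) = \langle|\tilde A|^2\rangle - \langle|\tilde B|^2\rangle
  + 2\,\mathrm{Re}\left[-\langle \tilde B\rangle^*
  (\langle \tilde A\rangle - \langle \tilde B\rangle)\right],
  \qquad I(q) = \langle D(\mathbf q)\rangle_\Omega .$$

The three terms are the scattering of solute-plus-hydration-layer, the
scattering of the excluded solvent, and the correlation between bulk water
and the density contrast inside the envelope. When the same system is
supplied as both inputs, the three terms cancel identically — the package's
strictest self-test.

**4. Orientational average.** $\langle\cdot\rangle_\Omega$ is evaluated per
$|q|$ shell over $J_q = \max\{100,\ 0.2\,(qD)^2\}$ directions placed by a
deterministic golden-angle spiral, with $D$ the envelope diameter. An exact
brute-force Debye sum over atom pairs serves as the independent oracle for
this average in the test suite.

## Assumptions

* Frames are configurations of an equilibrated, position-restrained system:
  the solute stays in one orientation (the orientational average is done by
  quadrature, not by the trajectory) and solvent configurations are
  approximately uncorrelated between frames.
* The envelope must fit inside the pure-water box in every frame (checked);
  both systems must share one coordinate frame.
* Atom-wise envelope selection: a water molecule may be split by the
  boundary. The density decomposition partitions *density*, not molecules;
  whole-molecule selection is available behind a flag.

# Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| envelope distance `d` | 7 | Å | minimum vertex distance from solute atoms |
| icosphere depth | 4 | — | 2562 vertices; the figure-level default |
| `q_max`, `n_q` | 1, 101 | Å⁻¹, — | uniform q grid |
| buffer density | 334 | e nm⁻³ | target bulk density (pure water) |
| subtraction scheme | reduced | — | `total`: $I_{sam}-I_{buf}$; `reduced`: $I_{sam}-(1-v)I_{buf}$ |
| convergence | normal | — | frame count $N_{fr}=2\times10^5/N_A^{0.77}$; quick = /4, thorough = ×5 |
| equilibration | 5 %, ≥ 3 ps | ps | leading trajectory time discarded |
| Guinier window | $qR_g \le 1.3$ | — | iterated to self-consistency |

# Numerical choices

**Water form factors.** Water species (`OW`, `HW`) start as the O/H
Cromer–Mann entries rescaled so that $f(0)$ is exactly the integer electron
count: the raw tabulated sums are ≈ 9.9991 e per molecule, and both the
charge-conservation property of the water correction and the
density-correction bookkeeping (10 e per water) are exact-integer
statements. The electron-withdrawing correction then moves
$\alpha Z_H$ electrons per hydrogen into the oxygen with a Gaussian profile
$e^{-q^2/2\delta^2}$ ($\alpha = 0.48$, $\delta = 2.2$ Å⁻¹), conserving the
10 electrons at $q = 0$ identically. The correction is stored as a fifth
Gaussian, so the table representation is closed under it.

**Solvent-density correction.** The bulk density of the water model is
measured from the pure-water box (electrons at $q=0$ over box volume) and
the deficit to the target buffer density is added to the *constant* term of
the water-oxygen entry — a q-independent point charge at the oxygen site,
the simplest realization of "a small uniform electron density", applied
identically in both systems and never fitted. Because the water correction
only touches the Gaussian part and the density correction only the constant
term, the two operations commute (asserted in tests). An alternative
spreading over all three sites was considered and rejected as
indistinguishable at the q-resolution of the method's own quadrature error.

**Reduced buffer subtraction.** The exact correction used by the reference
implementation's ancestry is not public. Algebraically the reduced scheme is
$I_{\text{total}} + v\,I_{buf}$; for $I_{buf}$ this package uses the
*fluctuation* part of the excluded-solvent term,
$\langle|\tilde B|^2\rangle - |\langle\tilde B\rangle|^2 \ge 0$. The
coherent part $|\langle\tilde B\rangle|^2$ is the shape scattering of the
observation envelope — an artifact of watching a finite volume — which a
real buffer measurement does not contain; with it included the correction
would be dominated by the envelope shape at small angles instead of growing
toward the water-dominated wide angles. The choice is recorded in the curve
metadata as an approximation. $v$ comes from an explicit flag, or from
$V_{\text{solute}}/V_{\text{envelope}}$ when a solute volume is given (the
CLI falls back to 20 Å³ per heavy atom, a standard packing estimate).

**Quadrature.** The golden-angle spiral is deterministic and near-uniform
(nearest-neighbor angles within a factor 2 of the ideal $\sqrt{4\pi/J}$,
asserted in tests). At exactly the $J_q$ rule the residual quadrature error
on a rigid ligand-sized configuration is a few 0.1 % relative to the Debye
oracle. Note that the *buffer-subtracted* curve is a small difference of
large terms at wide angles, so its pointwise relative sensitivity to $J_q$
is amplified well beyond the per-term quadrature error when few frames are
used; convergence statements are therefore made (and tested) on the
vacuum-mode intensity.

**Fitting.** The error-weighted metric has a closed-form minimizer (2×2
weighted normal equations); the experimental curve is always transformed,
never the prediction, which has no free parameters. The log-space metric is
minimized by a coarse logarithmic grid over $f$ (optimal $c$ by
one-dimensional search on the feasible region $fI_{exp}+c>0$) followed by a
Nelder–Mead polish in $(\log f, c)$ — fully deterministic. When the
experimental curve carries no errors, the weighted metric is *not* faked
with unit weights; the fit falls back to the log metric with a warning.
The calculated curve is interpolated linearly onto the experimental grid;
points outside the computed range are dropped, never extrapolated.

**Guinier analysis.** Straight-line fit of $\ln I$ against $q^2$, window
iterated to self-consistency from the lowest 20 % of points under
$qR_g \le 1.3$ (the community-standard bound). For a uniform sphere this
window carries an inherent upward bias of order 1–2 % (the Guinier
approximation is exact only as $q \to 0$), which is why the analytic-sphere
acceptance check at 2 % tolerance is tight but honest. A constant positive
offset biases $R_g$ downward — asserted as a direction, and worth knowing
when the offset $c$ absorbs buffer-subtraction errors.

**Degenerate inputs.** Envelope rays that no atom constrains are floored at
a small positive radius (star-shapedness requires positive radii); the
envelope center is the mean solute position over all build frames, which
maximizes star-shapedness for globular solutes. Containment ties on the
surface resolve to *inside*.

# The synthetic generator

`generate_water_box()` / `generate_system_pair()` stand in for the MD
engine: rigid 3-site waters (O–H 0.9572 Å, H–O–H 104.52°, random
orientations) dart-thrown with a minimum O–O distance of 2.4 Å, frames drawn
independently. The solute (single atom, uniform sphere-cluster, or helix)
gets per-frame Gaussian jitter (default 0.3 Å, the scale of thermal motion
under backbone restraints); waters are excluded from solute-atom spheres of
radius 2.8 Å and the water count targets the bulk density in the remaining
free volume, so the far-field density matches the companion pure-water box.

What this emulates: configurational statistics with the right bulk density,
contrast and envelope geometry — everything the scattering code consumes.
What it does **not** emulate: hydrogen-bond structure of water (no realistic
O–O radial distribution or water peak near $q \approx 2$ Å⁻¹), a dense
hydration layer, frame-to-frame correlation, or counter-ions. A green test
on synthetic systems therefore validates the *machinery* — envelope
selection, amplitude assembly, the three-term combination, corrections and
fits — not the physics of hydration; that validation lives in the MD world
that is explicitly out of scope. Tests needing a hydration-density excess
impose it explicitly rather than pretending the generator produces one.

Ligand-sized defaults (20 atoms, 6 Å cluster radius) keep the quadrature
rule's floor of 100 directions comfortably converged; configurations tens of
Å across sit exactly at the rule's quadratic branch, where the residual
error at the rule is about 1 % — visible in the oracle-equivalence test if
the fixture is made much larger.

# Structure clean-up rules

Hetero molecules are classified per molecule, blacklist first: residue names
`GOL`, `BNG`, `BOG`, `PG`, `PE`, `PGE` are always crystallization agents
(this must precede the size rule, or long PEGs would be kept). Otherwise a
molecule is kept if it is covalently bonded to the biomolecule (< 1.9 Å
heavy-atom pair, 2.4 Å with S/Se/metals — standard covalent-radius
practice), forms > 2.5 contacts per heavy atom within 3.5 Å, has > 20 heavy
atoms, or is named `HEM`. `PG`/`PE` collide with phospholipid residue names
in some entries; the printed list is followed regardless, and `keep-all`
mode is the escape hatch. Selenomethionine is replaced by methionine
(SE→SD, Se→S, coordinates untouched) unless disabled. Ions always keep
their own element's form factor, even exotic ones a simulation engine would
substitute; neutral-atom Cromer–Mann entries are used throughout (ionic
entries were considered; the package exposes the table, so adding them is a
data edit, not a code change).

# Known limitations

* No resolution smearing, polydispersity, SANS variant, or ensemble
  reweighting.
* The reduced-scheme correction is approximate (see above) and flagged as
  such in output metadata.
* Statistical errors are jackknife estimates over contiguous frame blocks —
  a plumbing-level uncertainty, meaningful only when frames are roughly
  uncorrelated.
* The envelope guarantees the distance property at *vertices*; between
  vertices the interpolated surface may locally dip below $d$ (accepted: the
  guarantee is stated for vertices, and depth-4 faces are small).
* PDB is the only native format; other trajectory dialects must be converted
  or adapted upstream.
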