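---
title: "Methods: simulating an oesophageal electrode for cardiac EIT"
author: "oesoEIT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating an oesophageal electrode for cardiac EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Electrical impedance tomography (EIT) images internal conductivity from
boundary current injections and voltage measurements. With a circular belt
of skin electrodes, sensitivity is highest at the periphery and poorest at
the centre — exactly where the heart sits, shielded by the resistive lungs.
One proposed remedy is to move a single electrode into the oesophagus,
directly behind the heart. `oesoEIT` implements an in-silico comparison of
the two designs: sixteen electrodes all on the boundary ("external"
arrangement) versus fifteen boundary electrodes plus one electrode on an
axial oesophageal channel ("internal" arrangement). The comparison is run as
difference imaging of a small blood-conductivity target moved through the
cardiac region, scored with GREIT-style figures of merit.

## Phantom geometry and conductivities

The thorax is a cylinder of diameter 2 and height 0.8 (model units), with
circular electrodes of diameter 0.1 centred at height z = 0.4. Electrode
$\ell$ sits at angle $\theta_\ell = \pi/2 - 2\pi(\ell-1)/16$, so electrode 1
points along +y and electrode 9 along $-y$. Two full-height lung cylinders
(diameter 0.8, conductivity 0.13 S/m, inflated lung at 50 kHz) flank the
centre; their axes are placed at $(\pm 0.55, 0)$, which keeps them strictly
inside the boundary and leaves a lung-free corridor along the $\pm y$ axis.
The blood target (diameter 0.1 unless stated, 0.7 S/m) is a full-height
cylinder moved along $-y$ — towards electrode 9 — at offsets 0.2 to 0.8 in
steps of 0.1. Background tissue is 0.48 S/m. The angular placement of the
lungs is the one genuinely free geometric choice (only their size is fixed
by the design); putting their axes on the $x$ axis keeps every sweep
position disjoint from both lungs, which the spec-level validator enforces.

In the internal arrangement an axial channel of diameter 0.1 (the
oesophagus) is removed from the mesh, and electrode 16 is placed on its
wall, same size and contact impedance as the others. The channel is modelled
as a void: the electrode sits on its wall and no current flows through the
lumen. Contact impedance is never stated in the study conditions; the
default is $z_c = 10^{-3}\,\Omega\,\mathrm{m}^2$ on every electrode,
configurable per electrode.

## Mesh generation

No tetrahedral mesher is available as an R package, so `build_phantom()`
implements a deterministic graded mesher specialised to this geometry:

* concentric node rings in the plane, each with its own angle list — fine
  across the target corridor (so the small target is resolved by centroid
  classification), fine near the electrode belt on the outermost rings, and
  graded away from the channel wall;
* consecutive rings are triangulated by an advancing-front "zipper" that
  handles unequal node counts;
* the disc (or annulus) triangulation is extruded through a graded z-stack
  (finer across the electrode band 0.35–0.45) and each prism is cut into
  three tetrahedra using the smallest-global-index diagonal rule, which
  guarantees a conforming mesh.

Element totals are targets, not exact counts: the `"forward"` preset
produces ≈35k elements and the `"inverse"` preset ≈31k, two genuinely
different discretizations (different bulk sizes, ring layouts and z-stacks)
so that simulated data are never inverted on the mesh that produced them —
the standard guard against the inverse crime. Electrode patches are facet
sets selected by geodesic distance from the electrode centre, with the patch
size chosen to match the analytic disc area $\pi (d/2)^2$ (asserted to 20%
in the tests). The inverse mesh deliberately keeps *coarse* elements around
the oesophageal channel: tiny elements there sit in the extreme near-field
of the internal electrode and would otherwise dominate the regularized
solution.

Region labels (lung / target / background) are assigned by element
centroid. This converges under refinement and, with the corridor
refinement, reproduces the analytic target volume to a few percent at
evaluation density.

## Forward model

The solver implements the complete electrode model: $\nabla \cdot \sigma
\nabla u = 0$ inside the domain, electrode patches with contact impedance
$z_c$, prescribed injected currents with $\sum_\ell I_\ell = 0$, and the
zero-sum voltage gauge $\sum_\ell U_\ell = 0$ (a grounded-node gauge at the
bottom-centre vertex is available; difference frames are gauge invariant,
which is asserted by test). Discretization is first-order tetrahedral FEM
with the standard augmented system in vertex potentials plus electrode
voltages; one sparse Cholesky factorization per conductivity state serves
all sixteen injections.

Stimulation follows the adjacent protocol: drive pairs $(\ell, \ell+1)$
cyclically at 1 mA, and for each injection measure every adjacent pair not
touching a drive electrode, starting just after the drive pair — 16 × 13 =
208 voltages per frame. The internal arrangement keeps index adjacency, so
pairs (15,16) and (16,1) span from the boundary to the oesophagus; these are
precisely the amplified channels visible in the voltage-profile experiment.

### Noise

The measurement model adds zero-mean Gaussian noise at 0.05% of the signal.
Two readings of "of the signal" are implemented. The default,
`scaling = "proportional"`, gives every channel a standard deviation of
$5\times10^{-4}\,|V_i|$ of its own reference voltage — the
measurement-accuracy model of real EIT hardware. The alternative
`"frame_max"` uses one common standard deviation $5\times10^{-4}\max_i|V_i|$.
The frame-max reading makes the noise norm about three times the entire
voltage-difference signal of the D = 0.1 target at offset 0.5; no
reconstruction method recovers position errors of a few hundredths of a unit
under that regime, while the proportional reading reproduces them. The
pipeline therefore uses the proportional model, applied with independent
draws to the reference and target frames (both scaled by the reference
frame, so the difference has a fixed, known noise level).

## Sensitivity and reconstruction

The Jacobian of the 208 measurements with respect to per-element
conductivity is computed by the adjoint method: with $w_\ell$ the unit-
current field of adjacent pair $\ell$,
$\partial V_m / \partial \sigma_k = -I\,\int_k \nabla w_d \cdot \nabla w_g\,dV$,
exact for the discrete system (verified against central finite differences
to the finite-difference truncation floor). Under the adjacent protocol the
measurement fields coincide with the drive fields, so one factorization
yields the whole matrix.

Difference imaging is one-step linearized Tikhonov:
$$\hat{\delta\sigma} = \arg\min \|L_n(\Delta V - J\,\delta\sigma)\|^2 +
\lambda^2 \|L_{\delta\sigma}(\delta\sigma - \delta\sigma^*)\|^2 .$$
Defaults are $\delta\sigma^* = 0$ and $L_n = I$. For the regularization
operator the pipeline uses the $L^2(\Omega)$ identity,
$L_{\delta\sigma} = \mathrm{diag}(\sqrt{V_k})$ with $V_k$ the element
volume. On a uniform mesh this is the plain identity; on a graded mesh the
raw coefficient identity penalises small elements far too little, and the
reconstructed amplitude migrates into the large bulk elements (measured:
amplitude response collapses by an order of magnitude and the blob shifts
off the refined corridor). NOSER-style sensitivity weighting
($L_{\delta\sigma} = \mathrm{diag}(\|J_{:k}\|^{1/2})$ or similar) is
available through `prior_model()`; it suppresses the near-electrode
amplitude concentration and markedly improves targets adjacent to the
oesophagus, but it also changes the resolution/λ trade-off enough to invert
the arrangement ordering of amplitude response at the cardiac position, so
it is not the default.

The minimizer is evaluated in dual form
$J^\top (J J^\top + \lambda^2 I)^{-1} \Delta V$ (208 × 208 system); the
L-curve scan reuses one economy SVD of the whitened operator, so a whole
λ grid costs a single decomposition.

### Choosing λ

`lcurve_scan()` walks a logarithmic grid (default 141 points, 0.05 decades
apart, spanning $[10^{-8}, 10^{-1}]$) and records the residual norm and
solution seminorm. The corner is the point of maximum signed curvature of
the (log residual, log seminorm) curve, computed by central differences with
endpoints excluded and ties broken toward smaller λ; all-zero data returns
the smallest grid λ by convention. The fine grid matters: with ~1.5×
steps the corners of the two arrangements frequently quantize onto the same
grid point, which would void any comparison of their optimal λ. The corner
detector is validated against an independent dense direct-solve oracle on a
classic ill-posed deblurring problem.

## Figures of merit

Reconstructions are point-sampled at the electrode plane onto a 64 × 64
raster covering the boundary circle (pixels outside the medium, including
the channel lumen, are masked, never extrapolated). On the quarter-amplitude
set Q (pixels ≥ ¼ of the peak amplitude, in the peak's sign direction):

* **AR** — summed image amplitude over Q divided by the true contrast
  (0.22 S/m) times the true-target pixel count; 1 for perfect recovery.
* **PE** — distance from the amplitude-weighted centre of gravity of Q to
  the true centre (weighting over Q, not the full image, suppresses ringing
  bias).
* **RES** — |Q| as a fraction of all in-boundary pixels.
* **SD** — spill-over: |Q outside the true target| / |true target|. This
  definition exceeds 1 whenever the quarter set is larger than the target,
  which is the normal situation for a regularized image of a small target.
* **RNG** — opposite-sign amplitude in the annulus around Q (out to twice
  Q's equivalent radius) relative to the amplitude in Q.

These conventions are deliberate choices; published variants differ (e.g.
square-root resolution, or shape deformation normalized by the quarter-set
area), and absolute RES/SD values are not comparable across conventions.
The arrangement *orderings* — internal better than external at the cardiac
position in all five metrics — are convention-robust and are the hard
checks in the test suite.

## Study design and replication

`run_sweep()` simulates, per arrangement and offset: reference and target
frames on the forward mesh, independent noise on each, corner-λ
reconstruction on the inverse mesh, rasterization and scoring. At 0.05%
noise the arrangement contrasts in PE, RES and SD at offset 0.5 are small
relative to the replicate-to-replicate spread, so single-draw comparisons
are not reproducible: the comparison table (`run_table1()`) averages over 60
noise replicates (paired-difference t-statistics at that size: AR ≈ 15,
λ ≈ 8, PE ≈ 4, RES and SD ≈ 2), and the sweep uses 10 per cell. All draw
seeds derive deterministically from one base seed, and re-running a
configuration reproduces its outputs byte for byte.

Problem sizes: forward mesh ≈ 35k elements, inverse ≈ 31k, raster 64 × 64,
141-point λ grid; the full comparison table runs in well under a minute per
arrangement on one core thanks to factorization, SVD and raster-map reuse.
Unit tests run the same code on few-thousand-element meshes.

## What the generator does and does not emulate

The phantom reproduces the tank-scale geometry, tissue conductivities at
50 kHz, the adjacent protocol, and measurement noise. It does not model
thorax-shaped boundaries, electrode movement or contact-impedance
variability, ventilation or perfusion dynamics, multi-frequency admittivity,
or oesophageal wall tissue (the channel is a void). Passing tests therefore
demonstrate the comparative geometry effect under idealized conditions, not
clinical performance.

## Known limitations

* With the default identity-type prior, a target immediately adjacent to
  the oesophagus (offset 0.2) reconstructs poorly in the internal
  arrangement: minimum-norm solutions concentrate amplitude on the channel
  wall where sensitivity is extreme. NOSER weighting rescues this case (at
  the cost described above). The deliberately coarse inverse-mesh channel
  only partially mitigates it.
* The optimal-λ ordering (internal ≤ external) reproduces cleanly in the
  cardiac region (offsets 0.4–0.6) but reverses slightly (≈10–20%) at the
  sweep ends; with proportional noise the internal arrangement's central
  high-sensitivity modes carry only noise when the target is peripheral.
* Frames converge first-order under bulk refinement (successive changes
  12.8% → 3.3% across a density quadrupling); electrode-zone resolution is
  held fixed across densities so the effective electrode geometry does not
  drift.
* The fixed-contact-impedance model leaves a ~1% deviation from exact
  voltage halving when conductivity doubles (electrode shunting), and a 10×
  contact-impedance change moves far-field measurements by a few percent —
  both are properties of the complete electrode model at these electrode
  sizes, not solver artefacts.
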