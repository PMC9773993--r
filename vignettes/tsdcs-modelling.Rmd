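---
title: "Modelling trans-spinal direct current stimulation with spinefield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trans-spinal direct current stimulation with spinefield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical model

Trans-spinal direct current stimulation (tsDCS) drives a few milliamperes of
DC current between two skin electrodes placed over the spine. At DC the
tissue behaves as a resistive volume conductor: the potential $\varphi$
obeys the quasi-static current-flow equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0,$$

with $\sigma$ the (possibly tensor-valued) tissue conductivity, insulating
boundaries at the body surface, and the metallic electrode connectors as
isopotential terminals. The electric field is $E = -\nabla\varphi$ and the
current density $J = \sigma E$. Everything of interest to dosimetry — where
along the cord the field concentrates, how strongly, and in which direction
relative to the fibre tracts and the dorsal root ganglia (DRG) — follows
from this single elliptic problem.

spinefield implements the full chain: a parametric synthetic torso/spine
anatomy, tissue conductivity assignment with volume-constrained anisotropy,
electrode montage construction, a conservative finite-volume solver, and
the cord-centred analyses (slice profiles, per-segment maxima,
suprathreshold regions, DRG probes, montage comparison).

```{r, eval = FALSE}
library(spinefield)
run <- run_simulation(params = anatomy_params("compact"), montage = "T8-L2")
glance(run)
autoplot(run$profile)
```

## The synthetic anatomy: what it emulates, and what it does not

Realistic whole-body models are licensed and cannot be redistributed, so the
package generates its own geometry from analytic primitives (elliptic
cylinders, stacked cylinders, boxes, ellipsoids). The generator reproduces
the *topology* that shapes trans-spinal current flow:

* a truncated elliptical torso with skin and fat shells around muscle
  (truncation planes are capped with skin so the shell is closed; beyond
  them is non-conducting background, mimicking a model truncated at the
  thighs);
* single-blob lungs, heart and viscera with their bulk conductivities;
* a vertebral column of low-conductivity bone — body, a bony ring around
  the spinal canal, and a dorsal spinous process per vertebra — separated
  by intervertebral disks, with a fused sacral block;
* a spinal canal holding a dura tube, CSF, and a white-matter cord with a
  grey-matter core ending at the conus (placed at the L1–L2 disk), a cauda
  equina bundle below it;
* lateral root channels through the intervertebral foramina (the ring gaps
  at disk levels) with DRG ellipsoids inside the foramina, bilaterally for
  T12–L5;
* electrode stacks stamped on the dorsal skin: conforming gel
  (50 × 50 × 2.5 mm), rubber pad (49 × 49 × 1 mm), connector disc (10 mm
  diameter).

The high-conductivity CSF channel inside a low-conductivity bone corridor
is the feature that channels current along the cord; the foramina are the
apertures that concentrate it at the roots. These are present. What is
*not* present: realistic surface detail, cord curvature, per-level
variation of canal and cord calibre, segmented organs, vertebral
microstructure. Consequently the package's field values are
order-of-magnitude comparable to subject-specific models, but absolute
maxima are anatomy-specific and should not be read as predictions for any
person. Passing tests demonstrate correctness of the *method* (the solver
against closed forms, the analyses against constructed fixtures, and the
montage-level symmetry/directionality properties), not anatomical fidelity.

All dimensions are parameters of `anatomy_params()` with literature-typical
adult defaults (canal radius 9.5 mm, cord semi-axes 6.5 × 4.5 mm, dura
2 mm, vertebral body radius 18 mm, height 20 mm, disks 4 mm). They are
artifact choices, stated once and not tuned: no published dimensions exist
for the licensed model they stand in for. The default vertebral span is
T5–L5 plus sacrum — enough column above the T8 anode and below the L1–L2
cathode for the montages of interest, while keeping the default grid
(2 mm, about 1.7 million unknowns) solvable on one CPU in a few minutes.
The `"compact"` preset (4 mm, smaller torso, about 8 × 10⁴ unknowns)
solves in seconds and is used for examples and the montage-level tests.

Optional geometric jitter (`jitter_mm`) displaces organ centres and the
foraminal DRG positions under a fixed seed, for sensitivity exploration; it
is off by default, and the default anatomy is exactly mirror-symmetric
about the mid-sagittal plane — which is what makes the left/right symmetry
checks of the spinous montage exact rather than approximate.

### The spinal segment map

The cord's segmental anatomy is standard knowledge rather than a printed
table: cord segments sit rostral to their same-named vertebrae because the
cord ends near the L1/L2 disk. The package encodes this as a configuration
table (`default_segment_map()`): nominal segment lengths stacked upward
from the conus (coccygeal 5 mm, sacral 4 mm, lumbar 10 mm, thoracic
20 mm), the most rostral listed segment absorbing the remainder up to the
model truncation. This places the lumbar segments adjacent to the T11–L1
vertebral bodies. A z exactly on a boundary belongs to the more caudal
segment.

## Conductivities and anisotropy

Isotropic conductivities follow the standard DC compilation used in spinal
stimulation modelling (S/m): skin 0.435, fat 0.040, muscle 0.355, lungs
0.046, heart 0.535, viscera 0.123, bone 0.006, disks 0.200, dura 0.030,
CSF 1.790, roots 0.154, spinal WM 0.143, spinal GM 0.333; electrode gel
4, conductive rubber 44.

Muscle and spinal white matter are fibrous: their tensors are built from
the isotropic reference under the volume constraint, longitudinal
eigenvalue $\sigma r^{2/3}$ and transverse $\sigma r^{-1/3}$ (twice), so
$\det \Sigma = \sigma^3$ for every ratio $r$. The literature does not fix
the ratios; the defaults are $r = 10$ for white matter and $r = 5$ for
muscle, both configurable in `tissue_table()`, and the isotropic reference
is interpreted as the geometric mean (that is what the volume constraint
preserves). White-matter fibres follow the local cord tangent, muscle
fibres the body axis; with the default straight cord both are grid-aligned
and every tensor is diagonal.

## Discretization and solver

The equation is discretized by cell-centred finite volumes on the uniform
voxel grid. Diagonal tensor entries produce the 7-point stencil with
harmonic face averaging — exact for layered 1-D media with face-centred
interfaces, and conservative by construction: the current through any face
is $g_{ij}(\varphi_i - \varphi_j)$ with a pairwise conductance, so interior
net fluxes vanish at convergence and electrode currents can be measured by
summing connector-face fluxes. Off-diagonal tensor entries (curved cord,
custom fibre fields) add symmetric couplings to edge-diagonal neighbours
with arithmetic averaging; this extended stencil is consistent (it
reproduces linear potentials exactly for any uniform SPD tensor, which the
tests verify) but is not an M-matrix, so the strict discrete maximum
principle is only asserted in its weak form there.

Electrodes enter as Dirichlet data: connector voxels at ±0.5 V. For a
two-terminal problem with isopotential connectors this is equivalent to
prescribing the total current, by linearity: the solved fields are rescaled
so the measured electrode current equals the target (4 mA by default).
Anode and cathode current magnitudes must agree — a mismatch beyond 1 % is
raised as an error since it can only come from a discretization bug.

The linear system is symmetric positive definite and is solved by
conjugate gradients with an IC(0) incomplete-Cholesky preconditioner
(diagonal-shift restart on breakdown), fully serial and deterministic. The
default relative-residual tolerance is 1e-8; the default 2 mm problem
converges in a few hundred iterations. Conductive voxels with no path to an
electrode are pruned with a warning rather than failing the solve; two
electrodes in different conductive components are an error.

Gradients are taken centrally within same-tissue runs and one-sided at
tissue interfaces, so interface jumps in $|E|$ are not smeared; where a
tissue is a single voxel thick the difference falls back to the
across-label neighbours.

## Analyses and their conventions

* **Components.** At every cord voxel the field is projected on the local
  cord triad: `e_long` positive rostral→caudal (the direction current takes
  from a rostral anode to the lumbar cathode), `e_vd` positive
  dorsal→ventral, `e_rl` positive right→left. The triad is orthonormal, so
  the squared components sum to the squared magnitude.
* **Slice statistic.** Per 1 mm slice (or the voxel size, if coarser —
  slices thinner than a voxel are refused): the magnitude is averaged as
  the mean of voxel magnitudes, the components as signed means. Opposing
  directions therefore cancel in the components but not in the magnitude;
  absolute values are taken only at the per-segment maximum step. This
  choice is made explicitly because directional claims (rostral–caudal
  orientation, lateralization) live in the signs.
* **Per-segment maxima** take, per segment and tissue, the maximum
  slice-mean magnitude and maximum absolute slice-mean components.
* **Threshold regions** use the 0.15 V/m neuromodulation reference value
  with an inclusive comparison (≥): "exceeds" is ambiguous at equality and
  inclusion is the conservative mask. The threshold itself is a carry-over
  from cortical DC modelling, not a measured spinal constant.
* **DRG probes** average the field in a sphere (default radius 2 mm,
  raised to the voxel size on coarser grids) around each DRG landmark and
  report the signed projection of the mean field on the root axis,
  positive meaning cord→periphery.
* **"Between the electrodes"** is defined as the segments whose z-range
  lies entirely between the facing inner edges of the two gel footprints.
  Directly under an electrode the field necessarily turns radial (large
  ventral–dorsal component), so longitudinal-dominance statements are made
  — and tested — for the segments between the electrodes, where the CSF
  channel carries the current.
* **Montage comparison** ranks runs on identical anatomy (enforced via an
  anatomy hash) by mean field magnitude over a stated DRG or segment
  target, ties broken lexicographically by montage name.

## Numerical and degenerate-input choices

* Coordinates: +x subject-left, +y dorsal, +z rostral; cell-centred,
  physical = origin + (index + 0.5)·h. One fixed convention avoids
  component-sign bugs.
* The canal centre is snapped to a voxel-centre row so the GM ⊂ WM ⊂ CSF ⊂
  dura nesting survives coarse discretization; the GM core is inset one
  voxel at the cord ends for the same reason.
* The connector is a 10 mm diameter disc, one voxel thick, on top of the
  pad: its only electrical role is an isopotential port, and a 1 mm wire
  is unresolvable at the working resolutions.
* Gel conforms to the curved skin by filling each footprint column from
  the local skin surface to a common pad plane — full gel–skin contact, no
  air gap.
* Anatomy resolution must not exceed the thinnest stamped structure
  (dura, roots); violating parameter sets are rejected with the violated
  constraint named, and the pipeline refuses to solve a grid that fails
  `validate_anatomy()`.
* Session dosimetry computes charge density I·t/A and current density I/A
  from first principles (4 mA, 900 s, 25 cm² → 144 mC/cm², 1.6 A/m²)
  and flags the 250 A/m² safety bound.

## Known limitations

* The torso is truncated just above the anode level; the canal above the
  anode is a short dead-end, which exaggerates the radial field component
  in the most rostral mapped segments relative to a whole-body model.
* The desk-scale torso places a paravertebral electrode much closer to the
  intervertebral foramina than in a full-size body, and the cord
  cross-section is only a few tens of voxels. Lateral current entering
  through the root channels therefore lifts the white-matter slice-mean
  magnitude noticeably under paravertebral montages (the white-matter rim
  has low transverse conductivity, so lateral current there means large
  lateral E). Longitudinal dominance of the slice means between the
  electrodes is consequently weaker in WM than in a full-size model —
  clearly so for paravertebral montages, and marginally at the
  electrode-adjacent segment even for the midline montage — while GM
  dominance and all directional signs behave as expected. The
  corresponding acceptance test is left failing rather than adjusting
  geometry or anisotropy ratios to pass it.
* The 27-point tensor path is exercised by consistency tests, not by the
  default pipeline (whose tensors are all diagonal); strongly anisotropic
  full tensors can violate the discrete maximum principle.
* No electrode–skin contact impedance, no capacitive effects, no neuron
  models: outputs are macroscopic field dosimetry only, intended as inputs
  to microscale models, not predictions of neural recruitment.
* DRG probe values depend on the probe radius and the synthetic foramen
  geometry; left/right *contrasts* are robust (they rest on symmetry), the
  absolute probe values are not.
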