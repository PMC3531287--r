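---
title: "Modeling spore clustering in Myxococcus xanthus fruiting bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spore clustering in Myxococcus xanthus fruiting bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxofruit)
```

## The scientific problem

When *Myxococcus xanthus* starves, hundreds of thousands of rod-shaped
gliding cells aggregate into a mound and a small minority differentiate into
spherical, immobile spores. Differentiation is driven by C-signal, a
contact-dependent morphogen that is only exchanged between motile cells
aligned end to end; C-signal accumulates on each cell until a threshold
triggers sporulation. Volumetric infrared imaging of mature mounds shows that
spores are not packed homogeneously: they sit in dense pockets, tens of
micrometres across, separated by lower-density material.

This package implements the computational side of that story:

1. a **1D circular-track model** isolating the interplay of *jamming*
   (spores impeding moving cells) and *contact signaling*;
2. a **2D stochastic agent-based model** of flexible self-propelled rods
   with realistic motility, reversals and alignment-gated signaling;
3. **volumetric image statistics** (moment ellipses, radial/angular
   profiles, isovolume components) for mound scans;
4. **point-pattern statistics** (smoothed density fields, radial and
   angular distributions) shared between simulations and scan
   cross-sections; and
5. **synthetic-data generators** that emulate the structures the analyses
   assume and return machine-readable ground truth, so every stage is
   testable without original scans.

## The 1D track model

Cells occupy discrete positions on a ring of `L` sites and all hop clockwise
one site per step. A site may hold any number of agents (side-by-side in a
pseudo-2D sense); only spores impede movement. A cell moving into a site
holding `n` spores passes with probability `P^n`. Each step every motile cell
gains a basal `0.005` units of C-signal plus `T` times the mean concentration
of motile cells one site ahead and behind (cells sharing its own site
contribute nothing; concentrations never decrease). At concentration `1.0`
the cell becomes a spore at its current position. Initial concentrations are
uniform on `[0, 0.5]`, so conversion times are spread over steps 100 to 200
and every run ends within `ceiling(1 / 0.005) = 200` steps on basal
production alone.

The two free parameters are the passing probability `P` and the transfer
rate `T`. The headline observable is the **void fraction** — the fraction of
ring sites holding no spores at the end — which measures clustering: more
clustering means fewer occupied sites.

### Choices the model statement leaves open

* **Track density.** The ring length and cell count are free parameters
  with no canonical values. The defaults are `L = 100`, `N = 60`, which put the
  free-flow (`P = 1`, `T = 0`) void fraction at `(1 - 1/L)^N ≈ 0.55`. The
  *relative* increase of the void fraction under strong jamming depends
  strongly on this density: at the default density the measured increase
  from `P = 1` to `P = 0.1` is about 17–22%, and matching a ~50% increase
  would need roughly two to three times as many cells per site. Both
  parameters are exposed, and the density dependence is worth keeping in
  mind when comparing absolute void-fraction values.
* **Update order.** Movement is sequential over agents in a freshly
  shuffled order each step (a simultaneous update would need an extra
  conflict-resolution rule); signaling is synchronous,
  computed from pre-update concentrations, so transfer is order-independent.
* **Neighbour average.** Spores are excluded from the neighbour mean: the
  biology requires movement for C-signaling, and the transfer rule is
  phrased over cells. Empty neighbour sites contribute nothing; with no
  motile neighbour the transfer term is zero.
* **Phase order.** Within a step: movement, then signaling, then threshold
  conversion (checked as `c >= 1.0` with a `1e-9` tolerance absorbing the
  accumulated floating-point rounding of two hundred `0.005` additions).
* **Replicate seeds.** The sweep derives the seed of replicate `r` as
  `seed + r - 1`, making the whole table reproducible.

```{r track, eval = FALSE}
sweep <- sweepTrack(reps = 100, base = trackParams(seed = 1))
head(sweep)
```

At `T = 0` the void fraction decreases monotonically with `P`, steeply at
low `P`; with transfer enabled the `T`-curve ordering reverses between the
strong-jamming and free-flow ends of the sweep, and all curves drop at
`P = 1` — contact signaling partially recovers clustering where jamming
alone cannot produce it.

## The 2D swarm model

Each cell is three nodes joined by two springs of rest length
`l0 = 2.5 µm` (total length 5 µm, width 0.5 µm), gliding at 2 µm/min on a
periodic square domain; `dt = 0.1` min. One step per motile cell, in
shuffled order:

1. **Reversal clock.** When the simulation clock passes the cell's scheduled
   reversal time, head and tail labels swap and the schedule advances by a
   fresh truncated Normal(8, 1) minutes interval. Scheduling from the
   previous scheduled time (not from the step time) keeps the logged
   inter-reversal intervals exactly the drawn ones, free of `dt`
   quantization. Reversals are independent of C-signal.
2. **Direction.** A normalized weighted sum: the head-ward long axis
   (A-motility, `wA = 1`), the sign-rectified mean orientation of motile
   cells sensed within one cell length ahead of the head (S-motility,
   `wS = 0.5`), the sign-rectified local slime-trail axis (`wT = 0.5`), and
   a uniform random unit vector (`wN = 0.1`). The weights keep A-motility
   dominant with every factor active; numeric values for the individual
   factors have no canonical values, so these are package defaults, all
   config-exposed.
3. **Head advance and trailing-node relaxation.** The head moves
   `v * dt` along the direction; middle and tail are then relaxed by a
   Metropolis scheme on the harmonic elastic energy
   `H = kb θ²/2 + ks Σ(l - l0)²/2` (θ the deviation-from-straight angle
   between segments; `kb = 10`, `ks = 20`, temperature 1). The proposal
   kernel is: first a deterministic follow-the-leader candidate that
   restores rest geometry (it has `ΔH ≤ 0` for an isolated straight mover,
   so open-space motion never stalls), then Gaussian jitters of sd
   `0.1 l0`, up to 10 proposals. A candidate that would *worsen* a body
   overlap (capsule-capsule between cells, capsule-disc against spores) is
   rejected; allowing non-worsening moves lets the initially overlapping
   random configuration relax instead of deadlocking. If every proposal
   fails the head move is reverted and the cell stalls this step — stalls
   are how collisions and spore obstacles impede traffic.
4. **Slime.** The body deposits onto a 1 µm grid with exponential decay
   (half-life 10 min). Deposits are stored *nematically* (angle-doubled
   components): slime trails are axial objects, and cells travel them in
   both directions — a vector memory would cancel under the reversing
   traffic this very model generates. On reading, the stored axis is
   sign-rectified toward the cell's own axis.
5. **Signaling.** Once per step, unordered pairs of motile cells exchange
   one C-signal count when (i) some end node of one is within the contact
   distance of some end node of the other, (ii) their body axes are within
   30 degrees (acute angle, polarity ignored), and (iii) their midpoints
   are farther apart than one segment length, which excludes side-by-side
   contacts. A cell in several pairs gains one count per pair. At 500
   counts a cell's body is replaced by an immobile circular spore
   (radius 1 µm) at its former midpoint, which remains a collision
   obstacle.

The default **contact distance is 1 µm (twice the cell width)**, measured
between end-node centrelines. With capsule collision geometry the centreline
separation of two touching cells cannot fall below one cell width, so a
contact distance equal to the width would make "touching end to end" a
measure-zero boundary event; twice the width corresponds to a surface gap of
at most half a width.

Cells start uniformly over the domain as straight rods; a cell whose
midpoint falls inside an aggregation disc is oriented along the disc's
counter-clockwise tangent (the chirality is a convention — only tangency is
prescribed), which seeds the rotational motion that slime trails and
S-motility then sustain.

### Study conditions and stop rule

The reference configuration is a 500 × 500 µm periodic domain with four
discs of radius 50 µm. The analyses in the test-suite use a scaled-down
single-disc configuration — a 125 µm domain with one radius-50 disc and 600
cells, i.e. about 300 cells inside the disc — sized so a full clustering
analysis over 20 seeds runs on one CPU in a few minutes. A full-scale mound holds orders of magnitude more cells than any
configuration that is practical to iterate on; the scaled configuration
keeps the in-disc packing fraction at roughly 10%.

The canonical analysis run stops when about a quarter of the in-disc cells
have sporulated (`stopInDisc = 75`). The stopping stage is an open choice:
in reality only a small minority of aggregated cells ever become spores
(the rest lyse and are consumed), so letting every agent convert is an
artifact of the model's closed population — conversions eventually fill the
voids between early clusters and erase the spatial signal the stage of
interest exhibits.

### What the clustering analysis shows

At the stop stage, conversions are spatially grouped: most early spores
have another early spore within two cell lengths, and the mean
nearest-neighbour distance of in-disc spores is below that of controls in
which the spore labels are shuffled over the positions of *all* in-disc
cells. The label-shuffle is the appropriate null here: spores are finite
obstacles and chain partners convert about a body length apart, so the
pattern carries a hard-core floor that makes a comparison against uniform
re-placement (which has no such floor) insensitive to the clustering.
Doubling the signal threshold to 1000 roughly doubles the time to reach the
same spore count while leaving the nearest-neighbour-distance distribution
statistically unchanged.

## Volumetric image statistics

An `IntensityVolume` is an 8-bit grayscale grid with physical spacing
(default 3.3 µm/pixel in-plane), slice 1 at the mound base. For each
in-plane cross-section the intensity-weighted image moments give the
centroid and covariance matrix; its eigen-decomposition gives orientation,
eccentricity and semi-axes. The semi-axis scale is `2·sqrt(λ)`, exact for a
uniform ellipse (variance along an axis of semi-length `a` is `a²/4`).
Radial profiles average intensity over elliptical annuli in the normalized
elliptical radius (20 equal-width rings by default, out to 1.5); angular
profiles average over pie-slice sectors (default 10°) of the ≥ 10 isovalue
mask; 10 is the outer-shell isovalue convention throughout. Axes-vs-height
regression quantifies the cone-like taper; 26-connected components of the
thresholded volume extract high-density pockets, reported with
equivalent-sphere diameters.

Conventions chosen here (all of them interchangeable in principle):
ITU-R 601
luminance weights for RGB conversion; orientation in degrees
counter-clockwise from +x mapped to (−90, 90]; a centered moving average of
window 5 intensity bins for histogram smoothing, implemented
mass-preservingly (each bin's mass is spread over its edge-truncated
window); fits with eccentricity below 0.05 or collinear mass are flagged as
orientation-unconstrained.

## Point-pattern statistics

Spore positions are binned on a 100 × 100 grid over a square window 1.2
times the disc diameter (120 × 120 µm for a radius-50 disc) and convolved
with a unit-mass Gaussian kernel, σ = 2 grid cells by default —
approximately one lateral resolution element of the imaging device at this
grid geometry — emulating the finite beam footprint. Edge handling is
renormalized truncation, so mass is conserved away from the window edges.
The radial curve averages field nodes in rings one grid cell wide; angular
counts use 3° sectors (120 sectors), computed from the raw points by
default (exact) with a grid-node mode available for parity with gridded
pipelines.

## Synthetic data and what passing tests mean

The generators produce: uniform-intensity ellipse phantoms (anti-aliased by
4 × 4 subpixel coverage so discrete moments track the continuous ellipse);
cone-shaped mound volumes — linearly tapering elliptical cross-sections,
interior intensity 130 (the middle of the observed 120–140 band) with
additive Gaussian noise of sd 8, background 2, and spherical pockets of
12–25 µm diameter boosted by +40, placed by rejection sampling with a
minimum centre separation of one pocket diameter; and clustered spore
patterns (uniform cluster centres in a disc, Poisson cluster sizes,
Gaussian scatter), plus matched uniform controls. Every generator is
deterministic under its seed and returns ground truth.

These volumes emulate the *large-scale statistical structure* the analyses
assume — taper, intensity bands, pocket scale — not the physics of the
instrument: there is no speckle, attenuation with depth, refractive
distortion, or anisotropic resolution. Recovery tests on them validate the
estimators (moments, taper regression, component extraction), not the
instrument model; real scans will be noisier in structured ways.

## Numerical notes and limitations

* Simulation reproducibility is exact under a seed: both simulators draw
  all randomness from R's RNG.
* The 2D model is two-dimensional by construction; it describes one
  in-plane cross-section of a mound, not 3D mound mechanics, nutrient
  bookkeeping or cell lysis.
* Problem sizes used by the test-suite: full 20 × 5 × 100 track sweep;
  500-replicate free-flow oracle; twenty 600-cell disc runs to 75 in-disc
  spores plus two threshold-doubling runs; a single-cell run logging
  ≥ 10,000 reversal intervals.
* The void-fraction *level* of the 1D model is density-dependent;
  qualitative structure (monotonicity,
  crossover, tower sizes) is density-robust, absolute percentages are not.
* Collision resolution tolerates pre-existing overlaps (it only rejects
  worsening moves), so the first few minutes of simulated time double as a
  relaxation phase for the random initial condition.
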