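---
title: "Model and methods: multiscale simulation of BMP-2-treated bone defect healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`callusim` simulates bone regeneration in a critical-sized (5 mm) femoral
osteotomy stabilized by an external fixator, under four treatment
scenarios: untreated control, weekly external mechanical stimulation,
rhBMP-2 delivered on a collagen sponge, and their combination. Three
coupled models run on nested lattices and exchange state every 2-hour
iteration.

## Geometry and lattices

The femur is idealized as a hollow cylinder (cortex between the endosteal
and periosteal radii, medullary cavity inside) with a transverse gap at
mid-shaft and a callus growth region surrounding the gap. Defaults: cortex
outer diameter 4.0 mm, inner 2.6 mm, callus outer diameter 7.0 mm, axial
callus overhang 2.5 mm per side, bone segments 10 mm. These dimensions are
assumptions (the in vivo geometry is not published as numbers) and are all
configurable in `domain_config()`.

Three lattices nest inside one another:

* **cell sites** at 60 µm pitch (so that one lattice hop per 2-h iteration
  equals the 30 µm/h progenitor migration rate);
* **BMP-2 agents**, each a 5 × 5 × 5 block of cell sites (at most 125
  cells per agent), carrying the growth-factor concentration in ng/cm³;
* **finite elements**, trilinear hexahedra, 0.25 mm inside the callus
  bounding box and coarser along the intact bone;
* a **voxel grid** (0.04 mm) used only for the microCT-style bone-volume
  readout.

Mesenchymal stromal cells (MSCs) initially occupy 30% of the sites in the
marrow and in a one-site periosteal band hugging the cortical surface; the
gap and callus start cell-free, as does the sponge.

## Mechanics and the differentiation stimulus

Each iteration solves a quasi-static small-strain poroelastic problem
(u–p, equal-order trilinear hexahedra, one backward-difference
consolidation step over the load ramp) with materials homogenized from the
local tissue composition by the volume-weighted rule of mixtures. Loading
is either habitual gait (default 7 N axial compression — an explicit
calibration knob, the habitual load magnitude being unreported) with the
fixator reduced to a 100 N/mm axial spring in parallel, or, on stimulation
days (7, 14, 21, 28, 35), a 500 µm axial displacement ramp at 10 µm/s with
the crossbar removed. Distal bone end clamped, proximal end loaded.

From the element-centroid solution the model computes the octahedral shear
strain $\gamma$ (squared-shear form; the unsquared variant that circulates
in print is dimensionally inconsistent, can yield negative radicands, and
is available only behind a `strict` flag), the Darcy fluid speed
$\upsilon$, and the Prendergast stimulus

$$S = \frac{\gamma}{0.0375} + \frac{\upsilon}{3\,\mu m/s},$$

which partitions MSC fate: $S \le 2.53$ mature osteoblast,
$2.53 < S \le 3$ immature osteoblast, $3 < S \le 5$ chondrocyte, $S > 5$
fibroblast (upper bounds inclusive).

A pluggable analytic **surrogate backend** (`surrogate_step()`) satisfies
the same contract: the interfragmentary column is reduced to axial layers
in series (each layer the parallel assembly of its elements), the fixator
to a parallel spring, and the fluid speed to a calibrated multiple of the
axial strain and relative permeability. It reproduces load sharing,
progressive unloading of a stiffening callus, and the crossbar-removal
effect, and is the default for reduced-resolution studies where a full FE
solve per iteration is not warranted.

## Cellular activities

Rates follow the published table (MSC 30 µm/h, 0.60/0.30/0.05 day⁻¹ for
proliferation/differentiation/apoptosis; fibroblast 30, 0.55, –, 0.05;
chondrocyte –, 0.20, –, 0.10; osteoblast –, 0.30, –, 0.16). Stochastic
rates convert to per-iteration probabilities as $p = 1 - e^{-r\Delta t}$
(Poisson waiting time), stable under step-size changes.

* **Migration** is a chemotaxis-weighted random walk: a motile cell draws
  one of its six face neighbors with probability proportional to the
  chemotaxis index at the candidate site; occupied or out-of-domain
  candidates are excluded. Updates are synchronous with random-priority
  conflict resolution, so occupancy never exceeds one cell per site.
* **Proliferation** places the daughter in a uniformly chosen free
  neighbor (skipped if none). A phenotype divides only where $S$ lies in
  its favorable window (MSCs and fibroblasts: any $S$; chondrocytes
  $3 < S \le 5$; osteoblasts $S \le 3$).
* **Differentiation** converts MSCs at 0.30/day to the fate given by the
  local $S$.
* **Apoptosis** removes cells at the phenotype rate, doubled (configurable)
  for differentiated cells outside their favorable window.
* **Limited recruitment** (the default for critical defects) zeroes MSC
  migration and proliferation after day 10, leaving differentiation and
  apoptosis untouched.

**Osteoblast maturity is functional in this implementation.** Mature
osteoblasts ($S \le 2.53$ at differentiation, or matured in place at
0.30/day where $S$ is in the mature range) are post-mitotic; the 0.30/day
osteoblast proliferation rate applies to immature osteoblasts only. With
proliferation (0.30/day) exceeding apoptosis (0.16/day) for *all*
osteoblasts, the population would grow without bound wherever $S \le 3$ —
which in a low-strain critical defect is nearly everywhere — so every
scenario would fill the callus and bridge, and the experimentally observed
arrest (non-union, plateaued bone volume) could never occur. Terminal
post-mitotic maturation is the standard biology of the osteoblast lineage
and is the minimal assumption that lets the arrest emerge; it is the one
deliberate departure from treating the maturity flag as bookkeeping only.

## BMP-2 field

Per agent and iteration, in order: carrier release, cellular
production/consumption, free decay, diffusion.

* **Production/consumption** (per agent):
  $\Delta[\mathrm{BMP}] = [\alpha/(\gamma_B[\mathrm{BMP}]+\gamma_0) -
  V_K[\mathrm{BMP}]/(K_M^A+[\mathrm{BMP}])](n_{MSC}+n_{OB})\Delta t$
  with $\alpha = 2\times10^{-9}$, $\gamma_B = 15$, $\gamma_0 = 0.01$,
  $V_K = 1.43\times10^{-7}$, $K_M^A = 11.01$ (units as in
  `bmp_kinetics()`). The production/consumption balance sits near
  0.10 ng/cm³.
* **Decay**: multiplicative survival with half-life 0.42 day for free
  BMP-2 (the printed update rule assigns the decrement to a decayed total;
  the survival form is its only dimensionally coherent reading) and
  3.25 day for carrier-bound (residual) BMP-2, which is otherwise inert.
* **Diffusion**: explicit flux-form finite volumes, $D = 8.64\times10^{-2}$
  cm²/day, zero-flux boundaries on the gap + callus domain, sub-stepped to
  the stability bound $D\,\Delta t/h^2 \le 1/6$; pairwise antisymmetric
  face fluxes conserve mass to rounding.
* **Sponge release**: the retention schedule
  $f(t) = (68e^{-0.012t} + 22.1e^{-0.00006t})/100$ ($t$ in minutes) is
  read as percent of the 50 µg dose; since $f(0) = 90.1\%$, the remaining
  9.9% is an instantaneous burst injected at the first iteration (a
  normalize-to-100% option exists, off by default). Scheduled decrements
  are scaled by the residual-degradation survival and spread uniformly
  over the sponge agents, which fill the defect gap exactly. The free mass
  ever injected is bounded by the dose.
* **Fast release**: the whole dose becomes a homogeneous free
  concentration over the gap agents at iteration 0.

**Dose–response curves.** The published curves pin peaks and asymptote but
not widths or formulas. Chemotaxis (MSC peak 3.5-fold, osteoblast
2.2-fold, both at 1 ng/cm³) and MSC proliferation (2-fold at 200 ng/cm³)
are log-concentration Gaussian bumps
$1 + (A-1)\exp(-\log_{10}^2(c/c_{peak})/2\sigma^2)$ with $\sigma = 0.8$
decades; bone production saturates as $1 + 2c/(c+K)$, $K = 10$ ng/cm³,
toward the 3-fold asymptote. All curves equal 1 at $c = 0$; $\sigma$ and
$K$ are explicit shape knobs. In exploratory runs, widening $\sigma$ from
0.8 to 1.2 did not change the scenario-level pattern, so the narrower
default was kept.

## Tissue update and outcomes

Fibroblasts, chondrocytes and osteoblasts deposit their matrix
(5000/5000/3000 µm³ cell⁻¹ h⁻¹; osteoblast production scaled by the local
BMP-2 bone factor) into their element, converted to volume fractions drawn
from the granulation filler; mismatched differentiated cells resorb
foreign matrix at the same rates, returning it to granulation. MSCs resorb
nothing and acellular elements are inert (the source material is silent on
cell-free resorption). Fractions remain on the simplex by construction.

Bone volume (BV) is quantified microCT-style: the callus bounding box is
voxelized at 0.04 mm, a voxel is "bone" iff the trilinearly interpolated
bone fraction at its center exceeds one half (strict inequality), cortices
are excluded, and BV is the bone-voxel count times the voxel volume.
Bridging is detected as a 6-connected path of bone voxels joining the
proximal and distal cortical ends — the operational reading of "bony
bridging", which has no published formal definition.

## Reduced-resolution studies

`generate_fixture(scale)` keeps the physical geometry and coarsens every
lattice by $1/\mathrm{scale}$. To keep the biology commensurate:

* each lattice agent represents $(h/60\,\mu m)^3$ biological cells in
  tissue production and BMP-2 reaction counts, so volumetric rates are
  scale-invariant at equal occupancy fraction;
* the migration hop-attempt probability scales as $h^{-3/2}$ — the
  geometric mean of the speed-preserving ($h^{-1}$) and
  diffusivity-preserving ($h^{-2}$) laws. Coarse lattices otherwise
  inflate random-walk dispersal and division-relay front speeds linearly
  in $h$, which erases the distinction between arrested and healed
  scenarios; the compromise keeps fronts close to native-scale speeds
  while retaining chemotactic drift.

The packaged studies (tests and examples) use scale 0.25 (240 µm cell
sites, 1 mm elements, 1.2 mm BMP agents, 0.16 mm BV voxels), the surrogate
mechanics backend, the full 42-day duration and seeds 1–3. At this
resolution the four-scenario physiology is reproduced qualitatively:
limited-recruitment controls encapsulate the marrow openings and arrest
(non-union, BV growth from week 4 to week 6 below 5%), sponge-release
BMP-2 bridges by week 2, and fast-release BMP-2 — whose peak concentration
falls below 1 ng/cm³ within 10 days — ends in non-union. Absolute BV is
over-predicted by roughly 3–4× relative to the published full-resolution
values: coarse lattices cannot fully suppress front overshoot, each
super-cell quantizes occupancy coarsely, and large elements smear the
sharp saturated-bone boundary. The published BV values are therefore
treated as order-of-magnitude calibration anchors at this resolution, not
reproduction targets; full-resolution runs (scale 1, FE backend) are
multi-hour computations left to dedicated hardware.

## Numerical and design notes

* One global RNG stream seeded once per run (`set.seed(config$seed)`): a
  run is bit-reproducible from configuration plus seed. Splitting streams
  per module was considered and rejected — R has a single global
  generator, and juggling `.Random.seed` states adds failure modes without
  strengthening the determinism contract.
* Update order per iteration is fixed: sponge release → reaction → decay →
  diffusion → mechanics → differentiation → maturation → proliferation →
  migration (MSCs with the MSC chemotaxis field, fibroblasts unweighted) →
  apoptosis → tissue production → degradation → reporting.
* Ties in migration and daughter placement break uniformly at random;
  simultaneous move conflicts resolve by random priority.
* The stimulation episode replaces gait for the first iteration of each
  stimulation day (the in vivo protocol is a single brief episode per
  week).
* Degenerate inputs: a callus radius equal to the cortex radius yields a
  valid domain with no periosteal callus; zero rates make every cell
  update a fixed point; zero permeability yields zero fluid speed.

## Known limitations

* No angiogenesis, no osteoclast-driven remodeling or low-stimulus "silent
  zone", no tissue formation inside the marrow niche, and no BMP-2 effect
  on differentiation or osteoblastogenesis — matching the scope of the
  modeled system.
* The gait load magnitude, fixator structural stiffness, callus dimensions
  and dose-response widths are calibration knobs; conclusions should rest
  on scenario contrasts, not absolute BV.
* Fibroblast proliferation is not mechano-gated (any $S$), so scenarios
  that generate large fibrous populations (frequent high-strain episodes)
  would be degraded gracefully but are outside the validated envelope.
* The voxel threshold acts on interpolated fractions; at coarse element
  sizes the interpolation smooths the bone boundary and can connect or
  disconnect marginal voxels.
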