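---
title: "Microstroke simulation in microvascular networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstroke simulation in microvascular networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvnstroke)
```

This vignette is the package's own account of its science: the blood-flow
model and its assumptions, the occlusion protocol and the topological
analyses built on top of it, the synthetic networks everything is
exercised on, and the numerical and design choices a maintainer would
want spelled out.

## The vascular graph and its units

A microvascular network is a geometric graph: nodes with 3-D positions
(µm; `z` is cortical depth, surface at `z = 0`) and vessels with a
diameter `D` (µm), a tortuous length `L` (µm, at least the chord length),
a polyline centerline whose arc length matches `L` within 1%, and a type
label (`PA`, `DA`, `C`, `AV`, `PV`). All volumes are µm³ (1 nl = 10⁶
µm³), flows µm³/ms, times ms; pressures are Pa internally with mmHg
accepted at every interface (1 mmHg = 133.322 Pa). Boundary nodes have
exactly one incident vessel and carry the Dirichlet pressures.

Penetrating-tree labels follow the diameter criterion: walking from each
surface root, vessels keep the DA (or AV) label until the first pair of
*consecutive* vessels both thinner than 6 µm; the first vessel of that
pair and everything beyond is capillary. The rule leaves a single thin
segment inside an arteriole labeled DA — the conservative reading of the
pair criterion — and each side's walk treats the other side's provisional
labels as a barrier so a walk cannot claim the opposite tree through a
wide capillary. Main branches are selected per bifurcation by smallest
deviation angle from the parent direction, overridden when the angular
winner's downstream subtree is shorter than 100 µm while a sibling's is
not; ties break to the lowest vessel id. The 100 µm threshold is a
configurable stand-in: only the *criterion shape* (angle plus length,
so short offshoots never become main branch) is fixed by the method.

## Steady hemodynamics

Flow obeys Poiseuille's law per vessel with conductance
`π D⁴ / (128 L µ µ_rel)` and mass conservation at every interior node,
giving a sparse SPD system in the interior pressures, solved by a direct
sparse factorization (`Matrix`). Plasma viscosity defaults to
µ = 1.2·10⁻³ Pa·s (conventional for this model family; configurable).
The creeping-flow assumption is diagnosed, not enforced: on the default
synthetic network all vessel Reynolds numbers are below 0.05.

Blood rheology enters through three empirical laws, transcribed from the
primary literature and locked by regression tests against an independent
transcription:

* **In-vitro relative viscosity** `µ_rel(D, H_d)`: the classical
  formulation built on `η₀.₄₅(D) = 220 e^{−1.3D} + 3.2 − 2.44
  e^{−0.06 D^0.645}` with the diameter-dependent shape exponent `C(D)`;
  equals 1 at `H_d = 0` and reproduces the Fåhraeus–Lindqvist minimum
  near 7–8 µm.
* **Fåhraeus effect**: tube-to-discharge hematocrit ratio
  `H_t/H_d = H_d + (1 − H_d)(1 + 1.7 e^{−0.415D} − 0.6 e^{−0.011D})`;
  RBCs travel faster than bulk blood by the inverse of this ratio.
* **Phase separation** at divergent bifurcations with parent diameter
  above 10 µm: logit-linear law in the fractional blood flow with
  `A = −13.29[(D₁²/D₂² − 1)/(D₁²/D₂² + 1)](1 − H_d)/D_f`,
  `B = 1 + 6.98(1 − H_d)/D_f`, `X₀ = 0.964(1 − H_d)/D_f`. Below 10 µm
  single-file flow is assumed and a cell follows the daughter with the
  largest pressure force.

The steady solver has a fixed-point companion
(`fixed_point_flow_hematocrit`) that alternates the pressure solve with a
downstream mean-field hematocrit propagation until the flow field is
stationary — a fast approximation wherever the discrete fluctuations do
not matter.

## Discrete RBC tracking

`rbc_step` advances point-like RBCs along their vessels at the cell
velocity (bulk velocity divided by the Fåhraeus ratio), routes cells
crossing a bifurcation by the two rules above (the >10 µm law is applied
stochastically with the law's flux fraction as probability), recomputes
vessel hematocrits from the cell counts, and re-solves the pressure field
with the updated viscosities. The "largest pressure force" of the
single-file rule is concretized as pressure drop across the daughter
times its cross-sectional area (a `dp`-only alternative is available);
ties break to the lowest vessel id. Cells are created only at inflow
boundaries — a deterministic accumulator meters the inflow discharge
hematocrit (0.3 by default), with a seeded phase offset — and destroyed
only at outflow boundaries; the count ledger balances at every step.
Convergent junctions merge cells in arrival order and cells may overlap
(point particles): excluded-volume handling is beyond this model family's
fidelity. A known fidelity knob: vessel resistance responds to the
hematocrit-mean viscosity of each vessel, not to individual cell
positions within it.

The time step is `0.8 × min(L/v_rbc)` over perfused vessels, capped at
1 ms, so a cell cannot skip a vessel. One **turnover time** is the time
until 85% of all vessels have cumulatively passed their own lumen volume;
`run_and_average` treats the first turnover as burn-in (the tracker
starts from vessels pre-filled to the inflow tube hematocrit) and then
averages over `n_turnovers` (default 10) turnover times, recording mean
signed and absolute flows, hematocrits, RBC fluxes, and the
direction-change frequency (sign flips divided by steps; zero-flow steps
count as no change).

## The microstroke protocol

An occlusion sets the capillary's diameter to 0.01 µm; in every scenario
exercised here the resulting flow is below ~10⁻¹⁰ µm³/ms, i.e. the
vessel is numerically closed while the graph stays intact, and
`restore_occlusion` is an exact inverse. Boundary pressures are held
fixed across the baseline and occluded runs.

Candidate MSCs pass six criteria, applied in order with survivor counts
reported: (1) within a 444 µm cylinder around the x-y centroid of the
node cloud (the centroid concretizes "the x-y-center"); (2) baseline mean
flow > 0.16 µm³/ms; (3) mean hematocrit > 0.02; (4) direction-change
frequencies ≤ 5% / 10% / 30% at the MSC / generation ±1 / generations
±2–3; (5) at least 3 segments (2 in the relaxed census variant) from the
DA and AV main branches, counted as edges on the shortest topological
path ignoring flow direction; (6) an axis-aligned bounding box of at most
0.2 nl. An optional baseline-flow window supports case-specific subsets.

The response measure is the thresholded relative change of the *absolute*
flow, `Δq = (|q_s| − |q_b|)/|q_b|`, hard-zeroed when the absolute change
is below 0.1 µm³/ms (0.2 RBC/s for the RBC-flux analogue); direction
changes are tracked separately as reversal/cessation flags. Generations
±1…±5 follow baseline flow directions outward from the occluded
capillary, first assignment (smallest |generation|) winning, upstream
preferred on an exact tie.

## Boxes, categories and tissue

The analysis box is the axis-aligned bounding box of the MSC centerline
grown symmetrically — all three sides extended by the same `Δ` solving
`(a+Δ)(b+Δ)(c+Δ) = V`, a monotone root found to 10⁻⁶ relative — so the
initial 0.2 nl volume corresponds to a 58.48 µm cube. Box inflow sums
|q| over every centerline crossing of the box wall directed inward
(multi-crossing vessels contribute per crossing; the field's convention
here is per-crossing flux accounting) plus the injections of any network
boundary nodes lying inside the box. Total flow is length-weighted with
the tortuous centerline clipped to the box. In-box vessels partition into
upstream/downstream (generations ±1…±5), parallel (vessels branching
off or into a generation-1/2 vessel, followed three further segments) and
distant. The supplied tissue volume discretizes the bounding volume into
4 µm cells and assigns each cell center to the nearest centerline point
(1.3 µm discretization; ties to the lowest vessel id), so per-vessel
volumes partition the grid exactly.

## AV-factor and flow paths

The flow-direction DAG orients every vessel by its time-averaged flow
sign, drops |q| ≤ 10⁻⁸ µm³/ms (below that a direction is numerically
meaningless), and must be acyclic — a potential flow cannot cycle, so a
cycle is reported as a numerical artifact. DA endpoints are the first
branch points after the main branch (walking each offshoot through
degree-2 nodes; where a main branch meets the bed directly, that node is
the endpoint), mirrored for AVs.

The AV-factor of a capillary on at least one DA→AV path is
`med(dist_DA)/(med(dist_DA) + med(dist_AV))` over the multisets of
upstream and downstream path lengths. The method's wording admits a
per-endpoint reading; the path-multiset reading is the default and a
per-endpoint-shortest mode ships behind a switch. Exhaustive enumeration
is used up to 10⁵ paths per side; beyond, paths are sampled uniformly via
dynamic-programming path-count weights (10⁴ samples by default; the
analysis scripts use 2000, which bounds the sampling error of a median
well below the 0.05 scale that matters here) and flagged. Path *counts*
are always exact: `U`/`W` dynamic programming in topological order, with
the per-edge identity `U(tail) × W(head)` and totals as the sum of `U`
over AV endpoints — exact in doubles below 2⁵³. Endpoint pairs connected
through the occluded capillary at baseline form category 1, the rest
category 2; pairs connected only through the MSC after the stroke would
be excluded (with the occluded vessel below the flow tolerance this set
is empty by construction, and the check is retained for robustness).

## The synthetic networks

The generator emulates the statistics the analyses assume, not any
specific reconstruction: a jittered cubic lattice (spacing 55 µm, jitter
18%) diluted from a random spanning tree by preferentially attaching
extra edges to nodes below degree 3 — so interior bifurcations are
predominantly degree 3 and connectivity is guaranteed — with lognormal
capillary diameters (mean 4 µm, cv 0.25) and lengths (mean 62 µm, cv
0.22, floored at 1.005× the chord so tortuosity ≥ 1), two DA and two AV
trees with tapered main branches (14→8 and 17→10 µm) and ≥ 6.2 µm
offshoots, boundary stubs on the lateral faces, and root pressures of
60/15 mmHg with stub pressures interpolated by normalized topological
distance. Under these defaults the capillary flow distribution is wide
and skewed with a median near 2 µm³/ms and a 95th percentile near
25–30 µm³/ms, all four MSC types occur among eligible capillaries (with
1-in-1-out most and 2-in-2-out least frequent), and the AV-factor is
assignable to roughly three quarters of capillaries.

What the generator does **not** emulate: anatomical layer-specific
densities, real degree distributions beyond the degree-3 dominance, pial
surface vasculature, and the capillary density of a real cortical bed —
the lattice is sparser. Two consequences are documented rather than
hidden. First, the multi-occlusion protocol's 0.3 nl box (chosen for real
networks, requiring > 12 capillaries) almost never qualifies here; the
analysis and acceptance runs therefore use a 1.5 nl box, preserving the
protocol while scaling its box to the synthetic density (the function
default remains 0.3 nl). Second, passing tests on these networks shows
the machinery is correct and the qualitative topology–severity
relationships hold; it does not certify quantitative agreement with any
real reconstruction, whose absolute deficits depend on the density of
parallel paths.

The distribution sampler is verified by a Kolmogorov–Smirnov self-test at
n = 10⁴; vessel diameters follow it exactly, lengths are subject to the
tortuosity floor (a geometric censoring of the lower tail).

## Numerical choices and degenerate inputs

* Solver: direct sparse Cholesky-type factorization; components without a
  boundary pressure are an error naming the component. Continuity
  residuals sit at ~10⁻¹² µm³/ms on the default networks, orders below
  the 10⁻⁸ tolerance asserted in the tests.
* Zero flows: |q| ≤ 10⁻⁸ µm³/ms is "direction unknown" for
  classification, generations and the flow DAG; `Δq` is undefined (NA)
  at exactly zero baseline flow and those vessels are excluded from
  aggregates.
* Ties: lowest vessel id everywhere a tie is possible (single-file
  routing, main-branch selection, nearest-vessel assignment).
* Degenerate boxes: a grid axis thinner than one cell collapses to a
  single cell layer; `grow_box` refuses targets below the initial
  volume.
* RBC stepping holds cells at a stagnant node until an outflow appears;
  injection accumulators carry fractional cells across steps so the
  long-run injected flux matches the inflow hematocrit exactly.
* Problem sizes: the shipped analyses use the 10×10×10 default network
  (~1600 vessels) in steady mode with 20 occlusions per MSC type, RBC
  tracking on motif networks and small lattices, an 8 µm tissue grid and
  2000-path sampling for the network-wide census — sizes chosen so the
  whole workflow runs on a laptop in minutes while every algorithmic
  path (enumeration and sampling, steady and RBC) is exercised.

## Known limitations

No pulsatility, vessel compliance, or active diameter regulation; the
occlusion is instantaneous and permanent; oxygen transport is out of
scope, so the supplied tissue volume is topological, not effective — the
two can differ where oxygen levels vary along the capillary path. The
RBC model treats cells as points and vessel resistance as
hematocrit-mean; both are standard for this model family but are the
first knobs to revisit for fidelity studies.
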