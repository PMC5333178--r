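---
title: "Exploring ligand transport trajectories: attributes and multi-scale simplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring ligand transport trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandpath)
```

## The problem

Enzymatic conversion of a small substrate requires the ligand to find its
way from the solvent, through a tunnel in the protein, to a buried active
site. Molecular-dynamics simulations capture this transport at femtosecond
resolution, but the resulting trajectories are long (tens of thousands of
snapshots, typically sampled every 2 fs) and dominated by thermal jitter.
`ligandpath` condenses such a trajectory into two complementary products:

* a **per-time-step attribute table** that quantifies where the ligand is
  and what the protein looks like around it, and
* a **multi-scale simplified trajectory** that removes jitter where the
  motion is simple while preserving detail where it is complex.

The package consumes trajectories as multi-model PDB, partial charges as
PQR, tunnels as CAVER-style sphere CSVs (`frame,x,y,z,r`), and an active
site as a list of residues. It never computes tunnels from geometry —
that is the job of dedicated tools — and it analyses one ligand per pass.

## Trajectory attributes

All attributes are frame-local (no superposition is performed) and indexed
by the 0-based time step. The ligand is represented by a single reference
point per step: the unweighted centre of geometry of its atoms by default
(mass-weighted optionally). The input never defines which single point "the
ligand position" is, so both conventions are available; for the
small rigid ligands this analysis targets the difference is far below the
thermal jitter.

**Stuckness.** In a temporal window of $2n+1$ consecutive positions around
step $x$ (default $n = 4$), the straightness ratio is

$$ s(x) = \frac{\max_{-n \le i, j \le n} \; d(P(x+i), P(x+j))}
               {\sum_{-n \le i < n} d(P(x+i), P(x+i+1))}, $$

the maximal displacement within the window divided by the path length. It
is exactly 1 for straight monotone motion and small when the ligand
oscillates in place. The window is shrunk at the trajectory ends. Because
"stuck" should read as *high* when the ligand rattles in a cage, the table
reports both `straightness` ($s$) and `stuckness` ($1-s$); plots default to
the latter. A frozen window (path length $< 10^{-9}$ Å) makes the ratio
0/0; we report `straightness = NA`, `stuckness = 1` and a `frozen` flag —
a motionless ligand is maximally stuck, and silently emitting a number from
a degenerate ratio would be worse.

**Distance and direction.** The active site is located at the
mass-weighted centre of all atoms of its defining residues, per frame;
`dist_active_site` is the Euclidean distance from the reference point.
The binary `direction` is the sign of the discrete derivative:
*toward* when the distance decreases. Ties inherit the previous label
(first step defaults to *away*) and the last step inherits its
predecessor — the derivative is undefined there and inheritance keeps the
series free of gaps.

**Free space.** With an imported tunnel, the free-space radius at step
$x$ is the radius of the sphere of frame $x$ that contains the reference
point (nearest centre wins when several do; when none does, the nearest
sphere's radius is reported with an `outside_tunnel` flag). Without a
tunnel, the *temporal tunnel* stands in: per step, the centre is the mean
position of the ten protein atoms nearest the ligand and the radius is the
minimum distance from that centre to any protein atom.

**Lining residues and profiles.** Residue–ligand distances are
vdW-*surface* distances — centre distance minus both van der Waals radii,
clamped at zero — because a 2 Å centre-to-centre cutoff would select
almost nothing (two carbons already occupy 3.4 Å); a centre-to-centre mode
is available. The three closest residues are reported per step. The
hydrophobicity profile is the unweighted mean Kyte–Doolittle value over
residues within the 2 Å lining cutoff (other scales load from a two-column
file), and the charge profile is the mean partial charge over protein
atoms within the same cutoff. Missing inputs propagate as missing: no
charges means a missing charge profile, never zero, because zero is a
meaningful charge. Residue turnover is the symmetric-difference size of
consecutive lining sets (at most 6 with three residues per side).

**Speed.** With uniform sampling every `dt` fs,
`speed(x) = |P(x+1) − P(x)| / dt`; the last step repeats its predecessor.
The identity `sum(speed * dt) == raw path length` holds exactly and is
asserted in the tests.

## Positional categories

Each step is categorised as `active_site`, `outside`, `inside` or
`surface`, in that priority order: within 4 Å of the active-site centre;
else more than 5 Å of vdW-surface clearance from every protein atom; else
at least 40 protein atoms within an 8 Å contact shell; else surface. The
taxonomy is standard; the thresholds are package defaults exposed in
`category_thresholds()`, chosen to match the geometry of a typical
globular enzyme: 4 Å spans a binding pocket, 5 Å of surface clearance is
clearly solvent, and ~40 heavy atoms within 8 Å distinguishes burial from
surface contact at ordinary protein packing density (~0.05 heavy atoms/Å³).

## Multi-scale simplification

A *simplification state* partitions the step range `[0, N)` into
contiguous half-open intervals, each with a non-negative integer level
(level 0 = raw; equal-level neighbours merge). Two back ends realise a
level:

* **smoothing** — level $k$ applies $k$ Savitzky–Golay passes (window 9,
  order 2 by default) to the interval's raw points, endpoints pinned so
  the global polyline stays continuous;
* **vertex-preserving** — level $k$ runs Douglas–Peucker with tolerance
  $0.5 \cdot 2^{k-1}$ Å; output vertices are a subset of the input, and
  every discarded vertex lies within tolerance of the output polyline
  (the implementation measures point-to-*segment* distance, so this bound
  holds by construction and is audited exhaustively in the tests).

Level semantics are a package design choice (the multi-scale scheme needs
them monotone and composable): repeated passes for smoothing, doubling
tolerances for decimation.

The canonical materialisation applies each interval's level to the raw
points independently — a pure function of (raw trajectory, state).
`simplify_interactive()` keeps the last result in a cache and takes an
incremental shortcut exactly when the edit raises the level of one cached
interval as a whole and no equal-level merge occurs — the typical
"simplify the same part again until satisfied" interaction. Savitzky–Golay
passes on a fixed pinned segment compose, so the shortcut is *bitwise*
identical to the canonical result; every other edit (lowering, partial
overlap, merges) recomputes from raw. For the vertex-preserving back end
the shortcut re-runs Douglas–Peucker on the cached kept vertices when the
cached tolerance does not exceed the target, which preserves the
subset-of-original-vertices guarantee; it is not guaranteed bitwise equal
to a from-scratch run (decimation does not compose across tolerances), so
coherence is asserted for the smoothing back end and subset/tolerance
bounds for the vertex-preserving one.

### Local complexity

`simplify_auto()` decides *where* to simplify using a local complexity
measure evaluated in an arc-length neighbourhood of radius $\nu$ (default
2 Å) around each vertex — all vertices whose distance *along* the
polyline is below $\nu$; a segment belongs when both endpoints do. For the
smoothing back end,

$$ c(x) = \sum_{(u,v)} (|u| + |v|)^2 \, \alpha(u, v), $$

summed over consecutive segment pairs inside the neighbourhood, with
$\alpha$ the angle between segment directions in radians (units:
rad Å²). Straight polylines score exactly 0; a right-angle elbow of unit
segments scores $2\pi$ at the corner. For the vertex-preserving back end
the measure is the path/chord ratio of the neighbourhood, dimensionless
and $\ge 1$; a chord shorter than $10^{-9}$ Å (a closed sub-loop) gets a
sentinel value of $10^6$ with a degeneracy flag rather than a division by
zero — a loop is legitimately "maximally complex".

The automatic loop starts with the whole range as one complex interval;
each iteration marks vertices with complexity below $\tau$ as simple and
removes them from the complex set permanently (splitting intervals),
raises the level of the remaining complex intervals by one,
re-materialises, and stops when the complex set is empty, the
total-complexity improvement drops below $\varepsilon$, or an iteration
cap (50) is hit — the cap returns the best result so far with a warning
flag in the trace. Defaults $\tau = 1$ rad Å² (1.2 for the path/chord
measure, which never drops below 1) and
$\varepsilon = 1\%$ of the initial total complexity are package choices:
on the synthetic fixtures a smooth helix scores $c \approx 0.1\text{–}0.3$
per vertex and thermal jitter of ~0.5 Å scores well above 1, so
$\tau = 1$ separates them with a wide margin.

## The synthetic validation scenario

Real transport simulations are large and rarely public, so the package
ships a deterministic generator (`generate_scenario()`) that emulates the
*structure* the analysis assumes — not the physics. The protein is a
static ball of 3-atom pseudo-residues (residue names cycle through the 20
amino acids so hydrophobicity lookups are exercised), atom centres between
3 and 15 Å from the origin at realistic packing density, with a cleared
channel of radius 2.5 Å along +z and a small central cavity ringed by
three active-site residues. Channel-lining residues carry alternating
±0.3 e charges so the charge profile has signal exactly where a tunnel
has chemistry.

The default ligand path (seed 42, 2000 steps) follows five labelled
phases — outside 500, surface 300, transit 400, stuck 500, active site
300 — with 0.1 Å Gaussian jitter everywhere. Transit is ballistic
shuttling along the channel at 0.7 Å per step (straight within the 9-step
stuckness window, yet confined to the channel), ending at the channel
bottom; the stuck phase is an Ornstein–Uhlenbeck oscillation of ~0.8 Å
amplitude around that point; the active-site phase approaches and then
oscillates at the cavity centre. The stuck amplitude and transit step were
chosen so the stuckness statistic separates the phases at $n = 4$ without
the speed attribute separating them trivially.

What the generator does *not* emulate: protein flexibility (the shell is
static), force-field energetics, solvent, and multi-atom ligand
conformations. Passing tests therefore demonstrate that the derivations
and simplification schemes compute what they claim on data with known
structure — not that the default thresholds are optimal for any particular
real enzyme; the thresholds exist as configuration for exactly that
reason.

```{r scenario, eval = FALSE}
sc  <- generate_scenario()          # seed 42, 2000 steps
tab <- derive_attributes(sc$frames, sc$ligand, sc$active_site,
                         ligand_atoms = sc$ligand_atoms)
mean(tab$category == sc$ground_truth$expected_category)  # ~0.98
```

## Numerical choices and degenerate inputs

* Angles use `acos` of a dot product clamped to [−1, 1]; zero-length
  segments (< 1e-12 Å) have no direction and contribute zero angle.
* The stuckness frozen-window guard triggers below 1e-9 Å of path.
* Douglas–Peucker ties (several farthest points) resolve to the first
  index, making results deterministic.
* Sliding-window means clip at the series ends and drop missing values;
  an all-missing window stays missing. Bar aggregation spreads the
  remainder over the leading bins and breaks modal-category ties by the
  classification priority order.
* Savitzky–Golay windows shrink to the largest odd size that fits a short
  segment; segments of fewer than 3 points pass through unchanged.
* All randomness flows through R's Mersenne-Twister with inversion
  sampling, seeded explicitly, so fixtures are identical across platforms.

## Problem sizes

The bundled scenario uses 2000 steps and ~800 protein atoms; attribute
derivation on it takes a few seconds and the full pipeline (`run_all()`)
under a minute. These sizes were picked so the whole validation suite,
including exhaustive brute-force cross-checks of the lining, charge and
temporal-tunnel scans, runs comfortably on a laptop; the algorithms
themselves are linear in steps × atoms and have been run on much longer
series.

## Known limitations

* The smoothing back end does not bound the deviation of the simplified
  trajectory from the raw one (reported as a diagnostic only); the
  vertex-preserving back end does, by its tolerance. Neither guarantees
  the simplified path stays inside computed tunnel void space.
* One ligand per pass; run the pipeline once per ligand.
* Donor/acceptor colouring uses a static residue-level table; there is no
  protonation-state or pKa modelling.
* The four-way classification is geometric; with the default burial
  threshold a ligand in a wide-open cleft may read as `surface` even when
  a chemist would call it bound.
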