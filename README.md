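# ligandpath

Tools for making sense of how a small ligand travels through a protein in a
molecular-dynamics trajectory. Transport to a buried active site — finding
the tunnel entrance, squeezing past bottlenecks, getting stuck, binding — is
what determines whether an enzyme can turn a substrate over at all, and the
raw trajectories that capture it are long and drowned in thermal jitter.
`ligandpath` is aimed at protein engineers and simulation analysts who want
per-snapshot numbers and clean overview figures out of such a trajectory
instead of scrubbing through a 3D animation.

The package does two things:

**1. Per-time-step attributes.** Given a multi-model PDB trajectory, an
active-site residue list, and optionally PQR charges and a tunnel sphere
profile (CAVER-style `frame,x,y,z,r` CSV), `derive_attributes()` computes,
for every step *x* with ligand reference point *P(x)*:

- **stuckness** — from the straightness ratio in a temporal window of
  2*n* + 1 positions (default *n* = 4),

  $$s(x) = \frac{\max_{-n \le i,j \le n} d\!\left(P(x+i), P(x+j)\right)}
                 {\sum_{-n \le i < n} d\!\left(P(x+i), P(x+i+1)\right)},$$

  reported both as *s* (straightness, 1 for ballistic motion) and 1 − *s*
  (stuckness, high when the ligand oscillates in place);
- **distance** $d_{AS}(x) = d(P(x), A(x))$ to the active site (centre of
  mass of its residues' atoms) and the binary **direction** (toward/away)
  from its discrete derivative;
- **free space** — the radius of the tunnel sphere containing the ligand,
  or, without tunnel input, the *temporal tunnel*: centre = mean of the 10
  nearest protein atoms, radius = distance from that centre to the closest
  atom;
- the three closest **lining residues** (vdW-surface distances), the mean
  Kyte–Doolittle **hydrophobicity** and mean partial-**charge** profiles
  within a 2 Å lining cutoff, **speed**, and **residue turnover**;
- a four-way positional **category** per step: `active_site`, `outside`,
  `inside`, `surface`.

**2. Multi-scale trajectory simplification.** A per-vertex complexity
measure — $c(x) = \sum_{(u,v)} (|u|+|v|)^2\, \alpha(\vec u, \vec v)$ over
consecutive segment pairs within an arc-length neighbourhood ν (default
2 Å) — drives an automatic scheme that smooths only the parts of the
trajectory that are still complex, and an interactive scheme that raises or
lowers the simplification level of any interval, with a cache that makes
repeated edits of the same interval incremental. Two back ends: iterated
Savitzky–Golay passes (smoothing) and Douglas–Peucker decimation
(vertex-preserving, with an auditable deviation bound and the path/chord
complexity measure $c_{DP}$).

A deterministic synthetic generator (`generate_scenario()`) builds a
labelled protein + ligand scenario — outer wandering, surface rolling,
channel transit, a stuck oscillation, active-site residence — so every
derivation is validated against known ground truth without any download.

## Worked example

```r
library(ligandpath)

sc  <- generate_scenario()      # default scenario: seed 42, 2000 steps
tab <- derive_attributes(sc$frames, sc$ligand, sc$active_site,
                         ligand_atoms = sc$ligand_atoms)

dplyr::select(tab[996:1000, ], step, dist_active_site, direction, speed,
              free_space, stuckness, category)
#> # A tibble: 5 × 7
#>    step dist_active_site direction speed free_space stuckness category
#>   <int>            <dbl> <chr>     <dbl>      <dbl>     <dbl> <chr>
#> 1   995             8.13 toward    0.488       2.60     0.238 inside
#> 2   996             7.19 toward    0.258       2.65     0.314 inside
#> 3   997             6.69 toward    0.204       3.27     0.455 inside
#> 4   998             6.30 away      0.523       2.52     0.507 inside
#> 5   999             7.30 away      0.338       2.38     0.382 inside
```

Around step 997 the ligand is ~7 Å from the active site and buried
(`inside`), shuttling down the channel (`toward`, then `away` as it
overshoots); the free-space radius ~2.5 Å is the channel width, and
stuckness is moderate. The per-step categories recover the generator's
ground-truth phase plan for 98.4 % of steps:

```r
mean(tab$category == sc$ground_truth$expected_category)
#> [1] 0.9835
```

Automatic simplification removes the jitter and reports its convergence:

```r
simp <- simplify_auto(sc$ligand)
glance(simp)
#> backend n_points n_intervals max_level iterations initial_complexity final_complexity converged
#> smooth      2000         210         3          3             20006.            5070.      TRUE
autoplot(simp)                  # total complexity per iteration
```

Three iterations cut the total complexity from ~20,000 to ~5,100 rad Å²,
leaving already-simple stretches untouched (210 state intervals, levels 0–3).
`build_overview()`, `build_residue_timelines()` and `export_scatter_data()`
turn the attribute table into the overview colour bar, lining-residue
timelines and raw + smoothed scatter exports; `run_all(run_config(...))`
chains everything and writes a hashed artifact manifest. A thin CLI over the
same functions ships in `inst/cli/ligandpath.R`.

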