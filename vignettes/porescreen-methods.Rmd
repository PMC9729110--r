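---
title: "Screening cancer mutations against an ion-channel pore: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cancer mutations against an ion-channel pore: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescreen)
library(dplyr)
```

porescreen asks a structural question about somatic mutation catalogs: do the
nonsynonymous mutations observed in a cation channel such as NALCN cluster in
3D space, and do they tend to close the channel pore? The package answers it
with four connected models — pore-radius profiling, effective-sphere
mutagenesis, a permutation test for spatial clustering, and nonparametric
stage statistics — each of which is exercised against synthetic channels
whose ground truth is known exactly. This vignette explains the models, their
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## Pore-radius profiling

A channel pore is characterized the way HOLE-type analyses do it: at each
station $z$ along the channel axis, find the largest sphere centered in the
station plane that avoids every atom's van der Waals sphere. With atom
positions $x_i$ and radii $r_i$, the objective at a plane point $c$ is

$$ f(c) \;=\; \min_i \bigl( \lVert c - x_i \rVert - r_i \bigr), $$

maximized over $c$ in the plane; the pore radius at the station is $f$ at the
optimum. Parameters, all in angstrom:

* `step` (default 0.25) — station spacing, the conventional profiling
  resolution.
* `radius_cap` (default 15) — above this the pore is reported as open to
  bulk and the station flagged unconverged.
* `search_radius` (default 5) — lateral bound of the center search around
  the seed point.
* vdW radii — the "simple" profiling set (C 1.85, N 1.75, O 1.65, S 2.00,
  H 1.00, P 2.10, default 1.70), overridable via a plain-text table.
  Hydrogens absent from cryo-EM models are not reconstructed; profiling runs
  on heavy atoms.

The original HOLE algorithm does Monte-Carlo simulated annealing from a
user-supplied interior point. porescreen instead uses derivative-free
multi-start Nelder–Mead, in two modes. The standalone sphere search
(`max_inscribed_sphere()`) seeds from the best points of a coarse grid over
the whole search disk, and on random structures it agrees with an exhaustive
0.05 Å grid to better than 0.1 Å. Profiling (`compute_profile()`), however,
deliberately uses *local* starts around the previous station's center. The
distinction matters: clearance grows again outside the channel wall, so a
globally seeded search will happily jump through a gap between wall atoms
and report the bulk solvent as "pore". Tracking the previous center keeps
the sphere on the continuous pore path, which is also the assumption the
original annealing scheme encodes. The cost is that profiling reports the
pocket connected to the pore path, not the globally largest pocket per
plane — for channels this is exactly what is wanted.

The channel axis defaults to the principal axis of the atom distribution
closest to laboratory z (cryo-EM channel structures are conventionally
deposited pore-along-z); it can be overridden with an explicit vector.

### Alignment on the selectivity filter

Wild-type and mutant profiles are compared at the selectivity filter, the
narrowest ion-discriminating segment. `align_on_filter()` takes a
user-supplied set of filter residues (no universal residue numbering exists,
so this is a required input for real structures; synthetic channels carry it
in their metadata), computes their axial span plus a margin (default 2 Å),
and shifts the z scale so the minimum-radius station inside that window sits
at $z = 0$. Ties on a flat-bottomed profile break toward the station nearest
the window midpoint, then toward lower z — a stable rule that keeps repeated
alignments consistent. `min_filter_radius()` is then the per-structure
readout.

## Effective-sphere mutagenesis

Full side-chain rebuilding (rotamer search, energy minimization) is out of
scope; the package ranks *steric* pore occlusion with a deliberately simple,
deterministic model. A mutant side chain becomes a single pseudo-atom on the
Cα→Cβ direction at distance $\max(1.5, r_\mathrm{eff})$ from Cα with van der
Waals radius $r_\mathrm{eff} = (3V/4\pi)^{1/3}$, where $V$ is the residue's
mean side-chain volume (Zamyatnin residue volumes minus the glycine
backbone volume; shipped in `amino_acid_table()`). Glycine has
$r_\mathrm{eff} = 0$: mutating *to* glycine removes the side chain, mutating
*from* glycine rebuilds an idealized Cβ direction from the backbone. No
backbone relaxation and no neighbor repacking happen; steric clashes with
neighboring residues are reported as warnings.

Two properties make the model testable: pore radius at a filter-lining site
is non-increasing in the mutant's side-chain volume, and self-substitution
is inert. The second holds exactly only when the wild-type side chain is
itself represented as an effective sphere, so the full-residue toy generator
(`make_residue_toy_channel()`) builds its side chains in that same
representation. On real all-atom structures, substituting a residue by
itself changes the modeled steric extent by a few tenths of an angstrom —
an inherent discretization of the model, which is why per-mutation radii
from this package are comparative (mutant vs wild type under the same
model), not reproductions of rotamer-level calculations.

## Spatial clustering of mutated residues

Mutated residues are clustered by single-linkage connectivity: any pair of
residue centers of mass closer than the threshold (default 12 Å) joins their
clusters; clusters are the connected components of the sub-threshold graph,
with strict `<` at the boundary. Centers of mass are mass-weighted by
default (a geometric variant exists for sensitivity analysis). Recurrent
mutations at one residue count once.

Significance of the observed top-two cluster sizes $(s_1, s_2)$ comes from a
permutation null: draw the same number of distinct residues uniformly from
all residues resolved in the structure (an event-level mode that samples
with replacement and deduplicates is available), recompute the statistic,
and count draws at least as extreme. Extremeness is joint quadrant
exceedance — $t_1 \ge s_1$ and $t_2 \ge s_2$ — with a largest-cluster-only
alternative, and the p-value uses the add-one estimator
$(1 + n_\mathrm{extreme})/(n_\mathrm{perm} + 1)$.

One subtlety is worth stating plainly. The quadrant-exceedance p answers
the direct question "how often do random draws produce two clusters at
least this large", but because $(t_1, t_2)$ is only partially ordered, that
p-value is *not* uniformly distributed under the null — it is valid yet
lumpy, conservative at some levels and anti-conservative at others. The
result object therefore also carries `p_calibrated`: every null draw is
scored by its own quadrant-exceedance count and the observed score is
ranked among them. That scalarization is a standard min-p-style correction;
it is uniform under the null up to the discreteness of the statistic, which
is what the calibration tests check. For sharply clustered catalogs the two
p-values agree; they diverge only in the gray zone, where the calibrated
one is the defensible choice.

The permutation loop runs in compiled code and computes pairwise distances
on the fly from the cached residue centers, so universes of tens of
thousands of residues need no $N \times N$ distance matrix. Draws use R's
RNG under the supplied seed and are bit-reproducible.

### Calibration and power study design

The synthetic clustering studies run on a sparse ring lattice (150 rings of
24 single-atom residues, ring radius 13 Å, spacing 3 Å; 3600 residues).
Geometry drives the design: a residue there has roughly 44 neighbors within
12 Å, so calibration draws of $k = 150$ residues sit near the percolation
transition of the sub-threshold graph, where the cluster-size statistic
takes many values and a uniformity test is informative rather than
dominated by discreteness. Power catalogs plant two compact clusters (sizes
10 and 9, members within 6 Å of their seed, seeds mutually > 18 Å apart)
among 20 background mutations; at these settings random draws essentially
never produce a comparable top-two pattern, and the planted signal is
detected at $p < 0.01$ in well over 95% of replicates at
$n_\mathrm{perm} = 10^4$.

A dense lattice cannot support this test: planting 25-member clusters
within a 6 Å spread requires a packing so tight that at a 12 Å threshold a
couple of hundred scattered mutations percolate into one giant component.
Mirroring an observed pattern of 25- and 20-residue clusters among ~200
mutations therefore needs a large sparse universe (the acceptance script
uses a 21,600-residue lattice with a 10 Å planting spread), which is the
regime real multi-domain channel structures occupy.

## Cohort statistics

Per-mutation impact is classified from the change in minimum filter radius:
`close` if it drops more than ε below wild type, `open` if it rises more
than ε above, `neutral` inside the band. ε defaults to 0.05 Å — one fifth
of a profiling step, small enough to be below the model's meaningful
resolution while absorbing optimizer noise; ε = 0 recovers a strict sign
rule. Records whose sites are unresolved in the structure (or whose
wild-type residue disagrees with the catalog, indicating a numbering
offset) are excluded from radii analyses but kept in catalog counts.

Stage association compares mutant filter radii between tumor stages with a
two-tailed Mann–Whitney U test: exact enumeration of all label assignments
when $n_a + n_b \le 16$ with no ties, otherwise the normal approximation
with midrank ties, tie-corrected variance and continuity correction (the
correction clamps at zero, so identical groups report $p = 1$ even under
heavy ties). Sub-stages collapse to their main stage (IIIA → III);
non-TNM strings map to UNKNOWN and are excluded from tests. Pairwise stage
p-values are reported raw, matching the way such panels are usually
presented; a Holm adjustment flag exists.

## Synthetic data and what passing tests do (and do not) show

`make_toy_channel()` builds stacked rings of pseudo-atom residues with an
analytically known profile: by symmetry the inscribed sphere at station $z$
sits on the axis, so its radius is exactly
$\min_j \sqrt{\rho_j^2 + (z - z_j)^2} - r$ over rings $j$ — which reduces to
the intuitive $\rho(z) - r$ wherever the ring-radius profile is gentle.
`simulate_stage_catalog()` plants per-stage shifts in mutant filter radius
with Gaussian noise and, when a target closed fraction is requested, solves
for the global offset whose analytic closure probability matches it. Stage
group sizes default to a realistic staged-cohort mix (47/73/74/27 for
I–IV).

These generators validate geometry, statistics, and the pipeline's
plumbing. They do not emulate real structures' irregular packing, missing
loops, multi-chain contacts, or the correlation between mutation recurrence
and sequence context — so green tests certify the method's correctness on
its stated model, not the biological accuracy of any particular channel
annotation (filter residue set, numbering offsets), which remain the user's
inputs.

## Numerical choices and limitations

* Problem sizes: analytic profiles use 21-ring toys; oracle comparisons 20
  random 30-atom planes; calibration 200 replicates at 2000 draws; power
  100 replicates at 10,000 draws; stage recovery 100 seeds at 40 per group.
  These sizes give stable Monte-Carlo estimates while keeping the whole
  suite desk-scale.
* Nelder–Mead runs with `reltol = 1e-12`, up to 400 iterations, from up to
  6 starts; the lateral bound is enforced by a quadratic penalty.
* Station planes only consider atoms within `radius_cap + r_i` axially —
  a pure speed cutoff whose result is verified unchanged on toys.
* Altloc resolution keeps the highest-occupancy conformer (ties: first in
  file); waters and HETATM ligands are excluded by default.
* Seeds fan out additively from the pipeline's global seed so stages are
  independently reproducible; rerunning with the same config and seed gives
  byte-identical reports.
* The package reads and writes fixed-column PDB only (via bio3d); no mmCIF,
  assemblies, or hydrogens. Multi-site mutants, rotamer libraries, and any
  energetic relaxation are out of scope by design.
* The command-line entry point (`inst/exec/porescreen.R`) wraps the
  shell-worthy operations (full pipeline, profiling, simulation); the R
  functions are the primary interface and each remaining step is a single
  call (`classify_impact()`, `permutation_test()`, `stage_association()`).

## A worked toy example

```{r example, eval = FALSE}
hg <- make_toy_channel(ring_radius = hourglass_radius(3.5, 0.05),
                       atom_vdw = 1.5, seed = 1)
profile <- compute_profile(hg$structure, axis = c(0, 0, 1),
                           step = 0.5, seed = 1) |>
  align_on_filter(hg$filter_residues, hg$structure)
min_filter_radius(profile)   # 2.0 A, the analytic waist radius
autoplot(profile)
```
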