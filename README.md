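# porescreen

Structural screening of somatic mutation catalogs against an ion-channel
pore. Given a channel structure (PDB), a table of nonsynonymous protein
changes with cancer-type and tumor-stage annotations, and a designated
selectivity-filter residue set, porescreen answers three questions:

1. **Does each mutation open or close the channel?** The pore is profiled
   HOLE-style — at each axial station $z$ the largest inscribed sphere is
   found by maximizing $f(c) = \min_i(\lVert c - x_i\rVert - r_i)$ over the
   station plane — and each mutation is introduced with a deterministic
   effective-sphere side-chain model ($r_\mathrm{eff} = (3V/4\pi)^{1/3}$
   from mean side-chain volumes). A mutation is called *close* / *open* when
   the minimum selectivity-filter radius shifts by more than ε = 0.05 Å
   below / above wild type.
2. **Do the mutated residues cluster in 3D?** Residue centers of mass are
   linked at < 12 Å (single linkage); the observed top-two cluster sizes are
   compared with random residue sets of equal size drawn from the structure
   (default 100,000 draws), giving a permutation p-value (plus a
   rank-calibrated variant that is uniform under the null).
3. **Is pore closure graded by tumor stage?** Mutant filter radii are
   compared between stages with two-tailed Mann–Whitney U tests (exact for
   small tie-free groups, tie- and continuity-corrected otherwise), with
   medians reported per stage.

Everything is testable without any external structure: the package ships
generators for toy channels with *analytically known* pore profiles,
full-residue channels for mutagenesis checks, and mutation catalogs with
planted spatial clusters and planted stage effects.

## Worked example

```r
library(porescreen)

# an hourglass channel whose waist pore radius is exactly 2.0 A
hg <- make_toy_channel(ring_radius = hourglass_radius(3.5, 0.05),
                       atom_vdw = 1.5, seed = 1)
profile <- compute_profile(hg$structure, axis = c(0, 0, 1),
                           step = 0.5, seed = 1) |>
  align_on_filter(hg$filter_residues, hg$structure)
profile
#> <pore_profile> 41 stations, z in [-10.00, 10.00]
#> filter window: [-2.00, 2.00], min filter radius 2.000 A
min_filter_radius(profile)
#> [1] 2

# plant two spatial clusters among background mutations and test them
toy <- make_toy_channel(n_rings = 150, atoms_per_ring = 24, ring_spacing = 3,
                        ring_radius = 13, atom_vdw = 1.5, seed = 42)
catalog <- plant_mutation_clusters(toy$structure, cluster_sizes = c(10, 9),
                                   cluster_spread = 6, n_background = 20,
                                   seed = 3)
pt <- permutation_test(toy$structure, catalog$key, threshold = 12,
                       n_perm = 10000, seed = 5)
pt
#> <perm_test> observed top-two cluster sizes (19, 1) at 12 A
#> 39 unique residues (39 events) from a universe of 3600
#> p = 9.999e-05 (0 of 10000 draws at least as extreme; seed 5, mode residues)
#> rank-calibrated p = 9.999e-05
```

Under this seed the two planted clusters happen to fall within linkage
range of each other, so single linkage reports one 19-residue component —
a pattern random draws never match, leaving the p-value at its floor
`1/(n_perm + 1)`. On a real channel
the same calls take `read_pdb()` + `assign_vdw_radii()` output, a catalog
from `parse_mutation_catalog()` mapped with `resolve_catalog_sites()`, and
a filter-residue list; `run_pipeline()` (or the thin CLI in
`inst/exec/porescreen.R`) chains every stage and writes profile TSVs, a
per-mutation calls table, cluster JSON and a reproducible `report.json`.

Result objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` / `plot_*()` views (profile curve, per-mutation impact, stage
panels).

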