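# pvrscan

Structural-evolution analysis for protein families that share a rigid fold:
multi-structure superposition, anchor-column classification, **Protein
Variable Region (PVR)** delineation, and per-structure divergence scoring,
plus the supporting geometry reports (metal coordination spheres, buried
interface areas, inter-chain hydrogen bonds).

The motivating system is the metallo-β-lactamase (MβL) superfamily, whose
members — lactamases, lactonases, RNases, phospholipases — keep a conserved
αββα core and diverge mainly by loops and domains inserted between conserved
scaffold positions. `pvrscan` quantifies that mode of evolution for any such
family.

## The method

For a set of single-chain structures and one reference structure:

1. **Pairwise alignment.** Each structure is aligned to the reference by
   iterative Kabsch superposition alternating with dynamic programming over
   the TM-score kernel `1/(1 + (d_ij/d0)^2)`, `d0 = 1.24 (L−15)^(1/3) − 1.8`.
   Reported per pair: RMSD, TM-score, structure-based sequence identity.
2. **Comparability filter.** Keep structures with more than 220 aligned
   residues *or* RMSD below 3 Å against the reference (both configurable).
3. **Star multiple alignment.** Pairwise alignments are merged on reference
   residues; target residues without a reference partner are kept as
   insertion runs between columns.
4. **Anchors.** Fully occupied columns whose cross-structure CA spread
   (RMSD about the column centroid, in the reference frame) is below
   `rmsd_cut = 2 Å`.
5. **PVRs.** Stretches between consecutive anchors (or beyond the terminal
   anchors) whose per-structure length range exceeds `range_cut = 10`
   residues, numbered PVR1..k from N to C.
6. **Σ_abs.** Per structure, the sum over PVRs of the absolute length
   difference to the reference — a one-number divergence score.

A seeded synthetic-ensemble generator with planted variable regions and
exact ground truth backs the whole validation suite.

## Worked example

Generate the standard validation ensemble (5 structures, 250-residue shared
core, three planted regions with length ranges 15/25/40 residues, 0.3 Å
core noise, random rigid motions) and run the full pipeline:

```r
library(pvrscan)
ens    <- generate_ensemble(synthetic_spec(seed = 42))
files  <- write_ensemble(ens, tempdir())
bundle <- run_pipeline(pvr_config(inputs = files, reference = "S1",
                                  filter = FALSE))
bundle$pvr_table
#> pvr_table: 3 PVR(s), reference 'S1'
#>  pvr_id     kind start_anchor end_anchor length_range
#>       1 internal           71         75           15
#>       2 internal          136        139           25
#>       3 internal          200        205           40
#> sigma_abs:
#> S1 S2 S3 S4 S5
#>  0 19 39 59 80
```

All three planted regions are recovered with their exact length ranges.
`sigma_abs` grows across S2–S5 because the generator plants progressively
longer loops in each structure; the reference S1 scores 0 by definition.
The pairwise summary shows why these structures are comparable at all:

```r
head(bundle$pairwise)
#>   structure_id n_aligned     rmsd  tm_score seq_identity kept
#> 1           S2       265 2.547608 0.9509061     94.71698 TRUE
#> 2           S3       265 2.369107 0.9532623     94.33962 TRUE
#> 3           S4       265 2.145488 0.9552162     95.47170 TRUE
#> 4           S5       265 2.476613 0.9509215     94.33962 TRUE
```

With `out_dir` set in the config the bundle is also written as
`pairwise.tsv`, `anchors.tsv`, `pvrs.tsv`, `sigma_abs.tsv`, `sites.json`,
`interfaces.json` and `provenance.json`. A thin command-line front-end
lives at `inst/cli/pvrscan.R` (`run`, `synth`, `align` subcommands).

Real structures work the same way — pass PDB/mmCIF paths as `inputs` and
the reference id; `find_metal_sites()`, `build_assembly()`,
`interface_area()` and `count_interface_hbonds()` cover the cofactor and
oligomer geometry. `scripts/paper_checks.R` runs the published-structure
checks when a network (or a local PDB cache) is available.

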