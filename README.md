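# extremoprot

Comparative sequence and structure analysis of extremostable proteins
(acidic, alkaline, halophilic, thermophilic, psychrophilic) against their
non-extremostable orthologs.

Proteins from extremophilic organisms tend to differ from their mesophilic
counterparts in systematic, measurable ways: enrichment in small nonpolar
residues (Gly, Ala, Val, Ile), shifted isoelectric points and surface
charge, extra salt bridges, and subtle backbone geometry effects such as
non-planar peptide bonds. `extremoprot` implements the full comparison
pipeline for ortholog pairs and a synthetic-data generator so that every
stage can be exercised and validated without downloading anything.

## What it computes

For each ortholog pair (and aggregated over groups):

- **Amino-acid composition** — per-protein residue percentages
  (`composition_percent`), binned occurrence distributions over 2 %-wide
  abundance bins (`bin_occurrences`), and per-residue two-group Student's
  t-tests (`compare_composition`).
- **Physicochemical descriptors** — Henderson–Hasselbalch net charge
  *Q(pH) = Σ_basic 1/(1+10^(pH−pKa)) − Σ_acidic 1/(1+10^(pKa−pH))*,
  isoelectric point by bisection (`isoelectric_point`), and
  hydrophobic / polar / nonpolar fractions with explicit, overridable
  residue sets (`physchem_profile`).
- **Global alignment** — Needleman–Wunsch with affine gaps (BLOSUM62,
  gap open 10, extend 0.5, free end gaps), percent identity over the full
  alignment length (`needleman_wunsch`).
- **Superposition** — Kabsch least-squares rotation on alignment-paired
  Cα atoms with iterative outlier rejection (5 cycles, 2.0 Å cutoff),
  reporting RMSD in Å (`superpose_chains`, `kabsch`,
  `refine_superposition`).
- **Backbone geometry** — φ/ψ/ω torsions (`backbone_torsions`),
  peptide-bond planarity classes with trans bonds non-planar at
  |ω| < 170° and cis bonds non-planar at |ω| > 20° (`classify_omega`,
  `count_nonplanar`), flanking-residue statistics of non-planar bonds
  (`flank_composition`), Ramachandran region assignment
  (`ramachandran_classify`), and salt-bridge detection by side-chain
  O–N distance ≤ 3.2 Å (`find_salt_bridges`).
- **Group statistics** — pooled-variance t-tests (`t_test`) and
  per-category Pearson correlation of sequence identity with structural
  RMSD (`category_correlations`).
- **Synthetic data** — group-biased sequence sampling
  (`extremophile_profile`, `sample_sequences`), a torsion-exact backbone
  builder (`build_backbone`), planted salt bridges
  (`plant_salt_bridge`), and benchmark structure pairs with a known
  expected RMSD (`make_benchmark_pair`, `make_ortholog_pair`).

Inputs are standard multi-record FASTA and PDB-format coordinate files
(first model, highest-occupancy alternate locations, waters excluded);
outputs are TSV tables and JSON reports.

## Worked example

```r
library(extremoprot)

# 30 extremophile-biased vs 30 baseline synthetic proteins
ext <- sample_sequences(extremophile_profile(), 30, seed = 1)
ctl <- sample_sequences(mesophile_profile(), 30, seed = 2)
tab <- compare_composition(lapply(ext, composition_percent),
                           lapply(ctl, composition_percent))
head(tab[order(tab$p), ], 5)
#>    residue mean_a mean_b     t df        p
#> 10       I  8.543   6.01  7.37 58 7.02e-10
#> 1        A 12.000   8.47  6.76 58 7.48e-09
#> 6        Q  2.074   3.93 -6.64 58 1.18e-08
#> 20       V  9.582   6.84  5.66 58 4.85e-07
#> 5        C  0.657   1.65 -5.66 58 4.98e-07
```

The planted enrichment in Ile/Ala/Val (and depletion of Gln/Cys) is
recovered with large t statistics at n = 30 per group.

```r
# synthetic ortholog pair: 30% substitutions, ~1 A structural noise
op  <- make_ortholog_pair(seed = 7, mutation_rate = 0.3, rmsd_target = 1.0)
aln <- needleman_wunsch(op$record_a, op$record_b)
fit <- superpose_chains(op$structure_a, op$structure_b)
round(c(identity_pct = aln$identity_pct, rmsd_A = fit$rmsd), 2)
#> identity_pct       rmsd_A
#>        68.33         0.96

# backbone with two planted non-planar (omega = 160) peptide bonds
omega <- rep(180, 20); omega[c(6, 14)] <- 160
st <- build_backbone(backbone_spec(strrep("A", 20), omega = omega))
count_nonplanar(st)
#> [1] 2
```

Whole-manifest runs (`read_manifest` + `run_group_analysis`) produce a
per-pair table, per-group descriptor t-tests, per-category
identity–RMSD correlations and occurrence distributions; a thin CLI over
the same functions is installed at `inst/scripts/extremoprot`
(subcommands `simulate`, `compose`, `physchem`, `align`, `superpose`,
`torsions`, `saltbridges`, `run`).

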