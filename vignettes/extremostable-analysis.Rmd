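---
title: "Methods: comparing extremostable proteins with their orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing extremostable proteins with their orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremoprot)
```

## The analysis

`extremoprot` compares proteins from extremophilic organisms with their
non-extremophilic orthologs along five axes: amino-acid composition,
sequence-level physicochemical descriptors, global sequence identity,
structural deviation after rigid superposition, and backbone geometry
(peptide-bond planarity, Ramachandran occupancy, salt bridges). Each axis
is an independent module with a small surface; `run_group_analysis()`
composes them over a manifest of ortholog pairs.

The unit of analysis is a single chain. Multi-chain entries contribute
one chain (the first, unless selected explicitly), because the
structural stages need a one-to-one residue-to-coordinate correspondence
and oligomer interfaces would confound per-chain composition. For the
same reason, the sequence that enters the aligner is derived from the
ATOM records whenever a structure is present, not from sequence
databases: alignment columns must map onto coordinates.

## Composition and occurrence bins

Composition is the percentage of each of the 20 standard residues per
chain; unknown residues (`X`) are excluded from numerator and
denominator rather than being guessed. Group-level views bin each
protein, per residue type, into ten half-open 2-percentage-point
abundance bins `[0,2), [2,4), ..., [18,20]`. The boundary convention is
half-open with the final bin closed; abundances above 20 % (possible
only for extremely biased sequences) are clamped into the last bin with
a warning rather than extending the axis. Group differences use a
pooled-variance Student's t-test per residue; with a Welch option.
No multiple-testing correction is applied — the per-residue tests are
reported as 20 parallel descriptors, and readers should treat borderline
p-values accordingly.

## Physicochemical descriptors

Net charge is the Henderson–Hasselbalch sum over ionizable groups with
both termini counted once:

$$Q(\mathrm{pH}) = \sum_{\mathrm{basic}} \frac{1}{1+10^{\mathrm{pH}-pK_a}}
 - \sum_{\mathrm{acidic}} \frac{1}{1+10^{pK_a-\mathrm{pH}}}$$

The default pKa table is EMBOSS-style (N-terminus 8.6, C-terminus 3.6,
K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1). Published pI web
calculators use different, mostly undocumented tables; rather than
reverse-engineering any of them the table here is explicit and every
value can be overridden (`default_pka(K = 10.5)`). Reported net charge
is at pH 7 (neutral).

The isoelectric point is the root of $Q$, found by bisection on
[0, 14]. $Q$ is strictly decreasing in pH and every sequence has both
termini, so the root exists and is unique. Bisection runs 60 halvings
(final interval ≈ 1e-17 pH units) and then asserts
$|Q(\mathrm{pI})| < 10^{-4}$; iterating on the interval rather than on
the charge keeps the pH accurate even where the titration curve is
steep.

Hydrophobic / polar / nonpolar fractions depend entirely on the residue
sets, and the sets behind the common web calculators are not
recoverable. The defaults are declared, not inferred: hydrophobic
{A,V,L,I,M,F,W,C,G,P}; polar {D,E,H,K,N,Q,R,S,T}; nonpolar is the
complement of polar, so polar + nonpolar always sums to 100 %. C, Y and
W are the contentious residues; they can be moved by configuration
(`default_residue_classes()`).

## Global alignment

`needleman_wunsch()` is a three-state affine-gap dynamic program.
Defaults mirror the widely used global aligner the field reaches for:
BLOSUM62, gap open 10.0, gap extend 0.5, end gaps unpenalized (but
present in the output and counted in the alignment length). A gap of
length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$, so setting
extend = open recovers linear gap scoring exactly. Percent identity uses
the full alignment length, including gap columns, as denominator — the
convention of that aligner's report — and percent similarity counts
columns with a positive substitution score. `X` scores 0 against
everything, so unknown residues neither attract nor repel alignment.
Traceback ties are broken deterministically (diagonal, then gap-in-b,
then gap-in-a), making the output alignment reproducible; tie-breaking
never affects the score. The implementation is cross-checked in the test
suite against exhaustive enumeration of all global alignments (lengths
≤ 6) and against an independent aligner on longer sequences.

## Superposition

Cα atoms are paired through the sequence alignment: one pair per
aligned (non-gap) column where both residues have a Cα. The optimal
rotation is the Kabsch SVD solution with the reflection case corrected
by flipping the smallest singular direction, so the result is always a
proper rotation. Refinement repeats {fit, drop pairs with post-fit
distance > cutoff} up to 5 cycles with a 2.0 Å cutoff — the documented
defaults of the structure viewer whose RMSD convention this follows —
and both the cycle count and the cutoff are parameters;
`refine = FALSE` gives the single plain fit. Refined RMSD is reported
over retained pairs only, with `n_used`/`n_rejected` carried in the
result. Degenerate geometry (collinear or coincident points, fewer than
3 pairs) is an error, not a silent answer.

Both modes are exposed deliberately: for closely related orthologs
refinement barely changes the value, but for distant pairs an
unrefined fit can report an RMSD an order of magnitude larger, and
published per-pair values do not always say which convention produced
them.

## Backbone geometry

Torsions follow the IUPAC sign convention, reported in (−180°, 180°]:
φ(i) = C(i−1)–N(i)–CA(i)–C(i), ψ(i) = N(i)–CA(i)–C(i)–N(i+1), and
ω(i) = CA(i−1)–C(i−1)–N(i)–CA(i) — ω belongs to the peptide bond
*preceding* residue i (a convention choice; the alternative merely
shifts indices by one). Angles are undefined at chain termini, where a
backbone atom is missing, and across chain breaks, defined as a peptide
C–N distance above 2.5 Å (about twice the covalent bond length, so
numbering gaps with intact geometry do not split the chain but true
breaks do).

Peptide bonds are trans when |ω| > 90° and cis otherwise. Planarity
uses the thresholds: trans bonds are non-planar when |ω| < 170°
(i.e. more than 10° from planar trans), cis bonds when |ω| > 20°. The
thresholds are applied to |ω| because the inequalities are unsigned —
a bond at ω = −165° deviates 15° from planarity exactly as +165° does.
The classifier is total on (−180°, 180°] and partitions it; the test
suite probes the boundaries at ±0.01°. Flanking statistics count the
residue before (ω_a) and after (ω_b) each non-planar bond.

Ramachandran assignment uses non-overlapping rectangles — beta
φ∈[−180,−45], ψ∈[90,180]; right-handed helix φ∈[−145,−35],
ψ∈[−70,−10]; left-handed helix φ∈[35,100], ψ∈[−20,90]; everything else
"other". Published Ramachandran tools use empirically contoured
polygons that are not reproducible from their text output; rectangles
are an explicit approximation and are configurable.

Salt bridges are residue pairs, not atom pairs: an (Asp/Glu, Lys/Arg)
pair with at least one side-chain O–N contact within 3.2 Å (Asp
OD1/OD2, Glu OE1/OE2 against Lys NZ, Arg NE/NH1/NH2; His ND1/NE2
opt-in). Multiple atom contacts within one residue pair count once,
with the closest contact recorded. The 3.2 Å default is the documented
O–N cutoff of the standard visualization tool's salt-bridge plugin. No
angular criterion is applied: none is defined precisely enough anywhere
in the lineage of tools this follows to justify one, and distance-only
detection is the reproducible choice.

## Structure input conventions

PDB files are reduced to a single conformer on reading: first MODEL
only, alternate locations resolved to the highest-occupancy copy (ties
to file order), waters and non-amino-acid heteroatoms dropped (MSE is
kept and maps to M; other non-standard residues inside a chain map to
X). Residues are ordered by author numbering with insertion codes.
These choices match common single-conformer analysis practice; they are
applied identically to downloaded entries and to files written by the
package's own generator, and a write/read round trip preserves
coordinates to the format's 0.001 Å precision.

## The synthetic-data generator

The generator exists so that every stage of the pipeline — including
group statistics — runs and is testable with no external data. It
emulates exactly the statistical features the analysis consumes, and
nothing more:

- **Sequences** are i.i.d. multinomial draws per residue from a group
  profile; lengths are rounded normal (default mean 250, sd 25,
  a typical globular protein). The baseline profile uses Swiss-Prot-like
  average frequencies; the extremophile profile scales G+A+V+I up to a
  combined 40 % and halves Q, H, M, C, mirroring the enrichment/
  depletion pattern reported for extremostable proteins.
  `shift_profile()` plants exact composition offsets (the +5
  percentage-point glycine shift used in the recovery checks).
- **Backbones** are built by natural-extension-reference-frame
  placement from ideal internal coordinates (N–CA 1.458 Å, CA–C
  1.525 Å, C–N 1.329 Å; angles 111.2°, 116.2°, 121.7°), so measured
  torsions reproduce the requested φ/ψ/ω to numerical precision
  (1e-6° in the round-trip tests). Only N, CA, C atoms are placed;
  carbonyl O and side chains are omitted and every stage tolerates
  their absence.
- **Planted features**: `plant_salt_bridge()` adds a pseudo OD1/NZ pair
  at an exact separation; `make_benchmark_pair()` applies a random
  rigid transform plus isotropic Gaussian noise with per-axis sd
  $t/\sqrt{3}$, so the expected post-fit RMSD is the target $t$ (the
  ≈ 6 fitted degrees of freedom bias this low by O(1/n), negligible at
  the 200 residues used); `make_ortholog_pair()` additionally mutates
  the sequence at a chosen substitution rate, planting identity and
  RMSD jointly so that identity–RMSD correlation signs can be planted
  per category.

What passing on synthetic data does **not** show: real proteins are not
i.i.d. residue strings (no secondary-structure periodicity, no
hydrophobic core), real structural divergence is not isotropic noise
(loops move more than cores), and real non-planarity is correlated with
local strain rather than planted at random positions. The synthetic
checks validate the *computations* — that planted signals of realistic
size are recovered — not the biological claims.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use sizes chosen to give
stable statistics at interactive runtimes: 30 proteins per group × 100
replicate cohorts for the composition-shift detection rate, 200
sequences for generator composition recovery, 150–200 residues for
superposition benchmarks, and a 12-pair two-category manifest for the
end-to-end correlation-sign recovery. All randomness flows from the
`--seed` argument (or explicit seeds in tests); re-running the pipeline
on identical inputs produces byte-identical JSON.

## Known limitations

- Descriptor class sets and pKa values are conventions, not physics;
  absolute hydrophobic percentages move by several points under
  alternative legitimate sets (which is why the sets are explicit
  configuration).
- Identity percentages depend on the end-gap and denominator
  conventions; values from aligners with other conventions can differ
  by a few points at low identity.
- Unrefined vs refined RMSD can differ drastically for distant pairs;
  compare like with like.
- Salt-bridge detection is distance-only and side-chain-only; it does
  not model hydrogen-bond geometry or charged termini.
- The Ramachandran rectangles are coarse; they are meant for occupancy
  summaries, not residue-level validation.
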