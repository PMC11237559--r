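---
title: "Profiling SoxY gene-family expansion: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling SoxY gene-family expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxyprof)
```

## The biological problem

SoxY is the sulfur-anion carrier of the periplasmic Sox (sulfur-oxidizing)
multienzyme system. Its substrate is bound covalently at a conserved
cysteine at the end of a flexible C-terminal "swinging arm"; in the
canonical protein the arm ends in the motif `VTIGGC`, with the
sulfur-binding cysteine at position 110 of the reference sequence. Many
sulfur-oxidizing bacteria — notably gammaproteobacterial symbionts of
marine invertebrates — carry not one but up to five *soxY* copies, and the
extra copies are often highly divergent: their arms carry one
(signatures S1b, S1c) or several (S2, S3, S4) substitutions, two of the
divergent forms are SoxY–SoxZ fusion ORFs, and their genomic neighborhoods
shift from classical *sox* operons to contexts rich in organosulfur and C1
/ alcohol metabolism genes. Repertoire breadth tracks ecology: symbionts
restricted to "extreme" environments tend to carry only the canonical
copy, while seagrass-associated generalists accumulate divergent copies.

`soxyprof` turns that analysis into a reusable, testable pipeline:

1. **profile search** — find SoxY homologs in annotated proteomes with a
   position-specific scoring profile and empirically calibrated e-values;
2. **quality filter + deduplication** — the length/motif rules and exact
   duplicate collapse used to assemble a tree set;
3. **signature classification** — read the swinging arm in profile
   coordinates and assign one of the six named signatures; detect SoxYZ
   fusions from two-domain local alignments;
4. **phylogeny** — neighbor-joining with column-resampling bootstrap and
   clade assignment against exemplar sequences;
5. **genome profiles** — per-genome copy numbers by signature plus
   presence/absence of a sulfur-gene panel;
6. **neighborhoods** — flanking-gene categorization, operon detection and
   synteny comparison;
7. **synthetic data** — seeded genomes with planted ground truth, so every
   stage above is verifiable offline.

Because the original study's inputs are hundreds of external genome
accessions, verification here rests on the synthetic module: every claim
the test suite makes is a claim about recovering *planted* truth.

## The scoring model

### Profile construction

A profile is built from an aligned seed set by
`build_profile()`. Columns with more than 50% gaps are dropped; each
retained column `j` receives log-odds emissions in bits,

$$ e_{j}(a) \;=\; \log_2 \frac{(c_{j}(a) + \tau\,b_a)/(n_j + \tau)}{b_a}, $$

with `c` the residue counts, `n_j` the non-gap count, `b` the background
(uniform by default) and `τ` the pseudocount weight (default 1). The
conserved-cysteine anchor column is tracked from an ungapped reference
position through column dropping.

The default seed alignment is deliberately **family-wide**: the canonical
sequence, near-canonical copies, and one perturbed copy of each signature
exemplar. A profile built only from near-canonical sequences cannot detect
30%-identity homologs at a 1e-5 cutoff — the divergent clades contribute
no column signal — whereas domain-level profiles used in practice are
estimated from the whole family. With the family-wide seed, every planted
class (including ~25–35% identity fusion proteins) scores far above the
decoy distribution, and 10,000 shuffled decoys produce no false hits at
the cutoff.

### Alignment

`align_to_profile()` computes a true global alignment of a sequence to the
profile columns by affine-gap dynamic programming (match, insert, delete
states; I↔D transitions disallowed). A gap run of length `k` costs
`open + (k − 1) · extend`; the global defaults are 4 and 0.25 bits.
Insertions carry no emission score. On instances with at most six
residues/columns the DP optimum is checked against explicit enumeration of
all alignment paths.

Local alignments (Smith–Waterman) are used in two places: sequence-vs-
sequence search of the sulfur-gene panel (BLOSUM62, gap open 11, extend
1), and profile-vs-sequence domain detection for fusions. Fusion-domain
alignments use stiffer penalties (open 8, extend 1 bit): with the cheap
global extension penalty, local paths can straggle across the Y/Z domain
junction and blur the envelope boundaries on which the fusion rule
depends.

### E-value calibration

Rather than assuming Karlin–Altschul statistics (which do not hold exactly
for arbitrary affine penalties), e-values are calibrated empirically: at
least 1,000 decoys — Fisher–Yates shuffles of supplied sequences, or
i.i.d. draws from the background when only lengths are given — are scored,
and a Gumbel location/scale is fitted by the method of moments
(`λ = π/(σ√6)`, `μ = x̄ − γ/λ`). Then

$$ E(s) \;=\; N \left(1 - e^{-e^{-\lambda (s - \mu)}}\right), $$

the expected number of decoys in a database of size `N` scoring at least
`s`. The fit recovers known parameters from 10⁴ draws within ±0.1 (μ) and
±0.05 (λ); monotonicity in score and linearity in `N` are asserted in the
tests.

### Thresholds

All thresholds default to the study's stated values and live in
`search_config()` / `default_config()`:

| parameter | default | meaning |
|---|---|---|
| homolog e-value cutoff | 1e-5 | SoxY profile search |
| quality filter length | ≥ 140 aa | length exactly 140 is retained |
| quality filter motif | `"GGC"` | substring anywhere in the sequence |
| sulfur panel cutoff | 1e-30 | panel entries ≥ 120 aa |
| sulfur panel cutoff (short) | 1e-6 | panel entries < 120 aa |
| fusion per-domain cutoff | 1e-5 | with envelope overlap ≤ 10 aa, Y before Z |
| operon max intergenic gap | 200 bp | same-strand run growth |
| neighborhood radius | 10 genes | each side of the focal locus |

## Signature classification

The arm is read from the profile alignment trace as the six columns ending
at the cysteine anchor (the length of `VTIGGC`); deletions appear as gap
characters and count as mismatches. Classification is minimum Hamming
distance over the signature table, ties broken by table order, with a
named call only within that entry's `max_mismatch` (0 by default — planted
arms are mutation-free, and real-data users supply their own table).
Proteins whose trace does not reach the anchor are reported
`unclassified`, never dropped. Clade membership is computed separately, by
phylogenetic distance, honoring the observation that arm signatures are
polyphyletic traits.

The default S1b–S4 motif strings are synthetic placeholders that satisfy
the documented distance constraints (single change for S1b/S1c, three or
more for S2–S4, `GGC` retained); the residue-level definitions in the
original supplementary material are not reproduced here, so any real-data
analysis must supply its own signature table.

## Phylogeny

Homolog sequences are stacked in profile coordinates (insertions dropped,
deletions as gaps — an automated stand-in for manual alignment trimming).
Distances are p-distances with pairwise deletion, optionally
Poisson-corrected (`d = −ln(1 − p)`). Trees are Saitou–Nei neighbor
joining with the Studier–Keppler Q criterion; ties take the smallest index
pair, negative branch lengths are clamped to zero, and the output is an
unrooted tree with a trifurcating root written in a fixed Newick dialect
(6 significant digits, supports as internal labels) whose write–read–write
round trip is byte-identical. Bootstrap support is standard column
resampling (default 100 replicates; configurable) with bipartition
frequencies evaluated against the base tree.

Distance-based NJ replaces the original maximum-likelihood inference
(IQ-Tree, `Q.pfam+I+G4`, 10,000 ultrafast bootstraps) deliberately: the
package implements its computation end to end, NJ is provably consistent
on additive inputs (asserted against brute-force least-squares topology
search at n = 5 and exact recovery on random additive matrices), and the
clade-level claims in scope are robust to the substitution. Users needing
ML trees can export `distances.tsv` / the stacked alignment and run an
external tool.

**Known limitation.** At the saturation levels of the most divergent
synthetic signatures (p ≈ 0.85–0.9 between groups), NJ on p-distances can
cluster long branches together, so the broad clade-1 grouping
(S1a + S1b + S1c, spanning 33–65% identity to canonical) is not always
monophyletic in full-cohort trees; the per-clade monophyly flag reports
this rather than hiding it. Exemplar-distance clade *assignment* is
unaffected. The bootstrap/clade-recovery checks use four clades generated
at moderate divergence (ancestors ~40% identity, tips 85–95% within
clades), where recovery is complete with supports ≥ 0.9.

## Genome profiles and ecology

Copy numbers count distinct loci per genome *before* cross-cohort
deduplication (deduplication serves tree building; repertoires are
per-genome gene counts). Classified and unclassified counts are reported
separately. Sulfur-gene presence uses one best local-search e-value per
panel entry per genome, with the 1e-30 / 1e-6 length-dispatched cutoffs;
the panel shipped with the package is synthetic (random sequences with
realistic lengths standing in for the classical markers — sqr, fccAB,
dsrAB, aprAB(M), sat, qmoAB, hdrBC), as the tests only require planted
homologs to be recovered and unplanted entries rejected.

The divergent-signature × environment association is formalized as a
permutation chi-square on the 2 × k contingency of "any of S1c/S2/S3/S4
present" against environment, with `p = (1 + #{shuffles ≥ observed}) /
(B + 1)`. This test is a package addition (the original argument is
qualitative) and its output says so. It is exact-minimal (p = 1/(B+1)) on
perfectly associated cohorts and verified super-uniform under shuffled
labels.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the tests run under.

* **Reference set** — canonical SoxY of 150 aa, arm `VTIGGC` ending at
  cysteine-110 (exactly one `GGC` in the arm window); canonical SoxZ of
  100 aa; per-signature full-length exemplars planted at the midpoint of
  each signature's identity band to canonical (S1a 52–65%, S1b 45–60%,
  S1c 33–43%, S2 24–34%, S3 28–32%, S4 26–37% — the ranges reported for
  the corresponding natural signatures).
* **Two-level planting** — each genome's copy of signature *s* is a
  mutant of the *s* exemplar at 85–95% identity, not an independent mutant
  of canonical. Independent mutants would share no within-signature
  ancestry, which would contradict the clade structure the analysis is
  meant to recover; two-level generation gives each signature a common
  ancestor, as in real gene families.
* **Mutation model** — uniform random substitutions outside the arm at
  positions drawn without replacement; no indels by default, which makes
  identity targeting exact to ±3 points (verified by hand counting).
* **Decoys** — Fisher–Yates shuffles of reference-derived residue pools at
  lengths 80–400 aa: composition preserved, positional signal destroyed.
* **Genomes** — one contig; planted copies are embedded in named
  neighborhood layouts (`sedimenticola_operon`,
  `thiodiazotropha_dispersed`, `s1c_dms`, `s2_adh`, `s3_otr`, `s4_c1`)
  reproducing the operon vs dispersed architectures and the
  characteristic flanking genes of each divergent signature; intergenic
  gaps are uniform 20–400 bp, except that gaps flanking multi-gene layout
  blocks are drawn from 250–400 bp (above the operon gap threshold) so a
  planted architecture can never bridge through neighbors — without this
  the dispersed-layout invariant ("clusters separated by more than the
  detection window") would fail stochastically. GFF3 coordinates are
  1-based inclusive with `3·len + 3` nt per CDS.
* **Ecology model** — environments `seagrass` (p = 0.5), `vent` (0.2),
  `mangrove` (0.2), `oxygen_minimum_zone` (0.1). Specialist labels draw
  from S1a/S1b-only repertoires; seagrass genomes receive one to four
  divergent signatures (always alongside a canonical S1a copy) with
  probability 0.9. Copy numbers never exceed five. These choices encode
  the observed pattern — divergent repertoires confined to seagrass-type
  environments — so the association test has a real signal to find at
  cohort sizes around 50.

What the generator does **not** emulate: nucleotide sequences, indels,
sequencing/assembly artifacts, contamination, genome incompleteness, and
annotation errors. Passing tests therefore demonstrate correctness of the
pipeline's logic under its stated model, not robustness to the full mess
of real metagenome-assembled genomes.

## Numerical and determinism choices

* Every stochastic routine takes an explicit seed; nested seeds are
  derived arithmetically and kept below 2³¹. RNG state is saved and
  restored around library calls.
* Tie-breaks are fixed everywhere: ascending e-value then lexicographic id
  in search output; table order in signature classification; smallest
  index pair in NJ; lowest clade label in assignment.
* Identical configuration + seed reproduces byte-identical output bundles
  (asserted on checksums of all TSV/Newick outputs).
* Problem sizes used by the checks: 50-genome cohorts (~60–120 genes
  each) for end-to-end recovery, 10,000 decoys per specificity run,
  100 bootstrap replicates on 32-taxon alignments, 999 permutations for
  the association test, and 200+ random small instances for the
  exhaustive-enumeration alignment oracles.

## Using real data

`run_pipeline()` accepts per-genome protein FASTA and GFF3 paths plus a
metadata TSV in place of the simulator (`simulate$enabled = FALSE`).
For real analyses you should supply: a curated seed alignment for
`build_profile()` (or a serialized profile via `read_profile()`), a
residue-accurate signature table, and clade exemplar sequences. The
thresholds above then apply unchanged.
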