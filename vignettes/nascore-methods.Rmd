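---
title: "Assessing nucleic acid structure predictions with nascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing nucleic acid structure predictions with nascore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nascore` implements the full assessment chain used to evaluate blind
predictions of RNA, DNA and nucleic-acid complex structures: structure
ingestion and residue correspondence, biomolecule-agnostic model-quality
metrics, base-pair and interface recovery scores, assembly stoichiometry
and point-group symmetry, alignment depth (Neff), and an outlier-trimmed
Z-score ranking with bootstrap confidence intervals. This vignette explains
the models and procedures, the parameters that matter, the synthetic-data
generator the test suite is built on, and the design decisions taken where
the methodology is genuinely open.

## Structures and correspondence

A structure is a flat atom table (chain, author residue number, insertion
code, residue name, atom name, element, coordinates) with polymer types
inferred from residue-name vocabulary: A/C/G/U are RNA, DA/DC/DG/DT are
DNA, the twenty amino acids are protein, anything else is a ligand. Author
numbering is authoritative and insertion codes order alphabetically;
alternate conformers collapse to the highest occupancy. Parsing and writing
go through bio3d (PDB fixed-column and mmCIF `atom_site`).

Model-to-reference correspondence is by sequence: chain id (optionally
through a chain map), residue number, insertion code. Reference residues
without finite coordinates are unresolved and are excluded from every
metric. For homo-oligomers the chain map is found by
`chain_mapping_search()`: model chains are grouped into sequence-identity
classes, and the label permutation maximising a scoring objective (default:
representative-atom lDDT, which is superposition-free and cheap) is
selected — exhaustively while the number of permutations is small,
otherwise by a greedy seed-and-extend that superposes one chain pair and
assigns the rest by centroid proximity. Ties break lexicographically, so
the search is deterministic.

## Global metrics

All four global metrics work on representative atoms — C4′ for nucleic
acids, CA for proteins — except lDDT, which uses every heavy atom.

**TM-score.** `tm_score()` maximises `(1/L) Σ 1/(1 + (dᵢ/d₀)²)` over rigid
superpositions, normalised by the reference length L (resolved polymer
residues). The nucleic-acid d₀ follows the published US-align convention:
`0.6·sqrt(L − 0.5) − 2.5` for L ≥ 30, stepwise constants down to a floor of
0.3 Å for very short chains; proteins use the classic
`1.24·(L − 15)^{1/3} − 1.8`. The optimum is found by a fragment-seeded
search: superpose on a seed window, then iterate selecting residues within
`max(2 d₀, 3.5)` Å and re-superposing until the selection is stable,
tracking the best TM seen. For chains of at most 40 residues the seed grid
is dense (every fragment length and start); longer chains use window
lengths {4, 8, L/4, L/2, L} on a stride of L/15. The search is entirely
deterministic. On small synthetic structures it agrees with an independent
exhaustive-fragment oracle to 10⁻³.

**GDT_TS.** For each threshold in {1, 2, 4, 8} Å the maximal number of
corresponding residues fitting under the threshold is found by iterative
peeling (superpose on a selection, keep the residues that fit, repeat),
followed by an extension phase that superposes on the k nearest residues
for growing k, which reaches non-contiguous fit sets. Toy inputs of at
most 12 residues are scanned exhaustively over residue subsets, which makes
the score exact there. GDT_TS is the mean of the four coverage fractions on
a 0–1 scale; multiply by 100 for the traditional percentage.

**lDDT.** The fraction of reference interatomic distances — within a 15 Å
inclusion radius, excluding same-residue pairs — reproduced by the model
within each of {0.5, 1, 2, 4} Å, averaged over thresholds. It is
superposition-free. The steric penalty is explicit and testable: a model
atom pair closer than the sum of the elements' van der Waals radii minus a
1.5 Å tolerance counts as unpreserved at every threshold. Consequently a
self-comparison scores exactly 1 only for clash-free structures, which the
synthetic generator guarantees by construction.

**TM-align score.** `tm_align()` finds a sequence-order-preserving residue
alignment between two structures of possibly different sequences: gapless
threading seeds at strided offsets, then iterative rounds of superposition
on the current alignment and Needleman–Wunsch dynamic programming on the
TM-weighted similarity `1/(1 + d²/d₀²)` with a linear gap penalty of −0.6.
Every seed alignment is itself scored and the best alignment is re-scored
with the full superposition search, which guarantees the relaxation
property: the fixed-correspondence TM-score never exceeds the aligned
score. The score is normalised by the length of the second structure, so
`tm_align(template, target)` is the template-difficulty covariate. On
unrelated 40-residue random walks the score stays below 0.3; 0.45 is the
conventional shared-fold threshold.

With multiple reference structures every metric is computed against each
reference and the best value is kept per metric, decoupled across metrics.

## Base pairs and topology

`annotate_pairs()` replaces an external annotation engine with an explicit
geometric rule set (an ingestion path for dot-bracket and pair-list CSV
annotations exists as a bypass). A detected pair is canonical when the
bases are complementary (A–U/A–T, G–C, or wobble G–U), the pairing-nitrogen
distance (purine N1, pyrimidine N3) is ≤ 3.5 Å, the base planes are within
30°, and the C1′–C1′ distance is within 10.4 ± 1.5 Å; covalently adjacent
bases never pair, and each residue joins at most one canonical pair
(closest nitrogen wins). Other detected proximal pairs are non-canonical.
These thresholds were chosen once to match the generator's ideal pairing
geometry with comfortable margins; they are parameters of the function.

`classify_topology()` works on canonical intramolecular pairs in the
chain-concatenated residue order. Crossing uses the symmetric interleaving
relation — (i,j) and (k,l) cross when `i<k<j<l` or `k<i<l<j` — so both
members of a pseudoknot are crossed; a singlet is a canonical pair with
neither stacked neighbour (i+1, j−1) nor (i−1, j+1) present. Intermolecular
pairs form their own class and are excluded from the topology predicates,
since sequence interleaving is not defined across chains.

F1 scoring follows the assessment conventions exactly: a predicted pair
matches a target pair when it joins the same two nucleotides; predicted
pairs touching a reference-unresolved nucleotide are removed first and
count neither for nor against; dual absence of an interaction type is a
null score (excluded from averages); a non-empty prediction of an absent
type scores 0; a missing submission scores 0. Across up to five models and
multiple references the best score is kept, where a null beats any number.

## Interfaces, ligands, degeneracy

Contacts are inter-chain residue pairs with any heavy-atom distance below
5 Å (the common contact convention; strict inequality, so a zero threshold
yields no contacts). ICS is the F1 over contact sets, IPS the Jaccard
coefficient over interface residues, and i-lDDT is lDDT restricted to
reference atom pairs spanning different chains (steric penalty retained).
For hybrid complexes the per-interface scores of NA–NA and NA–protein
interfaces are combined weighted by the number of reference interface
residues; protein–protein interfaces are excluded from the NA ranking.

Ligand pockets are the nucleotides with any atom within 4 Å of a ligand
heavy atom in the reference. `ligand_metrics()` reports the NA–ligand
interface lDDT, the pocket lDDT, and the pocket RMSD after superposing the
pocket nucleotides. When predictors can only model half of a dimeric
pocket, `normalize_half_pocket()` divides the model's score against the
dimer by the better of the two target half-pocket scores and caps at 1;
"better half" (max) was chosen because the assessment text names either
chain without a selection rule.

`detect_no_interaction()` flags degenerate multimer models: chains with no
inter-chain contact at 5 Å, or chain pairs with coincident centroids
(within 1 Å) where most atoms sit on top of an atom of the other chain.
Such models are flagged for exclusion review, never silently dropped;
actual exclusions come from an explicit, overridable list.

## Stoichiometry and symmetry

Chains cluster into entities at ≥ 95% sequence identity (tolerating minor
crystallisation mutations) and the stoichiometry string labels entities by
descending copy number ("A4B2"). Point-group detection considers cyclic Ck
for every divisor k ≥ 2 of the chain count n and dihedral Dk when 2k
divides n. Candidate axes come from the principal axes of the
chain-centroid cloud (plus chain and chain-pair directions for the
perpendicular two-folds); each rotation induces a chain permutation by
nearest centroid, and the fit RMSD is the optimal rigid-transform RMSD
between the structure and its permuted self over phosphate/CA atoms —
for a permutation to be accepted its cycle structure must match the
rotation order. Among candidates within the 10 Å cutoff the assignment
with the most chains involved and then the most symmetry elements wins
(|Cn| = n, |Dn| = 2n), with dihedral preferred on ties, so an exact D4
assembly whose C8-like arrangement also fits the cutoff is still called
D4. C1 is the universal fallback. On generator-built assemblies with up to
1 Å atomic noise the constructed group is recovered essentially always;
past the cutoff, assignments decay monotonically toward C1.

## MSA depth

Pairwise identity ignores columns gapped in both sequences; a gap against
a residue is a mismatch, T equals U, and N matches nothing. Each sequence
is weighted by the number of rows above 0.8 identity *including itself*,
and Neff = Σ 1/w. The include-self convention was chosen because the
literal "other sequences" reading allows zero weights (division by zero
for unique sequences) and include-self matches standard AlphaFold2-style
practice; it also guarantees 1 ≤ Neff ≤ n.

## Ranking

Scores reduce to one value per (group, target, metric): the maximum over
up to five models and all references. For each target and metric, Z-scores
are computed across groups with one trimming pass: scores at least two
sample standard deviations below the initial mean are set aside, the mean
and SD are recomputed without them, and every group — outliers included —
is scored against the trimmed statistics (zero SD yields all-zero Z).
Sample (n−1) standard deviations are used throughout; the choice is not
documented in assessment descriptions and the sample form is the safer
default at small group counts.

Category weights: monomers 0.3·Z(TM) + 0.3·Z(GDT_TS) + 0.4·Z(lDDT);
multimers and hybrids 0.3·(that blend) + 0.7·(⅓ Z(ICS) + ⅓ Z(IPS) +
⅓ Z(i-lDDT)); ligand targets 0.5·Z(i-lDDT) + 0.5·Z(lDDT-pocket). A missing
component is omitted with the remaining weights renormalised and the
result flagged. Same-sequence targets form grouping sets that contribute
only their best Z; negative Z floor at zero for the summed ranking; groups
participating in less than 60% of the category's (grouped) targets are
excluded, with the denominator taken after grouping. Confidence intervals
come from 1,000 bootstrap replicates resampling targets with replacement,
reported as the central 68.2% percentile interval; the seed is mandatory,
so reruns are bit-identical. Per-category intervals are summed for the
overall ranking.

## The synthetic-data generator

`build_structure()` folds a coarse-grained chain from a dot-bracket string
(multi-layer pseudoknot alphabets supported). Each nucleotide carries five
atoms: P, C4′, C1′, the pairing nitrogen and a base-centroid pseudo-atom.
Residue centres relax under distance constraints — backbone 6 Å, pairs
10.4 Å, ladder diagonals and skip-two struts that keep stacked pairs
collinear, and 7.5 Å excluded volume — from a deterministic seeded
initialisation; frustrated pseudoknotted folds get extra rounds,
progressively more room, and jittered restarts, and a topology whose
pairing constraints remain unsatisfied is rejected with an error. Paired
bases are then snapped onto ideal geometry (N–N 2.9 Å, C1′–C1′ 10.4 Å,
coplanar bases), unpaired bases point away from their local backbone and
are re-aimed if their nitrogens drift close to another base, and auxiliary
atoms are nudged out of incidental van der Waals clashes. The result is
that the geometric annotator recovers exactly the specified canonical pair
set, and references are clash-free so self-lDDT is exactly 1.

`build_assembly()` places exact Cn/Dn copies by group operators on a ring
(default radius 45 Å, dihedral rise 50 Å) and rejects radii that clash.
`perturb_model()` degrades a structure deterministically: per-atom Gaussian
noise, rigid shuffles of contiguous domains, or rigid per-chain placement
errors that leave each chain internally intact (so monomer scores stay
perfect while interface scores collapse). `simulate_msa()` mutates a master
sequence at a per-site rate solved from the three-alternative substitution
model so the expected pairwise identity matches the request.
`simulate_submissions()` builds a full roster: each group has a quality
profile — a nominal sigma and a per-target lognormal spread
(`roster_spec(sigma_spread=)`, default 0.5) — reflecting that real
predictor groups vary from target to target; the first model per target
carries the nominal sigma and later models are progressively worse, so the
ground-truth ordering is known.

What the generator does *not* emulate: all-atom geometry and realistic
sugar-phosphate backbones, non-canonical pair families with specific edge
geometries, base stacking energetics, sequence-dependent helix parameters,
and realistic experimental artifacts (partial occupancy, alternate
conformations beyond simple unresolved residues). Tests passing on this
generator therefore demonstrate the correctness of the scoring and ranking
machinery, not the behaviour of geometric annotation on experimental
coordinates.

## The quality-ordering recovery experiment

The strongest end-to-end check runs the whole pipeline on 30 synthetic
25-nt targets with six groups of strictly ordered quality (nominal sigmas
0.6–1.6 Å, two models per target) over 20 submission seeds and asks for
the true ordering (Kendall τ = 1). Two design choices matter. First, the
ordering is read off the *unfloored* summed Z: the floor-at-zero rule is a
competition-leniency device that deliberately zeroes every below-average
group, which ties them and makes a full ordering unrecoverable by
construction; floor behaviour is covered by its own tests. Second, the
per-target quality spread was set to 0.15 (lognormal sd) by a power
analysis on an abstracted simulation of the trimmed-Z sum, giving a
~99.9% chance that a single run orders all six groups correctly — large
spreads blur adjacent groups, and the experiment should fail only if the
pipeline is wrong, not because the design is underpowered.

## Numerical choices and degenerate inputs

Superpositions use the Kabsch SVD construction with the proper-rotation
correction and are validated against an independent quaternion-method
oracle; collinear or undersized point sets are rejected. Distance
comparisons use strict inequalities where the conventions say "above" or
"within" (identity > 0.8; contacts < 5 Å). Empty structures, unbalanced
dot-brackets (reported with the offending position), incompatible
stoichiometries and missing correspondences are errors; empty pair sets,
empty interfaces and single-group rankings take their defined degenerate
values (null scores, zero Z, point bootstrap intervals). All stochastic
steps — generators, rosters, bootstrap — require explicit seeds and are
bit-reproducible.

## Known limitations

The geometric pair annotator is tuned to the coarse-grained generator
geometry; on experimental all-atom structures a dedicated annotation tool
should be used and its output ingested via `ingest_pairs()`. The
chain-mapping search optimises a representative-atom objective and may
differ from an all-atom optimum for near-degenerate assemblies. The
symmetry detector covers cyclic and dihedral groups only — the point
groups that occur for nucleic-acid assemblies in practice — not
tetrahedral or higher. TM/GDT searches are heuristics: they are exact on
toy sizes and oracle-validated on small chains, but like all such searches
they can in principle return a lower bound on very unusual geometries.
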