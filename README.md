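# nascore

Assessment of nucleic acid structure predictions in R.

`nascore` scores predicted RNA, DNA, and nucleic-acid complex 3D structures
against experimental references and ranks predictor groups, the way blind
structure-prediction challenges are assessed. It targets assessors and
method developers who need reproducible, biomolecule-agnostic quality
metrics plus the bookkeeping around them (best-of-model reduction,
outlier-trimmed Z-scores, bootstrap confidence intervals, target difficulty
covariates), without depending on a zoo of external binaries.

## What it computes

**Global model quality** (representative atoms: C4′ for nucleic acids, CA
for proteins):

- **TM-score** — max over superpositions of
  (1/L) Σᵢ 1/(1 + (dᵢ/d₀)²), normalised by the reference length L, with the
  nucleic-acid d₀(L) = 0.6 √(L − 0.5) − 2.5 convention (floored at 0.3 Å);
- **GDT_TS** — mean over d ∈ {1, 2, 4, 8} Å of the maximal fraction of
  residues superposable within d (reported on a 0–1 scale);
- **lDDT** — superposition-free fraction of reference interatomic distances
  (15 Å inclusion radius) preserved within {0.5, 1, 2, 4} Å, with a steric
  penalty: model atom pairs closer than their van der Waals radius sum minus
  1.5 Å count as unpreserved;
- **TM-align score** — the same TM functional over a sequence-independent
  structural alignment (fragment seeding + iterative dynamic programming),
  used to quantify template availability.

**Secondary structure**: geometric base-pair annotation
(Watson–Crick–Franklin + wobble), pseudoknot (crossed), singlet,
non-canonical and intermolecular pair classes, scored by precision /
recall / F1 with null-score conventions (dual absence → no score,
overprediction → 0, missing submission → 0).

**Interfaces and ligands**: inter-chain contact F1 (ICS), interface-residue
Jaccard (IPS), interface lDDT (i-lDDT), residue-count-weighted aggregation
over NA-containing interfaces, ligand-pocket lDDT/RMSD with half-pocket
normalisation, and a degenerate-model detector.

**Assemblies**: stoichiometry inference ("A4B2" strings at 95% sequence
identity) and Cn/Dn point-group detection with a 10 Å fit cutoff and the
most-chains / most-elements / dihedral-over-cyclic selection rule.

**Ranking**: per-metric best over ≤5 models and all references; per-target
Z-scores with one-pass low-side outlier trimming (2 SD); category weights
0.3·TM + 0.3·GDT + 0.4·lDDT for monomers, 0.3·(monomer blend) +
0.7·(⅓ ICS + ⅓ IPS + ⅓ i-lDDT) for multimers/hybrids, 0.5·i-lDDT +
0.5·lDDT-pocket for ligands; same-sequence target grouping,
floor-at-zero summation, a 60% participation filter, and 1,000-replicate
bootstrap 68.2% confidence intervals.

**MSA depth**: Neff — each sequence weighted by the number of alignment
rows (self included) above 0.8 identity (dual-gap columns ignored); Neff =
Σ 1/w.

A deterministic synthetic-structure generator (`build_structure`,
`build_assembly`, `perturb_model`, `simulate_msa`, `simulate_submissions`)
builds coarse-grained nucleic acids from dot-bracket secondary structure
(pseudoknots included), exact Cn/Dn assemblies, graded-quality
"predictions" and full submission rosters, so the entire pipeline is
testable without any external data.

## Worked example

```r
library(nascore)

# a 25-nt pseudoknotted synthetic reference and a noisy "prediction"
ss  <- simulate_secstruct(25, seed = 1, pk = TRUE)
ref <- build_structure(secstruct_spec(ss$sequence, ss$dotbracket, id = "T1"),
                       seed = 1)
mod <- perturb_model(ref, perturbation_spec(1, "gaussian", seed = 9))

tm_score(mod, ref)   # 0.2893109
gdt_ts(mod, ref)     # 0.81
lddt(mod, ref)       # 0.6635215
```

The TM-score looks low for 1 Å noise because d₀ is small for short chains
(≈0.7 Å at L = 25): every residue is ~1.7 Å from its reference position, so
each contributes only ~1/(1 + (1.7/0.7)²) ≈ 0.15. GDT_TS is high because
most residues superpose within 2–4 Å, and lDDT sits in between because
local distances are preserved to within ~1.4 Å on average.

Ranking a synthetic submission roster:

```r
targets <- list(T1 = list(references = list(ref), category = "monomer"))
sub <- simulate_submissions(list(T1 = ref),
                            roster_spec(c(good = 0.5, bad = 2.5)), seed = 4)
res <- run_assessment(targets, sub$models,
                      config = ranking_config(seed = 7,
                                              participation_min = 0))
res$ranking
#>   group     sum_z     ci_lo     ci_hi
#> 1  good 0.7071068 0.7071068 0.7071068
#> 2   bad 0.0000000 0.0000000 0.0000000
```

With two groups the trimmed Z of the better one is 1/sqrt(2) (the weaker
group's negative Z is floored to 0), and a single target makes the
bootstrap interval degenerate; over many targets the summed Z and its
68.2% interval separate the groups.

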