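---
title: "PHBR scoring and immunogenic-selection analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PHBR scoring and immunogenic-selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phbrsel)
```

## The scientific question

Recurrent ("hot spot") driver mutations in cancer genomes create candidate
neoantigens: mutated peptides that may be presented by a patient's HLA
molecules and recognized by T cells. If immune surveillance shaped which
driver mutations a tumor can keep, mutations observed in a patient should be
those their MHC genotype presents *poorly*. An apparent signal of this kind
— observed mutations having systematically weaker predicted HLA affinity
than unobserved ones — can, however, arise without any genotype-specific
selection, if a handful of very common driver mutations happen to yield
poorly presented peptides for *most* genotypes. `phbrsel` implements the
full analysis needed to distinguish these explanations:

1. **PHBR scoring** of missense mutations against MHC genotypes from
   peptide-window percentile-rank tables;
2. **virtual-patient simulation**, including *isogenotypic* cohorts in
   which every patient carries one fixed prototypical genotype, so any
   surviving affinity difference cannot come from genotype variation;
3. **paired regression models and matrix randomizations** that separate
   frequency-driven from genotype-driven structure;
4. a **leave-one-out scan** attributing the aggregate effect to individual
   mutations;
5. a **substitution/amino-acid-context atlas** explaining *why* particular
   substitutions produce poorly presented peptides.

## The PHBR score

For a missense mutation with up to 14 flanking residues on each side, every
peptide window containing the mutated position is enumerated: lengths 8–11
for MHC class I (38 windows with full flanks) and length 15 for class II
(15 windows). Each window is scored against each allele as a percentile
rank in $(0, 100]$, lower = stronger predicted binding. Per allele, the
**Patient Best Rank** (PBR) is the minimum rank over windows; per genotype
(6 class I alleles, 10 class II, duplicates for homozygosity), the
**Patient Harmonic Best Rank** is

$$\mathrm{PHBR} = \frac{n}{\sum_{i=1}^{n} 1/\mathrm{PBR}_i},$$

the harmonic mean of the allelic PBRs, dominated by the best-presenting
allele. $\Delta\mathrm{PHBR} = \mathrm{PHBR} - \mathrm{PHBR_{wt}}$
contrasts the mutant against the corresponding wild-type peptide set;
positive values mean the substitution weakens presentation.

Numerical conventions:

* **Rank floor.** Ranks are clamped to $[0.001, 100]$ before harmonic
  aggregation. External predictors report 0.001 as their minimum; without
  the floor a zero rank would make the harmonic mean collapse.
* **Termini.** Near a protein end only windows fully inside the available
  sequence are enumerated, and the PHBR is computed over the windows that
  remain (a predictor cannot score out-of-bounds peptides). A mutation at
  position 1 therefore has exactly one placement per window length. A
  context too short for any window warns and yields no score rather than
  failing the whole run.
* **Context length.** Up to 14 flanking residues are stored on each side;
  the window lengths dictate how much is actually used (8–11-mers never
  reach past ±10). This reconciles the two context conventions found in
  practice (21-mers for class I, 29-mers for class II) with one storage
  format.
* **Homozygosity.** A duplicated allele contributes two identical terms to
  the harmonic mean; $n$ stays 6 (or 10).
* **Duplicate windows** are retained; they cannot change a minimum.
* Window enumeration order (by length, then left to right) is
  deterministic, so all output files are byte-stable.

## Rank tables and synthetic predictors

The contract boundary to any affinity predictor is the **rank table**:
`(peptide, allele) → rank`. The canonical interchange format is a long TSV
(`peptide`, `allele`, `rank`); a narrow adapter parses the tab-separated
export of NetMHCpan-style tools. Allele names are normalized by stripping
`*` and whitespace (`HLA-A*02:01 → HLA-A02:01`); the normalization rules
are versioned in `normalize_allele()`. Duplicated pairs with conflicting
ranks are rejected rather than silently resolved.

Because no neural-network predictor ships with this package (and none is
reimplemented), two deterministic synthetic predictors provide structural
stand-ins:

* the **hash predictor** maps `(seed, peptide, allele)` to a uniform-like
  rank via an integer string hash — an exchangeable null;
* the **composition predictor** sets
  $\log_{10}(\mathrm{rank}) = \mathrm{baseline} + \sum_j m_j\, w(aa_j)$
  over window positions, with optional anchor-position multipliers. It is
  monotone in any positive-weight residue, which lets tests *plant*
  composition effects (e.g. rank-raising glutamates) whose recovery can be
  verified downstream.

Neither predictor approximates real binding; they only reproduce the shape
of predictor output so the full pipeline is testable offline.

## Cohorts, virtual patients and the mutation matrix

Somatic calls are filtered to recurrent driver missense mutations by three
criteria: missense classification (configurable, case-insensitive), gene
membership in a driver list, and recurrence in at least 5 distinct samples.
Recurrence counts *distinct samples*, not call rows — duplicated calls per
sample are artifacts, and the binary patient × mutation matrix makes the
same choice implicitly. Protein changes are accepted in both `p.V600E` and
`V600E` spellings; one annotation per row is trusted as given.

Virtual patients are simulated by independent Bernoulli draws per
(patient, mutation) cell with the observed carrier frequencies — exactly
the "sample from a binary 0/1 vector with probabilities given by the
mutation frequencies" construction. This deliberately ignores mutual
exclusivity, clonality and cancer-type structure; real cohorts violate
independence, and any conclusion that depends on co-occurrence patterns is
outside what these simulations can support. Draws run in per-mutation
substreams keyed by mutation id, so adding a mutation never perturbs the
other columns. Genotypes are either *prototypical* (one fixed 6- or
10-allele genotype for everyone — the isogenotypic design, under which the
PHBR column of every mutation is constant across patients) or drawn from
per-locus allele pools, two independent draws per locus.

## Regression models and randomization controls

The central statistic regresses cell status on $\ln(\mathrm{PHBR})$ with a
random intercept grouped by **patient** (controls mutational burden) or by
**mutation** (controls carrier frequency), fitted by Laplace-approximated
maximum likelihood (`lme4::glmer`). The slope is reported as an odds ratio
per unit $\ln(\mathrm{PHBR})$ with a 95% Wald interval computed on the
log-odds scale and exponentiated. Natural log is used throughout; the OR
scale is arbitrary but must be fixed, and all tests are base-consistent.

Design choices worth knowing:

* **Inestimable slopes.** Under the within-mutation model on an
  isogenotypic cohort, $\ln(\mathrm{PHBR})$ is constant within every group
  and the slope is confounded with the random intercepts. The fit is
  reported as `converged = FALSE` with `NA` estimates instead of a
  fabricated OR. A plain-logistic fallback with cluster-robust sandwich
  errors exists behind an explicit `fallback = "glm_cluster"` flag — it is
  never applied silently.
* **Convergence.** Optimizer failure or lme4 convergence warnings mark the
  fit non-converged; *singular* fits (random-effect variance estimated at
  zero) still count as converged, since a zero variance is a valid
  boundary estimate and the fit then coincides with plain logistic
  regression (verified to $10^{-3}$ relative in the tests).
* **Caveat for mutation-constant predictors.** When the predictor is
  constant within mutations (isogenotypic cohorts, per-allele scans), the
  within-patient model treats mutation-level variation as if cell-level,
  so its p-values are anticonservative. This is inherent to the design —
  the per-allele scan on null alleles flags more than its nominal FDR, and
  the corresponding test asserts planted-signal recovery and OR dominance
  rather than strict null calibration.
* Wilcoxon comparisons use the exact null distribution when both groups
  have at most 25 values without ties, the tie-corrected normal
  approximation otherwise; fully tied data return $p = 1$.
* Zero-mutation patients are retained in the within-patient model (they
  inform the intercept); this is a possible source of numeric divergence
  from analyses that drop them.

Two randomizations bracket the models: permuting each patient's row
preserves per-patient loads but destroys which mutations carry the events;
permuting each mutation's column preserves carrier frequencies exactly.
A frequency-driven affinity signal survives the second and dies with the
first — the package's key diagnostic, exercised end-to-end in the
acceptance tests.

## Leave-one-out attribution

The within-patient model is refitted once per mutation, excluding that
mutation's column; the odds-ratio drop is normalized to the maximal
possible effect,

$$\mathrm{effect\%} = 100\,\frac{\mathrm{OR}_{\mathrm{base}} -
\mathrm{OR}_{\mathrm{excl}}}{\mathrm{OR}_{\mathrm{base}} - 1},$$

and mutations with effect strictly above 1% are flagged. Ties exactly at
the threshold are not flagged. The scan refuses to run when the baseline
fit is non-converged or $\mathrm{OR}_{\mathrm{base}} \le 1$: with no
baseline effect the normalization is meaningless, and near
$\mathrm{OR}_{\mathrm{base}} = 1$ the denominator makes tiny refit
perturbations explode into spurious "effects". For the same reason the
flag list from a *weak* baseline should be read with care; full-precision
ORs are reported precisely because rounded ORs do not reproduce published
effect percentages (1.20 → 1.13 gives 35.0% by the formula, not the 33.4%
obtained from unrounded values). The same `nAGQ` setting is used for the
baseline and all refits so the normalization is internally consistent;
`nAGQ = 0` (the fast pseudo-likelihood step) is the documented option for
large scans.

## The substitution atlas

All 64 codons × 3 positions × 3 alternative bases of the standard genetic
code (DNA-keyed, `T` not `U`) yield exactly **150** distinct ordered
missense substitution types after removing synonymous and stop-involving
changes — verified against an independently coded enumeration. Sampling a
fixed number of random contexts per type (100 per type gives the canonical
15,000-substitution dataset) and scoring them produces a 20 × 20 matrix of
median $\Delta\mathrm{PHBR}$, with unreachable cells absent and rows and
columns ordered by their medians. Flanks for these simulated substitutions
are drawn from a configurable background distribution (uniform by default)
or cut from user-supplied protein sequences; mapping real genome positions
through transcript annotation is out of scope.

Two composition analyses connect the atlas to mechanism. The
**composition regression** fits, per amino acid, an OLS regression of
$\ln(\mathrm{PHBR})$ on the percentage of that residue among all window
residues (per-window multiplicity, so residues near the mutation weigh
more), with BH correction across the 20 tests and slopes labelled
hydrophobic / polar / charged. The **enrichment scan** counts residues
over each mutation's windows *excluding the mutated position itself* (it
would otherwise appear in every window and dominate), compares each
amino-acid proportion against the pooled background by two-sided Fisher's
exact test, and reports proportion-ratio folds with BH q-values. Residues
absent from the background give undefined folds and are reported `NA`.
Unique-residue counting (each protein position once) is available behind
`unique_residues = TRUE` for sensitivity analysis.

## The synthetic scenario generator

`build_scenario()` realizes a self-contained world for testing the whole
pipeline:

* a long-tailed carrier-frequency spectrum
  $f_r = f_{\max}\, r^{-\alpha}$ with lognormal jitter, floored at
  $5\times10^{-4}$ and capped at $f_{\max} = 0.057$. With $\alpha = 1$ and
  200 mutations this reproduces the qualitative pan-cancer driver
  spectrum: a most-frequent mutation at 5.7%, a handful above 1%, and a
  rare tail with median near 0.06%;
* `n_hotspots` planted weak-affinity hot spots occupying the *top*
  frequencies, whose alternate residue is a reserved marker (default `E`,
  echoing phospho-mimicking glutamate substitutions). The marker carries a
  predictor weight of `hotspot_phbr_shift / ln 10` on every allele, and is
  excluded from all other draws, so every mutant window of a hot spot —
  hence its PBR on every allele, hence its PHBR — is elevated by *exactly*
  `hotspot_phbr_shift` on the ln scale. Planting acts through the
  predictor at the peptide level, never by editing PHBR values post hoc,
  so the entire window/PBR/PHBR path is exercised;
* per-allele random composition weights (`weight_sd`, default 0.15 on the
  log10-rank scale per residue) and jittered baselines, giving each allele
  its own preferences so PHBR varies across genotypes;
* genotypes drawn from a small allele pool by default, so that *both*
  regression models are estimable (prototypical mode is available and is
  the right choice for isogenotypic analyses, but leaves the
  within-mutation slope inestimable by construction).

**Calibration of `weight_sd`.** The default 0.15 makes the planted default
shift of 0.7 equal to roughly two between-mutation standard deviations of
$\ln(\mathrm{PHBR})$, so hot spots separate visibly from the bulk — the
qualitative situation in the published frequency-versus-PHBR scatter,
where the implicated hot spots sit clearly above the cloud. Smaller values
(e.g. 0.08) make the planted association implausibly strong (baseline ORs
above 10); larger values (0.3) push the spread to the point where the
planted signal needs the full 2,000-patient cohort to reach significance.
This parameter was calibrated once to this realism argument and is not a
per-test tuning knob.

What a green scenario test does *not* establish: realism of mutation
co-occurrence (cells are independent by construction), realism of binding
chemistry (composition predictors are structural stand-ins), or behavior
under genotype-frequency confounding absent from the generator.

## Scaling of the heavy tests

The acceptance criteria run on one CPU. The Wilcoxon/randomization and
model-asymmetry criteria run at the full stated scenario scale (2,000
patients × 200 mutations; two Laplace fits of 400,000 cells take about a
minute). The leave-one-out criterion needs ~201 refits, so it keeps all
200 mutations but scales the cohort to 500 patients and uses `nAGQ = 0`
(~10 minutes); keeping the full mutation count matters because each null
column's leverage on the baseline OR scales like $1/m$, and scans over
too few mutations flag noise columns whose selected exclusion overshoots
the odds ratio below 1. The type-I-error criterion uses 100 replicates of
200 × 50 cells. These sizes are documented scalings of the stated worlds,
chosen for budget, not tuned to outcomes.

## Known limitations

* The within-patient model's anticonservativeness for mutation-constant
  predictors (above) means per-allele q-values should be interpreted as
  rankings more than calibrated error rates.
* Leave-one-out effect percentages are unstable when the baseline OR is
  close to 1; the implementation refuses the degenerate case but cannot
  make a weak baseline informative.
* The virtual-cohort independence assumption overstates how many distinct
  patients carry rare mutations in real data.
* PHBR aggregation intentionally compresses to the best-presented window;
  mutations creating several mediocre binders are indistinguishable from
  mutations creating one.
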