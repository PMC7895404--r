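# phbrsel

**MHC presentation scores and immunogenic-selection analysis for cancer
hot spot mutations.**

Cancer driver mutations can create neoantigens — mutated peptides presented
by a patient's HLA molecules. If immune surveillance restricted which
drivers a tumor keeps, mutations observed in a patient should be those
their MHC genotype presents poorly. But the same statistical signal arises
without any genotype-specific selection when a few very common hot spot
mutations (BRAF V600E-like) yield poorly presented peptides for *every*
genotype. `phbrsel` implements the analysis pipeline that separates these
explanations, for computational immunologists and cancer-genomics
statisticians.

## What it computes

At its core is the **Patient Harmonic Best Rank** (PHBR). For a missense
mutation with flanking protein sequence, enumerate every peptide window
containing the mutated residue (8–11-mers for MHC class I: 38 windows with
full flanks; 15-mers for class II: 15 windows). Given percentile ranks
$r(p, a) \in (0,100]$ from any affinity predictor (lower = stronger
binding), the per-allele Patient Best Rank is
$\mathrm{PBR}_a = \min_p r(p, a)$, and for a genotype with alleles
$a_1,\dots,a_n$ ($n = 6$ or $10$):

$$\mathrm{PHBR} = \frac{n}{\sum_{i=1}^n 1/\mathrm{PBR}_{a_i}}, \qquad
\Delta\mathrm{PHBR} = \mathrm{PHBR} - \mathrm{PHBR_{wt}}.$$

High PHBR = poorly presented mutation. Around this score the package
provides:

* **cohort building** — MAF-style filtering to recurrent driver missense
  mutations and the binary patient × mutation matrix;
* **virtual patients** — Bernoulli simulation from carrier frequencies,
  with isogenotypic (one prototypical genotype for all) or allele-pool
  genotypes;
* **selection statistics** — Wilcoxon observed-vs-unobserved contrasts;
  within-patient / within-mutation random-intercept logistic models
  (odds ratio per unit ln PHBR, Wald CIs); row/column matrix
  randomizations; a leave-one-out odds-ratio attribution scan with the
  1% effect threshold; per-allele scans with BH-FDR;
* **substitution atlas** — the 150 single-nucleotide-reachable missense
  substitution types, 20×20 median-ΔPHBR matrices, amino-acid composition
  regression and Fisher-exact context enrichment;
* **synthetic data** — deterministic rank predictors and planted-hot-spot
  scenario generators, so everything above is testable with no external
  predictor or cohort download.

## Worked example

```r
library(phbrsel)

# Score one mutation against the prototypical class I genotype using a
# synthetic composition predictor with rank-raising glutamates planted
ctx <- protein_context("BRAF_V600E", "BRAF", "V", "E", 600,
                       upstream   = "PPISLQETAGGSPG",
                       downstream = "AFKSRWSGSHQFEQ")
g    <- prototypical_genotype("I")
pred <- random_composition_predictor(g$alleles, seed = 7,
                                     planted_weights = c(E = 0.3))
peps <- unique(c(enumerate_windows(ctx, 8:11),
                 enumerate_windows(ctx, 8:11, use_alt = FALSE)))
score_mutation(ctx, g, synthesize_ranks(peps, g$alleles, pred))
#> <phbr_score> BRAF_V600E vs prototype_I
#>   PHBR 2.3842  PHBR_wt 1.0611  dPHBR +1.3231  (38 windows)
```

The V→E substitution raises the PHBR from 1.06 to 2.38 (ΔPHBR +1.32): the
planted glutamate weight makes every mutation-containing window a weaker
binder, exactly the phospho-mimicking-substitution mechanism the atlas
module quantifies.

```r
# A planted scenario: 5 common hot spots with elevated PHBR among 100
# driver mutations in 1,000 virtual patients with pool genotypes
scn <- build_scenario(scenario_spec(n_patients = 1000, n_mutations = 100,
                                    n_hotspots = 5,
                                    hotspot_phbr_shift = 0.7, seed = 11))
cmp <- compare_phbr(scn$matrix, scn$phbr)
#> median PHBR observed 0.85 vs unobserved 0.78, p = 1.47e-06

fit_random_intercept_logit(scn$matrix, scn$phbr, "patient")
#> <phbr_fit within_patient, glmer (nAGQ=1)>
#>   OR 2.0883 (95% CI 1.6857-2.5870), p = 1.6e-11, n = 100000, groups = 1000
fit_random_intercept_logit(scn$matrix, scn$phbr, "mutation")
#> <phbr_fit within_mutation, glmer (nAGQ=1)>
#>   OR 1.1442 (95% CI 0.9248-1.4156), p = 0.215, n = 100000, groups = 100
```

Observed mutations have higher PHBR (p = 1.5e-06), and the model pair
shows the signature of frequency-driven structure: the within-patient
model (which does not control mutation frequency) finds OR 2.09 per unit
ln PHBR, while the within-mutation model (random intercept per mutation,
absorbing frequency) finds no effect (CI spans 1). `leave_one_out_scan()`
then attributes the within-patient effect to the planted hot spots.

## Command line

`inst/cli/phbr.R` exposes the pipeline as subcommands (`score`,
`build-matrix`, `simulate`, `synth-ranks`, `fit`, `loo`, `randomize`,
`subst-matrix`, `synth-scenario`), e.g.

```sh
Rscript inst/cli/phbr.R synth-scenario --n-patients 2000 --seed 7 --out scenario/
Rscript inst/cli/phbr.R fit --matrix scenario/matrix.tsv --phbr scores.tsv \
    --model within-patient
```

## Documentation

The methods vignette (`vignettes/phbr-methods.Rmd`) documents the model
and its assumptions, every tunable parameter with units and defaults, the
numerical conventions (rank floor, termini truncation, convergence and
singularity policy), what the synthetic generators do and do not emulate,
and the package's known limitations.
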