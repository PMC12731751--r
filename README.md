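# phylometab

Parsimony phylometabolomics: stratifying patients from untargeted serum
LC-MS metabolomics by cladistic analysis of their metabolite alterations.

## The problem and the approach

Untargeted LC-MS metabolomics of patient serum yields thousands of aligned
features (m/z, retention time, per-specimen intensity). Conventional
multivariate analyses reduce these to a few components or a handful of
differential features; this package instead treats each patient's
deviation profile as a set of **cladistic characters** and builds a
hierarchical classification of specimens — a cladogram — from them. It is
aimed at researchers analysing treatment-response cohorts (the motivating
application is prostate-cancer radiotherapy, with serum drawn before and
after treatment and a healthy outgroup) who want subgroup structure plus
the specific metabolites that define each subgroup.

The pipeline:

1. **Polarization.** For every feature, the healthy outgroup defines a
   normal intensity range (default: the outgroup min–max). Each patient ×
   feature cell is coded against it: within range → ancestral
   (plesiomorphic, `0`); outside it → derived (apomorphic, `1`). The
   direction of every derived call is kept as metadata:

   | observation | outgroup detected the feature | code | direction |
   |---|---|---|---|
   | intensity > hi | yes | 1 | up |
   | intensity > hi | no  | 1 | novel |
   | 0 < intensity < lo | yes | 1 | down |
   | not detected | yes | 1 | vanished |
   | not detected | no | 0 | none |

2. **Maximum parsimony.** The binary specimen × character matrix, plus an
   all-ancestral hypothetical taxon for rooting, is analysed by Wagner
   parsimony — for binary unordered characters, exactly Fitch counting:
   the tree minimising the total number of 0↔1 state changes
   L(T) = Σ_c min-changes(c, T). Search is by randomized and input-order
   stepwise addition with SPR (or NNI) branch swapping; an exhaustive
   (2n−5)!!-topology oracle certifies small instances. Fit quality is
   summarised by the consistency index CI = (variable characters) / L(T).

3. **Synapomorphy extraction.** Derived states are mapped onto the rooted
   cladogram; the characters derived in every member of a clade and in no
   one else are that clade's synapomorphies — the metabolite alterations
   that define the subgroup. Autapomorphies (single-specimen alterations)
   are reported separately, and a minimum-change (ACCTRAN/DELTRAN)
   reconstruction handles homoplasious data.

4. **Clinical correlation.** Clade membership is cross-tabulated with
   covariates (PSA, ADT, D'Amico risk group, metastasis, ...); biosignature
   carrier prevalences are reported per group, and Fisher / chi-square
   tests quantify clade–covariate association.

5. **Annotation.** Feature m/z values are matched against a local compound
   mass table at a ppm tolerance (default 5 ppm) under H, Na and K adduct
   conventions for putative identification.

A synthetic-cohort generator (`generate_cohort()`, `generate_null_cohort()`)
plants known clade structure, effect directions and clinical covariates so
that every stage is testable without access to patient data.

## Worked example

The numbered scripts under `analysis/` run a complete worked analysis on a
simulated cohort (16 patients, 20 healthy outgroup specimens, five nested
planted clades of 8 markers each, 150 noise features, log-normal noise):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_polarize.R
Rscript analysis/03_infer_cladogram.R
Rscript analysis/04_synapomorphies.R
Rscript analysis/05_clinical_correlates.R
Rscript analysis/06_annotation.R
Rscript analysis/07_null_calibration.R
```

Stage 03 prints, for this cohort:

```
Maximum-parsimony search: 10 random-addition replicates + 1 input-order replicate, swap = spr
 best length: 234   distinct best trees: 8
consistency index: 0.571 (1 = homoplasy-free; a single MP tree with high CI indicates clean data)
Robinson-Foulds distance to the planted tree: 5
```

i.e. at this noise level the search keeps 8 equally parsimonious trees
whose strict consensus still differs from the planted ladder at a few
poorly supported nodes — homoplasy from rank noise (a patient cell lands
outside the outgroup min–max with probability 2/(n_outgroup+1) even with
no planted effect). Stage 04 then reports

```
recovered 38 clade-defining characters; 37/40 planted markers found
precision 0.974, recall 0.925
```

so the clade-defining metabolites are recovered almost perfectly even
where deep topology is uncertain. At zero noise the recovery is exact:
one MP tree, Robinson–Foulds distance 0, precision = recall = 1 (this is
asserted by the test suite over 20 seeds).

Stage 05 also reproduces the published biosignature prevalences from the
packaged clinical fixtures, e.g. D-tryptophan altered in 7 of 11
metastatic patients (63.6%), hypoxanthine in 11 of 11 (100%), phosphoric
acid in 5 of 11 (45.5%), and ADT prescribed to 13 of 55 patients (23.6%).

## Layout

```
R/                 package code (polarization, parsimony, synapomorphy,
                   clinical, annotation, synthetic cohorts, pipeline)
analysis/          numbered worked-analysis scripts (write to results/)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (model, assumptions, design choices)
inst/extdata/      example local compound mass table
```
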