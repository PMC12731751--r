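---
title: "Methods: parsimony phylometabolomics of untargeted LC-MS profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony phylometabolomics of untargeted LC-MS profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylometab)
library(ape)
```

This vignette is the package's account of its own methods: the model and
its assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.

## The character model

The analysis treats a cohort's untargeted LC-MS feature table as a
cladistic data set. Each feature (an aligned m/z × retention-time peak
with per-specimen intensities) becomes one **binary character**; each
patient specimen becomes one **taxon**. A panel of healthy outgroup
specimens defines, per feature, the *normal* intensity range, and a
patient cell is coded **ancestral (0)** when its intensity lies inside
that range and **derived (1)** otherwise. Four kinds of deviation are
distinguished — up- and down-regulation of a peak the healthy panel also
shows, a *novel* peak absent from every healthy specimen, and a
*vanished* peak the healthy panel shows but the patient lacks. The
character matrix itself stays strictly binary; the direction is carried
as metadata so that reports can say *how* a clade's defining metabolites
are altered. Coding all specimens against the same fixed outgroup, rather
than clustering raw intensities, is the central modelling commitment: it
makes "abnormal" an explicit, asymmetric state with a biological polarity,
and it hands the grouping problem to a method designed for shared derived
states.

Assumptions this encodes:

- the healthy panel spans the normal biological and technical variation of
  each feature (see the outgroup-size discussion below);
- a missing cell means *peak not detected* and is equivalent to intensity
  0 (XCMS-style fill-in conventions differ; the reader declares one
  dialect and the polarizer applies one rule);
- pre- and post-treatment specimens of one patient are coded against the
  same outgroup snapshot;
- intensities are comparable across specimens as provided — the package
  performs no normalisation, drift correction or batch adjustment of its
  own (out of scope by design; see Limitations).

### Normal-range estimators

`compute_normal_ranges()` offers two estimators:

- **min–max** (default): the most literal reading of a normal range and
  the one used throughout the package's own analyses. Its false-derived
  rate follows from rank statistics: with $n$ exchangeable outgroup
  specimens, a patient cell drawn from the same distribution falls above
  the outgroup maximum with probability $1/(n+1)$, and below the minimum
  likewise, i.e. a per-cell floor of $2/(n_\mathrm{outgroup}+1)$. Ten
  healthy specimens imply ~18% spurious derived calls per cell; thirty
  imply ~6.5%. This floor, not the effect size, is usually what limits
  recovery on noisy cohorts, which is why the worked example uses a
  20-specimen panel.
- **mean ± k·sd** (`mean_k_sd`, `k = 2` by default), clipped at zero:
  tighter control of the false-derived rate under approximate normality,
  at the cost of a distributional assumption on log-intensities.

Whether the upstream parser of the original instrument software trims
outgroup outliers before setting ranges is not publicly documented; no
trimming is performed here, and `k` plus the `min_intensity` detection
floor (default 0) are the exposed knobs.

## Tree inference

With an all-ancestral hypothetical taxon appended (`HTU`), the matrix is
analysed by **maximum parsimony**. For binary unordered characters Wagner
parsimony is exactly **Fitch counting**, so `fitch_length()` implements
the Fitch post-order pass (state sets as 2-bit masks, vectorised across
characters, rooted at an arbitrary leaf — the count is rooting-invariant).

The default search mirrors classic practice with the MIX-style programs:
one **input-order** stepwise-addition replicate (the "non-randomized
input") plus 10 seeded **random-addition** replicates, each refined by
first-improvement **SPR** branch swapping (NNI available as a cheaper
move set) until no improving move exists. All distinct equally
parsimonious topologies encountered are retained (cap 100, deduplicated
by split sets); when more than one survives, the shipped cladogram is
their **strict consensus**, and the tree is rooted on the edge subtending
the hypothetical ancestor. `exhaustive_search()` enumerates all
$(2n-5)!!$ topologies up to a 9-taxon guard and serves as the exact
oracle: the test suite checks heuristic = exhaustive on 100 random 5–7
taxon matrices, and `fitch_length()` against brute-force enumeration of
ancestral labelings.

Numerical/tie-break choices, all made for reproducibility:

- stepwise addition resolves equal-length placements to the lowest-index
  attachment edge;
- per-replicate seeds are derived deterministically from one master seed
  (kept within 32-bit range);
- branch swapping accepts the first improving move in a fixed sweep
  order; at the local optimum one further sweep collects equal-length
  neighbours so multi-tree plateaus are reported rather than hidden.

The **consistency index** CI = (variable characters)/L(T) is reported as
the homoplasy diagnostic; CI = 1 is a perfect (homoplasy-free) fit, and a
single MP tree with high CI is the expected signature of clean data. CI
is undefined on a zero-length tree and returned as `NA` with a
`defined = FALSE` attribute.

## Synapomorphies

`extract_synapomorphies()` exposes two accountings:

- **strict** (default): a character annotates a node iff it is derived in
  every leaf of that clade and in no leaf outside — the
  unique-and-unreversed reading of "shared derived characters of the
  group". Each character annotates at most one node; single-specimen
  alterations (autapomorphies) are reported in their own table rather
  than as clade labels.
- **reconstructed**: a minimum-change ancestral reconstruction (Sankoff
  dynamic programme with unit costs, root fixed to the all-ancestral
  state) places every 0→1 change on an edge; a character annotates every
  node on whose stem edge a gain falls, so homoplasious characters may
  mark several nodes. Ties between equally parsimonious placements are
  resolved by **ACCTRAN** (changes pulled rootward, default) or
  **DELTRAN** (changes delayed tipward).

On homoplasy-free data the two accountings agree exactly, and the implied
change count per character equals the Fitch length — both are asserted in
the tests. Published clade counts in this field sometimes sum
inconsistently across nested nodes; exposing both accountings (plus the
shared-synapomorphy query for pairs of clades) lets users reproduce
either convention explicitly.

## Clinical correlation

Clade membership is taken from the rooted cladogram either by successive
root splits or by the **most balanced internal edge** ("the two major
clades"); the latter is what the calibration study uses, because basal
splits of weakly structured trees are often singletons. Prevalences are
percentages rounded **half-up to one decimal** (so 7/11 → 63.6 and
5/11 → 45.5, matching the printed convention of the motivating study).
Association between clade and a categorical covariate is tested by
Fisher's exact test (2×2) or Pearson's chi-square without continuity
correction (larger tables, or on request). No multiplicity correction is
applied; screens report how many tests they ran so users can correct.

The choice of test matters for calibration studies: conditionally exact
tests are discrete and conservative *by construction*, so their p-values
cannot be uniform under the null. The packaged calibration
(`null_association_calibration()`) therefore uses the chi-square branch
on cohorts of 30 patients with a three-level covariate, which keeps every
expected cell count at or above ~5. Two hundred null cohorts give
Kolmogorov–Smirnov uniformity p-values comfortably above 0.01, though a
mild residual discreteness of the statistic remains visible (KS D around
0.05–0.1), so the KS p-value itself fluctuates from seed to seed — a
property of testing discrete data against a continuous reference, not of
the implementation.

### Packaged clinical fixtures

`load_table1_fixture()` and `load_table2_fixture()` package the
motivating study's printed cohort margins (55 patients; risk 14/34/7;
ADT 13/42; 11 metastatic — 3 low, 6 intermediate, 2 high risk, 4 on ADT)
and biosignature counts (e.g. D-tryptophan 7/11 metastatic pre-RT,
hypoxanthine 11/11, phosphoric acid 5/11 post-RT). Only the margins are
published; per-patient values (ages, individual PSA trajectories,
which patients carry which marker) are **synthetic** assignments
consistent with those margins, and the documentation marks them as such.
Two printed subgroup records (carbamic acid 6/7, phosphoric acid 5/7) use
a 7-patient denominator that conflicts with the 11 metastatic patients
reported elsewhere in the same source; they are stored as printed,
unreconciled, rather than silently harmonised. Likewise the risk margins
follow the printed table (14/34/7, which sums to 55) over the running
text (14/29/7, which does not), and the ADT percentage (23.6%) uses all
55 patients as denominator, matching the table's percentage column.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not raw spectra:

- **Baseline intensities** are log-normal per feature (location uniform
  on log 10³–10⁶ counts, scale `noise_sd` = 0.3 natural-log units by
  default) — the conventional LC-MS abundance model, declared here as an
  assumption. `noise_sd = 0` gives noise-free cohorts.
- **Planted clades** form a nested ladder by default (five clades of five
  markers, echoing a five-subclade cladogram); each planted marker shifts
  every clade member multiplicatively outside the outgroup range (3× the
  outgroup max for *up*, ⅓ the min for *down*; defaults chosen to
  guarantee polarization at default settings), or realises *novel* /
  *vanished* presence patterns.
- **Clinical covariates** default to the motivating cohort's margins
  (risk 14/34/7, ADT 13/55 among intermediate/high risk, metastasis
  11/55) and are drawn **independently of clade structure** — mirroring
  the finding that clades did not track hormonal treatment, risk,
  metastasis or PSA; an optional knob couples metastasis to one clade for
  power studies.
- m/z is uniform on 50–850 Da and retention time on 0–10 min, the
  acquisition window and run time of the emulated assay.

What it does **not** emulate: chromatographic drift, batch effects,
adduct/isotope feature redundancy, heteroscedastic (intensity-dependent)
noise, or correlated metabolite panels. Passing tests on these cohorts
therefore demonstrate correctness of the inference chain under the
declared model, not robustness to instrumental artefacts.

`generate_null_cohort()` removes all planted structure; its documented
per-cell derived rate $2/(n_\mathrm{outgroup}+1)$ under min–max
polarization is verified by simulation in the tests.

### Problem sizes used in the packaged studies

The validation studies are sized for a single core: oracle-equivalence on
5–7 taxon matrices (where exhaustive enumeration is exact and cheap),
planted-recovery cohorts of 3–6 patients with 2–5 nested clades (so
MP-tree uniqueness can be *certified* by exhaustive search rather than
trusted to the heuristic), the worked example at 16 patients, and
calibration at 200 cohorts of 30 patients. These are the package's own
choices of demonstration scale; the algorithms themselves have no such
limits beyond the usual combinatorial growth of tree space.

```{r recovery, eval = TRUE}
coh <- generate_cohort(cohort_config(
  n_outgroup = 4, n_patients = 6, n_clades = 5, syn_per_clade = 3,
  n_noise_features = 20, noise_sd = 0, seed = 7
))
rng <- compute_normal_ranges(coh$feature_table, coh$manifest)
pm <- append_hypothetical_ancestor(polarize(coh$feature_table, rng, coh$manifest))
search <- heuristic_search(pm, n_replicates = 4, seed = 11)
search
clado <- root_on_outgroup(search$trees[[1]], "HTU")
extract_synapomorphies(clado, pm)
```

## Degenerate inputs and edge rules

- The mass-range filter is a **closed** interval (inclusive "50 to 850"
  reading); empty results propagate as empty tables, not errors.
- A missing internal standard is a report outcome, never an error; ppm
  deviation is $|obs-exp|/exp \times 10^6$, evaluated on the adduct m/z
  for annotation (whether a 5-ppm instrument spec applies to neutral or
  adduct mass is not documented; the adduct convention is declared here).
- Association tables with an empty row or column are flagged degenerate
  and return no p-value.
- Adducts are singly charged only (+H, +Na, +K, −H; proton mass
  1.007276 Da, Na−H +21.981944, K−H +37.955881). Instrument-reported
  lock-mass values can deviate from exact theoretical adduct masses by
  more than 5 ppm and are treated as reference values, not oracles.
- Characters are kept in full by default (no a priori selection);
  `drop_uninformative_characters()` is an explicit opt-in speed switch
  whose removals are returned so autapomorphy accounting can re-attach
  them.

## Known limitations

- **No spectra.** The pipeline consumes aligned feature tables; peak
  picking, alignment and identification against spectral libraries are
  upstream concerns. Annotation is putative, against a user-supplied
  local mass table only.
- **Outgroup size drives specificity.** The min–max false-derived floor
  $2/(n+1)$ means small healthy panels yield noisy matrices; the
  mean ± k·sd estimator or a larger panel is advisable below ~10 healthy
  specimens.
- **Heuristic search is heuristic.** Above the exhaustive guard there is
  no optimality certificate; the defaults (11 starts + SPR) recover the
  exact optimum on every tested instance, but hard instances exist.
- **QC injections.** Pooled-QC drift normalisation is not performed; QC
  columns are accepted but unused.
- **No survival or recurrence modelling**, and no multivariable risk
  models; the clinical module stops at contingency-level association.
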