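---
title: "Pyrrolizidine-alkaloid screening in honey: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyrrolizidine-alkaloid screening in honey: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patox)
```

This vignette is the package's own account of the science it implements:
what is modelled, which parameters matter, what the synthetic data do and
do not emulate, and where genuinely open design choices were settled.

## 1. The compound panel and exact-mass arithmetic

The regulated panel comprises 35 pyrrolizidine alkaloids (PAs) and their
N-oxides (PANOs): the lycopsamine-type monoesters (the C15H25NO5 isomer
block and the heliotrine series), the open-chain diesters (echimidine,
heliosupine, lasiocarpine), the senecionine-type macrocyclic diesters and
otonecine-type senkirkine, each paired with its N-oxide where regulated.
Some printed versions of this list circulate with a duplicated
senecivernine pair and a missing echinatine pair; `regulated_panel()`
follows the Regulation (EU) 2023/915 panel, which includes echinatine and
echinatine N-oxide — the pair is needed because echinatine + rinderine is a
routinely reported analyte group.

Ion m/z values are computed from hard-coded monoisotopic element masses
(6 d.p.) with one electron mass subtracted per positive charge. This level
of care matters: the diagnostic platynecine water-loss fragment must come
out at 140.1070 exactly, and the protonated base at 158.1176.

A note on a literature inconsistency: platynecine (C8H15NO2) is sometimes
printed with \[M+H\]+ = 156.1, which is the value for *retronecine*
(C8H13NO2). The package always stores the formula-derived value and
surfaces the conflict through `known_literature_discrepancies()`; the
printed 156.1 is deliberately not reproduced.

Unresolved isomer pairs — indicine/lycopsamine, echinatine/rinderine,
indicine N-oxide/intermedine N-oxide — are modelled as co-elution groups
and reported as group sums throughout (32 reporting analytes for 35
compounds).

## 2. The in-silico MS/MS library

Literature fragmentation compilations list, per compound: name, formula,
adduct, precursor, fragment m/z and (sometimes) relative intensities.
`parse_fragmentation_table()` converts such tables to spectrum records with
two strict rules:

* **missing intensities become exactly 100** for every fragment — matching
  is then driven by ion presence, not ion ratios, which is the honest
  choice when the source spectra come from heterogeneous instruments;
* missing precursors are computed from formula + adduct; rows with
  fragments but neither formula nor precursor are rejected.

`write_msp()`/`read_msp()` use plain NIST-style text blocks (Name /
Formula / PrecursorMZ / Adduct / RT / Comments with `provenance=` and
`citation=` pairs / Num Peaks / peak lines), chosen for maximal
interoperability; round-trips are exact to 4 d.p. on m/z and 1 % on
intensity.

The shipped default library (`in_silico_library()`) is a **synthetic
reconstruction**: each compound carries the fragment cations typical of its
necine class (e.g. 94.0651, 120.0808, 138.0913, 156.1019 for
retronecine/heliotridine esters; 136.0757, 154.0863, 172.0968 for
N-oxides; 122.0964, 150.0913, 168.1019 for otonecine) plus its own
in-source water loss. Saturated necines (platynecine) additionally retain
the dehydropyrrolizidinium series through H2 losses under collisional
activation — that overlap is what lets a platynecine-like unknown associate
with the ester cluster in networking, mirroring practice. No third-party
spectra are redistributed.

The **class-coverage ion list** (`default_class_ion_list()`) merges
fragment ions recurring in ≥ 3 library compounds with a curated set of
standard-observed fragment cations, deduplicated at 5 ppm; the default
build yields 30 ions. The true published 30-ion table is not public, so
this list is a labelled reconstruction with the same size and role.

## 3. The synthetic cohort and raw-run generator

`generate_cohort()` draws an 80-sample survey with fixed type counts
(orange blossom 15, eucalyptus 11, thyme 7, rosemary 17, wildflower 18,
lavender 5, heather 3, albaida 2, oak 1, anise 1). Its defaults are the
study conditions the package targets:

* **Per-type prevalence** (probability a sample carries ≥ 1 quantifiable
  PA): eucalyptus 0.91, wildflower 0.78, orange blossom 0.53, rosemary
  0.35. The remaining six types have no published rates; they default to
  0.50 and are configurable.
* **Analyte pattern**: a positive sample carries a truncated-geometric
  number of analytes (decay solved so the expected count equals the sum of
  the marginal detection targets; most positive samples carry 1–2 PAs),
  drawn by weighted sampling. The default weights are calibrated so that
  realized marginals land at the reported occurrence structure — indicine +
  lycopsamine in ~30 % and echimidine in ~28 % of samples overall, the
  other commonly detected analytes around 10 % of positives. The inflation
  of the large weights relative to their targets compensates the flattening
  of inclusion probabilities under without-replacement sampling.
* **Concentrations**: log-normal with median 1.5 µg/kg and σ(log) = 1,
  truncated at 30 µg/kg per analyte — chosen so that a survey's maximum
  lower-bound total lands in the upper-twenties µg/kg range. Values below
  the LOQ (0.1 µg/kg) are censored to `"<LOQ"`.
* **PANOs are absent by default** (`pano_present = FALSE`), reflecting
  their fast degradation in honey; a flag restores them for sensitivity
  analyses.

`generate_run()` turns a concentration vector into a DDA-style run:
spiked features with area = concentration × slope (default slope
2 × 10⁶ area units per µg/kg, so the 0.1 µg/kg LOQ level still clears the
10⁵ intensity filter), m/z jittered with sd 5/3 ppm (≥ 99 % of true
features inside a 5 ppm window), fixed synthetic retention times spread
over 2–15 min (necine bases near the void at 1.6–1.8 min), and MS2 spectra
drawn from the library with multiplicative intensity noise for every
feature above the DDA trigger. Each run adds 400 background features with
random m/z in 50–750, log-normal areas around 5 × 10⁴ and uniform peak
ratings; ~30 % of them carry random-fragment MS2. Blanks share the
background model with no spikes; calibration series scale areas by a
matrix-slope factor (0.86 emulates −14 % suppression).

**What the simulator does not emulate**: chromatographic peak shapes,
isotope patterns, adduct redundancy, real co-eluting matrix chemistry, or
instrument drift. Passing tests therefore demonstrate that the *logic* of
the cascade, networking and statistics is correct under controlled
conditions — not that the workflow's real-data performance figures follow.

## 4. Screening cascade and scoring

The cascade applies, in order: apex intensity ≥ 10⁵ → peak rating
strictly > 4 → RT ∈ [1, 15] min; mass error ≤ 5 ppm applies at annotation
time (it needs a candidate reference). Blank subtraction removes a
sample feature matching a blank feature (5 ppm, 0.2 min) only when the
sample/blank area ratio is ≤ 5. The class-coverage filter then requires
≥ 1 diagnostic ion in the feature's MS2. Because the simulated peak-quality
rating is uniform for background and high for genuine peaks, the filters
are individually testable: the survivor set equals an independent
brute-force application of each rule.

Annotations are ranked by source priority (in-house MS2 > external MS2 >
mass list > predicted formula), then similarity score, then |mass error|.
Confidence follows the Schymanski scale: level 1 needs MS2 + RT match to an
authentic standard, level 2 MS2 library evidence, level 3 class evidence,
level 4 formula, level 5 mass only. The FISh-style score is the percentage
of observed peaks (above a 1 % relative-intensity floor) explained by a
candidate's fragments.

S/N is estimated as apex over the run's baseline level; the peak-rating
proxy stands in for a vendor's undocumented rating, with the > 4 threshold
kept verbatim.

## 5. Molecular networking

Pairwise similarity uses greedy best-pair fragment matching within 5 ppm
(pairs taken by decreasing intensity product, each peak used once), then an
intensity-weighted cosine over matched pairs with norms over all peaks,
scaled to 0–100 so the published thresholds (score ≥ 20, coverage ≥ 20 %)
apply directly; the vendor's exact formula is undocumented. Forward and
reverse coverage are intensity-weighted by default; a peak-count mode
exists (`coverage = "count"`) because the vendor definition is ambiguous.

Edges require score, coverage (forward *or* reverse) and ≥ 3 matched
fragments; each node then keeps its top 10 edges (an edge survives if
either endpoint retains it); components above 100 nodes are split by
iteratively deleting their weakest edge (ties broken lexicographically) —
the cap-enforcement mechanism is unstated in the source workflow, and
weakest-edge removal is the deterministic choice that degrades cluster
cohesion least. Node order is canonicalized, so results are invariant to
input permutation. With the default in-silico library the 35 standards
form two PA clusters (free bases, 18 incl. senkirkine via shared core
ions; N-oxides, 17) and every standard connects to ≥ 1 other standard.
A query is flagged a *putative PA* when its cluster holds ≥ 3 annotated
PAs.

## 6. Quantification and validation metrics

Calibration is unweighted OLS of area on concentration (no weighting is
claimed by the reference workflow); R² ≤ 0.99 raises a `low_linearity`
flag. ME% is the slope-ratio deviation; recovery is the
before/after-extraction area ratio × 100; precision is 100 × sd/mean; the
LOQ is the lowest calibration level with S/N ≥ 10. Positivity requires
S/N ≥ 3 **and** ion-ratio agreement **and** concentration ≥ LOQ; the
ion-ratio tolerance defaults to ±30 % relative (a SANTE-style default —
the source rule says "should match" without a number) and is configurable.
Negative back-calculated concentrations clip to zero with a flag.

The lower-bound sum counts censored and absent analytes as zero and each
co-elution group once; `upper_bound_sum()` (censored = LOQ) is provided for
sensitivity analysis. Semiquantification of level ≤ 2 suspects borrows the
curve of the structurally nearest regulated analog (same ester type and
N-oxidation state, falling back to necine class) and labels the result
semiquantitative; with no analog the estimate is withheld.

## 7. Occurrence statistics

Statistics code censored values as zero (the lower-bound convention used
for totals; `censored = "omit"` is available for the ANOVA). Honey types
with fewer than five samples (heather, albaida, oak, anise in the default
cohort) are excluded from ANOVA and HCA. Reported percentages are rounded
to integers, raw fractions retained. The one-way ANOVA is a fixed-effects
F-test per analyte (or the total) against honey type; p-values are
unadjusted, matching how such surveys report them. HCA uses Euclidean
distance with Ward linkage (`ward.D2`, the Ward criterion on Euclidean
distances) on z-scored analyte columns; raw-scale mode is available since
standardization is a choice the source leaves silent.

## 8. Numerical and testing choices

* Tolerances are expressed in ppm everywhere (5 ppm default), not absolute
  Da; deduplication keeps the earliest entry.
* Seeds: every generator takes an explicit seed; identical config + seed
  gives identical output.
* Problem sizes in the test and acceptance runs were picked for desk-scale
  execution: 50 simulated runs for the cascade-equivalence check, 200
  cohorts for prevalence recovery, 20 runs and 50 cohorts in the
  acceptance script. Prevalence recovery is asserted with
  Bonferroni-adjusted simultaneous binomial bounds across the ten honey
  types (a family of ten 95 % checks would false-alarm ~40 % of the time).
* The calibration series in the acceptance script uses 7 levels × 3
  injections so the ME estimate's sampling noise (~1 point) is small
  against the −14 % suppression it measures.

## 9. Known limitations

* The in-silico spectra are class-template reconstructions; they validate
  workflow logic, not spectral prediction accuracy.
* Real-data figures that depend on raw instrument files (feature counts
  before/after refinement, FISh scores of specific acquisitions,
  per-sample concentration tables of the original survey) cannot be
  recomputed here; the package reproduces their *rules* and exposes the
  same code paths for user-supplied tables in the documented CSV layout.
* The simulator's independence assumptions (between analytes, between
  samples) understate the biosynthetic correlation structure of real PA
  profiles; the correlation and HCA demonstrations therefore use
  explicitly co-generated analytes.
* Supervised classification of botanical origin from PA profiles is out of
  scope (it performs poorly on cohorts of this size and imbalance).
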