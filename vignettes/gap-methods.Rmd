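---
title: "GAP modelling of flesh texture retainability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GAP modelling of flesh texture retainability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapred)
```

This vignette documents the statistical model behind `gapred`, the
assumptions it makes, the tunable parameters and their defaults, what the
bundled simulator does and does not emulate, and the design decisions taken
where the methodology left genuine freedom.

## 1. Phenotype model

### Retainability

A hybrid's flesh firmness (or crispness) is measured monthly during cold
storage, months 0 through 6, in kg/cm². *Retainability* is the maximum
storage time in whole months during which the trait stays at or above its
acceptability threshold — 7.0 kg/cm² for firmness, 0.7 kg/cm² for crispness.
`compute_retainability()` implements this as: the measured month immediately
before the first month whose value falls below the threshold; 0 when
acceptability is already lost at harvest; the last measured month, flagged
*censored*, when the series never crosses.

Three reading choices deserve a note:

* **No interpolation.** Retainability is reported on the measured monthly
  grid because the phenotype is recorded and reported in whole months.
  Fractional crossing times would suggest precision the assay does not have.
* **Continuity.** "Maintained" is read as *maintained continuously*: a
  single sub-threshold dip followed by recovery terminates retainability at
  the first crossing. Measurement noise can therefore shorten a score — see
  the noise discussion in §4.
* **Censoring.** The storage horizon (6 months by default) caps the score;
  censored records enter downstream class means as-is. Descriptions of
  "6–7 month" retainers are treated as month-6 censored observations rather
  than extrapolated to 7.

### Softening types

`classify_type()` maps each scored series to a softening-dynamics class:

* **Type I** — retainability 0 (acceptability lost at harvest);
* **Type II** — retainability ≥ 6 after a *rapid* first-month drop;
* **Type III** — retainability ≥ 6 with a constant slow decline;
* everything else (retainability 1–5) is `unclassified` — in a segregating
  population this is the majority, and these hybrids are never bulked.

The rapid/slow boundary is not a published constant. The default
`rapid_drop` is 1.0 kg/cm² for firmness and 0.1 for crispness, mirroring
the 10:1 ratio of the acceptability thresholds; both are arguments. A
month-6 retainer with no month-1 measurement cannot be assigned II vs III
and is returned `unclassified` with a warning.

### Broad-sense heritability

`estimate_h2()` uses a one-way random-effects ANOVA with hybrids as groups
and years as replicates: with `r` years, `var_g = (MS_hybrid − MS_error)/r`
clamped at zero, `var_e = MS_error`, and on the default *plot basis*
`H² = var_g/(var_g + var_e)`. The estimator behind published multi-year H²
values for this trait family is not stated anywhere we could verify, so the
plot basis was chosen as the conservative default and the *entry-mean*
basis (`var_g/(var_g + var_e/r)`, the heritability of hybrid means) is
available via `basis = "entry_mean"`. Printed H² values are consequently
not treated as reproduction targets. Hybrids missing any observed year are
dropped to keep the design balanced; the estimate is invariant to shifting
and rescaling the phenotype.

## 2. Marker effects and the GAP model

For each biallelic marker, genotype calls are normalized to unordered
allele pairs (`"G:A"` ≡ `"A:G"`; a single-allele call is read as
homozygous). The effect of genotype class *c* at marker *m* is

> effect(m, c) = mean(OPV of hybrids in class c) − overall mean OPV,

with the overall mean pooled across all phenotyped training hybrids and
crosses. Hybrids with a missing call at *m* are excluded from that marker's
class means but kept in the overall mean (maximizes data use; the
alternative — dropping them from the overall mean too — changes effects by
a negligible constant in large samples). Classes smaller than `min_class_n`
(default 3) are flagged and contribute a zero effect rather than a noisy
one. With complete calls and all classes retained, the count-weighted
effects at each marker sum to zero exactly; this is asserted to 1e-9
relative tolerance in the tests.

The genomics-predicted value pyramids the effects:

> GPV = overall mean + Σ over markers of effect(m, class of the hybrid).

Only hybrids genotyped at every model marker receive a GPV. A test-set
genotype class unseen in training contributes zero with a logged warning
rather than failing the prediction — this keeps cross-validation folds
intact and is auditable from the warning count.

**Effect span and allelic action.** The scalar "effect" of a marker is
reported as the range (max − min) of its retained class means. Published
texts give per-marker effect magnitudes without defining the scalar; the
range was chosen because class-mean plots display exactly that quantity.
Allelic action is classified from the dominance degree |d/a| with
`a = (m₁ − m₂)/2` and `d = m_het − (m₁ + m₂)/2` computed from the class
means: additive ≤ 0.2 < partial dominant < 0.8 ≤ complete dominant ≤ 1.2 <
overdominant, and undetermined when |a| < 1e-8 or when the marker does not
show exactly two homozygote classes and one heterozygote class (so
two-class, backcross-type markers are undetermined by construction). The
bin edges are the conventional quantitative-genetics ones; they are
arguments, since the class names are used in the field without numeric
thresholds.

### Accuracy and cross-validation

Prediction accuracy is the Pearson correlation of GPV and OPV. Both
resubstitution accuracy (train = test) and k-fold cross-validation are
exposed and labelled, because published full-data accuracies of this method
are consistent with resubstitution while the cross-validated figures are
lower. `gap_cross_validate()` uses simple random, unstratified partitions
into k near-equal folds, refits everything (overall mean included) on the
training folds, and reports the unweighted mean over k × runs fold
correlations (default 5 × 5). Folds with undefined correlation are skipped
and counted. All partitions derive from one seed.

### Simulative selection

`simulate_selection()` selects hybrids with GPV ≥ criterion (ties selected,
matching the "equal to or longer than" reading), reports the selection rate
over hybrids that have a GPV, and the efficiency — the fraction of selected
hybrids whose OPV also meets the criterion; efficiency is undefined when
nothing is selected. Rate is non-increasing and selected sets are nested as
the criterion rises; both are property-tested.

## 3. Candidate-gene filtering

`filter_candidates()` applies four conjunctive rules to genes in QTL
intervals: (R1) the gene span overlaps ≥ 1 interval by at least 1 bp under
0-based half-open arithmetic; (R2) the gene carries ≥ 1 variant disrupting
a promoter cis-element or a protein functional domain; (R3) expression is
detectable (max expression above a configurable floor, default 0); (R4) the
gene is not a promoter-only case — impactful variants confined to the
promoter *and* no differential-expression support. The audit trail records
the first rule (in R1..R4 order) that excluded each gene; since the rules
are conjunctive the surviving set is order-independent, which is fuzz-tested.
Whether a variant disrupts a cis-element or domain is consumed as an input
annotation (VCF INFO flags) — computing it is out of scope. The promoter
window is 2,000 bp upstream of the coding start, matching the constructs
used to validate such promoters; it is configurable.

## 4. The synthetic world

### F1 population generator

`simulate_f1_population()` draws each hybrid's genotype at each marker by
Mendelian gamete sampling from the two parental genotypes (het × hom
segregates 1:1, het × het 1:2:1; markers with neither parent heterozygous
are rejected). Genotypic values follow the (a, d) parameterisation — the
two homozygotes at −a and +a, the heterozygote at d — and a hybrid's
genetic value is the sum over markers (no epistasis, no linkage). Yearly
phenotypes add i.i.d. Gaussian noise with variance
`Var(g)·(1 − h²)/h²`, so the plug-in heritability equals `target_h2`
(default 0.84, matching multi-year estimates for these traits). In
*integer mode* yearly values are truncated to [0, 6] and rounded to the
month grid, mimicking observed retainability records; continuous mode skips
both, and the calibration and recovery tests run there because truncation
deliberately distorts variance ratios.

The default panel (`default_marker_panel()`) has 28 both-parent-
heterozygous markers — chosen so that all three genotype classes segregate
and the dominance loop can be closed; backcross-type markers are supported
through explicit `marker_spec()`s. Class-mean spans are evenly spaced
across 0.1–3.5 months, bracketing the per-marker effect magnitudes reported
for these traits, and dominance degrees cycle through 0.5 (most common),
0, 1.0 and 1.4 — partial dominance dominating, additive and complete
dominance less common, a minority overdominant. The intended action label
stored with each marker uses the same |d/a| bins as the estimator.

What the generator does **not** emulate: linkage and recombination maps
(markers are independent, so the sum of per-marker variances is larger than
in linked real panels with overlapping QTL), genotyping error,
non-Gaussian environmental effects, year × genotype interaction, epistasis,
and population structure beyond a per-hybrid cross label. A green test on
this world therefore establishes the correctness of the estimators and
bookkeeping, not field-realistic accuracy levels: clean-world CV
accuracies (≈ 0.94 at h² = 0.84) sit far above what real populations of
this design attain, exactly as expected when marker information is
complete and unlinked.

### Storage-trajectory generator

`simulate_storage_series()` emits noisy monthly trajectories per type:
type I starts below threshold; type II starts above, drops by a fast-phase
amount (default 1.8 kg/cm² firmness) in month 1 and then declines slowly;
type III declines linearly at a slow rate. Defaults keep the noise-free
trajectory at least 4 standard deviations (noise sd 0.05 kg/cm² firmness,
0.005 crispness) clear of every contract boundary, so the closed loop —
generate a type, score it, re-classify it — succeeds in ≥ 95% of draws as
required; parameter sets whose noise-free trajectory cannot satisfy their
type's contract raise an error before any series is emitted.

### Candidate-gene fixture

`simulate_candidate_tables()` assigns each gene one generative scenario —
pass, or fail exactly one of R1/R2/R3/R4 — and materializes intervals,
variants, expression and DEG membership to match. The manifest's survivor
list comes from the scenario labels at generation time, not from running
the filter, so filter tests compare against construction-known truth. A
zero variant budget suppresses all variants, and the manifest then contains
no survivors (nothing can pass R2).

## 5. Numerical choices and degenerate inputs

* Zero-sum and oracle-equivalence checks use 1e-9 (relative/absolute)
  tolerances; all arithmetic is double precision, no compiled code.
* Model JSON is written with full floating-point precision
  (`digits = NA`), so write → read round-trips reproduce effects exactly.
* Degenerate inputs have defined behaviour rather than NA propagation:
  empty series, all-missing markers, constant phenotypes (all effects 0),
  zero markers (mean-only model), zero-variance correlation inputs
  (explicit error), empty selections (rate 0, efficiency undefined),
  `k > n/2` cross-validation (error).
* `var_g` clamping at 0 means H² is 0, not negative, when hybrids explain
  less variance than noise.
* Seeds are mandatory for every stochastic operation; identical seeds give
  byte-identical artifacts (hash-tested through the CLI).

## 6. Known limitations

* Genotype-class effects are estimated marker-by-marker (marginally), as
  the method prescribes. In populations with many unlinked, large-effect
  markers, each class mean carries noise from *all other* markers' genetic
  variance. Effects themselves are recovered well (mean absolute error
  ≈ 0.08 months at n = 5,000, h² = 0.84 on the default panel), but the
  dominance degree |d/a| is a *ratio* of two noisy contrasts: for markers
  with spans below ~2 months its sampling standard deviation is comparable
  to the 0.2–0.3 width of the classification bins, and adjacent-bin flips
  are common (observed recovery: 79% of markers with span ≥ 0.5, against a
  stated 90% goal — every miss an adjacent bin). This is a property of
  marginal estimation, not an implementation defect; joint (multi-marker)
  estimation would reduce it but would be a different method.
* Markers are treated as independent at prediction time; pyramiding
  double-counts overlapping QTL if two markers tag the same locus.
* Two-class (backcross-type) markers get effects but no allelic-action
  class, and contribute no dominance diagnostics.
* The candidate filter trusts its input annotations; it performs no
  variant-effect prediction or motif scanning.
* The Excel layout of published supplementary tables is not parsed; users
  export them to the documented TSV schema first.
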