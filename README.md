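# gapred

Genomics-assisted prediction (GAP) of post-harvest flesh firmness and
crispness retainability for bi-parental fruit-tree breeding populations.

## The problem

Apple flesh firmness and crispness degrade during cold storage, and how long
a hybrid keeps them acceptable — its *retainability*, the maximum storage
time in months with flesh firmness ≥ 7.0 kg/cm² or crispness ≥ 0.7 kg/cm² —
is a quantitative trait controlled by many QTL with dominant and partially
dominant allelic effects. Pure additive genomic selection discards that
non-additive signal. GAP instead works directly on QTL-derived diagnostic
markers: for each biallelic marker it estimates the effect of every genotype
class as the deviation of that class's mean observed phenotype value (OPV)
from the overall training mean, and predicts a hybrid by pyramiding the
effects of its genotypes onto the population mean:

```
effect(m, c) = mean(OPV | genotype at m is c) − mean(OPV)
GPV(hybrid)  = mean(OPV) + Σ_m effect(m, genotype_m(hybrid))
```

Prediction accuracy is the Pearson correlation r(GPV, OPV), evaluated by
resubstitution and by five-fold cross-validation run five times. A GPV
truncation criterion then drives simulative selection (selection rate =
fraction selected; efficiency = fraction of selected whose OPV also meets
the criterion). Each marker's allelic action is classified from the
dominance degree |d/a|, where `a` is half the difference of the homozygote
class means and `d` the heterozygote deviation from their midpoint:
additive (≤ 0.2), partial dominant (< 0.8), complete dominant (≤ 1.2),
overdominant (> 1.2).

The package covers the full analysis path:

* **Phenotyping** — monthly cold-storage firmness/crispness trajectories →
  integer retainability scores (censored at the storage horizon) and
  softening types: I (acceptability lost at harvest), II (retained to month
  6 after a rapid first-month drop), III (retained to month 6 with constant
  slow softening); broad-sense heritability H² from multi-year records by
  one-way ANOVA; trait correlations.
* **GAP modelling** — genotype-class effect estimation with dominance
  classification, GPV prediction (hybrids with missing calls are excluded),
  repeated k-fold CV, simulative selection.
* **Candidate-gene filtering** — genes in QTL intervals are excluded when
  they have no cis-element- or protein-domain-disrupting variant, are not
  detectably expressed, or have impactful variants only in the promoter
  (2 kb upstream) without differential-expression support.
* **Synthetic data** — a seeded F1 simulator (Mendelian gamete sampling,
  (a, d) effect parameterisation, heritability-calibrated noise, type
  I/II/III storage trajectories, candidate-gene fixtures with
  construction-known truth) so every stage is testable without external
  data.

## Worked example

```r
library(gapred)

# simulate a 2,000-hybrid F1 population: 28 markers with class-mean spans
# 0.1-3.5 months, partial dominance most common, H2 = 0.84
sim <- simulate_f1_population(sim_config(n_hybrids = 2000, seed = 1))

model <- gap_fit(sim$genotypes, sim$phenotypes, "firmness_retainability")
pred  <- add_opv(predict(model, sim$genotypes), sim$phenotypes)
gap_accuracy(pred[pred$complete, ])
#> [1] 0.9422199

cv <- gap_cross_validate(sim$genotypes, sim$phenotypes, k = 5, runs = 5, seed = 1)
cv
#> cv_result: 5-fold x 5 runs on 2000 hybrids | mean accuracy 0.9353

sel <- simulate_selection(pred[pred$complete, ], criterion = 5.0)
sel
#> selection_result: criterion 5.00 months | 530/2000 selected (rate 26.50%) | efficiency 87.92% (466/530)
```

Read: on this synthetic population the pyramided marker effects predict
continuous retainability with r = 0.94 in-sample and 0.94 under five-fold
cross-validation, and a 5-month GPV cut-off selects 26.5% of hybrids, 87.9%
of which truly meet the criterion. These are clean-world numbers: real
populations — integer-month censored phenotypes, missing calls, linked
rather than independent loci — sit substantially lower (the `run-all`
pipeline, which simulates integer-mode phenotypes with 2% missing calls,
reports resubstitution 0.88 and CV 0.85 at the same seed).

Retainability scoring from raw trajectories:

```r
s <- simulate_storage_series("II", "firmness", seed = 3)
rec <- compute_retainability(s)        # retainability 6, censored
classify_type(rec, s)                  # "II": first-month drop >= 1.0 kg/cm2
```

## Command line

```sh
Rscript inst/cli/gapred.R run-all --seed 11 --out-dir out/
Rscript inst/cli/gapred.R fit --geno geno.tsv --pheno pheno.tsv --out model.json
Rscript inst/cli/gapred.R cv  --geno geno.tsv --pheno pheno.tsv --seed 17 --out cv.tsv
```

Subcommands: `simulate`, `score-phenotype`, `heritability`, `effects`,
`fit`, `predict`, `cv`, `select`, `filter-candidates`, `run-all`. Published
supplementary genotype/phenotype tables can be analysed by exporting them to
the documented TSV schema (`hybrid_id` + one column per marker with `X:Y`
calls; long-format phenotype table `hybrid_id`, `trait`, `opv`, `year`).

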