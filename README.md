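# discordr

Discordant pair analysis for sample-efficient evaluation of an updated
binary classifier.

## The problem

Replacing a deployed classifier (say, an atrial-fibrillation detector
screening ECG episodes from insertable cardiac monitors) with an updated
model normally requires a fresh, fully adjudicated validation set — every
sample labeled by experts. Discordant pair analysis avoids most of that
labeling: run both the baseline model M0 (whose sensitivity SENS0,
specificity SPEC0 and operating prevalence PREV are already known) and the
updated model M1 on the same n unlabeled samples, cross-tabulate their
predictions, and adjudicate **only the discordant samples** — those on
which the two models disagree.

With P = n x PREV assumed positives and N = n − P negatives, the concordant
true positives cancel between the models (both made the identical call), so
the updated model's metrics are identified by the discordant cells alone:

    SENS1 = (SENS0 * P − TP_0D + TP_1D) / P
    SPEC1 = (SPEC0 * N − TN_0D + TN_1D) / N

where TP_0D, TP_1D are the adjudicated true positives in the two discordant
cells and TN_0D, TN_1D the corresponding true negatives. Confidence
intervals come from a multi-stage Monte Carlo bootstrap that propagates
uncertainty in the prevalence (Beta prior with mean PREV), the realized
class split (Binomial), and the baseline model's performance (Binomial),
finishing with a Beta draw of the metric itself.

The package provides:

- the closed-form estimators and tabulation of paired prediction files
  (`tabulate_predictions()`, `estimate_sensitivity()`,
  `estimate_specificity()`, `adjudication_reduction()`);
- the bootstrap CI machinery (`sample_sensitivity()`,
  `sample_specificity()`, `estimate_with_ci()`, `dpa_report()`);
- a Gaussian-copula simulator of correlated paired predictions with known
  truth (`correlated_bernoulli_pair()`, `simulate_trial()`);
- simulation-study drivers sweeping between-model correlation, sample size
  and prevalence misspecification (`run_correlation_study()`,
  `run_samplesize_study()`, `run_prevalence_study()`);
- a command-line tool (`inst/cli/discordr`) with subcommands `estimate`,
  `simulate`, `study` and `fixture`, including an adjudication-worklist
  export for the labeling step.

## Worked example

`af_example_records()` reconstructs a published evaluation of 4,302
ICM-detected AF episodes scored by a baseline model (sensitivity 98.8%,
specificity 72.7%, prevalence 61.5%) and a specificity-improving update:

```r
library(discordr)

fix  <- tabulate_predictions(af_example_records())
fix$table
#> Paired prediction 2x2 table (baseline rows, updated columns)
#>           updated
#> baseline   positive negative
#>   positive     2640      272
#>   negative       35     1355
#> n = 4302, concordant C = 3995, discordant D = 307

base <- baseline_assumptions(sens0 = 0.988, spec0 = 0.727, prev = 0.615)
dpa_report(fix$table, fix$adjudication, base,
           bootstrap_config(k_samples = 10000, seed = 1))
#> Discordant pair analysis
#>   n = 4302, adjudicated D = 307 (92.9% reduction)
#>   sensitivity  99.1 (95% CI: 98.5, 99.6)
#>   specificity  87.5 (95% CI: 83.8, 91.8)
```

Only 307 of 4,302 episodes needed expert labels — a 93% reduction — yet the
updated model's specificity estimate (87.5%, CI lower bound 83.9–83.8%
depending on seed) demonstrates clear superiority over the baseline's
72.7%. The same analysis from the shell:

```sh
Rscript inst/cli/discordr fixture --out episodes.csv
Rscript inst/cli/discordr estimate --input episodes.csv \
    --sens0 0.988 --spec0 0.727 --prev 0.615 --seed 1 --out report.json
```

If some discordant rows are still unlabeled, `estimate` exits nonzero and
`--worklist todo.csv` writes exactly the rows that need adjudication.

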