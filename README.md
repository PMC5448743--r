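# seromir

Serum miRNA marker discovery and incremental cardiovascular risk value.

`seromir` is for biomarker studies that profile circulating microRNAs on
two-card qPCR array panels (377 unique + 4 control assays per card, 754
miRNAs in total) in patients stratified by a binary disease state — here,
the presence of severe multi-vessel atherosclerosis in elderly ischemic
stroke patients — and then ask the question that matters clinically: *does
the new marker add estimation power to the risk markers we already
measure?*

The package covers the full chain:

- **QC & quantification** — hemolysis screening (absorbance at 415 nm
  < 0.2), replacement of undetermined wells by the 40-cycle limit, and
  relative quantification ΔCt = Ct(miRNA) − Ct(reference),
  Q<sub>rel</sub> = 2<sup>−ΔCt</sup>.
- **Reference selection** — candidate normalisers (detected everywhere,
  fold change 0.9–1.1, t-test p > 0.05) ranked by a model-based
  (NormFinder-type) stability value, `mean over groups of |bias| +
  sqrt(variance/n)`, over all single miRNAs and pairs; the argmin set is
  the reference.
- **Marker discovery** — per-miRNA equal-variance t-tests with a
  <0.5 / >2.0 fold-change filter on Q<sub>rel</sub>, reduced by forward
  stepwise discriminant analysis (partial Wilks' Λ F-to-enter), validated
  in an independent cohort.
- **Risk modelling** — forward logistic regression (likelihood-ratio
  entry, Wald Exp(B) with 95% CI) over clinical covariates plus marker
  Q<sub>rel</sub>, with leave-one-out cross-validated accuracy.
- **Incremental value** — sensitivity/specificity/accuracy at a 0.5
  threshold, ROC AUC (Mann–Whitney) with paired DeLong comparison,
  category-free net reclassification improvement
  NRI = (up<sub>e</sub> − down<sub>e</sub>)/N<sub>e</sub> −
  (up<sub>ne</sub> − down<sub>ne</sub>)/N<sub>ne</sub>, and integrated
  discrimination improvement IDI = Δ(discrimination slope).
- **Synthetic studies** — `simulate_cohort()` plants stable reference
  miRNAs, differential miRNAs with chosen log2 fold changes, per-sample
  offsets, dropout above the detection limit, and clinical covariates with
  realistic group means/SDs, so every stage is testable against known
  ground truth.

See `vignettes/seromir-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(seromir)

disc <- simulate_cohort(simulation_params(n_per_group = 15, seed = 1))
val  <- simulate_cohort(simulation_params(n_per_group = 33, seed = 2))

report <- run_pipeline(disc$panel, disc$cohort, pipeline_config(),
                       validation_panel = val$panel,
                       validation_cohort = val$cohort)
report
#> pipeline_report
#>   QC: 30/30 samples retained
#>   reference: miR-sim-0006/miR-sim-0005 (202 candidates)
#>   markers past filter: 20; discriminant-selected: 5
#>   LOOCV accuracy: base 65.2%, +marker 95.5%
#>   AUC 0.7594 -> 1.0000; NRI 2.0000, IDI 0.7582
```

The reference stage picked a pair of planted stable miRNAs (a pair
averages away independent noise, so it can beat either member):

```r
head(report$reference$stability, 3)
#>                         set size   stability
#> 1 miR-sim-0006/miR-sim-0005    2 0.009487805
#> 2 miR-sim-0001/miR-sim-0005    2 0.011476587
#> 3 miR-sim-0007/miR-sim-0005    2 0.014695039
```

The marker filter reports group means of Q<sub>rel</sub>, the fold change
(event over non-event) and the t-test p-value — planted 4-fold shifts are
recovered with folds near 4 and 0.25:

```r
subset(report$markers$report, passed_filter)[1:4,
       c("mirna", "mean_nonevent", "mean_event", "fold", "p")]
#>           mirna mean_nonevent  mean_event      fold            p
#> 11 miR-sim-0011     3.4534179 20.13678618 5.8309729 0.0001430363
#> 12 miR-sim-0012     1.3209945  0.56684900 0.4291078 0.0010342040
#> 13 miR-sim-0013     2.0639207  8.42109596 4.0801451 0.0005060468
#> 14 miR-sim-0014     0.4313642  0.09667433 0.2241130 0.0015392105
```

In the validation cohort the discriminant-selected markers are re-tested;
truly differential ones stay significant, false positives from the small
discovery cohort fall away:

```r
report$validation[, c("mirna", "mean_nonevent", "mean_event", "p")]
#>          mirna mean_nonevent mean_event            p
#> 1 miR-sim-0021    0.01801913 0.06628115 2.479383e-05
#> 2 miR-sim-0126    0.01676927 0.02044286 2.519531e-01
#> 3 miR-sim-0017    0.25057779 0.83430570 4.675527e-07
#> 4 miR-sim-0462    0.04858194 0.04263664 4.039979e-01
#> 5 miR-sim-0019    0.14216852 0.47413272 8.552916e-07
```

`report$incremental` then quantifies what the marker adds to the
clinical-only logistic model: here LOOCV accuracy rises from 65.2% to
95.5% and the AUC from 0.7594 to 1.0 — the planted 4-fold marker nearly
separates the groups, so the NRI reaches its maximum of 2 and the model
(correctly) raises a complete-separation flag, the same behaviour that
produces the astronomically wide odds-ratio intervals typical of strong
markers in small cohorts.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/seromir-pipeline.R simulate --n-per-group 15 --seed 1 --out-dir sim
Rscript inst/scripts/seromir-pipeline.R run --ct-a sim/ct_panel.csv \
    --cohort sim/cohort.csv --out-dir results
```

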