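# faleak

Quantified fluorescein-angiography (FA) leakage as a predictor of anti-VEGF
treatment response in branch retinal vein occlusion (BRVO).

Macular edema after BRVO is treated with intravitreal anti-VEGF injections,
but eyes differ widely in how many injections they need. `faleak`
implements a semi-automated pipeline that turns a pair of FA frames — an
early frame at 1 min post-injection, when vessels are filled but leakage is
minimal, and a late frame at 5 min, when dye has leaked from injured
vessels — into a per-eye leakage severity score, and the statistical
framework that evaluates such scores as predictors of treatment response
(*responsive*: < 5 injections in the first year; *refractory*: ≥ 5
injections, or edema persisting after the 3 monthly loading injections).

## The measurement

For each eye, with frames `I₁` (1 min) and `I₅` (5 min) and a manually
located fovea:

1. rigidly align `I₅` onto `I₁` (the 1-min frame is the reference);
2. remove the background gradient with a rolling-ball filter
   (radius 50 px);
3. crop 384 × 384 px centred on the fovea;
4. binarize each crop at its own iterative-intermeans (IsoData "default")
   threshold;
5. form the leakage map `L = max(B₅ − B₁, 0)` — pixels hyperfluorescent
   at 5 min but not at 1 min;
6. read the **mean gray value** (MGV) of `L` over nested fovea-centred
   windows: parafoveal 120 × 120 px (~3 mm) and perifoveal 240 × 240 px
   (~6 mm). On a {0, 255} map the MGV is 255 × (leaking-pixel fraction).

Scores from two independent graders are averaged; grader agreement is
summarised by ICC(2,1). Predictors are compared by Mann–Whitney AUC with
DeLong variance, paired DeLong tests against the pre-treatment central
retinal thickness (CRT) reference, and backward stepwise logistic
regression (Wald elimination at p > 0.05).

Because no patient images are distributed, the package ships synthetic
generators with known ground truth: FA scenes (background gradient +
vessel tree + Gaussian leakage blobs that grow between timepoints, rigid
inter-frame motion, sensor noise) and cohort tables drawn from the
published group moments.

## Worked example

```r
library(faleak)

# one refractory-style synthetic eye, end to end
sc <- generate_fa_pair(scenario_params(seed = 21, blob_amp_5min = 150,
                                       n_leak_blobs = 8))
quantify_eye(sc$pair, quantify_config())
#> <leakage_result> eye synthetic-21 (grader1): parafoveal 11.9, perifoveal 10.9
#>   (thresholds 62/66)

# a full synthetic cohort run (defaults = the modelled study's group moments)
res <- run_pipeline(run_config(seed = 1, out_dir = tempfile()))
res$summary[c("n_eyes", "n_responsive", "pct_responsive")]
#> 89 eyes: 47 responsive (53%), 42 refractory
res$table2
#>                           predictor   auc          ci95 p_vs_crt_pre
#>              Pre-treatment CRT (um) 0.575 0.452 - 0.698    reference
#>        Post-treatment best CRT (um) 0.753 0.647 - 0.858        0.028
#>  Mean gray value, parafoveal region 0.812 0.725 - 0.899        0.001
#>  Mean gray value, perifoveal region 0.830 0.738 - 0.921        0.001
```

The per-eye scores are leakage severities in gray-value units (0–255);
`table2` shows that in this simulated cohort the leakage scores
discriminate refractory from responsive eyes far better than baseline CRT
does, and the paired DeLong p-values quantify that advantage. `table1.csv`
(group comparisons), `stepwise.csv` (the multivariate selection trace) and
a provenance JSON are written to the run directory. A thin command-line
wrapper lives in `inst/scripts/faleak-pipeline.R`.

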