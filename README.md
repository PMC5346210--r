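# likertfa

Exploratory factor analysis for short Likert questionnaires with strong
floor effects — and for studying how *sample selection* changes what that
analysis finds.

Screening instruments such as 12-item disability questionnaires (five
response categories per item, coded 0–4 and summed to a 0–48 score) are
usually validated on general-population samples in which most
respondents report no difficulty at all. The resulting pile-up of
all-zero response rows censors the data at the scale's floor and can
change how many factors an exploratory analysis retains. `likertfa`
implements the complete ordinal-EFA pipeline around this question:

* **Polychoric correlations** by two-step maximum likelihood
  (`polychoric()`, `polychoric_pair()`), with eigenvalue-clipping PSD
  repair (`smooth_psd()`);
* **Parallel analysis** with principal-component extraction and the
  mean-eigenvalue criterion, using column-permutation reference data that
  preserve each item's margins (`parallel_analysis()`,
  `retain_factors()`);
* **Factor extraction and rotation**: minimum residuals
  (`fit_minres()`) with oblique Geomin rotation (`rotate_geomin()`),
  Kaiser-Meyer-Olkin sampling adequacy (`kmo()`), salient-loading masks
  (`salient_loadings()`);
* **Two sampling schemes**: simple random sampling, which preserves a
  population's skewed score distribution, and symmetrizing stratified
  sampling, which draws with weights designed to make the sample's score
  distribution approximately symmetric around the population median
  (`srs_sample()`, `stratified_sample()`, `derive_symmetric_weights()`);
* **Repeated-sampling retention experiments** tabulating how many
  replicate samples retain 1, 2, 3, … factors per scheme
  (`run_retention_experiment()`, `select_representative_sample()`,
  `full_efa_report()`);
* A **synthetic censored-Likert generator** with known latent structure
  and a calibratable floor (`synthetic_spec()`, `generate_responses()`,
  `calibrate_floor()`, `floor_sweep()`), standing in for the
  controlled-access survey data such studies use.

The model underneath: item pairs discretize a latent bivariate normal
with thresholds τ estimated from the margins and correlation ρ
maximizing the contingency-table likelihood; k factors are extracted by
minimizing Σ<sub>i&lt;j</sub>(r<sub>ij</sub> − (ΛΛ′)<sub>ij</sub>)² and
rotated to minimize the Geomin criterion
Σ<sub>i</sub>(Π<sub>j</sub>(λ<sub>ij</sub>² + ε))<sup>1/k</sup>, giving a
pattern matrix Λ and factor correlations Φ. Everything is tidyverse
friendly: data frames in, tibbles out, `tidy()`/`glance()` on every
fitted object, `autoplot()` for scree, loading and retention displays.

## Worked example

Build a floor-heavy two-factor population, draw one skewed sample, and
analyse it:

```r
library(likertfa)

spec  <- synthetic_spec(n = 20000, k = 2)              # loadings 0.7, Phi12 = 0.4
delta <- calibrate_floor(spec, target_zero_rate = 0.32, seed = 5)
spec$severity_offset <- as.numeric(delta)
population <- generate_responses(spec, seed = 21)
population
#> Synthetic censored-Likert population: n = 20000 , items = 12 , k = 2
#>   severity offset delta = 1.7812 ; all-zero rows: 33.0%

scores <- simple_score(population$data)
describe_scores(scores)[, c("mean", "sd", "skewness", "p50", "zero_proportion")]
#>    mean    sd skewness   p50 zero_proportion
#> 1 3.212 4.382    2.246     2            0.33

sample_data <- population$data[srs_sample(scores, 750, seed = 1), ]
pa <- parallel_analysis(sample_data, n_replicates = 50, seed = 2)
pa
#> Parallel analysis (polychoric, PCA extraction, mean-eigenvalue criterion)
#>   n = 750 , items = 12 , replicates = 50 ( column permutation )
#>   factors retained: 2
#>             ev1   ev2   ev3   ev4
#> observed  5.437 1.646 0.751 0.673
#> reference 1.423 1.297 1.224 1.151

full_efa_report(sample_data, k = pa$n_factors, seed = 2)
#> Factor-analysis report
#>   KMO overall: 0.882 (adequate, > .60)
#>   factors retained: 2
#> Exploratory factor analysis: minres extraction, Geomin rotation
#>   k = 2  residual rms = 0.04
#>         F1     F2
#> item_01  0.68*  0.03
#> item_02 -0.03   0.70*
#> ...
#> Factor correlations:
#>      [,1] [,2]
#> [1,]  1.0  0.4
#> [2,]  0.4  1.0
```

The parallel analysis compares the observed polychoric eigenvalues
(5.44, 1.65, …) with mean eigenvalues of column-permuted replicates
(1.42, 1.30, …): two leading observed values exceed their reference, so
two factors are retained. The report confirms sampling adequacy
(KMO 0.88) and recovers the generating structure — nine items salient
(`*`, |loading| ≥ .40) on the first factor, the three-item cluster on
the second, with the factor correlation 0.4 matching the generator.

To compare sampling strategies at scale:

```r
experiment <- run_retention_experiment(
  population$data, sampling_scheme("stratified_symmetric"),
  n_samples = 1000, seed = 7)
tidy(experiment)       # counts of samples by retained factor number
autoplot(experiment)
```

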