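# epidiary

Temporal statistics for seizure diaries from chronic focal-epilepsy models.

Rodent models of acquired neocortical epilepsy (e.g. tetanus-neurotoxin
injection into the visual cortex) are monitored by continuous video-ECoG for
about a month, yielding per-animal *seizure diaries*: lists of electrographic
seizure onsets and durations, optionally with a behavioural (semiology)
class. `epidiary` is for the experimentalists and biostatisticians who
analyse those diaries. It implements, with S4 data containers and a tested
statistical core:

* **natural history** — latent period, induction rate, daily/weekly seizure
  frequency (per-animal-normalised percentages), cumulative distributions,
  daily median-duration trajectories;
* **semiology** — five-class tabulation with per-class duration
  distributions and per-animal-normalised duration histograms;
* **circadian structure** — within-animal-normalised hourly profiles,
  cosinor acrophase, light/dark seizure fractions, and an exact
  matched-pairs Wilcoxon signed-rank test (full 2^n sign-assignment
  distribution for n ≤ 20) for day/night duration differences;
* **clustering and periodicity** — inter-seizure-interval analysis with a
  Monte-Carlo Lilliefors test of exponentiality (KS distance to
  Exp(mean = sample mean), null re-estimated each replicate); the
  edge-corrected peri-seizure histogram, where the count in the lag bin
  centred at *c* days is divided by (30 − *c*) so that uniform event times
  give a flat expectation *n*(*n*−1)/*T*² (closed form, verified against
  brute-force resampling), with per-bin t-tests across animals; and partial
  autocorrelation of daily counts by Durbin–Levinson recursion with per-lag
  t-tests;
* **prediction** — Gaussian-process regression with the linear kernel
  k(x,x′) = σ_b² + σ_v²·x·x′ (equivalent to Bayesian linear regression, the
  package's correctness oracle) of log remaining-period count on log
  first-week count; interval probabilities under the lognormal predictive,
  >50%-confidence enrollment ranges, leave-one-out calibration, and
  stratified two-arm assignment;
* **a synthetic-diary generator** — a rate-normalised self-exciting
  (Hawkes-type) process with weekly shape, circadian gate, post-cluster
  suppression, bimodal durations and across-animal lognormal rate
  heterogeneity, sampled by exact Ogata thinning, so every stage has
  parameter-recovery tests without any animal data.

## Worked example

```r
library(epidiary)

co <- simulateCohort(simulatorConfig(nAnimals = 10, seed = 42))
co
#> SeizureCohort 'simulated-seed42': 10 animals, 597 events (0 seizure-free)

weeklyPercentages(co)$summary[, c("week", "mean", "median")]
#>   week mean median
#> 1    1 26.5   25.0
#> 2    2 23.9   24.2
#> 3    3 38.8   39.4
#> 4    4 10.8   10.1

prof <- circadianProfile(co)
c(prof$peakHour, mean(prof$lightPhaseFraction))
#> 15.7 0.65        # acrophase mid light phase; light-phase dominant

dayNightDurationTest(co)[c("statistic", "pValue")]
#> W+ = 23, exact p = 0.695   # no day/night duration difference

periSeizureHistogram(co)$bins[1:4, c("binCentre", "meanCorrected",
                                     "baseline", "tStat", "pValue")]
#>        binCentre meanCorrected baseline   tStat pValue
#> lag0_1       0.5        0.1080   0.0652  3.1617 0.0115
#> lag1_2       1.5        0.0582   0.0652 -2.4081 0.0394
#> lag2_3       2.5        0.0521   0.0652 -3.8116 0.0041
#> lag3_4       3.5        0.0570   0.0652 -2.3258 0.0451

cohortPacf(co)$lags[1:2, c("lag", "meanCoef", "tStat", "pValue")]
#>      lag meanCoef  tStat pValue
#> lag1   1    0.136  2.097  0.065
#> lag2   2   -0.209 -4.252  0.002

m <- fitGPLinear(co)
m
#> GPCountModel: 10 animals; k(x,x') = 3.11 + 0.525 x x', noise 0.0308
#>   Pearson r of log-log training pairs: 0.979

thresholdInterval(m, c(20, 100))$range
#> 6 51   # first-week counts giving >50% chance of 20-100 remaining seizures
```

Reading: seizure pairs separated by less than a day are significantly more
common than a memoryless process allows (the elevated day-1 bin), days 2–4
are significantly depressed (the post-cluster refractory dip), and daily
counts alternate quasi-periodically (positive lag-1, negative lag-2 partial
autocorrelation). The log-log first-week/remaining correlation (r = 0.98
here) is what makes first-week counts usable as an enrollment criterion.

Real diaries load from CSV (`readCohort(events, metadata)`: onsets and
durations in seconds, or ISO-8601 onsets; per-animal recording windows and
clock offsets in the metadata table), and `runPipeline(pipelineConfig(...))`
runs every stage with one seed and writes tidy CSVs plus a provenance-bearing
`summary.json`.

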