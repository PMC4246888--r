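# pewlsim

Monte Carlo assessment of the clinical utility of a modestly accurate
genomic predictor of bariatric-surgery weight loss.

## The problem

Whole-genome prediction (WGP) of percent excess weight loss (PEWL) after
gastric bypass currently achieves only modest accuracy (predictive
R² ≈ 0.07–0.1). Accuracy alone, however, is the wrong yardstick when
resources are finite: if a budget funds 1000 surgeries and the eligible
population is several times larger, *any* signal about who will respond
can be used to pick better candidates. `pewlsim` is for biostatisticians
and methodologists who want to quantify that utility: it simulates a
population-scale cohort, the surgery-eligible subset (BMI ≥ 35), actual
and genomically predicted PEWL, calibrated lifetime Type 2 diabetes (T2DM)
and surgical adverse-event (AE) risk models, and a decision threshold τ on
predicted PEWL that allocates the fixed surgical budget.

## The model in brief

- Height/log-weight ~ bivariate normal (female parameters
  N(160.6, 6.2²) cm, N(4.2, 0.19²) log kg, covariance 0.59), additive male
  offsets (+13 cm, +9.4 kg), outlier filters; eligibility at BMI ≥ 35,
  ideal weight at BMI 25.
- PEWL ~ N(63, 23²) with a −0.59 association with baseline weight;
  genomic prediction αᵢ ~ N(63, 7.6²) with corr(α, PEWL) = 0.316.
- A monotone BMI → lifetime-T2DM map (ECDF-based or anchored spline),
  log-odds-calibrated so the untreated eligible-cohort mean is 0.28;
  treated risk evaluates the same map at post-surgery BMI.
- AE risk: logistic in standardized baseline weight plus a male offset,
  intercept-calibrated to an eligible-cohort mean of 0.049.
- At threshold τ, the 1000 highest predictions above τ are treated. The
  additional cases prevented, relative to spending the same 1000 surgeries
  first-come-first-serve, is
  `N|τ = 1000 · (mean P(Cₜ) over the cohort − mean P(Cₜ) over the treated set)`
  (an untreated-baseline comparator is also reported).

## Worked example

```r
library(pewlsim)
man <- run_full_pipeline(sim_config(), seed = 1)
print(man)
#> <run_manifest> pewlsim 1.0.0 seed 1
#>   cohort kept: 149450; eligible (BMI >= 35): 3789
#>   eligible-cohort mean risks: T2DM untreated 0.280, adverse event 0.049
#>   corr(predicted, actual PEWL): 0.320
#>   additional T2DM cases prevented at tau = 80: 36.4 (vs random allocation), 182.1 (vs untreated)
```

Reading the numbers: of 150,000 simulated subjects, 149,450 survive the
outlier filters and 3,789 are surgery-eligible at this seed (about 3,600 on
average). After calibration the eligible cohort faces a mean lifetime T2DM
risk of 0.28 untreated and a mean surgical AE risk of 0.049. The genomic
predictor correlates 0.32 with actual weight loss — R² ≈ 0.1, a weak
predictor — yet allocating the 1000 fundable surgeries to those predicted
to lose at least 80% of their excess weight prevents roughly 36 additional
future T2DM cases at this seed (about 40 averaged over seeds) compared with
funding the same 1000 surgeries without the test.

Everything is a tibble and chains with the pipe:

```r
library(dplyr)
man$sweep |> tidy() |> filter(comparator == "random_allocation")
glance(man)                 # one-row headline summary
autoplot(man$sweep)         # prevented T2DM and AE cases vs tau
autoplot(man$curves)        # P(T2DM) with/without surgery vs prediction
```

`run_full_pipeline(cfg, output_dir = "out")` additionally writes
`cohort.csv`, `outcomes.csv`, `risks.csv`, `sweep.csv`,
`decision_curve.csv`, a `sweep.png` figure and a `manifest.json` that
reproduces the run bit for bit (`rerun_from_manifest()`). A thin command
line wrapper with `run` / `simulate` / `analyze` / `plot` subcommands is
installed at `inst/cli/pewlsim`.

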