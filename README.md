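# pbmselect

Population-based model selection for time-integrated activities in
molecular radiotherapy.

## The problem

Dosimetry after radioligand therapy (e.g. ¹⁷⁷Lu-PSMA) needs the
**time-integrated activity** (TIA) of each organ — the integral of the
organ's time–activity curve from zero to infinity, equal to the number of
radionuclide disintegrations in the organ. The TIA is obtained by fitting
a function to a handful of activity measurements per patient and
integrating it, so the choice of fit function drives the result. With 3–5
samples per patient, selecting that function from one patient's data alone
(**IBMS**, individual-based model selection) is unstable: the corrected
Akaike criterion AICc needs `K ≤ N − 2` parameters for `N` data points, so
a 3-point patient only admits one-parameter functions.

**PBMS** (population-based model selection) fits each candidate function
*jointly to all patients* — every patient keeps individual parameters, and
some candidates share one parameter across the whole population — and
performs the model selection on the pooled fit, where `N` is the pooled
sample count. This raises the usable model complexity and stabilises the
selection, and the estimated shared parameter can later be fixed for new
patients with very few samples.

## What the package implements

* a fixed catalog of 20 mono-/bi-exponential functions
  (`model_catalog()`), all with the physical decay λ_phys = ln 2 / T₁/₂ as
  an explicit factor and all parameters constrained non-negative; six
  variants of `f3a` carry a population-shared parameter, e.g.

  `f3aS4(t) = A₁ β e^−(λ₁+λ_phys)t + A₁ (1−β) e^−λ_phys·t`, shared β ∈ [0,1];

* weighted nonlinear least squares (σᵢ = 0.15·yᵢ fractional-SD variance
  model) with box constraints and deterministic multi-start, individually
  (`fit_individual()`), jointly with shared parameters
  (`fit_population()`), or with the shared parameter fixed for future
  patients (`fit_fixed_shared()`);
* a goodness-of-fit gate (`goodness_of_fit()`): all parameter CVs < 0.5,
  no off-diagonal parameter correlation ≥ 0.90, curve non-negative with no
  standardized residual beyond ±4;
* AICc = −2lnL + 2K + 2K(K+1)/(N−K−1) and Akaike weights
  wᵢ = e^(−Δᵢ/2) / Σⱼ e^(−Δⱼ/2) over the gate-passing candidates
  (`select_models()`, PBMS or IBMS);
* leave-one-patient-out stability of the selection
  (`jackknife_selection()`);
* closed-form TIAs per patient (`compute_tias()`) and relative deviations
  between two TIA sets (`relative_deviation()`);
* a synthetic-population generator (`simulate_population()`) emulating a
  sparse 5-session post-therapy imaging design for end-to-end validation,
  and a command-line wrapper (`inst/scripts/pbms`).

## Worked example

```r
library(pbmselect)

sim <- simulate_population(seed = 9)        # 13 patients, N = 46 samples
sel <- select_models(sim$data, mode = "PBMS",
                     models = c("f2b", "f3a", "f3aS3", "f3aS4", "f3aS6"))
tidy(sel)[, c("model_id", "K", "aicc", "weight", "gof_verdict")]
#>   model_id     K  aicc weight gof_verdict
#> 1 f2b         26  160.     NA fail
#> 2 f3a         39  607.     NA fail
#> 3 f3aS3       27  153.     NA fail
#> 4 f3aS4       27  152.      1 pass
#> 5 f3aS6       27  191.     NA fail
attr(sel, "best_model")
#> [1] "f3aS4"
```

Only `f3aS4` passes the gate here, so it carries the whole Akaike weight;
its population-shared fraction is recovered as β = 0.9631 ± 0.006
(generated with β = 0.9632). TIAs and their deviation from the
mono-exponential alternative `f2b`:

```r
fit <- attr(sel, "fits")[["f3aS4"]]
tias <- compute_tias(fit)                   # %IA·h per patient
head(relative_deviation(tias, compute_tias(fit_population(sim$data, "f2b"))), 4)
#>   patient_id tia_a tia_b rd_pct
#> 1 P01         182.  158.  15.3
#> 2 P02         127.  110.  16.4
#> 3 P03         551.  530.   4.03
#> 4 P04         518.  501.   3.23
```

The 3-point patients (P01, P02) are the ones whose TIA depends most on the
chosen function — exactly the situation PBMS is designed for: their curve
beyond ~51 h is constrained by the population-shared fraction rather than
extrapolated from three points.

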