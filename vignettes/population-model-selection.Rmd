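---
title: "Population-based model selection for time-integrated activities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based model selection for time-integrated activities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the numerical choices, and
the design decisions behind `pbmselect`, in the spirit of a methods
section: what is computed, under which assumptions, and what the shipped
validation does and does not demonstrate.

## Model and objective

Each patient $p$ contributes $n_p$ activity measurements $y_{pi}$ (% of
injected activity) at times $t_{pi}$ hours post-injection. Every candidate
function in the 20-entry catalog is a sum of one or two exponentials (one
family carries an extra factor $t$, the degenerate-eigenvalue limit of a
biexponential), with the physical decay $\lambda_{\mathrm{phys}} =
\ln 2 / T_{1/2}$ included as an explicit factor so that all fitted rates
$\lambda_i \ge 0$ are biological clearance rates. The default radionuclide
is Lu-177 with $T_{1/2} = 159.528$ h (6.647 d); the half-life is
configurable through `radionuclide()` because any literature value shifts
$\lambda_{\mathrm{phys}}$ slightly.

Measurement uncertainty follows the absolute, data-based fractional-SD
variance model $\sigma_{pi} = \mathrm{fsd} \cdot y_{pi}$ with
$\mathrm{fsd} = 0.15$ by default. We deliberately use *data-based* (fixed)
weights rather than model-based reweighting: with fixed weights the
Gaussian objective
$$-2\ln L = \sum_{p,i} \frac{(y_{pi} - f(t_{pi}))^2}{\sigma_{pi}^2}
          + \sum_{p,i} \ln(2\pi\sigma_{pi}^2)$$
has a model-independent second term, so AICc *differences* between
candidate functions compare likelihoods on identical data. The constant
term can be toggled off (`include_constant = FALSE`) without affecting any
selection result.

Shared-parameter candidates (`f3aS1`–`f3aS6`) estimate one parameter once
for the whole population and the remaining parameters per patient, giving
$K = p \cdot n_{\mathrm{patients}} + 1$ adjustable parameters. For
candidates without a shared parameter the pooled objective separates
exactly, so `fit_population()` solves the per-patient problems
independently and combines them with joint bookkeeping (pooled $N$, total
$K$, summed $-2\ln L$, block-diagonal correlation matrix); this is an
identity, not an approximation, and is asserted by a test.

## Optimization

The bound-constrained weighted least-squares problems are solved with the
trust-region Levenberg–Marquardt implementation in `minpack.lm`
(`ftol = ptol = 1e-12`, up to 500 iterations). Boxes are $[0, 10^4]$ %IA
for amplitudes, $[0, 100]$ /h for rates, and exactly $[0, 1]$ for the
fraction $\beta$; the generous upper limits exist only because a bounded
optimizer needs finite boxes.

Because the objectives are multimodal (a sparse curve can be explained by
a fast-decay/large-amplitude corner or by a slow washout), fitting is
multi-start and fully deterministic given the seed:

* a data-driven heuristic start (terminal rate from a log-linear fit
  through the last two points, amplitudes back-extrapolated to $t = 0$,
  $\beta$ started at 0.9);
* for single-curve problems, a deterministic grid over the clearance-rate
  decades $\lambda_1 \in \{0.005, 0.05, 0.5, 5\}$ /h with the amplitude
  back-extrapolated through the first sample — this covers the distinct
  basins directly;
* for shared-parameter models, a deterministic grid over the shared
  parameter combined with *profile starts*: at each grid value the shared
  parameter is fixed, every patient's small conditional problem is solved
  by its own multi-start, and the joint optimizer then refines all
  parameters. The shared value is the only direction coupling the
  patients, so this reaches the joint optimum where independent random
  joint starts in ~27 dimensions reliably stall in per-patient local
  minima (we initially used purely log-uniform random joint starts and
  observed exactly that failure mode);
* seeded jittered and log-uniform random starts filling up the configured
  `n_starts = 10`, followed by an alternating polish (per-patient
  conditional refits at the current shared value, then a joint refit,
  repeated while the objective improves).

Ties between starts are broken by the lowest $-2\ln L$ (first start index
within $10^{-10}$). Runs with the same seed are bit-reproducible.

## Uncertainty and the goodness-of-fit gate

At the optimum, the parameter covariance is the inverse Gauss–Newton
information matrix $(J^\top W J)^{-1}$ with $W = \mathrm{diag}(1/\sigma^2)$
and $J$ the Jacobian of the model curve (computed by central differences
folded inside the box at active bounds). Reported per parameter:
$\mathrm{SD}$, $\mathrm{CV} = \mathrm{SD}/|\hat\theta|$, and the
correlation matrix. A singular information matrix is flagged as degenerate
(CVs set to $+\infty$), never thrown. Parameters pinned at a bound remain
counted in $K$ but are flagged.

Model selection is gated before weights are computed:

* **CV rule** — every parameter CV < 0.5 (threshold configurable);
* **correlation rule** — no off-diagonal $|r| \ge 0.90$. The nominal
  guideline is $|r| < 0.8$ for most elements with slightly larger values
  tolerated; the 0.90 cut operationalizes that tolerance as a
  deterministic rule (fits with largest correlations up to ~0.86 pass,
  from 0.92 fail), and is configurable;
* **shape rule** — an automated stand-in for visual inspection: the
  fitted curve must be non-negative on $[0, 2\times$ last sample time$]$
  (201-point grid) and no standardized residual may exceed 4 in absolute
  value. Plots (`autoplot()`) are still available for human review;
  several catalog members (e.g. `f2c`, which is non-positive by
  construction) are expected to die here rather than being forbidden up
  front.

AICc $= -2\ln L + 2K + 2K(K+1)/(N-K-1)$ requires $N - K - 1 \ge 1$, i.e.
$K_{\max} = N - 2$; infeasible models are excluded, as are
shared-parameter models in IBMS mode (they are meaningless for a single
patient). Akaike weights are normalized over the gate-passing subset only,
so excluded models carry no weight; whether to renormalize this way is the
documented convention and the subset is reported per model in
`excluded_reason`. Models supported by the data are those with weight
above 0.05 (configurable).

The leave-one-patient-out jackknife reruns the *entire* pipeline (fits,
gate, weights) per replicate; a model failing the gate in a replicate
enters that replicate with weight 0 and stays in the summary
(median [min, max]).

## TIAs

TIAs are computed analytically from
$\int_0^\infty A e^{-\lambda t}\,dt = A/\lambda$ and
$\int_0^\infty A t e^{-\lambda t}\,dt = A/\lambda^2$; a non-positive
effective rate raises a divergent-integral error. The test suite verifies
every catalog member against piecewise adaptive quadrature at relative
tolerance $10^{-8}$. Relative deviations between two TIA sets use the
second argument as the reference (denominator); this convention is stated
in the report header because no universal convention exists.

## The synthetic population

`simulate_population()` emulates a sparse post-therapy imaging study:

* 13 patients; 3 attend 5 sessions, 1 attends 4, 9 attend 3
  ($N = 46$ samples);
* nominal sessions at $1.1 \pm 0.7$, $20.7 \pm 2.3$, $51.0 \pm 10.1$,
  $92.3 \pm 47.2$, $163.8 \pm 2.1$ h p.i. (Gaussian, redrawn until
  $> 0.1$ h, sorted); patients with fewer points keep the *first*
  sessions by default — early time points are the clinical standard —
  with a random-subset option;
* kinetics from `f3aS4` with population-shared $\beta = 0.9632$;
  per-patient $A_1 \sim$ log-normal(median 8 %IA, gSD 1.4) and
  $\lambda_1 \sim$ log-normal(median 0.02 /h, gSD 1.5). These
  inter-individual distributions are plumbing choices with no biological
  claim attached, fully configurable;
* multiplicative Gaussian noise with CV 0.15, redrawn until positive.
  The truncation keeps the fractional-SD variance model valid; the small
  positive bias this induces is accepted and is negligible at CV 0.15.

What the generator does *not* emulate: imaging physics (attenuation,
scatter, ROI delineation, background correction), inter-session
correlation of errors, and any real inter-individual correlation between
$A_1$ and $\lambda_1$. Passing the shipped simulation tests therefore
demonstrates the correctness and stability of the *estimation and
selection machinery* under the stated design, not clinical performance on
real data.

## What the validation shows — and a known tension

The pipeline-closure tests show that the joint population fit recovers the
generating shared fraction essentially unbiasedly: across 20 seeded
populations the mean recovered $\beta$ deviates from the generating value
by well under 1% (the acceptance script recomputes this number from
scratch).

Full model *recovery*, however, is limited by the interaction of the CV
gate with the generator's inter-individual spread: patients who draw
$\lambda_1 \lesssim 0.013$ /h and attend only the first three sessions
($t \le$ ~51 h) cannot have their $\lambda_1$ identified to CV < 0.5 under
15% noise, so the max-CV rule fails the *generating* model in the majority
of seeds — our acceptance test measures a best-model recovery rate far
below its nominal target, and we report that honestly rather than
loosening the gate or narrowing the generator's spread. In the seeds where
the gate passes, `f3aS4` is selected with weight near 1. The practical
reading: with populations this sparse, the max-over-all-parameters CV rule
is a harsh gate, and a real analysis would inspect *which* parameter of
*which* patient fails it before discarding a candidate.

## Problem sizes and runtime choices

The shipped tests use 20-seed simulation batches for recovery properties,
one seed (13 replicates) with a 5-model catalog subset for the jackknife
property, 10 (catalog) or 200 (acceptance) random draws per model for the
TIA oracle, and 60 replicates for the noisy-recovery oracle — sizes chosen
to make Monte-Carlo conclusions stable while keeping the default suite
fast on a single CPU. The full-catalog, 20-seed selection experiment runs
in the acceptance test only.

## Known limitations

* Shared parameters are fixed effects: no random-effects (NLME) or
  Bayesian estimation, no multimodel averaging of TIAs, no BIC/F-test
  alternatives — one best function is selected.
* The Gaussian $-2\ln L$ with fixed data-based weights is a stated
  interpretation of "absolute variance model with fractional SD"
  semantics; extended least squares with model-based variance would change
  absolute AICc values (not the comparisons under fixed weights).
* The catalog is closed by design; organs with qualitatively different
  kinetics (e.g. long accumulation phases) would need additional members.
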