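---
title: "Modelling walking rehabilitation with a fitness-fatigue impulse-response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling walking rehabilitation with a fitness-fatigue impulse-response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitfatigue)
library(dplyr)
```

## The problem

Patients with peripheral artery disease (PAD) at the claudication stage are
commonly prescribed structured walking programmes. In the test-in train-out
(TiTo) scheme the programme is prescribed at the hospital and performed at
home: two 10-minute sessions a day of intermittent walking — ten 1-minute
bouts at a metronome-paced cadence, separated by 1-minute rests — with the
cadence starting near 60% of the patient's habitual walking cadence and
increasing by about 3% each week until it reaches 90–100%. Performance is
measured at sparse clinic visits (around weeks 0, 5, 12, 20 and 28) by the
6-minute walking test, which yields the total distance (6MWD) and the
distance walked before claudication pain starts (PFWD), both in metres.

This package implements the full analysis chain for asking whether those
sparse measurements are predictable from the prescribed training alone:
quantify each diary session as a training impulse (TRIMP), drive a Banister
two-component impulse-response model with the daily TRIMP series, calibrate
the model per subject against the visit measurements, and assess agreement
between model-estimated and measured performance across the cohort.

## Training quantification

A session's TRIMP is the product of three factors:

* **intensity** — prescribed cadence divided by habitual cadence
  (steps/min over steps/min, dimensionless);
* **density** — walking time over total elapsed time. A session of $r$ walk
  bouts has $r - 1$ rests: the session ends on the last walk, so ten 1-min
  walks with 1-min rests elapse 19 minutes, giving $10/19$;
* **volume** — steps performed: cadence $\times$ bout duration $\times$
  bouts done. Partial adherence enters as the fraction of prescribed
  repetitions actually performed, because diaries record sessions done or
  skipped rather than time walked.

For the canonical worked example (habitual 100 steps/min, ten 1-min bouts at
60 steps/min, 1-min rests) this gives $0.60 \times 10/19 \times 600 \approx
189.47$ arbitrary units at full precision. A separate *printed* presentation
mode rounds intensity and density to two decimals before multiplying and
rounds the product to the nearest unit — $0.60 \times 0.53 \times 600 = 191$
a.u. — so the conventional worked arithmetic is reproduced digit for digit
while the modelling pipeline keeps full precision.

```{r trimp}
session_trimp(60, 100, 1, 1, 10)
session_trimp(60, 100, 1, 1, 10, mode = "printed")
```

The daily training quantity $w(t)$ sums the TRIMPs of all sessions on a
calendar day (two under the TiTo prescription); days without training
contribute zero. Missed sessions are not imputed — they simply contribute
$w = 0$, matching how a diary records them.

## The impulse-response model

Each subject is a linear time-invariant system with the daily TRIMP series
as input and performance as output. A single session produces a first-order
response $g(t) = k\,e^{-t/\tau}$: at $t = \tau$ the response has decayed to
$e^{-1} \approx 37\%$ of its initial value. Predicted performance is the
baseline plus a positive fitness component minus a negative fatigue
component, each a discrete convolution of the input with its own
exponential:

$$
p(t) = p_0
  + k_1 \sum_{i < t} w(i)\, e^{-(t-i)/\tau_1}
  - k_2 \sum_{i < t} w(i)\, e^{-(t-i)/\tau_2}.
$$

The sum runs over training days *strictly before* $t$: a session does not
affect performance measured the same day. This is the standard
discretisation; the implementation uses the equivalent one-step recursion
and is verified in the test suite against a brute-force $O(T^2)$ double
loop to $10^{-9}$ relative error. Days beyond the last training day take
$w = 0$, so extending the prediction horizon simulates detraining. Note the
sign convention: the impulse response is implemented with a negative
exponent, which is what the 37%-decay definition of $\tau$ requires.

Both outcomes (PFWD, 6MWD) are driven by the *same* TRIMP series; only the
parameter set differs.

### Detraining decay

Because both components decay exponentially, the modelled gain never
reaches baseline exactly, so "return to baseline" needs an operational
definition. `decay_to_baseline()` reports the first day (and week) after
the post-training peak at which the residual gain $p(t) - p_0$ falls to at
most a threshold fraction — 5% by default, configurable — of that peak.
With a single impulse and no fatigue the crossing has the closed form
$-\tau_1 \ln(0.05) \approx 3\tau_1$, which the tests check to within one
day. Published decay horizons for comparable cohorts have no stated
operational definition, so we make no claim of reproducing them exactly;
at population-mean PFWD parameters and a full TiTo series the 5% rule
lands in the same few-month range.

## Calibration

Per subject and outcome, parameters minimise the residual sum of squares
between prediction and measurement at the visit days.

* **$p_0$ is fixed** at the measured baseline (day-0) visit, not fitted.
  With only ~4 follow-up visits this saves a degree of freedom and makes
  the model explain changes from baseline.
* **Profiled grid, then refinement.** Given $(\tau_1, \tau_2)$ the model is
  linear in $(k_1, k_2)$, so the magnitude factors are solved exactly by
  nonnegative least squares at each point of a deterministic 1-day grid
  over $\tau_1 \in [10, 80]$, $\tau_2 \in [5, 60]$ days (covering the
  population means ±2 SD reported for this kind of cohort). The best grid
  point — ties broken by smallest $\tau_2$, then smallest $\tau_1$, so
  output is deterministic — seeds a bounded L-BFGS-B polish of the profiled
  RSS. This avoids non-convex four-parameter descent from arbitrary starts.
* **$k_1, k_2 \ge 0$** by construction (the physiological sign convention:
  training cannot produce negative fitness or negative fatigue). The
  two-variable nonnegative solve is closed-form candidate enumeration,
  which vectorises across the whole grid; it is verified against a
  general-purpose NNLS routine in the tests.

Fit quality is summarised by $R^2 = 1 - RSS/TSS$ (TSS about the mean of the
measured values at the fitted visits) and an ANOVA-style F test on the RSS
with model df 2 (the two magnitude factors; the profiled decay constants
are not charged) and residual df $n_{\text{visits}} - 3$. No published df
convention exists for this fit, so both are configurable via
`banister_control()`. A fit is flagged *acceptable* when $R^2 > 0.30$.

A caveat the tests make explicit: from four residual points the individual
parameters can be weakly identified — when $\tau_1 \approx \tau_2$ the two
exponentials nearly cancel and the $k$'s can drift large in compensation —
but the *predicted performance* at the visit days is tightly determined.
Parameter-level recovery is therefore asserted from richer (7+ point)
schedules, prediction-level recovery (≤ 0.1 m) from the standard 5-visit
schedule.

## Agreement statistics

Measured and model-estimated values are pooled over subjects and
post-baseline visits into one paired series per outcome (this ignores
within-subject correlation — a documented limitation, matching the pooled
procedure such studies report) and compared with:

* **Passing–Bablok regression**, implemented from first principles: the
  slope is the shifted median of all pairwise slopes (slopes equal to −1
  excluded, median index offset by the count of slopes below −1, making
  the estimate invariant to swapping the methods), the intercept is
  $\mathrm{median}(y - bx)$, confidence bounds use the asymptotic rank
  formula (chosen over bootstrap for determinism), and deviation from
  linearity is assessed by a cusum test against the Kolmogorov–Smirnov
  distribution.
* **ICC(A,1)** — two-way random effects, absolute agreement, single
  measures, the standard form for method comparison; the form was not
  specifiable from the source material, so the choice is documented here
  and the mean squares are returned alongside. The confidence interval
  uses the McGraw–Wong F-distribution bounds. Verified against an
  independent ANOVA decomposition and an external reference
  implementation.
* **Paired t-tests** for systematic measured-vs-estimated differences and
  for baseline vs end-of-treatment changes, with degenerate inputs (zero
  variance of differences) guarded explicitly.

## The synthetic cohort generator

No public dataset exists for this protocol, so `generate_cohort()` is a
first-class module that emulates the study conditions end to end: baseline
distances PFWD $114 \pm 61$ m and 6MWD $287 \pm 85$ m (PFWD drawn as a
fraction of 6MWD so the ordering holds at baseline), 75% male, habitual
cadence normal(95, 15) truncated at 40 steps/min (no cadence distribution
is published; this is a plausible claudicant range, and it means published
cohort-level TRIMP magnitudes are matched only qualitatively), TiTo
prescriptions with a per-subject cadence cap uniform in 90–100%, sessions
skipped independently with probability 0.08 (92% adherence), visits at
weeks {0, 5, 12, 20, 28} with uniform jitter of ±{0, 1, 2, 2, 3} weeks,
and Gaussian measurement noise (SD 15 m by default, chosen so that typical
noisy fits land in the $R^2$ range reported for real cohorts of this
kind).

Impulse-response parameters are drawn per subject from truncated normals
matching the published marginal summaries (PFWD: $k_1\,0.03 \pm 0.06$,
$k_2\,0.03 \pm 0.06$, $\tau_1\,45 \pm 13$ d, $\tau_2\,25 \pm 10$ d; 6MWD:
$0.02 \pm 0.03$, $0.03 \pm 0.03$, $37 \pm 11$ d, $26 \pm 9$ d), with the
decay constants truncated to the calibration's admissible ranges. Marginals
alone, however, generate physiologically impossible subjects: independent
draws let predicted PFWD overtake 6MWD for a large fraction of the cohort
and let some trajectories collapse to zero. Real PFWD/6MWD dynamics are
strongly coupled, and real cohorts of completers show performance changes
of tens to ~120 metres, not many hundreds. The generator therefore
separates *shape* from *magnitude*: the decay constants and the $k_1:k_2$
ratio come from the truncated-normal draws, the common magnitude of
$(k_1, k_2)$ is rescaled so the modelled end-of-follow-up gain equals a
draw from the observed change distribution (+121 ± 70 m PFWD, +33 ± 50 m
6MWD; the SDs are change-score SDs consistent with the published visit
SDs under a typical test-retest correlation), and the whole set is redrawn
by rejection until the trajectory stays above 10% of baseline and PFWD
stays at or below 6MWD on every day of the study window. Visit-level
clipping (PFWD to 6MWD, distances to ≥ 0) remains only as a safeguard
against noise excursions and is inactive in noiseless runs.

What passing tests on this generator do and do not show: they demonstrate
that the *pipeline* is correct (round-trip recovery, agreement statistics
near 1 on noiseless data, the acceptability rule binding under noise), not
that the model describes real PAD physiology; the generator contains no
comorbidity effects, dropout, medication changes, or activity outside the
diary.

## Problem sizes and numerical choices

The shipped tests exercise: 200-day series for the convolution oracle;
noiseless cohorts of n = 100 and noisy cohorts of n = 40 for the
end-to-end properties; n = 2000 draws for the truncated-normal
law-of-large-numbers check; method-comparison fixtures up to n = 15 for
the exhaustive Passing–Bablok oracle. These sizes were chosen to make the
Monte-Carlo tolerances meaningful while keeping the full suite around a
minute of compute.

Degenerate inputs are signalled, not silently absorbed: zero habitual
cadence, all-zero TRIMP series (unidentifiable), fewer than three
post-baseline visits, constant measurements (zero TSS, $R^2$ undefined),
zero between-subject variance (ICC undefined), constant nonzero paired
differences (infinite t), and vertical method-comparison data all raise
errors with the cause named. Grid ties and the rejection sampler are
deterministic given the seed; a rejection budget of 5000 draws per
parameter set falls back to the least-violating draw with a warning.

## Design choices that were genuinely open

* The spec-level texts for this model family are ambiguous about whether a
  single-component (fitness only) or two-component system was fitted;
  the reported parameter tables and figures carry both components, so the
  two-component form is implemented.
* Whether all four constants were fitted freely or tied ($k_1 = k_2$) is
  not stated; the 6MWD parameter summaries differ between $k_1$ and
  $k_2$, so the package fits them freely.
* Daily $w(t)$ sums the two daily sessions, because the Banister input is
  per-day; the printed worked examples are single sessions.
* Subjects failing the $R^2 > 0.30$ rule are *retained* in the pooled
  agreement statistics by default (matching the pooled "all time points"
  procedure), with `exclude_unacceptable = TRUE` available.
* Visit days are used as recorded (jittered), never idealised to exact
  weeks.

## A worked run

```{r pipeline}
cfg <- cohort_config(n_subjects = 20, seed = 42)
res <- run_pipeline(config = cfg)
res$agreement |> select(outcome, pb_slope, icc, icc_low, icc_high, n)
res$summary |> filter(outcome == "pfwd")
performance_deltas(res$visit_table)
```

```{r plot, fig.width = 7, fig.height = 4}
co <- generate_cohort(cfg)
s1 <- co$subjects[1, ]
w <- trimp_series(filter(co$diary, subject_id == s1$subject_id),
                  habitual_speed = s1$habitual_speed_spm)
autoplot(predict_performance(banister_params(s1$pfwd_m, 0.03, 0.03, 45, 25),
                             w, horizon = 250))
```

## Known limitations

* Pooling subject × visit pairs treats repeated measures as independent;
  agreement CIs are therefore optimistic.
* With the standard 5-visit schedule, individual $(k, \tau)$ estimates are
  soft; comparisons between subgroups should be read with that in mind.
* The generator's habitual-cadence distribution and change-score SDs are
  informed choices, not published values; cohort-level TRIMP magnitudes
  are matched qualitatively (rising roughly two-fold over the programme),
  not numerically.
* Heart-rate- or lactate-based TRIMP variants, nonlinear or time-varying
  model extensions, and mixed-effects pooling across subjects are out of
  scope.
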