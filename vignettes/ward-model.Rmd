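---
title: "The ward model: probability dynamics, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ward model: probability dynamics, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardsim)
```

wardsim simulates a referral maternity ward as a discrete-time stochastic
process in 15-minute cycles, tracking individual patients, the staff pool,
and the medicine inventory. This vignette is the package's account of the
model itself: the probability bookkeeping, the assumptions baked into each
step, the parameters a user can turn, the calibration procedure, and the
places where the design was genuinely open and a choice had to be made.

## State and the four-step cycle

Every patient carries, per condition, a *probability of mortality* `p` on
`[0, 1)`: her chance of dying from that condition over the remainder of her
stay. Uncomplicated deliveries carry `p = 0` (they still consume staff time
and prophylactic oxytocin, which is what couples them to complicated
patients under scarcity). Each cycle runs:

1. **Admission.** A Bernoulli draw with the current shift's admission
   probability admits at most one patient per cycle. Complications are
   assigned by incidence — a single categorical draw by default, so each
   patient has at most one complication; a `multi_morbidity` flag switches
   to independent per-complication draws, under which the composite
   arithmetic below becomes load-bearing.
2. **Plan assignment and allocation.** Conditions whose plan finished last
   cycle advance to the successor plan; patients whose whole chain is
   complete are discharged alive. The cohort is then walked in strictly
   descending composite mortality
   `p_c = 1 − ∏_k (1 − p_k)` (independent contributions; ties broken by
   earlier admission, then patient id, for deterministic replay). A patient
   is treated only if every staff unit and drug dose her plans demand this
   cycle is available — all-or-nothing; a missing half-dose refuses the
   whole treatment. Staff demanded on consecutive cycles can be flagged to
   *hold*: they stay with the patient and leave the pool until the plan
   completes or the patient dies.
3. **Dynamics and survival.** Treated conditions improve geometrically,
   `p ← p(1 − η)`; untreated patients increment a consecutive-untreated
   counter `c` and every condition worsens as `p ← p^{λ/(λ+c)}`. Survival is
   then evaluated against the per-cycle hazard
   `p = 1 − (1 − p_c)^{1/n}`, where `n` is the number of cycles left in the
   patient's plan chain (floored at 1).
4. **Restock and clock.** Inventory is topped up at multiples of the
   restock interval; shift boundaries swap staff totals and the admission
   probability. Held staff carry across shift changes and availability is
   recomputed as `max(0, on-shift total − held)`.

## The deterioration update

The untreated update is defined as `p ← p^{λ/(λ+c)}`. Composing it over
`c = 1, …, C` raises the starting probability to
`∏_{k=1}^{C} λ/(λ+k) = λ^C Γ(λ+1)/Γ(λ+C+1)`, the gamma-function closed form
the package exposes as `deterioration_closed_form()`. This is the unique
per-cycle rule consistent with both that closed form and a sigmoidal rise of
`p` on the open interval (0, 1): the exponent is below 1, so each untreated
cycle strictly worsens the condition yet never reaches certainty in finite
time. Larger `λ` means *slower* deterioration. The closed-form exponent is
computed with log-gamma differences so large `λ` or `C` cannot overflow, and
the update clamps at the largest double below 1.

## Severity distributions and calibration

Each complication's admission severity is a normal distribution truncated to
the unit interval, centred on the complication's case fatality rate μ. The
standard deviation is not free: the model pins the 2.5% upper tail — two
standard deviations above the mean — to the probability of dying once a
patient is classified as a severe maternal outcome (SMO), giving
`σ = (p_SMO − μ)/2` (`derive_severity_sd()`). Note that after truncation at
0, the *conditional* mass above `μ + 2σ` is slightly larger than 2.28%
(≈ 2.7% when μ = σ = 0.1); the anchoring statement is about the untruncated
distribution. Sampling is by inverse CDF on the truncated quantile range:
exact, rejection-free, and reproducible under a seed.

Calibration then has three layers, only the last of which simulates:

* **σ** follows analytically from the SMO anchor, as above.
* **η** (treatment efficacy, per plan) follows analytically from the rule
  that complete, timely treatment drives the mean severity to a numerical
  floor of 10⁻¹⁰ by the end of the plan chain:
  `η = 1 − (10⁻¹⁰/μ)^{1/D}` with `D` the total chain duration in treated
  cycles. Every plan in a chain shares its complication's η.
* **λ** (deterioration rate, per complication) is fitted by bisection on
  `log λ` against the simulated pooled case fatality rate, holding other
  complications fixed, with identical seed blocks for every evaluation
  (common random numbers). The objective is monotone — more λ, slower
  worsening, fewer deaths — up to Monte-Carlo noise; targets outside the
  CFR range attainable within the bracket `λ ∈ [10⁻², 10⁴]` are flagged as
  non-converged rather than forced. Incidence rates are inputs (the
  admission mixture), never fitted.

## Randomness and common random numbers

Each trial uses one seeded RNG stream (`run_trials()` gives trial *i* the
seed `base_seed + i`). Two design choices make paired scenario comparisons
sharp:

* **Fixed draw schedule.** Every cycle consumes the same number of uniforms
  whether or not a patient is admitted, so the admission process — arrival
  times, complications, severities — is bit-identical across scenarios that
  differ only in resources.
* **One lifetime survival variate per patient.** Survival is evaluated by
  comparing a single uniform `U`, drawn at admission, against the running
  product of per-cycle survival probabilities `S_t = ∏(1 − p_τ)`; the
  patient dies the first cycle `U > S_t`. This factorisation is
  distributionally identical to drawing a fresh uniform against the scaled
  hazard every cycle, but it keeps a patient's fate comparable across
  scenarios: a patient who is pathwise sicker (treated less, deteriorated
  more) under one scenario dies there whenever she dies under the gentler
  one. This is what makes the dominance property — more staff, more stock,
  or less influx never increases deaths under common seeds — hold
  trajectory-wise rather than only in expectation.

## Numerical choices

* Probabilities of exactly 0 and 1 are reserved for the uncomplicated
  baseline and (unattained) certain death; severity draws and deterioration
  updates clamp inside the open interval.
* Composite mortality and the per-cycle hazard are computed with
  `log1p`/`expm1` to keep precision at both ends of the scale.
* The efficacy solve uses `η = −expm1(log(10⁻¹⁰/μ)/D)` and the geometric
  closed form evaluates `p₀·exp(c·log1p(−η))`. The decay spans ~19 nats, so
  the best achievable round-trip accuracy of `μ(1−η)^D = 10⁻¹⁰` is a few
  parts in 10¹⁵ — one ulp of η moves the chain-end value by roughly `D·ε` —
  which is the tolerance the test suite asserts.
* Stock comparisons are exact (`demand ≤ stock`), so fractional-pack
  inventories never go negative; the stock ledger
  (final = initial + restocked − dispensed) balances to the 10⁻⁹ expected
  of sequential floating-point dispensing.
* Deaths are attributed to the condition with the largest individual `p` at
  the time of death; the ward-level outcome measures (mortality rate among
  complicated patients, per-complication CFR and incidence) are computed
  from those tallies, and rates over empty cohorts are reported missing,
  not zero.

## The packaged baseline and what it does (not) show

`default_mmh_config()` emulates a busy East-African referral maternity
ward: three symmetric 8-hour shifts (06:00/14:00/22:00) staffed 5/3, 3/2,
3/1 nurses/doctors with admission probabilities 0.4, 0.28, 0.625 per
15-minute cycle; five complications totalling 13.05% of admissions; chained
acute-then-recovery treatment plans (20 h uncomplicated stay, 1.5–2 days
complicated); 200 packs of oxytocin and 11 packs of hydralazine restocked
monthly. Prophylactic oxytocin for every delivery and hydralazine demand
from the hypertensive disorders couple all patients through the inventory.

Under that schedule the expected admission volume is an arithmetic
consequence of the shift table — `32·(0.4 + 0.28 + 0.625) = 41.76`
patients/day, about 1,253 per 30-day month — and the uncomplicated chain
length (80 cycles) sets a steady census in the 40s (arrival rate times
mean stay, plus queueing under scarcity).

Severity means, the SMO mortality anchor (0.17), deterioration rates, plan
demands and dosages are *illustrative*: clinically plausible stand-ins,
flagged `"illustrative": true` in the config, chosen once so that the
baseline ward operates under mild pressure (mortality among complicated
patients in the low single-digit percent, hydralazine the tightest
resource). Passing tests therefore demonstrate that the mechanism is
implemented correctly and that its comparative statics (stockouts and
understaffing kill; restocking and triage save) behave as designed — they
do not validate the absolute rates against any real facility. Real use
requires facility-specific plans, incidences and severity parameters.

The synthetic generator also does not emulate: referral networks upstream
of the ward, operating-theatre and ICU logistics, mid-stay acquisition of
new complications, diagnostic error, or patient-procured medication.

## Design decisions that were genuinely open

* **Shift boundaries** are not implied by staffing totals alone; symmetric
  8-hour shifts starting 06:00 are the default and the boundaries are
  configurable.
* **At most one admission per cycle** (Bernoulli), rather than Poisson
  arrivals; at 15-minute resolution the difference is negligible and it
  matches the one-intake-per-cycle structure of the model.
* **Untreated cycles do not advance plan progress**, so a stay extends
  implicitly under shortage: plan durations are defined in *treated*
  cycles. The remaining-stay `n` in the survival hazard is the remaining
  chain length, floored at 1.
* **Same-cycle evaluation**: patients admitted in a cycle are allocated,
  updated and survival-evaluated in that same cycle.
* **Holds across shift changes**: staff held with a patient stay held; the
  incoming shift's availability is what remains (floored at zero).
* **Fungible staff**: staff are counted units within type, not named
  individuals.
* Test and calibration problem sizes are deliberately small — short
  horizons (2–15 days), handfuls of trials, single-complication wards — so
  the whole suite exercises every invariant (closed-form equivalence,
  conservation, allocation optimality, calibration recovery, dominance) in
  a few minutes; the packaged 90-day × 50-trial baseline is reserved for
  the acceptance script.

## Limitations

Deterioration and treatment act on each condition independently; there are
no interaction terms between simultaneous conditions beyond the composite
survival product. The untreated counter is per patient, not per condition.
Resource demand is binary per cycle (met or not); partial treatment has no
effect. The calibration fit is one-dimensional per complication and
sequential, which is adequate because cross-complication coupling acts only
through resource competition, but a strongly coupled ward could require a
joint fit the package does not attempt.
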