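---
title: "Ward-network occupancy simulation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ward-network occupancy simulation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wardsim` forecasts short-term hospital bed occupancy by simulating a
network of wards in discrete time and, crucially, by re-initialising that
simulation from the observed bed state — a *symbiotic* simulation. This
vignette is the package's own account of the model, its assumptions, the
parameters that matter, and the places where a design decision had to be
made.

## The model and its assumptions

Time advances in steps of one day; the unit of observation is the
*midnight bed census* $M_t^w$ — the number of patients occupying beds on
ward $w$ at the midnight of day $t$, split into emergency and elective
admissions. Patients whose entire hospital spell begins and ends on the
same calendar day never span a midnight and are excluded from the metric.

Four stochastic components drive the dynamics:

* **Emergency arrivals.** The daily count of emergency hospital
  admissions to each ward is drawn from an empirical distribution
  specific to the day of the week. Arrival counts on different days and
  wards are independent.
* **Elective arrivals.** Electives are the decision variables: a schedule
  lists the planned (day, ward) of each elective patient. A non-attendance
  probability (default 0) independently thins the schedule.
* **Ward length-of-stay (WLOS).** Every admission draws the number of
  midnights $T \ge 1$ it will spend on the ward from an empirical pmf
  stratified by (ward, admission type, weekday of arrival at that ward).
  The weekday stratification reflects the empirical association between
  admission weekday and subsequent stay length.
* **Transfers.** When a ward stay ends, a destination — another ward or
  discharge — is drawn from a row-stochastic matrix $\pi^{type}$
  estimated per admission type. Transitions depend only on the current
  ward and type (a first-order, memoryless simplification); a transfer
  starts a new stay with a fresh WLOS draw conditional on the new ward
  and the transfer day's weekday.

**Infinite servers.** Occupancy is never capped. The model deliberately
excludes capacity constraints and the behavioural responses they trigger
(turn-aways, outlier placement); its purpose is to estimate the *offered
load* and hence the probability that demand would exceed capacity. Bed
capacities enter only in reporting.

**Within-day order.** Departures and transfers resolve before the day's
census; arrivals of the day are counted in that day's census; a patient
transferring on day $t$ occupies only the destination ward at midnight
$t$. A stay is the half-open interval $[\text{arrival},
\text{departure})$, so WLOS equals departure minus arrival in days, and a
same-day ward stay (an intra-day transfer segment) has zero midnights but
is retained in the records — the same-day *exclusion* applies at spell
level only, because dropping intra-day segments of multi-day spells would
break transfer chains.

## Estimation

`hospital_model()` estimates every input from ward-stay records:

* **Ward selection.** Wards are ranked by mean midnight occupancy; the
  smallest prefix covering a `coverage` share (default 0.9) is modelled
  individually, the remainder aggregated as `Other`. Ties break by label.
* **Arrival distributions** are the empirical pmfs of daily emergency
  *hospital admission* counts per (ward, weekday), zeros included.
  Transfers into a ward are reproduced by the transition model, not the
  arrival model, so only stays whose arrival equals the spell's hospital
  admission date count as arrivals. The observation window spans the
  record set's admission days.
* **WLOS distributions** are empirical pmfs of observed midnight counts
  per (ward, type, weekday). Sparse strata fall back along the pooling
  ladder (ward, type, weekday) → (ward, type) → (ward) → global; the
  first non-empty level wins, and the level used is recorded in the
  fitted object. No smoothing is applied: empirical distributions keep
  the estimator aligned with the data-driven character of a symbiotic
  simulation. A ward with no closed stays at all is an error.
* **Transition matrices** are departure proportions: the next stay of the
  same patient beginning on the departure day is a transfer to its ward;
  anything else is a discharge. Rows with no observed departures default
  to a point mass on discharge.

Two conventions resolve ambiguities in the underlying data model: the
conditioning weekday for a transferred patient is the weekday of arrival
*at the current ward* (WLOS is a per-ward quantity), and a patient's
admission type is carried unchanged through the spell.

## Conditional remaining length-of-stay

A resident who has spent $s$ midnights on a ward does not face the
unconditional WLOS distribution. With $F_T$ the estimated CDF and the
convention $F_T(-1) = 0$,

$$F_R(r, s) = \frac{F_T(s + r) - F_T(s - 1)}{1 - F_T(s - 1)},$$

sampled by the inverse-transform method (the right-continuous generalized
inverse: the smallest support value whose CDF strictly exceeds the
uniform draw). For geometric WLOS the conditional equals the
unconditional distribution — the memoryless case in which conditioning is
unnecessary — and the package's tests verify this identity analytically.

Two boundary rules: an elapsed time beyond the empirical support (a
long-stayer unseen in training data) is clamped down to the largest
supported elapsed time, keeping the patient in-system rather than
erroring; and `conditional_cdf()` permits $r = 0$, departure at the next
midnight boundary.

**Resident loading in the engine.** A snapshot captured from the midnight
census contains exactly the patients present at that midnight, and such a
patient necessarily has $T \ge s + 1$. The engine therefore samples a
resident's remaining stay as $1 + R$ with $R \sim F_R(\cdot, s + 1)$: the
initiation midnight is certain, and the remainder is conditioned on
having reached it. This choice makes the simulated census at the
initiation time equal the loaded state exactly (the "collapse" property
that distinguishes a symbiotic simulation), and makes a resident with
$s = 0$ distributionally — in fact bit-for-bit, under shared seeds —
identical to a fresh admission that day. Conditioning at $s$ instead
would make every loaded resident depart one midnight early in
expectation, a bias the self-validation tests detect immediately.

## Random-number discipline

Each replication runs on its own stream seeded from the base seed, so
results are bit-reproducible. Within a replication, draws are
*positional*: arrival counts first, then (if active) the information
Bernoullis, then chain rounds in which every active patient consumes
exactly two uniforms — a length-of-stay slot and a destination slot —
whether or not it needs them. Patients are processed in a fixed creation
order (residents, emergencies, electives in schedule order). The payoff
is exact common-random-number coupling: comparing two schedules that
differ by appended or removed electives leaves every shared patient's
draws untouched, so cancelling a patient can never increase simulated
occupancy pathwise, and the discharge-information experiment's $d$ grid
is coupled patient-by-patient (the set of patients using truth grows
monotonically in $d$ for a given replication). A naive
one-block-per-draw scheme silently breaks all of these couplings, because
inserting one draw shifts every subsequent patient's position in the
stream.

## Validation: the Δ-method

A re-initialised simulation is transient by design, so its output
distribution depends on time since initialisation. The Δ-method compares
distributions of the *changes* $\Delta_{t,h} = M_t - M_{t+h}$: observed
changes pooled over all day pairs of the record, against simulated
changes $M_{t_0} - \hat M_{t_0+h}$ pooled over weekly initiation points
and replications, where $M_{t_0}$ is the shared observed starting value.
The two collections are compared per horizon offset $h$ with a P–P plot
— empirical CDFs evaluated at the union of observed values, simulation on
the horizontal axis. The maximum absolute deviation from the identity is
reported as a numeric convenience; it is a summary of the visual
assessment, not a test statistic with a reference distribution.
Prediction-interval coverage complements it: the central 90% band from
replication percentiles (order-statistic quantiles with linear
interpolation; ties at an endpoint count as covered) should contain about
90% of observed values, pooled over wards and non-initiation days.

Three statistical cautions, which shaped the package's own acceptance
tests:

* With $k$ initiation points the simulated pool is a $k$-state sample of
  a state mixture; its CDF carries irreducible noise of order
  $1/\sqrt{k}$, visible as per-ward P–P deviations of a few hundredths
  even for a perfectly specified model. Aggregate (all-ward) comparisons
  and initiation points spread across the record both temper it.
* The method pools observed changes over all start days but simulated
  changes over one weekday's initiations; its identity-line premise
  therefore presumes the change distribution is start-day invariant.
  Strong weekday structure moves the two pools apart for reasons other
  than misspecification.
* Synthetic records begin from an empty hospital; the warm-up transient
  (longer than the maximum WLOS) must be excluded from both pools, since
  a real extract from a running hospital has no such epoch.

## Decision support

`warning_report()` turns replications into exceedance probabilities —
strictly above the warning threshold (fraction × capacity, default 0.9)
and strictly above capacity — and into BMOC, the per-replication total of
beds in excess of capacity summed over wards and midnights, averaged over
replications and reported to two decimals. When the simulation was
snapshot-initialised, the initiation day is excluded from both the
probabilities and BMOC (its occupancy is loaded, not predicted).
`compare_schedules()` evaluates named schedules under a shared base seed
and reports deltas against the first.

`edd_experiment()` models clinicians' estimated discharge dates: with
probability $d$ a patient's true (remaining) length-of-stay is used,
otherwise a fresh draw from the applicable conditional distribution —
independently per patient and replication. Truth must be supplied for
every snapshot resident and scheduled elective; emergency arrivals within
the horizon never have truth. The response is the standard deviation of
midnight occupancy across replications, per ward and day, averaged by
weekday; it is non-increasing in $d$, and $d = 1$ with no exogenous
randomness collapses it to zero.

## The synthetic hospital

`ground_truth_config()` states a fully known world: per-ward Poisson (or
empirical) weekday arrival rates, truncated-geometric (or empirical) WLOS,
transition matrices, a deterministic elective plan and a non-attendance
probability. `generate_records()` follows every patient to discharge, so
all generated stays are closed and the records satisfy the stay
invariants by construction; `generate_snapshot()` additionally captures
each resident's true remaining stay, hidden from the simulator but
available as a test oracle and as the $d = 1$ information source.

Defaults in the package's tests are chosen once, before any test was run,
at scales a district hospital would recognise: ward arrival rates of 3–20
per day, geometric WLOS with means of 2–3.3 midnights truncated at 30,
transfer probabilities below 0.15, elective plans of 0–6 patients per
ward-day. Poisson arrivals are the default family because they admit
closed-form oracles (the stationary census of a single uncapacitated ward
is Poisson with mean λ/p); the empirical-table family mirrors exactly what
the estimator produces. What the generator deliberately does *not*
emulate: seasonality and trend, case-mix, capacity feedback on admissions,
and intra-day timing — so a green test establishes correctness of the
estimation–simulation–validation chain under the model's own assumptions,
not the realism of those assumptions for any particular hospital.

## Numerical choices

* Weekdays are integers 1–7, Monday first; dates are ISO-8601 at day
  granularity; intra-day times are discarded on read.
* `sample_pmf()` maps $u$ to the smallest support value with CDF $> u$;
  the conditional pmf is built from the CDF-difference formula with the
  floating-point residue absorbed into the last atom (tests check
  agreement with exact ratio arithmetic to $10^{-12}$).
* Percentiles are type-7 (linear interpolation) throughout.
* Truncated geometric pmfs renormalise by default; exact memorylessness
  checks use an untruncated tail (mass below $10^{-12}$) instead.
* Parameter files are JSON at full floating-point precision, so
  serialisation round trips are exact and a reloaded model simulates
  bit-identically.

## Known limitations

Occupancy is uncapacitated, so wards that often run at capacity show
lower variance in reality than in simulation — the validation plots make
this visible as an S-shaped P–P curve, and for such wards the model warns
of pressure rather than reproducing censored occupancy. Transfer routing
is first-order in the current ward; lengths-of-stay are independent
across stays of one patient; elective scheduling is evaluated, not
optimised. The records-facing code assumes the extract's transfer chains
are contiguous in dates; messy real extracts may need cleaning before
`read_ward_stays()`.
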