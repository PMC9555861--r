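---
title: "A stylized model of temporary disruptions to cervical screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stylized model of temporary disruptions to cervical screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screendelay)
library(dplyr)
```

## The question the package answers

When primary cervical screening pauses — as it did in 2020 — the harm is not
spread evenly. A woman screened last year can absorb a one-year pause; a woman
already five years overdue cannot. `screendelay` simulates birth cohorts of
women through HPV acquisition, precancer, and invasive cancer, under routine
screening schedules that are interrupted for one, two, or five years, and
reports two families of statistics:

* **Short-term:** the rate of *symptomatically detected* cancer accumulated
  during the delay window, per 100,000 women at risk at the window start, and
  its ratio (RR) against a guidelines-compliant screener (3-yearly cytology or
  5-yearly primary HPV testing) experiencing the same delay.
* **Long-term:** the lifetime risk of diagnosed cervical cancer to age 84, the
  incremental risk and excess cases per 100,000 women attributable to the
  delay, and the percent of cancers prevented relative to never screening.

The default experiment grid crosses three birth cohorts (1965, 1975, 1985 —
aged 55, 45, 35 at the 2020 disruption), four underlying screening frequencies
(1-, 3-, 5-, 10-yearly, aligned so a screen falls due in 2020), two primary
modalities (cytology with reflex HPV triage; primary HPV testing with partial
16/18 genotyping), and four delays (0, 1, 2, 5 years): 96 cells plus a
no-screening reference per cohort.

## Natural-history model

Each woman progresses monthly through

```
HEALTHY <-> HPV_INFECTED <-> PRECANCER -> PRECLINICAL_CANCER -> DIAGNOSED_CANCER
```

with benign hysterectomy and other-cause death as competing risks from any
non-cancer state (hysterectomy is only allowed before invasive cancer), and
treatment of a detected precancer returning the woman to `HEALTHY` with the
causal infection cleared. Two genotype groups are tracked — HPV16/18 and the
pooled other high-risk types — because management rules refer only to that
split: 16/18 accounts for 25% of acquisitions but progresses to precancer four
times as readily, so it contributes roughly 60% of cancers. Low-risk types,
CIN1, cancer staging, and cancer mortality are out of scope; a diagnosed
cancer is an absorbing endpoint.

All sojourns are geometric: each state has constant per-cycle exit
probabilities, so the mean time in a state is the reciprocal of the total
monthly exit probability. The cycle is one month — coarser cycles would alias
a one-year delay against the annual screening interval.

**Ordering of events within a cycle.** The model resolves, in order:
(1) symptomatic presentation of a preclinical cancer; (2) scheduled screening
or surveillance contacts; (3) other-cause death; (4) benign hysterectomy;
(5) at most one disease transition, drawn from a single uniform partitioned
over the competing transitions. Two consequences are deliberate: a
symptomatic diagnosis can never coincide with an attended screen, and a
configuration with all test sensitivities at zero reproduces the no-screening
risk *exactly*, which the test suite asserts.

## The three dwell-time variants

The generator ships three parameter sets that differ only in rate values, not
structure, emulating the way independently built natural-history models
disagree about how long disease dwells before presenting:

| variant | mean dwell, acquisition to symptomatic cancer | occult fraction |
|---|---|---|
| `short_dwell` | 10 years | 0.10 |
| `medium_dwell` | 15 years | 0 |
| `long_dwell` | 20 years | 0 |

The total dwell is split 15% / 50% / 35% across the HPV, precancer, and
preclinical stages, so for example the short variant spends on average 18
months infected, 60 months in precancer, and 42 months in preclinical cancer.
Conditional exit splits are fixed across variants:
P(progress to precancer | infection) is 0.18 for HPV16/18 and 0.045 for other
high-risk types, and P(invade | precancer) is 0.32. The short-dwell variant
additionally makes 10% of new precancers *occult*: persistently invisible to
cytology (think lesions deep in the canal) though fully visible to HPV testing
and colposcopy. The flag is assigned once at lesion onset and never
reassigned.

These dwell targets and splits are stylized stand-ins — the literature
supports their *ordering*, and the parameter files are labelled accordingly in
their metadata. `dwell_time_summary()` recovers the stage means analytically
and the test suite confirms the simulated sojourns match.

**Self-calibration.** Within each variant the HPV acquisition curve (a gamma
shape over age, zero before 12, peaking near 22, negligible past 60, split
25/75 between genotype groups) is scaled by a four-step fixed-point iteration
until the *no-screening* lifetime risk under the default demography equals
1.0% — inside the 0.5–2% range implied by screened-population risks of a few
tenths of a percent that prevent 70–85% of cancers. No registry calibration is
attempted; equalizing the no-screening risk across variants makes
between-variant contrasts interpretable as dwell-time effects.

## Screening, triage, and management

* **Primary cytology:** positive (ASCUS+) with sensitivity 0.55 against
  precancer and 0.80 against preclinical cancer (zero against occult lesions),
  false-positive rate 1 − 0.97 in lesion-free states. Positives receive
  reflex HPV testing; only reflex-positive women are referred.
* **Primary HPV:** positive with sensitivity 0.90 whenever infection or a
  lesion is present, false-positive rate 1 − 0.94 otherwise (false positives
  are genotyped as other-HR). HPV16/18 calls go directly to colposcopy; other
  high-risk calls are referred only on ASCUS+ triage cytology, which uses the
  same cytology characteristics (so occult lesions can reach colposcopy only
  through a 16/18 call).
* **Colposcopy and treatment:** referred women attend with probability 0.79;
  colposcopy sees a prevalent lesion with sensitivity 0.95; detected
  precancers are treated with probability 0.73. Detected-but-untreated
  lesions enter *annual surveillance*: a management visit every 12 months
  until the lesion is treated, diagnosed, or regresses. Surveillance is
  explicitly unaffected by the screening disruption, and women under
  surveillance skip routine screens. Non-attenders of a first colposcopy
  referral simply return to the routine schedule.

The compliance values 0.79 and 0.73 are the published Kaiser Permanente
Northern California patterns for colposcopy and precancer treatment; the test
suite recovers both from simulation. Colposcopy sensitivity 0.95 and the
reuse of the primary HPV test characteristics for reflex/triage testing are
package defaults where the source material is silent. Co-testing is not
implemented.

## Schedules and the disruption

Schedules are anchored *backward* from the screen due in 2020: a "10-yearly"
1975-cohort woman screened in 2010 and 2000, and would screen at 45, 55, and
65. The disrupted 2020 screen moves to 2020 + delay; later screens keep the
fixed frequency from the shifted anchor; screens landing past the stop age
(65) are dropped rather than moved, which is the only reading consistent with
published last-screen ages (56/57/60 for the 10-yearly example, 61 for a
5-yearly screener under a 1-year delay). First screens never precede age 21.
In primary-HPV scenarios the modality switches at the first scheduled screen
at or after age 30 — no off-cycle screen is inserted at exactly 30, so a
10-yearly 1985-cohort woman screens with cytology at 25 and first uses HPV
testing at 35. Routine attendance is deterministic; the delay window is
half-open, `[2020, 2020 + delay)`.

## Demography and vaccination

Other-cause mortality is Gompertz plus a small background hazard (survival to
84 about 0.79); the benign-hysterectomy hazard is bell-shaped around age 45
with a lifetime fraction near 26%. Both are stylized, monotone/unimodal by
construction, and shipped as age-indexed monthly-probability CSV tables.
After hysterectomy no further events are simulated: the woman can no longer
develop cervical cancer and her subsequent mortality does not enter any
reported statistic. Lifetime risks are cohort proportions over *all* simulated
women — including those who die or lose the cervix to hysterectomy — so risk
differences convert directly to excess cases per 100,000 women.

Vaccination is a cohort property: coverage 0 for the 1965 and 1975 cohorts
and 0.35 (efficacy 0.95 against HPV16/18 acquisition) for the 1985 cohort by
default — configurable, since coverage estimates live in external sources. A
vaccinated woman's 16/18 acquisition probability is multiplied by
1 − efficacy for life. Full coverage at full efficacy provably eliminates
16/18-attributed cancers, and under full efficacy the 16/18-attributed risk
is exactly linear in coverage (the solver mixes a vaccinated and an
unvaccinated stratum).

## Two engines, one transition structure

The Monte Carlo engine (`simulate_cohort()`, compiled) samples individual
life courses: death and hysterectomy months are pre-drawn by inverse CDF from
their marginal monthly processes, and each month resolves contacts and at
most one disease transition. Every woman owns a reproducible random stream
keyed by `(seed, cohort, woman index)` — common random numbers — so the same
woman flows through every scenario arm with identical latent randomness and
arm contrasts are not diluted by sampling noise; a delay-0 arm compared with
itself differs by exactly zero.

The deterministic solver (`cohort_solve()`) propagates the full state
distribution through the *same* monthly algebra, including the surveillance
countdown (lesion states carry a 12-month phase) and the genotype/occult
split. It is the package's verification oracle: for every grid cell the
microsimulation's lifetime risk and window incidence must sit within three
binomial standard errors of the solver's expectation at the simulated n, and
the suite also checks a closed-form case — a cohort placed in preclinical
cancer at age 20 with constant annual symptomatic hazard 0.001 and no
competing risks must return a lifetime risk of 1 − exp(−0.064), exactly for
the solver and within Monte Carlo error for the engine.

Numerical choices worth knowing: state-occupancy mass is conserved to 10⁻¹⁰
per cycle; the solver errors on any per-cycle probability block summing above
one; zero transition rates are reported as infinite sojourns, not errors; and
a delay of zero makes the window rate "not applicable" (`NA`), excluded from
RR tables. One statistical caveat on the oracle sweep: a per-cell 3·SE band
applied to roughly five hundred binomial comparisons is expected to show
about one marginal exceedance purely by chance even when the two engines are
exactly equivalent, so a single cell near the boundary at a fixed seed is the
behaviour of a correct implementation, not evidence of bias.

## What the defaults reproduce — and what they cannot

With the shipped variants and the deterministic solver, the full grid shows
the qualitative findings one expects of this scenario family: underscreeners
face window-rate ratios above 1 against compliant screeners at every delay;
lifetime risk rises monotonically with the screening interval and excess
cases rise monotonically with the delay; every screening scenario prevents a
positive share of no-screening cancers; and delays cost less under primary
HPV screening than under cytology for the longer-dwell variants at common
frequencies (the more sensitive test leaves less undetected disease standing
when the disruption hits).

One published between-model pattern is *not* reproducible inside this
package's structure, and we state it rather than tune toward it: with
geometric sojourns and variants that differ only in rates, the
underscreener-vs-compliant rate ratio necessarily *increases* with dwell
time — per-screen interception compounds over more screening opportunities,
scaling the per-lesion escape-probability ratio like
\((1-q)^{-D(1/3 - 1/5)}\) for per-screen interception \(q\) and dwell \(D\)
years. Multi-model comparisons in which the shortest-dwell model shows the
*largest* underscreener rate ratio rely on structural differences between
the models (non-geometric dwell distributions, age-dependent progression,
independent registry calibrations) that are deliberately outside this
package's scope. Similarly, exactly where the cytology-vs-HPV excess-case
balance tips is a fine quantitative trade-off (a lower standing burden at
disruption versus losing a more sensitive screening moment); the
medium-dwell variant tips at a slightly different frequency than its
real-world counterpart. Simulated dwell-time variants are a mechanism probe,
not replicas of any calibrated model — passing this package's tests says the
engine is faithful to *its* stated model, not that the stylized variants
quantitatively match any published projection.

## Worked example

```{r example, eval = FALSE}
params <- make_variant("short_dwell", seed = 1)
dem <- make_demography()
spec <- scenario_spec(1975, 5, "CYTOLOGY", delay_years = 1)
sol <- cohort_solve(build_schedule(spec), params, dem,
                    make_vaccination_profile(1975))
lifetime_risk(sol)
symptomatic_rate_in_window(sol)

# the full grid, solver engine, with derived outcome statistics
out <- run_scenarios(run_config(engine = "cohort", seed = 1))
summary <- summarize_outcomes(out)
summarize_table1(summary)   # excess cases of a 5-year delay, by frequency
plot_rate_ratios(summary)
```

Problem sizes used by the shipped tests: the solver sweeps all 99 cells per
variant in well under a minute; the Monte Carlo oracle-equivalence sweep runs
200,000 women per cell over the 96-cell grid for all three variants, and the
compliance-recovery and closed-form checks use 100,000 women each.

## Known limitations

* Geometric sojourns cannot express "scheduled" lesion biology; see above.
* Treated women rejoin routine screening with no elevated risk (no treatment
  failure or recurrence), and cleared infections confer no natural immunity.
* Routine attendance is all-or-nothing per the schedule; there is no
  opportunistic catch-up compressing post-delay intervals.
* Cancer survival, stage at diagnosis, diagnostic-delay disruptions, and
  cost-effectiveness are out of scope by design.
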