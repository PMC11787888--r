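---
title: "Humanized antibiotic exposures in murine plasma and ELF: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Humanized antibiotic exposures in murine plasma and ELF: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsrsim)
```

## The problem

Murine pneumonia models are a standard preclinical stage for antibiotics
seeking a pneumonia indication, but a mouse given a clinical dose does not
experience clinical exposure: clearances, protein binding and — critically —
lung penetration all differ between species. A *human-simulated regimen*
(HSR) is a murine dosing schedule engineered so that the mouse's unbound
drug exposure approximates that of a patient receiving the clinical
regimen. Because penetration from plasma into pulmonary epithelial lining
fluid (ELF) is itself species-dependent, plasma-matched regimens generally
do not match ELF: each matrix needs its own HSR.

`hsrsim` implements the full quantitative workflow behind developing and
confirming such regimens for three drugs with established use in
Gram-negative pneumonia — meropenem, cefiderocol (both 2 g q8h as 3 h
infusions in humans) and tobramycin (7 mg/kg as a 30 min infusion):

1. closed-form pharmacokinetic simulation of multi-dose subcutaneous
   regimens, including the periodic steady state;
2. PK/PD exposure metrics — %fT>MIC across MIC doubling dilutions for the
   β-lactams, fCmax and fAUC~0–24~ for the aminoglycoside;
3. matrix corrections — ultrafiltration free fractions, BAL urea-dilution
   estimation of ELF concentrations, and a linear plasma→ELF penetration
   model;
4. naive-pooled nonlinear least-squares parameter estimation with AIC model
   selection and IQR outlier filtering;
5. an optimizer that formalizes "humanizing" a regimen as exposure
   matching; and
6. a seeded synthetic-data generator so that every stage is testable
   without animal data.

## The concentration model

All murine dosing is subcutaneous bolus on a per-kg basis, described by a
one-compartment model with first-order absorption and elimination. For a
dose $D$ (mg/kg) given at time zero,

$$C(t) = \frac{D}{V}\,\frac{k_a}{k_a-k_{el}}
  \left(e^{-k_{el}t}-e^{-k_a t}\right),$$

with apparent volume $V$ (L/kg) and rate constants $k_a, k_{el}$ (1/h).
Bioavailability is fixed at 1; $V$ is apparent, so any $F<1$ is absorbed
into it. The parameterization is only identified up to the *flip-flop*
exchange $(V,k_a,k_{el}) \to (V k_{el}/k_a,\,k_{el},\,k_a)$, which leaves
the curve unchanged; flip-flop orientations are therefore permitted
(meropenem murine plasma has $k_a = 1.34 < k_{el} = 27.13$, i.e. the
terminal slope is absorption-limited) and recovery assessments align
orientations with `align_flipflop()`.

Profiles are stored as explicit term lists — exponentials
$c\,e^{-r(t-s)}$, the degenerate-absorption term $c\,(t-s)e^{-r(t-s)}$
(used when $|k_a-k_{el}|/k_a < 10^{-9}$), and constant/linear pieces for
zero-order infusions and penetration products. Everything downstream
(evaluation, maxima, level crossings, AUC) works on this closed form;
dense 0.001 h grids are only display views.

Linear kinetics make multi-dose profiles superpositions of shifted
single-dose terms. For a block of doses repeated every $\tau$ hours, each
exponential term accumulates geometrically, and the within-interval
steady-state profile adds, per term of coefficient $c$, rate $r$ and onset
$s$, a carry-over term
$c\,e^{-r(\tau-s)}/(1-e^{-r\tau})$ active from the interval start. An
independent route — stacking intervals until the interval-start
concentration changes by less than $10^{-6}$ relative — agrees with the
analytic route to the same tolerance and is the fallback for the
degenerate absorption case, which has no geometric closed form in this
term basis.

## Exposure metrics

* **AUC** is the exact analytic integral of the term list; trapezoidal
  integration on a 0.001 h grid agrees within 0.1% and is used as a test
  oracle only.
* **Cmax** is found by optimizing each inter-onset segment (the only
  non-smooth points are dose onsets) and comparing with segment endpoints.
* **%fT>MIC** measures $\{t : C(t) > \text{MIC}\}$: crossings are
  bracketed on a 0.001 h grid and refined by bisection to ~$10^{-9}$ h, so
  reported percentages are stable well below 0.01 points. The inequality
  is strict; the boundary has measure zero.

Evaluation windows follow use: the q8h β-lactam regimens are evaluated at
periodic steady state over one 8 h interval (equivalent to any steady
24 h), the single-course tobramycin regimens over 0–24 h. Plasma profiles
are multiplied by the murine unbound fraction (meropenem 0.92, cefiderocol
0.684, tobramycin 0.776 from the escalating-dose ultrafiltration study);
ELF lacks albumin, so ELF concentrations are treated as unbound without
correction.

```{r}
ss <- hsr_profile("meropenem", "plasma")
doubling_grid_summary(ss)
```

## Matrix corrections

**Free fraction.** Each ultrafiltration replicate gives
$f_u = C_{uf}/C_{total}$; replicates are averaged within dose group and
dose groups pooled by an unweighted mean, treating binding as
exposure-independent across the studied range. Fractions above 1 (assay
noise) are capped with a warning; non-positive totals are dropped.

**ELF from BAL.** Lavage dilutes ELF with saline. Urea equilibrates freely
between plasma and ELF, so the dilution factor is recovered from paired
urea measurements:
$C_{ELF} = C_{BAL}\,\times\,\mathrm{urea}_{plasma}/\mathrm{urea}_{BAL}$.
Only the urea ratio enters, so any consistent unit works (mg/dL by
default). The correction is exactly inverse to the generative dilution
model, which the synthetic BAL generator exploits for round-trip tests.

**Penetration line.** Where human ELF data exist only as single-timepoint
penetration ratios, an OLS line $\mathrm{ratio}(t) = at + b$ is fitted
(for tobramycin: $a = 0.1223$ /h, $b = 0.1567$, $R^2 = 0.986$ on ratios at
0.5, 2, 4 and 8 h, shipped as a fixture since the source ratios are not
public). `apply_penetration()` multiplies a plasma profile by the line —
the product stays inside the closed-form term basis, so the projected ELF
profile and its AUC remain exact. By default the line is only applied
inside its fitted time range; extrapolation to a full 0–24 h window (its
published use, yielding an AUC ratio of 0.69) requires an explicit flag.
Negative predicted ratios are refused with the offending endpoint named.

## Parameter estimation

Destructive sparse sampling (groups of six mice per timepoint, two
retro-orbital bleeds plus one terminal sample each) leaves no within-animal
profile, so all observations are pooled naively into one curve. Weighted
least squares
$\sum_i w_i (y_i - \hat C(t_i))^2$ is minimized on the log-parameter scale
by multi-start optimization (Nelder–Mead then BFGS polish): $k_{el}$ is
seeded from the terminal log-linear slope, $V$ from back-extrapolation,
and $k_a$ from a log-spaced ladder, so fits are deterministic given data.
Weighting options are none (default — the reference software's scheme is
unknown), $1/y$ and $1/y^2$; sensitivity to the choice can be read off the
fit report. Observations below a configured LLOQ are dropped, never
imputed.

A two-compartment-disposition candidate (tri-exponential closed form,
5 parameters) is fitted alongside for model selection by the
least-squares AIC, $n\ln(\mathrm{RSS}/n) + 2k$, with ties going to fewer
parameters. Outliers are removed in a single pass per
timepoint × analyte × matrix group by Tukey fences
$[Q_1 - 1.5\,\mathrm{IQR},\,Q_3 + 1.5\,\mathrm{IQR}]$ with interpolated
quartiles; groups smaller than four pass through, and exclusion tallies
are reported per matrix in the conventional `x/n (p%)` form.

## Regimen design

The published workflow modified baseline regimens "by hand" until murine
exposures matched human targets; `design_regimen()` formalizes this as a
reproducible two-stage search over dose amounts at fixed candidate
injection times: bounded continuous optimization (L-BFGS-B, one even start
plus seeded random starts), then rounding to a deliverable dose grid
(0.05 mg/kg by default, finer than the 0.25 mg/kg granularity of the
published schedules) with greedy single-step polish. The loss is either a
log-scale profile mismatch (floored at 0.01 mg/L so troughs cannot send
the log to $-\infty$) or a weighted squared relative mismatch of fCmax,
fAUC and the %fT>MIC vector (differences in percentage points scaled by
100). Default weights follow drug class: β-lactams match the %fT>MIC
vector, aminoglycosides match fCmax and fAUC equally. Exposure matching is
degenerate — many schedules achieve the same indices — so the contract is
the achieved exposure, not the dose vector.

## The synthetic-data generator

The generator emulates the structure of the in-vivo studies: destructive
sampling with six mice per timepoint and at most three samples per mouse;
proportional observation noise $y = C(t)(1+\varepsilon)$,
$\varepsilon \sim N(0, \mathrm{CV})$ truncated at $-0.99$, with CV
defaulting to 20% (below the <30% variability typical of antibiotic PK
parameters); per-mouse lavage dilution drawn Uniform(0.01, 0.10) with
paired urea (plasma urea fixed at 40 mg/dL — no published dilution or
urea statistics exist, so these are labelled placeholders); escalating
2.5/5/10 mg/kg ultrafiltration designs; and seeded multiplicative
outliers with recorded flags. All randomness flows from one explicit seed
and every generator records its truth, so recovery is scoreable.

What it does **not** emulate: inter-animal kinetic variability (the truth
is one parameter set — appropriate for validating a naive-pooled
estimator, but real mice differ), assay-specific error structure beyond a
single CV, BLQ censoring mechanics, infection or renal-impairment effects
on clearance, and inter-occasion variability. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under the
stated noise model, not field performance on real studies.

## Numerical choices and reference study sizes

* Steady-state convergence and analytic/simulated agreement: $10^{-6}$
  relative; crossing refinement $10^{-9}$ h; degenerate-absorption switch
  at relative $10^{-9}$.
* The canonical parameter-recovery design uses 9 timepoints at 0.05, 0.1,
  0.2, 0.4, 0.75, 1.5, 3.25, 6 and 9 h with 6 mice each: tobramycin
  absorbs fast ($t_{max} \approx 0.19$ h), so the absorption phase must be
  sampled below 0.5 h for $k_a$ to be identified — as any competent study
  design would. At 20% CV, median relative errors over 100 seeds are
  ~2% ($V$), ~11% ($k_a$) and ~4% ($k_{el}$).
* Reference simulation sizes used by the test suite: 100 seeds for
  parameter recovery, 200 seeds for filter operating characteristics,
  20 replicates for the AIC selection check, 10 000 draws for the
  noise-calibration check.

## Known limitations

* Tukey fences on groups of six have a breakdown point of one outlier:
  when two large outliers land in the same timepoint group they inflate
  $Q_3$ enough to mask each other, so heavy clustered contamination
  (~9% with ×10 spikes) is only partially removed (~65% of injected
  points; false exclusions stay below 5%). Larger groups or iterated
  filtering would help but are outside the single-pass design.
* Reproduction of the published %fT>MIC table from the printed parameters
  is limited by their 2–3 significant digits: 30 of 32 murine cells agree
  within 1.6 percentage points, but the cefiderocol plasma row — the most
  sensitive to the rounding of $k_{el} = 0.74$ — deviates by up to ~5.5
  points mid-grid.
* The murine model is deliberately one-compartment naive-pooled; no
  mixed-effects, multi-compartment murine, or mechanistic lung models.
* Human reference exposures (Table rows, tobramycin fCmax/fAUC, the 0.69
  ELF/plasma AUC ratio) are literature fixtures loaded from
  configuration, never recomputed: the underlying human datasets are not
  public.
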