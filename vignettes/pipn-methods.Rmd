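---
title: "Methods: disproportionality, up-down thresholds, and fiber morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, up-down thresholds, and fiber morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipntools)
```

pipntools quantifies paclitaxel-induced peripheral neuropathy (PIPN) along
two complementary routes: a pharmacovigilance route that asks whether
concomitant exposure to an α1-adrenergic receptor antagonist is associated
with fewer PIPN reports in a spontaneous-report database, and a preclinical
route that quantifies mechanical allodynia (von Frey withdrawal thresholds)
and sciatic-nerve histopathology (fiber morphometry). Everything is driven
by synthetic data with known ground truth, so each estimator can be held to
account against the quantity it claims to estimate.

## 1. Case/non-case disproportionality

### Model

Within the stratum of reports that list the target drug (paclitaxel), each
report is classified by exposure (does its drug list intersect the
concomitant drug group?) and case status (does its event list intersect the
case definition — for PIPN, the three preferred terms *peripheral
neuropathy*, *peripheral sensory neuropathy*, *peripheral sensorimotor
neuropathy*, matched exactly after normalization). This yields the 2×2
table $(n_{11}, n_{12}, n_{21}, n_{22})$ — exposed cases, exposed
non-cases, unexposed cases, unexposed non-cases — and the reporting odds
ratio

$$\mathrm{ROR} = \frac{n_{11}/n_{21}}{n_{12}/n_{22}}
             = \frac{n_{11}\,n_{22}}{n_{12}\,n_{21}},$$

with the Woolf (log-normal) confidence interval

$$\exp\!\left[\ln \mathrm{ROR} \pm z\sqrt{\tfrac{1}{n_{11}} +
\tfrac{1}{n_{12}} + \tfrac{1}{n_{21}} + \tfrac{1}{n_{22}}}\right],
\qquad z = 1.96.$$

The natural logarithm is used throughout. An ROR below 1 means the event is
reported relatively less often among exposed reports — under the usual
(strong) assumptions of non-differential reporting, a protective signal.

Association is tested with the 1-df Pearson chi-squared closed form
$N(|ad-bc|)^2/(r_1 r_2 c_1 c_2)$, applying the Yates continuity correction
($|ad-bc|$ reduced by $N/2$, floored at zero) when any **observed** cell is
below 5. That observed-cell trigger is the package default because it is
the literal reading of the rule "a correction when the number of cases for
each item is less than 5"; the textbook expected-cell trigger, plus
`"always"`/`"never"`, are available through the `yates` argument since the
intended rule is ambiguous.

### Numerical and degenerate-input policy

* **Zero cells.** The ROR and its CI are undefined when any cell is zero.
  The default is an explicit error — counts are never silently altered. The
  Haldane–Anscombe correction (+0.5 to all four cells) is opt-in
  (`haldane = TRUE`) and flagged in every output row that used it.
* **Zero margins.** A zero row or column margin makes the chi-squared test
  vacuous: the package returns $\chi^2 = 0$, $p = 1$ with a `degenerate`
  flag rather than `NaN`.
* **Rounding.** Presentation rounding (reporting-rate percentages, printed
  ROR/CI) is half-away-from-zero at 2 decimals, matching how published
  tables are rounded; all internal comparisons run at full precision.
* **Pooled classes.** The "any α1 antagonist" exposure is just a drug
  group with more members (default: tamsulosin, doxazosin, alfuzosin,
  silodosin, terazosin, prazosin, urapidil, naftopidil — a package default,
  fully configurable, since no canonical enumeration of the class exists).
  "Concomitant use" means the drug appears anywhere in the same report;
  there is no therapy-date overlap logic.

### Count inversion

Published disproportionality tables often print only the rounded ROR and
CI plus the stratum margins; the underlying cells appear, if at all, in a
figure. `invert_counts()` enumerates every integer table consistent with
the printed values: for each exposed-case count $n_{11}$ it inverts the ROR
formula to bracket the feasible $n_{12}$ (the ROR is monotone decreasing in
$n_{12}$ at fixed $n_{11}$), then keeps the tables whose exact ROR and CI
round back to the printed triple. The search is linear in the case margin.
Ambiguity — several matching tables — is a property of the printed
precision, and is reported, not suppressed.

```{r invert}
t <- contingency_table(8, 492, 3260, 67591)
invert_counts(round_half_up(ror(t), 2), round_half_up(unname(ror_ci(t)), 2),
              total_reports = 71351, total_cases = 3268)
```

## 2. The synthetic report universe

`generate_reports()` draws, per report: target-drug membership
(`p_target_drug`), concomitant-drug membership (`p_exposed_given_target`),
and case status with probability derived **on the odds scale**: baseline
odds $p_0/(1-p_0)$ multiplied by `exposure_odds_multiplier` for exposed
reports. Generating on the odds scale (rather than multiplying risks) makes
the multiplier exactly the estimand of the ROR, so parameter recovery is a
clean test. Decoy drugs (~1–2 per report, guaranteeing a non-empty drug
list) and decoy events (~1 per report) are attached independently of case
status — no confounding by construction. The generator returns its realized
cell bookkeeping alongside the tables, and `simulate_contingency()` is a
cells-only fast path sharing the same RNG stream (the equality of the two
routes, and of both with `build_contingency()` on the full tables, is
asserted in the test suite).

Default parameters: `baseline_event_prob = 0.0458` matches the observed
PIPN reporting rate among paclitaxel reports (4.58%). `p_target_drug = 0.3`
and `p_exposed_given_target = 0.2` are a deliberate desk-scale choice: in
the real database the target fraction is ~0.5% of ~14 million reports, and
reproducing that geometry at 20,000 reports would leave ~5 cases and
undefined intervals. Inflating the target fraction keeps every Monte-Carlo
experiment informative (expected exposed-case cell ≈ 55 at $n = 20{,}000$)
while preserving the quantity under study — the odds ratio — exactly. These
values were fixed once, before the calibration experiments, and are not
tuning knobs.

What the generator does **not** emulate: stimulated reporting, duplicate
case versions, missing drug fields, confounding by indication (an optional
hook exists but defaults off). Passing calibration on this generator
therefore shows the estimator chain is correct, not that real FAERS signals
are unbiased.

At these defaults, the 95% Woolf CI excludes a true null odds ratio in
close to 5% of replicates (1,000 replicates at $n = 20{,}000$ in the
acceptance suite), and the median point ROR over 100 replicates at
$n = 100{,}000$ recovers multipliers 0.2–2.0 within 10%.

## 3. Von Frey up-down thresholds

### Estimator

The up-down (Dixon staircase) procedure applies filaments from an
ascending series, stepping down after a withdrawal response and up after
none. The 50% withdrawal threshold is estimated as

$$T = 10^{\,X_f + k\,\delta}$$

where $X_f$ is the log10 force of the final trial, $\delta$ the series'
mean log10 spacing, and $k$ a tabulated offset indexed by the terminal
response pattern. The stopping rule collects 4 trials after the first
response reversal, capped at 9 trials (both configurable); trials recorded
after the rule fires are ignored with a warning, so over-long recording
sheets do not shift estimates.

**The k table.** The shipped default is the symmetric midpoint convention:
$k = +0.5$ when the final response was negative (the staircase was about to
step up), $-0.5$ when positive — i.e. the threshold is placed half a step
beyond the last filament in the direction the staircase was heading.
Lookup is by longest matching suffix of the session's X/O response string,
so supplying a fuller table of pattern-specific offsets (e.g. Dixon's
published maximum-likelihood values) overrides the default wherever a
longer pattern matches, without code changes. The default was chosen over
hard-coding a reproduction of Dixon's table because an unverifiable copy of
a lookup table is worse than a simple documented convention; with a steep
psychometric function the two agree to within half a filament step, which
is the resolution of the method anyway.

**Censoring.** A session whose responses are all positive (even the weakest
filament elicits withdrawal) or all negative is floor-/ceiling-censored:
the boundary filament force is reported with an explicit flag, rather than
$\pm\infty$, so group means remain computable. This matches common practice
for cutoff designs; analyses can exclude or sensitivity-test censored
sessions via the flag.

### Simulator

`generate_updown_session()` draws responses from a logistic psychometric
function on the log10-force scale centered at the true threshold, starts at
the middle filament (the standard convention; no protocol statement exists
to the contrary), and walks the staircase under the same stopping rule. At
steep slope the staircase locks onto the two filaments bracketing the
threshold, and the mean estimate over 500 sessions sits within one filament
spacing of the truth (asserted in the acceptance suite); the estimator's
resolution is set by the series spacing, not by sample size.

The default filament series (0.4–26 g, nine filaments, near-uniform log
spacing) is a package convention for rat testing — configurable, and not a
claim about any particular study's hardware.

### Group comparison

`tukey_kramer()` computes one-way ANOVA plus all-pairs studentized-range
tests with the Tukey–Kramer unequal-$n$ standard error
$\sqrt{(MSE/2)(1/n_i + 1/n_j)}$ and p-values from `ptukey`. It agrees with
`stats::TukeyHSD` to 8 decimals in the test suite (the base implementation
serves as the oracle, not the implementation). ANOVA significance does not
gate the pairwise tests; gating is a user decision.

## 4. Fiber morphometry

### Indices

For each myelinated fiber — an axon polygon nested in a fiber (outer
myelin) polygon, coordinates in µm:

* **Circularity** $= 4\pi A / P^2$ (shoelace area, exact vertex-path
  perimeter), computed on the **axon** contour by default, since the index
  targets axonal damage; `circularity_on = "fiber"` is available because
  the choice of contour is a genuine open point.
* **g-ratio** $= d_\mathrm{axon}/d_\mathrm{fiber}$ with $d = 2\sqrt{A/\pi}$
  the equivalent-circle diameter — an area-based estimator, robust to
  boundary noise compared with caliper diameters.
* **Myelin thickness** $= (d_\mathrm{fiber} - d_\mathrm{axon})/2$ in µm.

Polygon mode is the exact reference pathway. Mask mode
(`measure_from_labelmask()`, axon label $2k$ / myelin label $2k+1$ per
fiber $k$) traces each region's boundary to an ordered pixel-center
contour and then applies the same polygon measurements. Raw pixel-edge
paths overestimate smooth perimeters by ~7% (the staircase effect), which
alone would push a perfect circle's circularity down to ~0.89; the
contour is therefore smoothed with a periodic 5-point moving average
before measurement. Measured accuracy: a rasterized r = 50 px circle is
within 0.4% of circularity 1, and polygon-vs-mask agreement is under 1%
for axon diameters ≥ 20 px (the tests enforce 2% and 3% bounds).

### Synthetic nerves

`generate_nerve_cross_section()` places non-overlapping fibers (rejection
sampling with a bounded attempt budget — an impossible density yields a
warned shortfall, never a hang). Fiber diameters are lognormal (mean 8 µm,
SD 2 µm — typical of rat sciatic myelinated fibers); healthy g-ratios are
normal (0.6 ± 0.05) truncated to (0, 1), near the canonical optimum.
`degeneration_level` $\in [0,1]$ does two things: adds smooth low-order
Fourier radial irregularity to the boundaries (full amplitude on the axon,
half on the fiber outline; amplitude 0.25 × level on the radius) and thins
myelin by moving each g-ratio a fraction $0.6 \times$ level of the way
toward 1. At level 0 every boundary is a regular 64-gon, whose circularity
$(\pi/64)/\tan(\pi/64) \approx 0.9992$ bounds the discretization error.
Degeneration therefore lowers circularity and myelin thickness and raises
the g-ratio — the qualitative signature of paclitaxel neurotoxicity that
the end-to-end acceptance test checks (direction only; no claim of
magnitude against real histology, whose values were never printed
numerically).

## 5. Pipeline, determinism, problem sizes

`run_pipeline()` executes any combination of the three arms from a single
validated YAML/list config (exactly one of `inputs` or `generator` per
arm; a seed is mandatory whenever anything is generated), writes one CSV
per product plus a manifest (config echo, package version, seed, row
counts, MD5 digests — no timestamps), and is byte-reproducible: identical
config + seed gives identical file digests. A failing arm is recorded in
the manifest and does not abort the others.

Every generator is a pure function of (params, seed) via an isolated RNG
scope, so library loading order and prior RNG state are irrelevant.

Problem sizes used by the shipped analyses and checks — chosen as the
smallest sizes at which each property is sharply testable: 1,000 replicates
of $n = 20{,}000$ for CI calibration; 100 replicates of $n = 100{,}000$ per
multiplier for recovery; 100 forward-generated tables on the 71,351/3,268
margins for count inversion; 500 sessions for up-down consistency; 100
fibers per nerve for the morphometry contrast; 1,000 random tables and
polygons for the formula/isoperimetric oracles.

## 6. Known limitations

* Exact term matching only: no MedDRA hierarchy, no fuzzy matching; a
  misspelled preferred term is not a case.
* No FAERS case-version deduplication; report counts are taken at face
  value.
* The ROR is a reporting association, not a causal or incidence estimate;
  the synthetic universe's no-confounding default makes calibration tests
  clean but optimistic relative to real spontaneous-report data.
* The up-down estimator's resolution is one filament step; the default k
  convention differs from Dixon's pattern-specific maximum-likelihood
  offsets by up to half a step for some terminal patterns.
* Mask-mode accuracy degrades below ~20 px axon diameter; polygon mode is
  the reference where geometry is available.
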