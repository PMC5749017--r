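---
title: "Ascertaining exclusive breastfeeding from primary-care EMR notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertaining exclusive breastfeeding from primary-care EMR notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebfemr)
```

## The problem

Population surveys of infant feeding rely on maternal recall and voluntary
response. Primary-care electronic medical records (EMRs) offer an
alternative: family physicians see infants repeatedly through the first year
(typically shortly after birth and near 2, 4 and 6 months, anchored to the
immunization schedule) and document feeding at each well-baby visit, often
on a standardized form (in Canada, the Rourke Baby Record). `ebfemr`
implements the full chain needed to turn such a chart corpus into
epidemiological estimates of exclusive breastfeeding (EBF):

1. a **synthetic EMR generator** with known ground truth, standing in for
   chart data that can never be public;
2. a **rule-based search algorithm** that detects Rourke Baby Records and
   classifies per-visit feeding status from note text and structured
   fields;
3. **longitudinal inference** of EBF status at 60, 122 and 182 days of age,
   including backward inference from future visits;
4. the **epidemiological statistics**: rates, rate ratios with confidence
   intervals, standardized differences and Cohen's kappa.

Because real well-baby charts are governed data, the package's tests run
the pipeline against its own generator, whose latent trajectories provide
an exact oracle, and against the published summary tables bundled as
plain-text fixtures.

## The synthetic cohort generator

### Registry

`generate_birth_registry()` draws term singleton infants with independent
covariates at configurable marginal frequencies
(`default_registry_marginals()`): maternal age \(\sim N(30.2, 5.3^2)\)
years, 75.6% urban, 12.4% immigrant mothers (world region drawn jointly),
near-uniform income quintiles with a 0.4% unknown fraction, birthweight
\(\sim N(3490, 464^2)\) g, gestational age truncated at \(\ge 37\)
completed weeks, 51.4% male, and 77.2% of births in the 2008–2013 band
(EMR uptake grew over the study window, so later birth years dominate).
Preterm and multiple births are not modelled — the emulated design excludes
them — but the eligibility filter still enforces both rules, so hand-built
records exercise the exclusion paths in tests.

### Feeding trajectories

Each infant carries a latent trajectory: the age `ebf_end_age` at which
exclusive breastfeeding ends (0 = exclusively formula-fed from birth,
point mass `p_never_ebf` = 0.145), followed by an exponential tail of
mixed feeding (mean 60 days) before full weaning. Discontinuation times
come from a piecewise-constant hazard on the intervals (0, 60], (60, 122],
(122, 182] and (182, 750] days, solved in closed form so that at reference
covariates

\[
P(\text{ebf\_end} > t) = S^*(t), \qquad
S^*(60) = 0.395,\; S^*(122) = 0.324,\; S^*(182) = 0.251 .
\]

These are the package's calibration targets (configurable in
`sim_config()`); the tail hazard continues the last solved rate. This is
the simplest model that reproduces three marginal survival probabilities
exactly, and sampling is by inversion of the cumulative hazard, so a
degenerate all-zero hazard cleanly yields end ages beyond the 750-day
record limit.

Covariates act as multiplicative hazard ratios
(`default_covariate_effects()`, log scale: younger, rural, lower-income
mothers wean earlier; immigrant status near-neutral; earlier birth years
wean earlier). Two choices matter here:

* **Effects are modest** (|log HR| \(\le\) 0.24). Per-infant hazard ratios
  are normalized by the analytic population mean implied by the configured
  marginals, so the population-average survival stays within a fraction of
  a percentage point of the reference targets (the residual is a Jensen
  term of order \(S (\ln S)^2 \mathrm{Var}(H)/2\), below half a binomial
  SE at \(n = 8000\)). Exact published rate ratios are *not* a generator
  target — only the qualitative gradients.
* **Reference covariates** mean `covariate_effects = NULL`; the
  calibration property is stated and tested there.

### Notes

`render_visit_corpus()` draws visits at target ages {7, 60, 122, 182} days
(attendance probability 0.9, Gaussian jitter SD 7 days truncated at 0 —
the emulated design says nothing about visit timing beyond the
immunization anchors, so these are the package's own realistic defaults)
and renders one note per visit. With probability 0.80 an infant's chart
carries a Rourke form name (one of the configured variants, case
randomized); Rourke notes record feeding in a structured field half the
time and as free text otherwise. With probability 0.118 an infant's notes
carry no feeding terms at all. Feeding sentences are consistent with
ground truth at the visit age, in current tense, or — for weaned infants,
with probability 0.5 — as a past-tense statement of the true EBF duration
("was exclusively breastfed until 4 months, now on formula"; months
granularity above 60 days, exact days below).

What the generator deliberately does **not** emulate: misspelled or
ambiguous clinical language beyond the lexicon's reach, conflicting
statements within one note, French text, scanned attachments, or the
selection process that determines which practices contribute charts.
Passing closure tests therefore shows the *pipeline logic* is exact on
lexicon-complete text; it does not bound the extraction error on real
charts, which the original study addressed with manual abstraction and
inter-rater kappa.

## The search algorithm

`detect_rourke_record()` does case-folded, whitespace-normalized,
word-boundary-anchored matching of the form-name variants; the earliest
match wins. `classify_feeding()` applies a fixed decision order:

1. a structured Rourke feeding field, when present, overrides the text;
2. breast term + formula term (or a mixed marker) → MIXED;
3. breast term + exclusivity marker, no formula term → EBF;
4. breast term alone → EBF;
5. formula term alone → FORMULA;
6. nothing → NONE_DOCUMENTED.

Rule 4 is a genuine design decision: the three-way scheme has no
"breast, non-exclusive" bucket, and an unqualified "breastfeeding" in a
well-baby note most often describes the sole feeding mode. It is
overridable by editing the lexicon. A mixed marker that itself names both
modes ("breast and formula", "mixed") is accepted alone; bare
co-occurrence markers ("both", "supplementing") need a feeding term in
the note — without this, "feeding both breast and formula" (no bare
breast *term*) would be unclassifiable.

Negation ("no", "not", "stopped", "weaned", "discontinued") within three
tokens before a term cancels it; the scope breaks at sentence punctuation
so "no formula, breast milk only" keeps its breast term. Past-tense
duration patterns are extracted first and blanked before current-status
classification, so one note can yield a current FORMULA observation plus
a historical EBF observation with a parsed duration (months × 30.44 days,
rounded half away from zero). The shipped lexicon is a reconstruction and
is user-overridable YAML; nothing downstream depends on its exact
contents.

## Timepoint inference

Eligibility (`build_cohort()`): singleton, term (\(\ge 37\) weeks — the
design says "term" without a threshold; 37 completed weeks is the
standard definition), at least one visit before 190 days; observations
beyond 750 days dropped.

For each target age \(t \in \{60, 122, 182\}\) the **index visit** is the
visit closest to but not preceding \(t\). Within a carry-forward window
(62/60/568 days — the gap to the next target, unbounded for the last) the
index visit's current status decides EBF vs NOT_EBF. Beyond the window,
only three things are informative: current EBF at the index visit
(breastfeeding is still exclusive later, so it was exclusive at \(t\)); a
past-tense statement whose stated duration covers \(t\); or a past-tense
statement whose duration ends *before* \(t\) (the infant had already
stopped — this yields NOT_EBF and is needed for internal consistency of
the rule set). Anything else is UNDETERMINED. EBF at a later target
propagates to all earlier targets. Notes with no feeding terms still
count as visits (they anchor denominators) but carry no status.

Rates are computed among infants with a qualifying visit *and* a
determined status; UNDETERMINED infants leave both numerator and
denominator, matching the published convention of rates "among infants
with documented feeding status". The complete-case subset keeps infants
determined directly from an index visit at all three targets.

One subtlety is worth stating because it shapes the tests: the index-visit
rule measures survival at the *visit* age, which sits a few days past the
target under jittered schedules. With the default 7-day jitter this
depresses measured rates by roughly one percentage point relative to the
latent survival at the target itself — a feature of the design being
modelled, not an estimator bug. The parameter-recovery test therefore uses
on-schedule (jitter-free) visits, where the index visit falls exactly on
the target and recovery is exact up to binomial noise.

## Statistics

* **Rate ratio CI**: Katz log-transform normal approximation,
  \(\exp\!\big(\ln \mathrm{RR} \pm z \sqrt{(1-p_1)/(n_1 p_1) +
  (1-p_0)/(n_0 p_0)}\big)\). The emulated study names no method; this
  standard choice reproduces every published CI bound within ±0.012 when
  fed the printed rates and denominators (numerators recovered as
  `round(n * rate / 100)`).
* **Standardized difference**: pooled-variance form for both binary and
  continuous characteristics.
* **Cohen's kappa**: \((p_o - p_e)/(1 - p_e)\) with marginal expected
  agreement; degenerate marginals (\(p_e = 1\)) error rather than return
  0/0.
* **Referent convention**: the published tables fix referents (Q1, rural,
  age < 20, ...) that are mostly but not provably always the lowest-rate
  level, while the stated rule is "lowest rate". Both are supported
  (`referent = "fixed"` / `"lowest"`); fixed is the default because it
  reproduces the published table layout deterministically.
* Display rounding is half-away-from-zero (rates 1 dp, ratios 2 dp,
  standardized differences 1 dp); all computation is done unrounded.

## Numerical and degenerate-input choices

* All ages are integer day offsets from birth; calendar dates exist only
  at the I/O boundary (`registry.csv`, `notes.jsonl`).
* Randomness is governed by one seed; the three generator stages use
  `seed`, `seed + 1`, `seed + 2` so stages can be re-run independently yet
  the whole corpus is byte-reproducible.
* Zero denominators, zero referent rates, empty label vectors and
  schema mismatches raise classed errors (`ebf_config_error`,
  `ebf_data_error`, `ebf_io_error`); a zero numerator flags the CI
  non-computable instead of fabricating a bound.
* An empty *referent* stratum (possible in small simulations) yields an
  all-NA ratio column rather than an error; empty non-referent strata are
  emitted with \(n = 0\).

## Problem sizes

The bundled test suite runs the full pipeline at a few hundred infants per
case, closure checks at 1000, calibration at 8000 draws, and marginal
checks at the full cohort size of 8815; `scripts/acceptance.R` runs the
complete simulate–extract–analyze chain at 8815 infants twice (for the
determinism check). These sizes were chosen so every statistical tolerance
is a 3-binomial-SE bound at the stated n.

## Known limitations

* The lexicon is a reconstruction; real chart language will defeat it in
  ways the generator cannot measure.
* Backward inference is implemented for exclusive breastfeeding only;
  whether MIXED/FORMULA statements should propagate backwards is left
  undone deliberately (the emulated design describes only EBF inference).
* No imputation of missing feeding status, no regression modelling, no
  survey weighting, no age standardization.
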