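---
title: "Methods: time-standard indicator scoring and blocked comparison of indicator performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-standard indicator scoring and blocked comparison of indicator performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micqi)
```

## The measurement model

Regional medical command and control at a declared major incident is
expected to take eleven strategic decisions, each within a stipulated number
of minutes from alert. The rubric scores each indicator on an ordinal
three-point scale: 2 when the decision is documented within its time
standard, 1 when documented late, 0 when never documented. The unit of
observation is one incident's coded decision log; the unit of analysis is
the incident-by-indicator score.

Three modelling assumptions follow from this design:

* **Documentation is the measurement.** A decision that was taken but never
  written down scores 0; the rubric cannot distinguish "not done" from "not
  recorded". This is a property of the instrument, not a defect of the
  implementation.
* **Applicability is a property of the incident, not of single
  indicators.** The set is applied as a whole to incidents that directly or
  indirectly involve casualties (accidents, threats, fires, CBRNE events);
  incidents with other characteristics and time frames
  (hospital-infrastructure interference, infectious events, weather alerts,
  inter-regional support, incidents abroad) are filtered out rather than
  scored partially. A per-record override flag can reverse the category rule
  in either direction, because recorded cohorts may classify borderline
  incidents differently than their category label suggests.
* **Exclusion, not imputation.** An incident in which any decision is
  documented without a usable timestamp is unevaluable on that indicator
  and is excluded from the score matrix, mirroring how under-documented
  incidents are dropped from the original evaluation. The alternative
  `lenient_timeless = TRUE` scores such decisions 1 (met, timing unknown);
  it is off by default since imputing partial credit changes the estimand.

### Boundary convention

"Within *x* minutes" is read inclusively: elapsed time exactly equal to the
standard scores 2. The published rule does not state the tie-break; the
inclusive reading is the plain-language one and is fixed as a package
convention, tested at the boundary (`x` scores 2, `x + ε` scores 1).
Elapsed times are stored to 1-second resolution and compared in minutes as
reals, so minute-granular logs are represented exactly without forcing
rounding on finer-grained sources. Alert and event datetimes are normalized
to UTC on parsing to avoid daylight-saving artifacts; event times may be
given absolutely or as minutes from alert, with identical results.

## Comparing indicators: blocked ANOVA and Tukey HSD

Scores from a complete cohort form an *n* × 11 matrix with one observation
per cell. Indicator performance is compared by a two-way additive analysis
of variance treating incidents as blocks and indicators as treatments:

$$ y_{ij} = \mu + \beta_i + \tau_j + \varepsilon_{ij}, \qquad
   SS_{total} = SS_{treat} + SS_{block} + SS_{error}, $$

with degrees of freedom $a-1$, $b-1$ and $(a-1)(b-1)$. There is no
replication within cells, hence no interaction term; the error stratum is
the block-by-treatment residual. Scores are ordinal, yet they are analyzed
on the interval scale by parametric ANOVA — this follows the original
analysis deliberately (no rank transform is offered), and the tests verify
the arithmetic, not the appropriateness of normal theory for ordinal data.

Pairwise comparisons use Tukey's honestly-significant difference. With
equal replication ($b$ blocks per indicator),

$$ HSD = q_{1-\alpha;\,a,\,(a-1)(b-1)} \sqrt{MS_{error}/b}, $$

and a pair differs significantly iff its absolute mean difference exceeds
this single constant. Adjusted p-values are computed from the studentized
range distribution of $|\bar y_i - \bar y_j| / \sqrt{MS_{error}/b}$, so
"p < 0.05" statements are testable quantities rather than binary flags.
The quantile and CDF delegate to `stats::qtukey`/`stats::ptukey`; at very
small error degrees of freedom these routines are accurate to roughly three
significant figures, which bounds the precision claimed anywhere a quantile
is compared against its closed form (for $k = 2$,
$q = \sqrt{2}\,t_{1-\alpha/2}$, and the Tukey decision coincides with the
paired t-test — a property the suite checks).

The compact line display sorts indicator means ascending and draws one line
under every maximal contiguous run whose range is at most HSD. Under equal
replication this construction is exactly equivalent to the pairwise rule —
two indicators share a line iff they do not differ significantly — because
the threshold is one constant; it would not be valid for unbalanced
designs, which are out of scope.

### Numerical choices and degenerate inputs

* $SS_{error}$ is obtained by subtraction; a value below
  $10^{-10} \cdot SS_{total}$ is clamped to zero so that perfectly additive
  matrices (cell = block effect + treatment effect) are recognized exactly
  despite floating-point cancellation.
* Zero error variance is handled as the continuity limit: F and p are
  reported as exact limits and every nonzero difference is flagged
  significant, each with a warning.
* Matrices need at least 2 blocks and 2 treatments; anything smaller is an
  error, as is any unevaluable cell.
* Ties in means are harmless to the grouping: sorting is stable and the
  run construction depends only on differences.

## What the synthetic generator emulates

The cohorts the original analysis used are not publicly deposited, so the
package generates synthetic cohorts with the published structure. The
generator is first-class, tested code, and its defaults are the study
conditions; they are not tuning knobs.

* **Score distributions.** Each indicator draws its score from a {0, 1, 2}
  distribution obtained by inverting the target mean: given target mean
  $m$ and late share $\lambda$ (the fraction of met objectives that were
  met late), $p_{met} = m/(2-\lambda)$, $p_1 = \lambda p_{met}$,
  $p_2 = (1-\lambda) p_{met}$. The expected score is exactly $m$, so
  empirical cohort means converge to their targets at rate $1/\sqrt{n}$
  with no bias. The default $\lambda = 0.3$ is a package choice: published
  aggregate counts constrain the met/not-met split but not the 1-vs-2 split
  per indicator.
* **Latencies.** A score-2 decision gets a latency uniform on
  (0, standard); a score-1 decision gets $standard \times (1 + E)$,
  $E \sim \mathrm{Exp}(1)$ bounded away from zero. Neither law can cross
  the standard boundary, so rescoring a generated record recovers the drawn
  score exactly — the round-trip property the suite and acceptance checks
  rely on. The laws themselves are package choices; no latency
  distributions are published.
* **Case-flow replica preset** (`flow_replica_preset()`): exactly 130 records
  with the published 9-category mix (48/37/23/15/2/2/1/1/1). The published
  stage counts are internally inconsistent with the category table (the
  casualty categories sum to 110, not 102; the listed non-applicable
  incidents to 20, not 28), so the replica does not invent a reassignment:
  28 records carry explicit not-applicable override flags (the 20
  non-casualty records plus 8 casualty-category ones) and 36 applicable
  records are forced under-documented via one timeless decision event. The
  flow 130/28/102/36/66 is therefore exact by construction, at any seed.
* **Calibration preset** (`calibration_preset()`): 66 complete incidents in the
  four casualty categories, indicator means set to the published values
  (1.48, 1.41, 1.32, 1.63, 1.53, 0.86, 0.75, 0.18, 0.93, 0.03, 0.97).
* **Durations.** Activation time is log-normal with median 60 min and
  `sdlog = log(4)/qnorm(0.75) ≈ 2.06`, the unique log-normal matching both
  published duration summaries (median 60 min; 75% of incidents at or
  under 4 h). The 4-h cutoff is inclusive (240 min).
* **Ancillary fields.** Staffing extent is multinomial in the published
  proportions (50/36/34/10 of 130); casualty counts, receiving-hospital
  counts and hospital-plan flags are drawn with published aggregate rates.
  These feed the descriptive summary only and carry no calibration claim
  beyond their rates.

Reproducibility: one global seed yields per-record substreams drawn up
front, so a record's content is a deterministic function of the seed and
its index.

What the generator does **not** emulate: inter-indicator correlation within
an incident beyond the shared block effect (scores are drawn independently
given the incident), report-delay mechanisms between scene and region, any
causal structure between decisions, and seasonal or secular trends. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline's
arithmetic, filters and inference are correct under the published marginal
structure — not that real logs satisfy that structure.

## Reporting conventions

Percentages in reports are rounded half-up to integer percent, which
reproduces the published renderings 102/130 → 78% and 446/726 → 61%. The
complement 280/726 = 38.6% renders as 39% under this rule although it was
originally printed as 38%; the package recomputes every percentage from the
numerator and denominator in the same report and does not special-case that
value. Reports are written as CSV/JSON plus a plain-text underlining
display; re-running a pipeline with the same inputs and seed reproduces
them byte-identically.

## Problem sizes

The test suite and acceptance script run the analysis at its natural scale:
66 × 11 score matrices, a 130-record replica cohort, and 200 replicate
calibration cohorts for parameter recovery (13 200 incident scores per
indicator), with Monte-Carlo acceptance bands of 3 standard errors for the
designated indicators and 4 standard errors when all 11 indicators are
checked simultaneously (a per-indicator 3-SE band would false-alarm on
roughly 3% of seed sets even for an unbiased generator). Oracle checks for
the ANOVA run on random 2–8 treatment × 2–12 block matrices against an
explicit mean-based brute-force decomposition at relative tolerance 1e-9.

## Known limitations

* The ordinal-as-interval ANOVA is inherited by design; no nonparametric
  alternative is provided.
* Only balanced, complete matrices are supported — no missing cells, no
  mixed models.
* The applicability rule is category-based with per-record overrides;
  free-text incident narratives are out of scope, as is re-deriving
  categories from text.
* The rubric can be replaced from a JSON config (same schema, 11 items),
  e.g. for modified indicator sets for hospital-infrastructure incidents,
  but no such alternative set ships with the package.
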