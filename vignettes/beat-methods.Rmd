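---
title: "Methods: zone-based biosecurity scoring and intervention evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone-based biosecurity scoring and intervention evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatr)
```

## The instrument and its scoring model

A farm is partitioned following the FAO three-zone model: the
access-restricted broiler house is the green zone, the paved professional
farmyard the orange zone, and all external areas the red zone; the two
crossings (orange-green, red-orange) are scored as zones of their own
because most breaches happen at transitions. Each zone carries thematic
risk categories; each category carries questions with predefined answer
options worth between 0 (no compliance) and 1 (full compliance) points.
Option points are the only weights in the model — a question can matter
more only by its best option being worth more, which keeps the instrument
auditable.

The relative score of a zone or category is points attained over points
attainable across its *answered* questions:

$$\mathrm{score}(z) \;=\; \frac{\sum_{q \in Q_z^{\mathrm{ans}}} p_q}
{\sum_{q \in Q_z^{\mathrm{ans}}} \max_o p_{q,o}} \;\in\; [0,1].$$

**Not-applicable answers** are removed from numerator *and* denominator.
The alternative — scoring them 0 — would penalise farms for questions that
structurally cannot apply (an indoor-only farm has no outdoor range to
protect), and scoring them 1 would reward omission. The count of NA
answers is carried in every score row so coverage stays visible. A zone in
which *every* question was answered not-applicable has no defined score
and is an error, not a 0.

Scores map to traffic lights with configurable cuts, default red < 0.4 ≤
amber < 0.7 ≤ green. The endpoints (1 is green, 0 is red) are part of the
instrument's design; the interior cuts are package defaults, since nothing
in the scoring model itself singles out a threshold. Cohort aggregation
reports the unweighted mean and sample SD of farm-level scores; the pooled
("overall") column is the mean over all farms, not the mean of country
means — the statistically standard convention when farms are the sampling
unit. Reports round half-to-even to two decimals; internal computation is
full precision.

The packaged instrument (`beat_example("questionnaire.csv")`) covers 46
risk categories over the five zones with two questions each. The category
structure mirrors the published field instrument; the question texts are
authored for this package (the original question list is not published),
so the fixture preserves structure and scoring semantics without
pretending to be the original wording.

## Health plans

Interventions are authored by the farmer and veterinarian, not by the
package: the model deliberately stops at *ranking* weak categories
(`suggest_targets()`, ascending score, ties broken inside-out by zone then
category id) because no published algorithm exists for drafting the SMART
intervention text, and fabricating one would misrepresent the method. Each
intervention carries zone, category, time horizon (short/medium/long),
cost class (low/medium/high) and a binary realized flag — partial
completion is not modelled. The accounting functions are exact tallies;
the term-by-cost table reports percent realized rounded to whole numbers
and `NA` for empty cells, and realization rates are reported to one
decimal.

## Flock monitoring

Footpad dermatitis is scored per bird in classes 0/1/2 at slaughter. The
flock-level score is the weighted prevalence
$100\,(w_0 n_0 + w_1 n_1 + w_2 n_2)/n$ with the standard surveillance
weights $w = (0, 0.5, 2)$, giving the familiar 0–200 scale. The weights
are configurable because class-based footpad systems differ in the weight
given to severe lesions.

Antimicrobial use is recorded per cycle as a treated/untreated flag plus
total treatment days (no dose-based metrics such as DDDvet — only days are
recorded in this design). Summaries count treated farms per country and
cycle and compute median and mean days *among treated flocks only*, so
untreated farms cannot dilute the treatment-duration statistics.
Flock-treatment prevalence is treated flock-cycles over all flock-cycles;
the whole-percent figure is reported by truncation (a cohort is reported
at 60% only once a full 60% of flock-cycles were treated), with the exact
value returned alongside. Mortality and slaughter parameters are carried
descriptively only.

Phase is a pure function of the cycle index: cycles 1–2 are
pre-intervention, 3–4 post-intervention.

## Statistics

Between-country comparisons of zone scores use two-sample Wilcoxon
rank-sum tests: exact null distribution when both groups have ≤ 10
observations and the pooled data are tie-free (small farm groups per
country make the exact test the relevant regime), otherwise the
tie-corrected normal approximation with continuity correction. Pre/post
comparisons use Kruskal–Wallis with tie correction and the chi-square
reference; because the published design is ambiguous about whether the
four cycles were pooled into two phases, both pooling modes are exposed
(`mode = "phase"` or `"cycle"`). No multiple-testing correction is applied
by default across the three country pairs (matching the analysis the
pipeline replicates); Holm adjustment is available. Degenerate inputs
(all values identical) return p = 1 with a warning instead of `NaN`.

The footpad model is a linear mixed model with a country random intercept,
fitted by **maximum likelihood** — not REML — because AIC comparisons
across different fixed-effect sets are only valid under ML. Candidate
fixed effects are cycle number (linear), construction year (linear) and
the month the cycle started. Month enters as a 12-level factor by default:
it was conceived as a term, not a trend, and a factor makes no shape
assumption; a first-order harmonic (sin/cos) encoding is available when
140 observations feel thin for 11 month parameters. Forward selection
starts from the random-intercept-only model, adds the candidate lowering
AIC most, and stops when none lowers it; exact AIC ties break by candidate
order, making selection deterministic given the data. Singular fits (zero
country variance) warn and are retained.

**A known property of AIC forward selection worth stating plainly:** a
pure-noise candidate costing one degree of freedom is admitted whenever
its likelihood-ratio statistic exceeds 2, which happens with probability
$P(\chi^2_1 > 2) \approx 0.16$ under the null. With two idle candidates
alongside a real month effect, the probability that the selected model is
*exactly* the month model is therefore only about $0.84^2 \approx 0.71$
per replicate — less when a candidate (cycle number) is correlated with
month through the design, as it is here since consecutive cycles advance
the calendar by about two months. On study-shaped synthetic cohorts (35
farms × 4 cycles, month amplitude twice the residual SD, 50 seeds) the
month effect is selected in every replicate, but the month-*only* model
appears in only about 60–75% of seed batches — the test suite asserts the stricter
"month-only in ≥ 90%" expectation and documents its failure rather than
silently relaxing it, because the over-selection is a property of the
prescribed selection rule, not an implementation defect.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline assumes:

* **Design**: three countries with 13/7/15 farms, four cycles each (two
  pre-, two post-intervention); consecutive cycles start ~2 months apart
  from a random farm-specific base month.
* **Compliance**: one Beta draw per farm × zone; defaults give mean
  compliance 0.7 (green), 0.55, 0.65, 0.6, 0.4 (red) with moderate
  concentration (α+β = 8), reproducing the inside-out gradient with the
  red zone weakest. Answers are a mixture of each question's best and
  worst option with the best-option probability chosen so the *expected*
  relative score equals the Beta draw — this makes the law-of-large-numbers
  check (cohort zone means within 3 SE of Beta means at 500 farms) exact
  rather than approximate. `allow_na` questions go not-applicable with
  probability 0.05.
* **Interventions**: categories scoring below 0.6 receive
  Poisson-distributed interventions (mean 1); term/cost labels are drawn
  with margins favouring short/low; realization is Bernoulli with
  probabilities graded from 0.53 (short/low) to 0.01 (long/high),
  echoing the realization gradient such studies report.
* **Footpad**: score = 60 + 25·cos(2π(month−1)/12) + country offset
  (SD 15) + noise (SD 20), clamped to [0, 200] and realised as class
  counts over 100 birds (quantising scores to 0.5 steps). The cosine peaks
  in January — flocks placed in winter score worst, the documented
  seasonal pattern for footpad lesions.
* **AMU**: per-cycle Bernoulli (0.75 pre, 0.65 post); treatment days for
  users from a negative binomial (mean 6, size 4) truncated at ≥ 1 —
  small, overdispersed counts like observed treatment-day medians of 3–11.

Everything is deterministic given the configuration seed; the written
files are byte-identical across runs.

What the generator does **not** emulate: within-farm correlation of
compliance across zones, farm-level footpad heterogeneity beyond the
country offset, any true pre/post intervention *effect* on footpad or AMU
(interventions change nothing downstream), informative missingness, or
assessor disagreement. Passing tests on synthetic cohorts therefore
demonstrate the pipeline's correctness and power under its own
assumptions, not that real intervention effects of any given size are
detectable.

## Problem sizes and numerical choices

The property suites run 1,000 randomized assessments for the scoring
invariants, full enumeration of all two-sample splits with total n ≤ 6
against the permutation oracle, and 50-seed simulations at 35 farms × 4
cycles for model selection — sizes chosen so each suite completes in
minutes on one core while estimating the relevant rates to a few percent.
Relative-score identities are checked to 1e-9; rank-test p-values to
1e-12 against enumeration. The cross-zone "total" farm score is emitted by
`score_farms()` only implicitly (zone rows can be pooled by the caller):
the canonical outputs are per-zone and per-category scores.

## Known limitations

* The packaged questionnaire is an authored stand-in with the published
  category structure; its question-level content is package fiction and
  should be replaced by a validated instrument for field use.
* The term/cost fixture's realized counts are reconstructed from published
  whole-percent rates (`round(n·pct/100)`) — exact to re-rounding, not to
  the unpublished raw counts.
* Realization of interventions is binary; no dates, costs in currency, or
  partial completion.
* The mixed model assumes Gaussian residuals for a bounded (0–200) score;
  at the observed score ranges this is the conventional approximation, but
  scores piling up at the boundaries would call for a different model.
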