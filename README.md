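# beatr — zone-based biosecurity assessment for broiler farms

`beatr` implements a BiosEcurity Assessment Tool (BEAT) for broiler farms
and the evaluation pipeline built around it. The tool follows the FAO
three-zone farm model: the access-restricted broiler house (**green**
zone), the paved professional farmyard (**orange**), the external
surroundings (**red**), and the two transition zones where they meet
(**orange-green**, **red-orange**). Each zone carries risk categories
(thinning, access of transport vehicles, cadaver storage, ...) with
predefined-answer questions scored from 0 (no compliance) to 1 (full
compliance).

The package is for veterinary epidemiologists and herd-health advisors who
want to run the assessment, draft and track farm health plans, and evaluate
an intervention study on flock monitoring data.

## What it computes

**Relative BEAT score.** For zone (or category) *z* with answered questions
*Q_z*,

```
score(z) = Σ_{q ∈ Q_z} points(answer_q)  /  Σ_{q ∈ Q_z} max points(q)
```

Not-applicable answers are excluded from numerator **and** denominator, so
an inapplicable topic (no outdoor range, say) neither rewards nor penalises
a farm. Scores map to traffic lights (default cuts 0.4 / 0.7).

**Health-plan accounting.** Interventions carry zone, category, time
horizon (short/medium/long), cost class (low/medium/high) and a realized
flag; the package tallies zone totals, the term-by-cost cross-tab with
percent realized, and per-country realization rates.

**Flock monitoring.** Per production cycle (four per farm: two
pre-intervention, two post): antimicrobial use as a treated/untreated flag
plus treatment days, footpad dermatitis as class counts (0/1/2) turned into
the 0–200 weighted flock score `100·(0·n0 + 0.5·n1 + 2·n2)/n`, and
mortality.

**Statistics.** Wilcoxon rank-sum tests between countries per zone
(exact for small tie-free samples), Kruskal–Wallis pre/post comparisons,
and a linear mixed model for the flock footpad score with a country random
intercept and AIC-based forward selection over cycle number, start month
and construction year (ML fits, so AICs are comparable).

**Synthetic cohorts.** A generator draws study-shaped cohorts (default
13 + 7 + 15 farms in three countries, four cycles) with per-zone Beta
compliance, graded intervention realization, winter-peaking seasonal
footpad scores and overdispersed treatment days — so the whole pipeline is
testable without farm-level data.

## Worked example

```r
library(beatr)

q   <- load_questionnaire(beat_example("questionnaire.csv"))
coh <- generate_cohort(cohort_config(seed = 42))

report_farm(coh$farms$farm_id[1], q, coh$answers, coh$plans, coh$cycles)
```

```
== Farm report: NL01 ==

Zone scores:
  green          0.44  [amber]
  orange_green   0.50  [amber]
  orange         0.57  [amber]
  red_orange     0.83  [green]
  red            0.30  [red]

Weakest categories (intervention targets):
  g_cd_entree_room             green          0.00
  g_contaminated_feed          green          0.00
  g_dead_bird_removal          green          0.00
  g_thinning                   green          0.00
  og_personnel_visitors        orange_green   0.00

Health plan: 6/28 interventions realized

Monitoring (4 cycles): footpad 64 -> 51 -> 63.5 -> 51.5
```

The zone scores are points attained over points attainable for the
answered questions of each zone; the traffic light applies the 0.4/0.7
cuts; the target list is the farm's lowest-scoring risk categories (ties
broken inside-out by zone); the footpad trajectory is the 0–200 flock
score per cycle. The exact numbers depend on the seed. Cohort-level tables — category × country mean
scores with intervention counts, the term × cost cross-tab, and the
per-cycle antimicrobial summary — come from `report_cohort()`; the
between-country rank tests from `compare_countries()`; the seasonal
footpad model from `forward_select_aic()`.

A thin command-line front end over these functions is installed at
`system.file("scripts", "beat.R", package = "beatr")` with subcommands
`score`, `suggest`, `plan`, `monitor`, `analyze`, `synth`, `report`.

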