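# lymphCODA

Compositional analysis of T- and B-lymphocyte subset hierarchies.

Immunophenotyping panels report every subset as a percentage of its
*parent* gate (naive CD4 cells as a share of CD4 cells, CD4 cells as a
share of T cells, ...), so the raw columns live on incompatible
denominators. lymphCODA is for biostatisticians and immune-ageing
researchers who want to analyse such panels as one system: it encodes
the gating hierarchy as a tree, closes it into a 16-part composition
(percent of total lymphocytes), and applies the machinery of
compositional data analysis end to end.

## What it does

* **Composition tree** — the 21-node, 16-leaf T/B hierarchy with a
  derived "other" child under every internal node; validation (missing
  values, children exceeding 100% of a parent), conversion of
  percent-of-parent panels to closed compositions, and per-part
  detection-limit replacement of exact zeros.
* **Pairwise logratios and stepwise selection** — all
  $\binom{16}{2} = 120$ logratios $L_{ij} = \ln(x_i/x_j)$, the total
  logratio variance $T = \sum_{i<j} w_i w_j \mathrm{Var}\,L_{ij}$, and
  greedy stepwise redundancy analysis: at each step add the logratio
  whose inclusion most increases the fraction of $T$ explained by
  projecting the centred-logratio (CLR) matrix onto the selected
  columns. On generic data the trace closes at exactly 100% after 15
  steps.
* **Conditional-dependence networks** — CLR transform followed by a
  graphical lasso (C++ block coordinate descent) or
  Meinshausen–Bühlmann neighbourhood selection (glmnet), with StARS
  stability selection of the penalty; signed, weighted edges from
  partial correlations.
* **Penalised log-contrast regression** — for outcome $y$, log-parts
  $Z$ and covariates $W$:
  $\min \frac{1}{2n}\lVert y - Z\beta - W\gamma\rVert^2 + \lambda\lVert\beta\rVert_1$
  subject to $\sum_k \beta_k = 0$ (ADMM with an exact equality-constrained
  KKT step), BIC-tuned $\lambda$, case-resampling bootstrap percentile
  intervals, and three covariate-adjustment tiers (none; age + gender;
  + race, education, CMV serostatus).
* **OLS on selected logratios** — classical fits of each outcome on the
  selected logratio basis, with an adjusted-$R^2$ comparison against the
  minimum-norm fit on all 120 logratios.
* **Synthetic cohorts with known truth** — logistic-normal compositions
  with three planted conditional-dependence edges, detection-limit zero
  inflation, survey-like covariates, and outcomes (chronic disease index
  0–8, self-reported health 1–5, deficit-accumulation frailty) generated
  from a sparse sum-to-zero log-contrast model.
* **Pipeline** — `runPipeline()` orchestrates
  simulate/ingest → compose → network → selection → regressions →
  markdown report, with YAML config, seeds and full provenance; a thin
  CLI lives at `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(lymphCODA)

tree   <- lymphocyteTree()
cohort <- simulateCohort(2000, seed = 42)          # known ground truth
kept   <- validateSubjects(cohort@panel, tree)
comp   <- replaceZeros(toComposition(kept$panel, tree))

totalLogratioVariance(comp)
#> [1] 0.5425

trace <- srdaSelect(pairwiseLogratios(comp), targetFraction = 0.90)
head(trace@steps[, c("step", "pair", "additional", "cumulative")], 5)
#>   step           pair additional cumulative
#> 1    1   TCD4CM/LYMPO 0.11063288  0.1106329
#> 2    2      TCD8CM/TO 0.07735550  0.1879884
#> 3    3   TCD4O/BMIgD+ 0.07241815  0.2604065
#> 4    4   TCD4O/TCD8CM 0.07128041  0.3316869
#> 5    5 TCD8TDEM/TCD8O 0.06979695  0.4014839

inferNetwork(comp, method = "glasso", seed = 1)
#> ConditionalNetwork [glasso], penalty 0.1012: 3 edges over 16 nodes
#>   node_i node_j sign      weight
#> 1 TCD4CM  TCD4O    +  0.09156794
#> 2 TCD8CM  TCD8O    +  0.02782219
#> 3 TCD4CM  LYMPO    - -0.21422462

fit <- logContrastRegression(comp, cohort@outcomes$score,
                             cohort@covariates, tier = 3,
                             B = 200, seed = 1)
fit
#> LogContrastFit (tier 3): lambda 0.06067, 5/16 non-zero part coefficients (sum -2.6e-18)
#>   TCD4N   TCD4O  TCD8CM   TCD8O   LYMPO
#> -0.0184  0.0047  0.0119 -0.0094  0.0113
```

The total logratio variance (0.54 squared nats) is the quantity the
stepwise selection explains: its first logratio, other-lymphocytes over
central-memory CD4, alone accounts for 11% of it, and 14 logratios reach
the 90% target on this cohort. The network finds exactly the three
conditional-dependence edges the generator planted (central-memory
compartments tracking their "other" remainder, signs included), and the
BIC-selected log-contrast fit is non-zero on exactly the five parts that
generated the outcome — negative on naive CD4 and other CD8, positive on
other CD4, central-memory CD8 and other lymphocytes, i.e. the planted
immune-ageing pattern.

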