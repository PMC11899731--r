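---
title: "Methods: compositional analysis of lymphocyte subset hierarchies"
author: "lymphCODA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional analysis of lymphocyte subset hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphCODA)
```

## The problem

Flow-cytometry panels of T and B lymphocytes report each subset as a
percentage of its *parent* gate: naive CD4 cells as a share of CD4 cells,
CD4 cells as a share of T cells, T cells as a share of lymphocytes. The
raw columns therefore live on incompatible denominators and cannot be
analysed jointly. lymphCODA closes the panel into a single 16-part
composition (every subset as a share of total lymphocytes) and then
treats it with the standard machinery of compositional data analysis:
pairwise logratios, stepwise selection of a small logratio basis,
conditional-dependence networks on centred logratios, and sum-to-zero
penalised log-contrast regression of health outcomes. A synthetic cohort
generator with fully known ground truth makes every stage testable, which
matters because the motivating class of survey biomarker data
(population-ageing studies with venous-blood immunophenotyping) is
access-restricted.

## The composition tree

The gating hierarchy is a rooted tree, four levels deep: lymphocytes
split into T cells, B cells and a remainder; T cells into CD4, CD8 and a
remainder; CD4 and CD8 each into naive (N), central memory (CM), effector
memory (EM), terminally differentiated effector memory (TDEM) and a
remainder; B cells into naive, IgD− memory, IgD+ memory and a remainder.
Measured children rarely sum to 100% of their parent, so every internal
node owns exactly one *derived* "other" child (LYMPO, TO, TCD4O, TCD8O,
BO) carrying the unexplained share. With the 15 measured populations this
gives 21 nodes and 16 leaves; the leaves, in a fixed depth-first order,
are the parts of the composition.

```{r tree}
lymphocyteTree()
```

Conversion multiplies percent-of-parent values (as proportions) down each
root-to-leaf path, so each leaf is its subset's share of total
lymphocytes; rows close to 1 up to floating point, and the constructor
enforces closure at `1e-9`. Two exclusion rules are applied first:
subjects with any missing measured percentage, and subjects whose
measured children exceed 100% of a parent beyond `1e-9` (sums of exactly
100 are valid and produce a zero remainder). A remainder within `1e-9` of
zero is snapped to an exact zero — otherwise the floating-point residue
of an exact partition (around 1e-14 on the percent scale) would later
masquerade as a real but absurdly small part and corrupt every log-scale
statistic.

**Zeros.** Logratios need strictly positive parts. Each exact-zero cell
is replaced by the smallest *positive* value observed for the same part
across the dataset — a per-part detection-limit imputation; "smallest
value of the cell type" is read per cell type rather than globally
because detection limits are part-specific. No renormalisation follows by
default: the perturbation is tiny and all logratio statistics are
invariant to closure anyway; `replaceZeros(renormalize = TRUE)` re-closes
for users who prefer exact unit sums. The operation is idempotent.

## Total logratio variance and stepwise selection

For a composition with $D$ parts there are $D(D-1)/2$ pairwise logratios
$L_{ij} = \ln(x_i/x_j)$ (120 for $D = 16$). The total logratio variance
is
$$T \;=\; \sum_{i<j} w_i w_j\, \mathrm{Var}\, L_{ij},$$
with uniform part weights $w_i = 1/D$ by default, which makes $T$
identically the mean variance of the centred-logratio (CLR) columns.
Part-mean weighting (the default of some compositional software) is
available via `weights = "part_means"`; the two differ numerically, and
neither is privileged here — the choice is exposed because published
totals rarely state their weighting. Natural logs are used throughout;
the base only rescales variances and never changes a selection order.

Stepwise redundancy analysis (`srdaSelect()`) greedily builds a small
basis: at each step, every remaining pair is scored by the fraction of
$T$ explained when the (weighted) centred CLR matrix is least-squares
projected onto the span of the selected logratio columns, and the best
pair is added. Because successive gains are orthogonal increments, the
cumulative fraction is non-decreasing and reaches exactly 1 after
$\mathrm{rank} = D-1$ steps on generic data (15 steps for 16 parts).
Ties in the argmax are real, not numerical accidents: once $L_{ij}$ is
selected, the candidates $L_{ik}$ and $L_{jk}$ span the same enlarged
subspace. Ties are therefore resolved to the lexicographically first pair
within a $10^{-9}$ relative tolerance on the gain, making the trace fully
deterministic. Note that the *first* selected pair is generally **not**
the maximum-variance logratio — a single pair's explained fraction is
$\sum_k w_k \mathrm{Cov}(\mathrm{clr}_k, L_{ij})^2 / \mathrm{Var}(L_{ij})$
(over $T$), which orders pairs differently than $\mathrm{Var}(L_{ij})$.

All logratio statistics are invariant to per-subject rescaling of the raw
input and to re-closure (subcompositional-coherence surrogate), and
permuting the part order permutes labels while leaving every
additional/cumulative fraction unchanged; both are enforced by tests.

## Conditional-dependence networks

Marginal correlations among proportions are distorted by closure, so
conditional dependence is estimated on CLR-transformed data
($z_{ik} = \ln x_{ik} - \overline{\ln x_{i\cdot}}$), the approach of
sparse inverse covariance estimation for compositional data. Two
estimators are provided:

* **Graphical lasso** (`fitGlasso()`): an L1-penalised precision matrix
  estimated by block coordinate descent on the covariance (implemented in
  C++). An edge exists where $|\Theta_{ij}| > 10^{-8}$; its sign and
  weight come from the partial correlation
  $-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$.
* **Neighbourhood selection** (`fitMB()`): node-wise lasso regressions of
  each CLR column on the others (via glmnet), symmetrised with the OR
  rule by default (AND available); the edge weight is the mean of the two
  directed coefficients and carries the sign.

The CLR covariance is exactly singular (rank at most $D-1$), so at
penalty 0 a small ridge ($10^{-6}$ times the mean variance) is added for
the glasso; positive penalties need no ridge. This singularity is also
why a *plain* inverse of the CLR covariance cannot be read edge-wise:
conditioning on all remaining parts of an exactly collinear system
distorts and can flip partial correlations. The sparse penalty is what
recovers the latent conditional-dependence structure, and the package's
tests verify exactly that on planted ground truth.

Sparsity is chosen by StARS (`selectSparsityStars()`): refit on `B = 50`
subsamples without replacement of size
$\min(\lfloor 10\sqrt n\rfloor, \lfloor 0.8 n\rfloor)$ over a grid of 30
log-spaced penalties (defaults; all configurable), compute the mean edge
instability $2\xi(1-\xi)$, monotonise it by a running maximum from the
sparse end downward, and return the smallest penalty — the densest stable
graph — whose monotonised instability stays at or below 0.05. The
monotonisation matters on CLR data, where the fully dense end of the path
is trivially "stable". If no penalty qualifies, the largest penalty is
returned with a warning (pure-noise data routinely land here, and
correctly yield an empty or near-empty graph).

## Penalised log-contrast regression

Health outcomes are regressed on all 16 log-parts under the log-contrast
constraint:
$$\min_{\beta,\gamma}\ \tfrac{1}{2n}\lVert y - Z\beta - W\gamma\rVert^2
  + \lambda\lVert\beta\rVert_1
  \quad\text{s.t.}\quad \textstyle\sum_k \beta_k = 0,$$
where $Z$ holds column-standardised log-parts (penalised) and $W$ the
covariate tier (unpenalised): tier 1 intercept only, tier 2 adds age and
gender, tier 3 adds race, education and CMV serostatus. The sum-to-zero
constraint makes predictions invariant to per-subject scaling of the
composition — verified numerically to $10^{-6}$ — and is what makes
coefficients interpretable as log-contrasts. Ordinal outcomes
(self-reported health 1–5, frailty level 1–4) are treated as numeric, as
is conventional for linear modelling of such scales.

The solver is ADMM with the equality constraint absorbed into the
quadratic KKT step (factorised once per fit, C++ inner loop); the
reported $\beta$ is the sparse iterate with entries below $10^{-8}$
zeroed and then re-projected *exactly* onto the constraint over its
support, so $\sum_k\hat\beta_k = 0$ to machine precision at every path
point. At $\lambda = 0$ the solution agrees with the closed-form
Lagrange equality-constrained least squares to $10^{-6}$; at large
$\lambda$ it collapses to the covariate-only OLS.

**Penalty choice.** $\lambda$ minimises
$\mathrm{BIC}(\lambda) = n\ln(\mathrm{RSS}_\lambda/n) +
\mathrm{df}(\lambda)\ln n$ over a 30-point descending grid (warm
starts), with df the number of non-zero part coefficients plus the
covariate dimension. $\mathrm{RSS}_\lambda$ is taken from the
constrained least-squares *refit* on the support selected at $\lambda$
— the usual relaxed convention. The alternative (scoring the shrunken
fit itself) systematically favours the null model whenever signals are
moderate, because the lasso bias inflates the RSS of every sparse
candidate; with the refit convention, BIC at $\lambda_{\max}$ still
equals the covariate-only model's BIC exactly. Ties go to the larger
(sparser) penalty.

**Uncertainty.** 95% intervals are case-resampling bootstrap percentiles
over 200 replicates (the conventional count for this design), each
refit at the original selected $\lambda$; re-tuning per replicate is
available by flag but not default, being an order of magnitude slower
and answering a slightly different question. Replicates with a constant
resampled outcome are skipped and counted. Fixed seeds make intervals
bit-reproducible.

Coefficients are reported on the standardised log-part scale; published
tables of this kind rarely state their scale, and standardisation makes
the L1 penalty treat parts symmetrically.

## OLS on selected logratios

The selected logratio basis (by default the pairs reaching 90% of $T$)
enters an ordinary least-squares fit per outcome and tier with classical
95% intervals; aliased columns (exact dependencies such as a completed
logratio triangle) are dropped and logged. As a yardstick,
`compareR2()` fits the same outcome on *all* 120 logratios by
minimum-norm least squares — the design has rank at most 15, so the
pseudoinverse fit is the honest "full" model — and reports both adjusted
$R^2$ values, the full model's degrees of freedom being its effective
rank. On cohorts where the selected basis carries the outcome signal,
the difference is small; the tests require $|\Delta| < 0.02$ at
$n = 5000$.

Two outcome constructions are provided. The chronic disease index is the
sum of eight binary condition flags (0–8). The deficit-accumulation
frailty index (mean of 44 items scored in $[0,1]$) is categorised at the
conventional cut points 0.15 / 0.25 / 0.35; the bins are implemented as
half-open intervals $[0.15, 0.25)$, $[0.25, 0.35)$ — printed two-decimal
ranges like "0.15–0.24" are exhaustive and non-overlapping only under
this reading, and the boundary values are tested exactly.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be exercised
against known truth. Design choices:

* **Logistic-normal, not Dirichlet.** Latent log-abundances are drawn
  from a multivariate normal and mapped to the simplex by
  exponentiate-and-close. The Dirichlet family has no free dependence
  structure, so it cannot carry planted conditional-dependence edges;
  the logistic-normal is exactly the model class the CLR-Gaussian
  analysis assumes.
* **Planted precision.** Unit diagonal with exactly three edges, partial
  correlations $+0.3$ (TCD4CM–TCD4O), $-0.3$ (TCD4CM–LYMPO), $+0.3$
  (TCD8CM–TCD8O) — the canonical immunosenescence-adjacent pattern of
  central-memory compartments tracking their "other" remainder. These
  are the only entries with partial correlation above 0.2, so network
  recovery tests have unambiguous truth.
* **Location and scale.** Latent means are the logs of typical
  older-adult median percentages (e.g. LYMPO ≈ 21%, TCD4N ≈ 20%,
  TCD4EM ≈ 0.07%); the latent covariance is scaled to a mean variance
  of 0.6, giving per-part log SDs around 0.75 and a total logratio
  variance near 0.55 — the magnitude seen in real immune-subset panels.
* **Zero inflation** emulates detection limits: within each of the four
  smallest-median parts (TCD4EM, TCD8EM, BMIgD−, BO), the lowest 14.3%
  of values become exact zeros, so roughly 46% of subjects carry at
  least one zero — the order of magnitude reported for real panels of
  this kind. Real zero co-occurrence patterns are unpublished; this
  scheme is a declared stand-in.
* **Outcomes.** A latent score
  $s = \ln(x)\beta^* + W\gamma^* + \varepsilon$,
  $\varepsilon \sim N(0, 1)$, drives everything. $\beta^*$ has five
  non-zeros summing exactly to zero ($-0.15$ TCD4N, $+0.10$ TCD4O,
  $+0.10$ TCD8CM, $-0.14$ TCD8O, $+0.09$ LYMPO) — lower naive CD4 and
  higher memory/"other" compartments mean worse health. The noisy score
  itself is emitted (`score`); the chronic disease index is a
  binomial(8) draw with a logistic link on the standardised score, the
  self-reported health grade cuts it into five bins, and the frailty
  index averages 44 Bernoulli deficits whose probabilities rise with
  the score. The links are calibrated on the standardised score so
  that the typical subject lands at CDI ≈ 2, self-reported health ≈ 3
  and frailty level ≈ 2 regardless of the covariate effect sizes;
  without that affine calibration the marginals would drift with
  $\gamma^*$.
* **Determinism.** Everything regenerates bit-identically from
  `(truth, seed)`; `simulateCohort()` co-serialises the ground truth
  with every dataset and emits the raw percent-of-parent panel so
  synthetic data enter the pipeline through the same front door as real
  data.

**What passing tests do and do not show.** The generator matches the
analysis model's assumptions by construction (CLR-Gaussian dependence,
linear score). Tests passing on it demonstrate the estimators are
correct and well-calibrated under those assumptions; they do not
demonstrate robustness to gating artefacts, batch effects, survey
weights, heavier-tailed subsets, or structured missingness in real
panels, none of which the generator emulates.

## Numerical choices and problem sizes

Closure and round-trip tolerances are $10^{-9}$; the ADMM residual
tolerance is $10^{-10}$ with the objective contract at $10^{-8}$; glasso
convergence is $10^{-7}$ on the working covariance; edges require
$|\Theta_{ij}| > 10^{-8}$; SRDA declares a candidate redundant below a
$10^{-9}$ relative residual norm. The test suite exercises SRDA to
exhaustion at $n = 200$ ($D = 16$) and against the brute-force oracle at
$D = 5, n = 40$; network recovery at $n = 4000$ with StARS over 20
subsamples and a 15-point grid (10 replicates, plus 5 null replicates);
sign recovery of the outcome model at $n = 2000$ over 20 seeds; and the
$R^2$ comparison at $n = 5000$ — sizes chosen so each property is
measured well away from its small-sample noise floor while the whole
suite stays quick to run.

One honest caveat is worth stating: at the generator's default noise
level ($\sigma = 1$, signal standard deviation ≈ 0.2), the weakest
active coefficient carries a t-statistic near 3 at $n = 2000$, while
BIC-consistent inclusion needs roughly $t > \sqrt{\ln n} \approx 2.8$.
All-five sign recovery therefore succeeds in most but not all seeds —
an intrinsic property of BIC at this signal-to-noise ratio, not of the
solver — and the corresponding acceptance check reflects whatever the
measurement gives. At lower noise (or equivalently stronger
$\beta^*$), recovery is essentially certain, which the unit tests
demonstrate separately.

## Limitations

Cross-sectional linear models of ordinal outcomes; no survey weights or
sampling design; no ordinal/logistic log-contrast variants; no debiased
lasso inference; the full-logratio comparison model is a pseudoinverse
fit, not an interpretable model. The pipeline orchestrates one cohort at
a time; longitudinal or multi-wave designs are out of scope.
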