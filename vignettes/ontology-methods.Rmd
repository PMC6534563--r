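---
title: "Methods: discovering psychological ontologies from behavioral batteries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering psychological ontologies from behavioral batteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`psychspace` implements a complete data-driven workflow for organizing large
batteries of psychological measurements — behavioral task scores and
self-report survey scales, decomposed into dependent variables (DVs) — into a
quantitative "psychological space" plus a set of clusters, and for testing
how well the resulting trait scores predict self-reported real-world
outcomes. This vignette explains the models behind each stage, the tunable
parameters and their defaults, the numerical choices we made where the
methodology left them open, and what the synthetic validation battery does
and does not establish.

## The factor model

The backbone is the common factor model. For standardized DVs,

$$X - \mu = L F + \varepsilon,$$

with $X$ the $m \times n$ data (DVs by participants), $L$ the $m \times f$
loading matrix, $F$ the $f \times n$ latent factor scores, and
$\varepsilon$ unique variance. We fit by maximum likelihood on the Pearson
correlation matrix (`fit_efa()`), delegating the uniqueness optimization to
`stats::factanal` and treating the correlation matrix — not the covariance —
as the model input, because DVs arrive in incommensurate units.

Two numerical guards matter in practice:

* **Degenerate likelihoods.** When the correlation matrix carries no shared
  signal (in the limit, an identity matrix), the ML solution is non-unique:
  a single variable's loading can trade off against its uniqueness at zero
  discrepancy. We always evaluate the boundary candidate ($L = 0$,
  $\Psi = I$) and prefer it when it fits as well — the parsimonious
  tie-break. Uniquenesses are bounded below at 0.001; solutions pinned at
  the bound are flagged as Heywood cases rather than hidden.
* **Near-singular correlation matrices** are ridge-regularized by `1e-8`
  (and renormalized), with a message.

**Rotation.** Interpretability comes from direct oblimin ($\gamma = 0$,
i.e. quartimin) rotation, implemented as a gradient-projection algorithm on
the oblique manifold. Rotation is a change of basis: it alters $L$ and the
factor correlation matrix $\Phi$ but not the fit, which the test suite
checks numerically (communalities and likelihood-ratio statistic invariant
to $10^{-6}$). Because the quartimin criterion is non-convex we run 10
seeded starts (identity plus 9 random) and keep the lowest criterion value.
Factors are then ordered by explained variance and sign-fixed so each
factor's loading sum is non-negative.

**Dimensionality.** `select_dimensionality()` fits each candidate $f$ and
minimizes $\mathrm{BIC} = \chi^2 - \mathrm{df}\,\ln n$ with the
Bartlett-corrected likelihood-ratio $\chi^2$ and
$\mathrm{df} = [(m-f)^2 - (m+f)]/2$. Only the argmin is contractual; the
absolute BIC value depends on conventions. The default candidate grid is
$1..\lfloor m/3 \rfloor$ capped at 25; analyses at scale narrow it for
speed (the desk-scale validation sweeps 2–8 for the task battery and 8–16
for the survey battery, keeping the planted optima interior to the grid).

**Scores.** Factor scores use the ten Berge correlation-preserving
construction, the appropriate choice for oblique factors: with
$L^* = L\Phi^{1/2}$ and correlation matrix $R$,
$C = R^{-1/2} L^* (L^{*\prime} R^{-1} L^*)^{-1/2}$ and
$W = R^{-1/2} C\, \Phi^{1/2}$; scores are $Z W$. Their sample correlation
matrix reproduces $\hat\Phi$ essentially exactly, which the tests use as a
method-defining oracle. `apply_weights()` freezes $W$ and applies it to new
data (e.g. a retest session); the new sample is standardized with its own
means and standard deviations by default (`scaling = "own"`), a convention
switch because the original procedure did not state one.

**Robustness.** `bootstrap_loadings()` refits on 90% subsamples drawn
without replacement (1000 by default; "fraction kept" suggests subsampling
rather than case resampling, and a `replace` flag switches). Refit solutions
are aligned to the base model before averaging: the column
permutation-and-sign ambiguity is resolved by maximizing total absolute
Tucker congruence, solving the assignment problem exactly with a
shortest-augmenting-path algorithm. `drop_measure_robustness()` removes each
measure's DVs wholesale and reports per-factor congruence after alignment.

## Reliability and the noise ceiling

Test-retest reliability bounds what any model of stable traits can explain.
`retest_pearson()` and `icc3k()` compute per-DV Pearson correlations and
ICC(3,k) (two-way mixed, consistency, average of $k = 2$ sessions) over the
retest subsample. Attenuation correction divides communality by squared
retest reliability, estimating the share of *stable* variance the factors
capture. The ratio is unbounded above, so values over 1 are flagged, and
clipped to 1 only in aggregates (the per-DV raw values are preserved);
negative or zero reliabilities are excluded from the correction (an error),
consistent with the $r > 0.2$ filter applied before correlating communality
with reliability.

## Clustering in loading space

DVs are clustered in the factor embedding, not in raw participant space:
each DV's coordinates are its loading row, and distance is
$d_{ij} = 1 - |\mathrm{cor}(L_{i\cdot}, L_{j\cdot})|$. The absolute value
makes the metric invariant to each measure's arbitrary direction (an
"impulsivity" DV is a flipped "self-control" DV). Trees use average linkage
(UPGMA), the standard companion of dynamic tree cutting.

`dynamic_tree_cut()` implements a dynamic hybrid procedure: scanning merges
bottom-up, a branch becomes a cluster when it (i) has at least
`min_cluster_size` members (default 3 — the clusters of interest can be
small), (ii) is internally tight (the mean height of its earliest "core"
merges falls below a threshold), and (iii) is separated from its sibling
(the gap between attachment height and branch top exceeds a threshold).
Both thresholds scale with the tree's height range through `deep_split`
(0–4, default 2, mapped to core-scatter fractions 0.64–0.95 of the range
above the 5th-percentile merge height, with the gap threshold at 3/4 of the
complement). One absolute guard, `min_split_height = 0.05`, prevents
splitting structure whose entire scale is noise-level: merges below that
absolute height never separate clusters, so a single tight block remains
one cluster. In the hybrid second stage, unassigned objects attach to the
nearest cluster by average dissimilarity. If no split qualifies anywhere,
the battery is one cluster.

`fixed_height_cut()` provides the single-height comparison, in sweep mode
choosing the cut that maximizes mean silhouette over all merge heights
(heights are searched at midpoints between consecutive merge heights —
a continuous search cannot change the resulting partitions). Silhouette
follows the usual convention ($s = 0$ for singletons; unassigned DVs are
excluded from the mean with a warning). Agreement between partitions is
measured by adjusted mutual information with the *exact* hypergeometric
expected-MI term, validated against a brute-force average over all
permutations of small label vectors.

`consensus_cluster()` quantifies stability: 5000 simulated loading matrices
(element-wise Gaussian draws from the bootstrap mean/sd), each dropping 20%
of DVs at random, are re-clustered with the identical pipeline. Pairwise
co-occurrence is accumulated *conditional on joint retention* — with
dropout, unconditional proportions would be biased low — and the consensus
partition is the same tree/cut pipeline run on $1 - $ co-occurrence.

2-D maps use metric MDS (SMACOF majorization of raw stress, classical
scaling start plus seeded random restarts; the stress trace is
non-increasing by construction) or PCA with its variance-explained share.

## Partial-correlation networks

`fit_partial_correlation_graph()` estimates a sparse Gaussian graphical
model over all DVs with the graphical lasso (block coordinate descent on
the correlation matrix, written in C++; its penalty-free limit is verified
against the matrix inverse). The penalty is chosen on a 100-point
log-spaced grid spanning $[0.01\lambda_{\max}, \lambda_{\max}]$ by the
extended BIC with $\gamma = 0.5$. Following the original EBIC-for-glasso
formulation, the criterion is evaluated at the *edge-pattern-constrained
maximum likelihood* (a refit with zero penalty on selected edges), not at
the shrunken estimate; this is what lets the criterion actually prune
spurious edges — on a simulated chain $X \to Y \to Z$ the $X$–$Z$ edge is
dropped exactly. Edge exports support both documented thresholds
($|\rho| \ge 0.05$ figure-style, 0.01 methods-style) without
privileging either. `cross_category_prediction()` quantifies task–survey
separability directly: every DV is predicted by 10-fold cross-validated
ridge regression from all *other* task DVs and, separately, all survey DVs.

## Outcome prediction

Outcome DVs are first residualized on age and sex by OLS, then reduced by
the identical BIC/oblimin/ten Berge pipeline to target factor scores.
`cv_predict()` evaluates a feature set against one target with balanced
10-fold cross-validation: the continuous target is decile-stratified and
strata are dealt across folds, so fold target means are balanced and fold
sizes differ by at most one (522 participants split 469/53 and 470/52).
The primary metric is the squared Pearson correlation between concatenated
out-of-fold predictions and the actual target — the convention of the
original analysis — with $1 - SSE/SST$, the signed correlation, and MAE
reported alongside (squared correlation alone hides anti-prediction).

Ridge regression is the primary model (random forests overfit this regime
badly); the penalty is selected *inside each training fold* by closed-form
leave-one-out error over a 25-point grid $10^{-3}..10^{3}$, and
standardization also uses training-fold statistics only — the suite
includes leakage sentinels (a target copied into the features must give
cv $R^2 \approx 1$; shuffled features must give $\approx 0$). Lasso
(glmnet), random forest (ranger) and SVM (e1071) are available alternates
behind the same interface.

Significance uses a permutation null: the target is shuffled, folds are
rebuilt on the shuffled target, and the entire pipeline (including penalty
selection) is rerun — 2500 shuffles by default, with
$p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$. Because the test statistic
and the null runs share every analysis choice, the test is exact up to
Monte-Carlo error; the suite verifies type-I error calibration at 200 null
targets × 200 permutations (a smaller 200-participant, 6-feature design —
calibration is a property of the procedure, not of the study's dimensions).
Fingerprints are the standardized ridge coefficients of the full-data fit,
arranged target-wise or transposed feature-wise.

## The synthetic battery

All validation runs on generated batteries with planted truth
(`battery_config()`, `generate_battery()`, `generate_retest()`,
`generate_outcomes()`). The generative model mirrors the analysis model:
traits $f \sim N(0, \Phi_{joint})$ with exchangeable within-category factor
correlations (0.30 task, 0.25 survey) and a weak uniform cross-category
coupling (0.10); each DV is
$\ell_i' f + s_i \xi_i + e_i$ with stable specific factor $\xi_i$ and
session-only noise $e_i$, scaled to unit variance so that retest
reliability equals communality plus stable specific variance. Reliability
therefore can never fall below communality — the generative counterpart of
attenuation correction staying $\le 1$ when the model is true. Explicit
per-DV reliabilities below communality are rejected; drawn reliabilities
are floored at communality plus a 0.02 margin.

The default ("study-like") configuration plants 522 participants, a
150-participant retest, 129 task DVs on 5 factors and 64 survey DVs on 12;
task reliabilities are drawn from $N(0.45, 0.21)$ clipped to (0.05, 0.95)
and survey reliabilities from $N(0.80, 0.06)$ — the published reliability
summaries for this kind of battery — and primary loading ranges
(0.30–0.60 task, 0.60–0.90 survey) were chosen so mean planted
communalities sit near 0.23 and 0.58, the levels reported for real task and
survey batteries. Outcome traits mix survey factors through a sparse
coefficient matrix with exact population $R^2$ targets (default eight
outcomes averaging $\approx 0.1$, maximum 0.29) plus age/sex effects that
the residualization step must remove.

What passing these tests shows: the pipeline recovers dimensionality,
loadings, clusters, reliabilities, graph structure and predictive $R^2$
when its own assumptions hold, at study-realistic sizes and noise levels.
What it does not show: robustness to non-Gaussian DVs (real task scores are
often skewed or heavy-tailed), to ordinal survey items, to missingness
(the pipeline requires imputed input by design), or to model misfit such as
minor factors and local dependence. Gaussian DVs are a deliberate
limitation — every stage here operates on linear correlation structure.

## Problem sizes used in validation

The packaged validation (`scripts/acceptance.R` and the acceptance test
file) runs, per seed batch: 20-seed dimensionality recovery at full study
scale; one full-scale loading-recovery battery with primary loadings
0.5–0.8; the 3-variable closed-form factor problem; planted 3-block
clustering with the brute-force AMI oracle on 6–8 item partitions;
permutation calibration at 200 × 200; 20-seed outcome recovery at
$n = 500$ with targets $R^2 = 0.25$ and 0; graphical-lasso oracles at
$n = 5000$; and 5-seed retest emulation at $n_{retest} = 150$. These sizes
were chosen as the smallest designs that make the checks sharp (Monte-Carlo
error comfortably below each tolerance).

## Known limitations

* The dynamic hybrid cut is an independent implementation of the published
  branch-detection idea, not a line-for-line port; printed cluster counts
  for a given real dataset may differ by a couple of clusters under
  default parameters, which is within the method's own sensitivity to its
  cut parameters.
* BIC is the only dimensionality criterion implemented; other criteria
  (parallel analysis, MAP) are known to give overlapping but not identical
  answers.
* The permutation null shuffles targets before fold construction;
  shuffling within folds is a different (less conservative) design.
* ICC(3,k) can be negative for anti-reliable DVs and is reported as
  computed.
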