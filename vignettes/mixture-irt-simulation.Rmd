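---
title: "Mixture polytomous IRT models: estimation and Monte Carlo design"
author: "mixirtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture polytomous IRT models: estimation and Monte Carlo design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixirtsim)
```

## The models

`mixirtsim` studies two mixture models for ordered rating-scale responses:
the restricted mixed generalized partial credit model (rmGPCM) and the mixed
partial credit model (mPCM). Both assume a population composed of $G$ latent
classes that differ in how respondents use the response categories — e.g. an
extreme-responding class, an ordinary-responding class, and a class that
prefers the outermost two categories on each side.

Within class $g$, responses follow an adjacent-category logit model. For
item $i$ with categories $x \in \{0, \dots, C-1\}$ and latent trait value
$\theta$,

$$\log \frac{P(X_i = x)}{P(X_i = x - 1)}
  = \Delta\beta_{xgi} + \lambda^{i}\,\theta ,$$

where $\Delta\beta_{xgi}$ are class- and item-specific step parameters (the
differences of adjacent category intercepts) and $\lambda^i$ is the item
discrimination, equal across classes. The rmGPCM frees $\lambda^i$ over
items with $\lambda^1 = 1$ for identification; the mPCM fixes all
$\lambda^i = 1$. The trait of a class-$g$ member is $\theta = \lambda_g z$
with $z \sim N(0,1)$, so $\lambda_g$ is the within-class trait standard
deviation. Class sizes $\pi_g$ are parameterized as multinomial logits with
the first class as reference. The equivalent IRT threshold form uses
$\tau_{isg} = -\Delta\beta_{sgi} / \lambda^i$: thresholds locate the trait
value at which two adjacent categories are equally likely, and unordered
thresholds signal avoided categories — the signature of a response style.

**Trait-scale semantics.** The scale parameter of the latent trait is
sometimes described as a class-specific *variance*. We treat the stored
$\lambda_g$ as the trait *standard deviation* (a loading on a standard
normal factor), which matches the single-factor logistic form above; a
variance reading is available everywhere via `trait_scale_is_variance`. The
standard-deviation reading also reproduces the magnitudes of the bundled
population model's accuracy profile (trait-scale and class-size recovery at
small $N$) in our own simulations, whereas the variance reading distorts
them, so it is the package default.

## The bundled population models

`load_generating_fixture()` returns the generating parameters of two
three-class population models (rmGPCM-3, mPCM-3; 5 items, 11 categories)
obtained from an empirical application to a national panel survey's 5-item
job-satisfaction scale with an 11-point rating scale. They are shipped as a
checksummed CSV, including:

* a marked subset of 5 of the 10 step parameters per item, used to build the
  6-category study conditions;
* flags for entries whose extreme source estimates were substituted by
  $|4|$, and low-confidence flags for a few typographically ambiguous cells;
* class-size logits implying proportions 0.33/0.40/0.27 (rmGPCM-3) and
  0.32/0.43/0.25 (mPCM-3).

`derive_condition()` produces every design cell from the fixture: 15-item
tests replicate the five base items three times; 6-category tests keep the
marked step subset per item; 2-class conditions keep classes 1–2 with
class logits $(0, 0.75)$.

## What the generator emulates — and what it does not

`generate_dataset()` draws, per respondent, a class from the class
proportions, a trait $\lambda_g z$, and item responses from the
class- and trait-conditional category probabilities. This reproduces the
features that make the design statistically challenging: a short scale, many
categories, unequal classes, unordered thresholds, and *sparse tables* — the
population model implies several cells with expected counts below one at
$N = 500$ (e.g. the two lowest categories of item 3 in the
ordinary-responding class), which is the main driver of extreme estimates
and boundary standard errors.

It deliberately does **not** emulate survey weights, item nonresponse, panel
attrition or dependence, local dependence between items, or
differential item functioning. Passing tests therefore demonstrate correct
behavior of the estimator and study machinery under the stated mixture
model, not robustness to the messiness of real survey data.

## Estimation

`fit_em()` maximizes the marginal likelihood: the trait is integrated over a
quadrature grid (default 80 Gauss–Hermite points, converted to the
probabilists' normalized form; a rectangular grid is available for
cross-checks) and classes are summed over. The E-step computes each
respondent's joint posterior over (class, node) in compiled code and
accumulates the complete-data sufficient statistics: posterior cell masses
and posterior-weighted response counts. The M-step updates class logits in
closed form and takes one damped Newton step per (class, item) block on the
expected complete-data log-likelihood, plus scalar Newton steps for
discriminations and trait scales (a generalized EM). Two safeguards matter
in sparse data:

* a trust region caps each block's per-iteration move at one logit, so
  data-poor coordinates drift slowly instead of escaping along near-null
  Hessian directions;
* all block updates are jointly step-halved until the expected
  complete-data criterion does not decrease, which guarantees a monotone
  ascent of the (penalized) marginal objective.

EM stops when the objective changes by less than 0.01 (default) or at
10,000 iterations. `refine_newton()` then runs a bounded quasi-Newton
(L-BFGS-B) stage on the free parameters with the analytic score, obtained
from the E-step statistics by Fisher's identity; its convergence flag is a
scaled gradient criterion ($10^{-8}\,(1 + |\ell|)$ by default, capped at 600
iterations). `multi_start_fit()` runs a capped number of EM iterations from
each of $n$ random start sets (defaults: 100 sets, 200 iterations — scale
these down for desk runs) plus an optional warm start, continues the best
candidate, and refines it.

The parameter-recovery arm (`run_recovery_study()`) fits by warm-started EM
*without* the Newton stage by default: on sparse 11-category data the rapid
Newton stage rarely satisfies its strict gradient criterion, and its main
effect is to walk information-poor step parameters along near-flat
likelihood directions away from their warm-start anchor, which degrades
rank concordance and discrimination coverage without changing the
likelihood materially. Class enumeration (`run_condition()`,
`multi_start_fit()`) keeps the full EM-then-Newton protocol, where the
refined log-likelihood feeds the information criteria.

**Optional prior smoothing.** `fit_config()` can add Dirichlet
pseudo-counts ("Bayes constants"): `bayes_categorical` observations per
item, distributed over the class × category × node cells proportionally to
the item's observed marginal category distribution (so observed margins are
untouched), and `bayes_class` observations over the class sizes. All
EM/Newton machinery, scores and information matrices then consistently
target the penalized (posterior-mode) objective. The default is plain
marginal maximum likelihood (both 0): under MML, adjacent-category models
genuinely diverge at empty cells — at $N = 500$ roughly 15% of step
estimates escape beyond $|10|$ — and the trimming rules below then
eliminate exactly those coordinates, which reproduces the reference
accuracy profile of the bundled population models; smoothing instead
retains those coordinates at moderate values, which inflates the robust
error indices and degrades the rank concordance of the step profiles. For
applied work on a single sparse data set the smoothing option is a
pragmatic stabilizer; for the simulation battery it stays off.

**Standard errors.** `compute_standard_errors()` builds the observed
information of the fitted objective by central finite differences of the
analytic score (step $10^{-4}\max(1, |\theta_j|)$), symmetrizes it, drops
parameters sitting at their clamps, and inverts it spectrally:
eigendirections carrying less than $10^{-9}$ of the largest eigenvalue are
numerically zero for a finite-difference Hessian, and inverting them would
let noise in the cross-terms contaminate every other standard error.
Coordinates living mostly in that null space are reported with their
marginal standard error $1/\sqrt{I_{jj}}$ — typically enormous, so the
SE > 50 trimming rule eliminates them — while coordinates in genuinely
negative-curvature directions are flagged as boundary values, as are
standard errors above $10^4$ and parameters at their clamps. An
outer-product-of-gradients estimate (`se_method = "opg"`) serves as a
cross-check. A solution with strictly more than 10% boundary standard
errors is declared improper and is dropped from all downstream summaries.

## Accuracy battery

Before any index is computed, `trim_estimates()` eliminates, pairwise with
their standard errors, estimates beyond $|10|$, standard errors above 50,
and boundary-flagged standard errors. The indices are

* RMdSE $= \sqrt{\mathrm{Md}_t\,(\hat p_t - p)^2}$ — robust absolute
  accuracy;
* SE bias $= \mathrm{Md}_t\,|\hat{se}_t - SD_{\hat p}|$ with the empirical
  SD taken over all retained estimates ($n-1$ denominator);
* median CI width $= \mathrm{Md}_t\,(2 \times 1.959964 \times \hat{se}_t)$
  (the quantile is fixed to six decimals for bit-stable output);
* 95% coverage of the Wald interval;
* Spearman rank correlation between generating and estimated step
  parameters per item, averaged over items then replications, with trimmed
  coordinates dropped pairwise from the rank vectors — the elimination step
  precedes *all* indices, this one included.

Per-coordinate indices are aggregated per parameter type and class by the
median (coverage by the mean). Class-size accuracy is computed on the
multinomial-logit scale, where the generating parameters live and where the
reported recovery magnitudes (about 0.23 at $N = 500$) are reproduced; a
proportion-scale summary is available via
`class_size_on_proportion_scale`.

## Class enumeration

`information_criteria()` implements AIC, BIC, CAIC, AIC3 and SABIC with
natural logarithms; the SABIC penalty is Sclove's $\ln((N+2)/24)$. (A
literal $\ln(N + 224)$ variant is exposed for audit; it makes SABIC nearly
indistinguishable from BIC and is used nowhere.) `select_best()` takes the
argmin with ties broken toward fewer classes. In `run_condition()`,
replications whose true-class solution is improper are eliminated entirely;
improper non-true candidates are excluded from that replication's argmin
only. Free-parameter counts follow the identification constraints:
$G\,I\,(C-1)$ step parameters, $I-1$ discriminations (rmGPCM), $G-1$ class
logits, $G$ trait scales.

## Label alignment

Class labels are permutation-symmetric. `align_labels()` matches fitted to
generating classes by exhaustively minimizing the squared distance between
class-wise step-parameter blocks ($G! \le 24$), then permutes every
class-indexed block, re-referencing class logits from the permuted
proportions. With warm starts at the generating values the identity
permutation is recovered in practice; when a permutation moves the
reference class, the class-logit standard errors are not recoverable from
per-parameter standard errors and are set to `NA`.
`check_label_separation()` additionally reproduces the multinomial-logistic
certificate: a classifier trained on class-wise step-parameter vectors
across replications must separate the classes without error.

## Problem sizes and reproducibility

The full design (500 replications × 10 sample sizes × 2 models, 100 start
sets each) is cluster-scale. The package's test suite and the
`scripts/acceptance.R` summary instead use 50 warm-started replications of
the challenging condition (rmGPCM-3, 5 items, 11 categories) at $N = 500$
and $N = 2{,}500$ — enough for the median-based indices and mean
concordances to stabilize — plus analytic identities and property checks on
small models (including a dense-grid trapezoid oracle for the quadrature and
a consistency check at $N = 100{,}000$). Every replication's seed derives
deterministically from the base seed, the condition id, and the replication
index, and is recorded; identical configurations produce byte-identical
outputs.

## Known limitations

* The Newton stage reports non-convergence by its scaled gradient criterion
  more liberally than the reference software reported for the same designs;
  NR convergence percentages are implementation-specific and are not a
  contracted quantity here.
* Person-parameter (EAP/MAP) scoring, covariate-extended mixtures,
  multidimensional traits and Bayesian (MCMC) estimation are out of scope.
* Class-logit standard errors after a reference-moving relabeling are
  reported as missing rather than delta-method transformed.
* The improper-solution rule (> 10% boundary standard errors) and the
  boundary flags themselves are necessarily implementation-defined; rates
  of flagged replications are comparable to, but not identical with, those
  of other implementations.
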