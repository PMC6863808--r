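# mixirtsim

Monte Carlo simulation toolkit for **mixture polytomous item response
models** on short rating scales with many response categories.

Panel surveys often measure attitudes with very short scales (say, five
items) equipped with long rating scales (say, 11 points). Such data are
prone to *response styles* — latent subpopulations that use the categories
differently (extreme responding, ordinary responding, partial-extreme
responding) — and mixture IRT models can detect them. But five items with
eleven categories and three latent classes mean ~160 free parameters and
inevitably *sparse tables*, so the practical question is: **how many
respondents do these models need before their estimates, standard errors
and class-enumeration criteria can be trusted?** `mixirtsim` packages
everything required to study that question by simulation.

## The models

The restricted mixed generalized partial credit model (rmGPCM) and the
mixed partial credit model (mPCM). In class $g$, the adjacent-category
logit of item $i$ is

$$\log \frac{P(X_i = x)}{P(X_i = x-1)} = \Delta\beta_{xgi} + \lambda^i \lambda_g z, \qquad z \sim N(0,1),$$

with class-specific step parameters $\Delta\beta$, item discriminations
$\lambda^i$ (free over items in the rmGPCM, all 1 in the mPCM), class trait
scales $\lambda_g$, and multinomial-logit class sizes. Estimation is
marginal maximum likelihood: EM over a (class × Gauss–Hermite node) grid
with a compiled E-step, followed by a bounded quasi-Newton stage, with
observed-information standard errors, improper-solution diagnosis, label
alignment, the robust accuracy battery (RMdSE, SE bias, CI width, coverage,
Spearman concordance, with the |10|/50/boundary trimming rules), and
class-enumeration by AIC, BIC, CAIC, AIC3 and SABIC.

The package ships the generating parameters of two empirically derived
three-class population models (5 items, 11 categories) and derives all
design cells from them (15-item, 6-category, and 2-class variants).

## Worked example

Generate one challenging data set (rmGPCM-3, N = 1,000), fit the
three-class model warm-started at the generating values, and inspect it:

```r
library(mixirtsim)

truth <- load_generating_fixture("rmGPCM")
dat   <- generate_dataset(truth, N = 1000, seed = 7)
cfg   <- fit_config()               # EM tol 0.01, 80 GH nodes, plain MML
fit   <- fit_em(dat, start = truth, config = cfg)
fit   <- compute_standard_errors(fit, dat, cfg)
fit
#> rmGPCM fit: loglik -9592.366, 159 free parameters, EM converged in 85 iterations

round(class_proportions(fit$estimates$class_logit), 3)
#> [1] 0.329 0.312 0.360
fit$mean_assignment_probability
#> [1] 0.8546825
fit$improper
#> [1] FALSE
round(information_criteria(fit$loglik, fit$n_free_parameters, 1000), 2)
#>      AIC      BIC     CAIC     AIC3    SABIC
#> 19502.73 20283.06 20442.06 19661.73 19778.07
```

The fitted class-1 share matches its generating proportion (0.33), while
the single N = 1,000 draw visibly shuffles mass between the two
harder-to-separate classes (generating 0.40/0.27, fitted 0.31/0.36) — the
kind of small-sample behavior the simulation study quantifies. Each
respondent's maximum posterior class probability averages ~0.85, and no
more than 10% of standard errors hit a boundary, so the solution is proper.

A whole design cell, scaled down to 10 replications:

```r
cc  <- condition_config("rmGPCM", n_items = 5, n_categories = 11,
                        true_classes = 3, sample_size = 1000,
                        n_replications = 10, base_seed = 1)
rec <- run_recovery_study(cc)
rec$summary   # RMdSE / SE bias / CI width / coverage / Spearman per type x class
```

`run_condition()` additionally fits neighbouring class counts per
replication and tabulates, per criterion, how often each class count is
selected; `export_tables()` writes the convergence, accuracy and selection
tables as CSV. A thin command-line front end lives at
`inst/cli/simstudy.R` (`run`, `fixture` subcommands, YAML study configs).

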