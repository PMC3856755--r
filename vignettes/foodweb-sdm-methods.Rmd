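---
title: "Methods: latent-trait food-web inference coupled to distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-trait food-web inference coupled to distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodwebSDM)
```

## The problem

Bipartite feeding webs between herbivores and their host plants are almost
never observed completely: a plant-butterfly pair can only reveal its link
status where the two species co-occur, and in sparse landscapes a large
share of pairs is never seen together. `foodwebSDM` couples three pieces to
work around this: a probabilistic food-web model that infers link
probabilities from measured and latent traits, a phylogenetic regression
that extrapolates the latent traits to species without recorded
interactions, and species distribution models (SDMs) that use the resulting
link probabilities as a biotic predictor before per-species predictions are
stacked into site communities.

## The link model

For plant $i$ and butterfly $j$ the probability of a trophic link is

$$\operatorname{logit} P_{ij} = \alpha + \beta_1 N_i + \beta_2 \mathrm{AvH}_i
  + \delta_1 v_i^{(1)} f_j^{(1)} + \delta_2 v_i^{(2)} f_j^{(2)}$$

with $N_i$ the plant's leaf nitrogen content (% dry mass) and
$\mathrm{AvH}_i$ its average canopy height. Each species carries two latent
traits ($v$ for plant susceptibility, $f$ for butterfly foraging) whose
products, scaled by $\delta_1 \ge \delta_2 \ge 0$, absorb structure the
measured traits cannot express. The likelihood is a product of Bernoulli
terms over *knowable* cells only — pairs co-occurring at least once
($z_{ij}=1$); masked cells contribute exactly nothing, which the tests
assert by flipping them.

Two identifiability problems are resolved by construction rather than left
to chance:

* **Scale**: $\delta_d v f$ is invariant to $v, f \mapsto cv, f/c$. Latent
  traits get a standard-normal prior, pinning their scale, while
  $\delta_1, \delta_2$ carry half-normal(sd 10) priors.
* **Label switching and sign**: the two latent dimensions are ordered by
  $\delta_1 \ge \delta_2$, and $(v^{(d)}, f^{(d)}) \mapsto (-v^{(d)},
  -f^{(d)})$ leaves every $P_{ij}$ unchanged. After sampling, each retained
  draw's signs are aligned to the first retained draw by the inner product
  of plant latents, so posterior-mean latents are meaningful inputs for the
  downstream phylogenetic regression.

`fit_trophic_model()` runs block-wise Gaussian random-walk
Metropolis-Hastings: one block for $(\alpha, \beta_1, \beta_2)$, one for
$(\delta_1, \delta_2)$ (proposals violating the ordering are rejected), and
one per species' latent pair, so a species update touches only its own row
or column of the likelihood. Proposal scales adapt toward roughly 30%
acceptance during burn-in only; the retained chain is a fixed-kernel Markov
chain and is bit-reproducible from (control, seed). Measured traits are
z-scored internally — slopes are reported on the standardized scale, and the
centering is stored so predictions accept raw-scale traits. All Bernoulli
terms are computed from the logit with `log1p`-style stable forms;
probabilities are never clipped inside the likelihood.

Two point summaries of link probability are kept: `fitted()` returns the
posterior mean of $P_{ij}$ across retained samples, and `predict()`
evaluates the model at the aligned posterior-mean parameters (needed when
imputed species extend the species set). They agree closely in practice;
the first is used when only fitted species matter, the second for dense
prediction over fitted plus imputed species.

## Phylogenetic extrapolation

Latent traits of species with no knowable interaction cannot be estimated
from the web. Each latent dimension of each guild is treated as a trait
evolving on that guild's ultrametric phylogeny and regressed (intercept
only) under a Pagel's-$\lambda$ covariance: diagonal $\sigma^2$,
off-diagonal $\sigma^2 \lambda t_{ij}$, where $t_{ij}$ is the shared-time
fraction — the depth of the pair's most recent common ancestor over tree
depth, measured from the root of the input tree with no rescaling. The
profile likelihood over $\lambda \in [0,1]$ uses closed-form GLS estimates
of $(\mu, \sigma^2)$ at each $\lambda$; a single eigendecomposition of the
shared-time matrix makes each evaluation $O(n)$, and an 11-point grid
pre-scan followed by `optimize()` (tolerance $10^{-4}$) avoids local
optima. Tests confirm agreement with a dense $10^{-3}$ grid search and with
an independent reference implementation (`phytools::phylosig`).

Because $\lambda = 0$ sits on the boundary of the parameter space, the
signal test refers $2(\ell(\hat\lambda) - \ell(0))$ to the 50:50 mixture of
a point mass at zero and $\chi^2_1$.

Missing species are filled in by the conditional expectation of the fitted
multivariate normal — kriging on the tree:
$\hat y_x = \mu + C_{xo} C_{oo}^{-1} (y_o - \mu)$, conditioning only on
species with at least one recorded interaction. At $\lambda = 0$ this
collapses to $\mu$; at $t = 1$ it interpolates exactly. The four
dimensions (plant $v^{(1)}, v^{(2)}$; butterfly $f^{(1)}, f^{(2)}$) are fit
and imputed independently; no cross-dimension phylogenetic covariance is
modelled. Imputation uses the point estimates (posterior-mean latents);
propagating per-sample uncertainty through the imputation is possible by
calling `impute_latent()` per retained sample, but is not the default path.

The fitting and the imputation deliberately share one shared-time matrix
computed on the full species set, so pruning a subtree cannot silently
rescale the time fractions between the two steps.

## Distribution models and the trophic term

For a focal butterfly, site-level predictors come in three sets sharing six
abiotic columns — linear and quadratic terms of z-scored growing degree-days
(`ddeg`), moisture index (`mind`, precipitation minus evapotranspiration)
and solar radiation (`srad`). Quadratic logistic responses are the standard
choice for unimodal niches along elevation-like gradients; the GAM variant
instead uses thin-plate smooths (basis size 5) of the three gradients. The
biotic column is either a literature host-presence indicator or the
"best-case scenario" trophic term: the maximum modelled link probability
between the butterfly and any plant present at the site, defined as 0 where
no plant is present (no host is the worst case for an herbivore).

Four techniques are supported — binomial GLM, GAM (`mgcv`), gradient
boosted trees (xgboost backend: depth 2, learning rate 0.1, 100 rounds, a
deliberately shallow, slow-learning configuration for small presence
tables) and random forest (500 trees). Tenfold cross-validation stratifies
folds by presence/absence so no training fold is single-class; the fold
assignment depends only on the response and the seed, hence is identical
across predictor sets and techniques, giving the paired design that the
Wilcoxon comparisons require. The 10-occurrence modelling filter applies to
the full dataset; training folds, which hold 90% of the data, are exempt
from it. Abiotic standardization is recomputed on each training fold.

## Stacking and evaluation

Per-site community predictions use threshold-independent stacking: the
predicted richness is $\operatorname{round}(\sum_s p_s)$ and the community
is the richness top-ranked species, ties broken by species-id order. A
seeded Bernoulli resampling variant is available behind
`method = "resample"`; the deterministic rank form is the default because
it is exactly testable. Evaluation uses the Sørensen index
$2a/(2a+b+c)$ (two empty sets count as agreement 1, logged when it occurs),
signed richness residuals (predicted − observed; the convention is recorded
in the report, and medians of absolute residuals do not depend on it),
rank-based AUC with ties counted ½, paired Wilcoxon signed-rank tests
(zero differences dropped, exact null for $n \le 25$ without ties,
two-sided) and Kruskal-Wallis comparisons across butterfly families. All
rank statistics are checked against exhaustive enumeration oracles at
$n \le 10$.

## The synthetic generator

Because the motivating field data are not redistributable, every test runs
on synthetic studies with known truth (`make_study()`). The generator
emulates an alpine-grassland style study and, by default: 30 plants, 40
butterflies, 150 sites; pure-birth depth-1 phylogenies; latent traits drawn
with $\lambda = 0.8$, $\sigma^2 = 1$ per dimension (within the range
reported for real plant-herbivore webs); link parameters $\alpha = -1$,
$\beta = (1, 0.5)$, $\delta = (2, 1)$ on the standardized trait scale; leaf
nitrogen $\sim N(2.5, 0.6)$ % dry mass and log-normal canopy height (median
30 cm). Site environments sit on an elevation-like gradient (degree-days
fall, moisture rises, radiation independent). Plant occupancy follows
quadratic logistic niches; butterfly occupancy adds $\gamma$ times the
true-link trophic term on the logit, with $\gamma = 3$ by default — a
trophically constrained community — and $\gamma = 0$ as the null. Species
intercepts are calibrated so each species hits a target prevalence (plants
5–50%, butterflies 15–50%): this keeps every species usable by the SDM
stage at any $\gamma$ and makes rare plants produce genuinely
never-co-occurring pairs, so the co-occurrence mask is exercised. One
global seed expands into fixed per-component substreams, making each study
bit-identical under regeneration and insensitive to the addition of new
components.

What the generator does *not* emulate: spatial autocorrelation in the
environment, detection error, the empirical dimensions or prevalences of
any real dataset, and environment-dependent link probabilities. Passing
tests therefore demonstrate the statistical machinery under the generative
assumptions, not field realism.

## Numerical and design choices

* Likelihood terms use $y x - \log(1 + e^x)$ with overflow-safe branches;
  finite parameters can never produce infinite terms.
* Trees must be ultrametric within a relative depth spread of $10^{-6}$
  ($10^{-6}$ of tree depth); beyond that the shared-time matrix is refused
  rather than silently normalized. Negative branch lengths are refused.
* The $\lambda$-covariance Cholesky in the generator adds a $10^{-10}$
  ridge, needed only at $\lambda = 1$ on deep trees.
* Proposal scales are clipped to $[10^{-3}, 10]$ during adaptation.
* Monte-Carlo standard errors in `summary()` use batch means (30 batches),
  which accounts for autocorrelation in the retained chain.
* Empty-set conventions: trophic term 0, Sørensen on two empty sets 1,
  stacking tie-break by species id.
* `uniroot` on $[-30, 30]$ calibrates each synthetic species' intercept to
  its prevalence target; the interval brackets any attainable prevalence.

## Problem sizes used in the shipped checks

The statistical acceptance checks simulate a 30 × 40 web with full and
80%-knowable masks (20,000 MCMC iterations), recover Pagel's $\lambda$ on
200-tip trees (20 replicates at each of $\lambda = 0, 0.5, 1$), and run the
full SDM comparison on 150-site landscapes with 30 butterflies (tenfold
GLM cross-validation, one constrained landscape plus ten null
repetitions). These sizes are large enough for the statistical claims to be
stable yet small enough to run on a laptop in minutes; the structural
properties (oracle equalities, masking invariance, reproducibility) are
additionally checked at small sizes in the per-module tests.

## Known limitations

* The MCMC point estimate is the posterior mean; multimodality beyond the
  handled sign/label symmetries (e.g. genuinely multimodal latent
  configurations) would be averaged over, not resolved.
* The phylogenetic regression is intercept-only per dimension; measured
  covariates are not carried into the imputation step.
* Imputation from point-estimate latents understates downstream
  uncertainty in link probabilities for imputed species.
* The trophic term uses observed plant presences; propagating plant SDM
  uncertainty into the butterfly models is out of scope.
* No spatial structure: cross-validation assumes exchangeable sites.
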