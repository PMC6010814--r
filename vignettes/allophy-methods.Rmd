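---
title: "Phylogenetic allometry with allophy: models, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic allometry with allophy: models, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allophy)
```

## The statistical model

An allometric relationship `trait = a * mass^s` is fitted on log10-log10
axes as the linear model

$$y = i + s \cdot x + \varepsilon,$$

with $y$ the log10 trait, $x$ the log10 adult mass (grams), $s$ the scaling
exponent and $i = \log_{10} a$ the scaling constant. Because species are
related, the errors are not independent: under Brownian-motion trait
evolution on a rooted phylogeny, $\varepsilon \sim \mathrm{MVN}(0,
\sigma^2 V)$ where $V_{ij}$ is the root-to-MRCA path length of species $i$
and $j$ (the shared part of their evolutionary history), $V_{ii}$ the
root-to-tip path length, and $\sigma^2$ the Brownian rate in trait variance
per unit branch length. Pagel's $\lambda$ generalizes this by multiplying
only the off-diagonal entries:

$$V_\lambda = \lambda V + (1 - \lambda)\,\mathrm{diag}(V),$$

so $\lambda = 1$ is pure Brownian motion, $\lambda = 0$ the star phylogeny
under which PGLS reduces exactly to ordinary least squares. For $\lambda \in
[0,1]$ this is a convex combination of two positive semi-definite matrices
and therefore remains a valid covariance; the package's default search
interval is $[0, 1]$ for exactly that reason, and `apply_lambda()` refuses
values outside the configured bounds.

## Estimation

Coefficients are estimated by generalized least squares,
$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$, implemented via a single
Cholesky factorization of the working covariance (`gls_solve()`); the
explicit-inverse formula is the contract checked by the test suite's
brute-force oracle. The scale is estimated from the residual quadratic form,
$\hat\sigma^2 = r^\top V^{-1} r / (n - p)$.

$\lambda$ is estimated by maximizing the restricted likelihood (REML) over
the bounded interval with Brent's method (`stats::optimize`, tolerance
1e-6), with both endpoints also evaluated so a boundary optimum is never
missed by the interior bracketing. REML is used for coefficient reporting
because it estimates the variance after profiling out the regression
coefficients; the implemented criterion is the reparameterization-invariant
(Harville) form

$$\ell_R = -\tfrac12\Big[(n-p)\big(\log 2\pi\hat\sigma^2_{R} + 1\big)
 + \log|V| + \log|X^\top V^{-1}X| - \log|X^\top X|\Big],$$

which is exactly invariant under full-rank reparameterization of the design
and under rescaling of $V$ (the scale is absorbed into the profiled
$\hat\sigma^2_R$). Model selection across covariance structures
(star, Brownian, Pagel-$\lambda$) instead uses full maximum likelihood,
because restricted likelihoods are the natural currency for variance
estimation while ML AIC is the appropriate basis for comparing covariance
families on a fixed design; the parameter count is $k = p + 1$ (residual
variance) $+ 1$ when $\lambda$ is estimated. AIC ties are broken by the
smaller parameter count, then input order.

Confidence intervals are t-intervals on $n - p$ degrees of freedom,
matching the semantics of standard GLS summaries. Clade comparison follows
the interval-overlap rule: a difference between clades is declared for a
coefficient if and only if the two confidence intervals are disjoint;
touching endpoints count as overlap. This is deliberately the study-style
inference rule rather than a formal interaction test — it is conservative,
and its operating characteristics are exercised by simulation in the test
suite (the disjointness frequency rises monotonically with the true slope
separation).

## Non-ultrametric trees

When a tree is not time-calibrated its root-to-tip distances differ between
taxa, so tip variances are unequal. The Brownian diagonal then supplies
fixed per-taxon variance weights (`fixed_variance_weights()`). Two working
covariances are available:

* `combine = "correlation"` (default): $W = D^{1/2} C_\lambda D^{1/2}$,
  where $D = \mathrm{diag}(V)$ and $C_\lambda$ is the $\lambda$-transformed
  correlation matrix derived from the Brownian matrix. At $\lambda = 1$ this
  reproduces $V$ exactly; for ultrametric trees it coincides with applying
  $\lambda$ to $V$ directly.
* `combine = "weights-only"`: the pure diagonal $D$ — taxa treated as
  independent with unequal variances.

The combined form is the default because it retains both the unequal tip
variances and the shared-history correlation; the weights-only mode is kept
for sensitivity analysis since the two readings are both defensible when
variance weights are described separately from the correlation structure.
`fit_pgls()` engages weights automatically (`use_weights = "auto"`) whenever
the tip variances are unequal beyond a 1e-8 relative spread.

## Trees: reading, pruning, merging

Newick parsing, pruning and the Brownian matrix go through `ape`
(`read.tree`, `keep.tip`, `vcv.phylo`) behind validating wrappers that
enforce the package's invariants: unique tip labels after whitespace /
underscore normalization, finite non-negative branch lengths, and positive
root-to-tip depths for covariance work. Missing branch lengths default to 1
with a warning — consistent with the unit-branch convention used for
composite trees — and are rejected in strict mode. Pruning preserves
patristic distances exactly because suppressed degree-two nodes have their
branch lengths summed; this is asserted against an independent path-sum
oracle in the tests. Polytomies are accepted as-is: nothing in the GLS
algebra requires binary trees.

Pooled analyses across clades whose source trees sit on incomparable
branch-length scales use a composite tree: each backbone tip (default
backbone `(Squamata,(Testudines,Crocodilia));`, configurable) is replaced by
its clade's topology and every branch length is set to unity
(`mode = "unit-all"`). A `retain-subtree-lengths` mode keeps within-clade
branch lengths, for users whose subtrees share a common scale; unit-all is
the default because it is the only defensible choice when the scales are
incommensurable. A unit-branch composite is ultrametric only when all tips
sit at the same edge depth, which is why the pooled fit estimates $\lambda$
on that tree rather than assuming pure Brownian motion.

## The synthetic-data generator

`simulate_allometric_dataset()` reproduces exactly the structure the
analysis assumes: an ultrametric pure-birth tree (exponential waiting times
between birth events, via `ape::rphylo`), log10 masses drawn uniformly over
a configurable range, and

$$\log_{10}\mathrm{trait} = i + s\,\log_{10}\mathrm{mass}
 \,(+\, b_{\mathrm{alt}}\,\log_{10}\mathrm{altitude}) + \varepsilon,
 \qquad \varepsilon \sim \mathrm{MVN}(0, \sigma^2 V_\lambda).$$

Defaults are `n_tips = 128`, `s_true = 0.75`, `i_true = 0`,
`sigma2 = 0.1`, `lambda_true = 0.8`, masses spanning five orders of
magnitude (1 g to 100 kg) — the span and noise level a comparative reptile
dataset of this kind realistically exhibits, and the conditions at which the
package's recovery experiments are run. `sigma2 = 0` is accepted as the
exact noiseless limit (the dataset then lies exactly on the generating
line), although as a generative default the rate is strictly positive.
Missingness is applied completely at random at a configurable fraction;
structural missingness (a trait absent for a whole clade, as happens for
crocodilian birth traits in real data) is emulated by knocking a trait out
of one clade's rows, and the pipeline reports such cells as
"insufficient data" while continuing.

What the generator does *not* emulate: clade-specific trait distributions,
empirical tree shapes (it uses pure-birth trees only), measurement error,
and non-random missingness mechanisms. Passing recovery tests therefore
demonstrates the estimators are correct under the model's own assumptions —
not that real data meet those assumptions.

Reproducibility contract: every simulator is a pure function of its
arguments and an integer seed; sub-streams for masses, altitude, errors and
missingness are derived deterministically from the root seed, and replicate
$r$ of experiment cell $c$ uses seed `seed + 1000 * c + r`.

## Numerical choices and degenerate inputs

* All solves use Cholesky factorizations; a failed factorization is
  reported as a degenerate covariance, distinctly from a rank-deficient
  design (collinearity).
* A perfect fit yields $\hat\sigma^2 = 0$ and degenerate zero-width
  intervals at the estimate; coverage bookkeeping in
  `recovery_experiment()` allows a 1e-10 slack so that this boundary case
  counts as covering the truth.
* Zero-depth tips (a tip at distance 0 from the root) are refused when
  building covariances — their Brownian variance would be 0.
* Fits are refused below 4 complete species for the univariate allometry
  (5 for the altitude model), mirroring the practical limit at which
  clade-level regressions stop being meaningful.
* Tip-label matching between tables and trees is exact after whitespace /
  underscore normalization; case is preserved.

## Validation surface and problem sizes

The test suite validates each layer against an independent oracle computed
a different way: MRCA depths and patristic distances by explicit path
walks over the edge matrix; the GLS estimator by naive dense inversion of
the normal equations (200 random problems, relative tolerance 1e-8); REML
against the textbook iid-error formula and its invariance identities; the
whole REML-$\lambda$ fit against `nlme::gls` with `ape::corPagel` — the
standard route practitioners use — agreeing on coefficients, standard
errors, $\hat\lambda$ and intervals. Statistical performance is checked at
the generator's default conditions: slope CI coverage within [90%, 99%] of
nominal 95% over 500 replicates at $n = 128$, mean slope within 0.02 of the
truth, mean $\hat\lambda$ within 0.1, and AIC selection frequencies over 200
replicates per signal regime. At $n = 32$ the REML $\hat\lambda$ is noisy
and may be biased; the suite asserts only that its median is monotone in the
generating $\lambda$, which is the property that matters for interpretation
at small sample sizes. These sizes keep the full suite around a minute on a
single CPU while leaving the Monte-Carlo error well inside the asserted
bands.

## Known limitations

* No Ornstein–Uhlenbeck, early-burst or measurement-error covariance
  models; no multivariate-response PGLS; no phylogenetic ANOVA.
* No tree inference, dating or calibration; trees are taken as given.
* $\lambda$ is estimated per fitted model, not shared across traits.
* The mammal/bird reference allometries shipped by
  `amniote_allometries()` are literature constants for overlay only — the
  package never refits those groups.
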