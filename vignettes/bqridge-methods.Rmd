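---
title: "Bootstrap-quantile selection of the ridge biasing parameter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-quantile selection of the ridge biasing parameter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its canonical form

The package works with the no-intercept linear model

$$ y = X\beta + \varepsilon, \qquad \mathbb{E}\varepsilon = 0,\ \operatorname{Var}\varepsilon = \sigma^2 I_n, $$

with an $n \times p$ design $X$, $n > p$. When predictors are collinear,
$X'X$ has near-zero eigenvalues and the OLS estimator
$\hat\beta = (X'X)^{-1}X'y$ becomes unstable. Ridge regression replaces it
by $\hat\beta(k) = (X'X + kI_p)^{-1}X'y$ with a biasing parameter
$k \ge 0$.

Everything is computed in the canonical rotation: with
$X'X = U \Lambda U'$, $\Lambda = \mathrm{diag}(\lambda_1 \ge \dots \ge
\lambda_p)$, set $Z = XU$ and $\alpha = U'\beta$. The ridge estimate then
separates coordinate-wise, $\hat\alpha(k)_w = (Z'y)_w/(\lambda_w + k)$, and
its exact mean squared error given the truth is

$$ \operatorname{MSE}(\hat\alpha(k)) \;=\;
   \sigma^2 \sum_w \frac{\lambda_w}{(\lambda_w + k)^2}
   \;+\; \sum_w \frac{k^2 \alpha_w^2}{(\lambda_w + k)^2}, $$

which at $k = 0$ reduces to the OLS risk $\sigma^2 \sum_w 1/\lambda_w$ and
is minimised coordinate-wise at $k_w = \sigma^2/\alpha_w^2$. This formula
(`theoretical_mse()`) is the comparison currency of the whole package: the
quantile-selection strategies evaluate it, the fit report prints its
plug-in version, and the simulation engine checks empirical MSEs against
it.

Two numerical conventions make results reproducible across platforms: the
sign of each eigenvector column is fixed so that its largest-magnitude
entry is positive, and an eigenvalue below $10^{-10}\lambda_{\max}$ is
treated as zero (OLS then refuses with a singularity error naming the
coordinate; ridge with $k > 0$ remains computable). The error variance is
estimated by the unbiased residual mean square
$\hat\sigma^2 = \sum_j \hat\varepsilon_j^2 / (n - p)$.

## The classical rules for k and their bootstrap-quantile versions

All rules start from the canonical OLS coefficients $\hat\alpha$ and
$\hat\sigma^2$. With $\hat k_w = \hat\sigma^2 / \hat\alpha_w^2$:

| rule | value | relation to $\hat k_w$ |
|------|-------|------------------------|
| HK   | $\hat\sigma^2 / \max_w \hat\alpha_w^2$ | minimum |
| HKB  | $p\hat\sigma^2 / \sum_w \hat\alpha_w^2$ | harmonic mean |
| HSL  | $\hat\sigma^2 \sum_w (\lambda_w\hat\alpha_w)^2 / \bigl(\sum_w \lambda_w\hat\alpha_w^2\bigr)^2$ | eigenvalue-weighted |
| AM   | $\tfrac1p \sum_w \hat\sigma^2/\hat\alpha_w^2$ | arithmetic mean |
| GM   | $\hat\sigma^2 / \bigl(\prod_w \hat\alpha_w^2\bigr)^{1/p}$ | geometric mean |

The mean inequality gives the ordering HK $\le$ HKB $\le$ GM $\le$ AM on
every dataset; HSL is not comparable in general. "Max" in HK is the
largest-magnitude coefficient (only its square enters, so a sign-sensitive
reading would be arbitrary). GM's product is evaluated in log space.
Coefficients smaller than $10^{-12}$ in magnitude make the
ratio-type rules (per-coordinate, AM, GM) undefined; they raise a
degeneracy error rather than returning infinity.

The bootstrap-quantile (BQR) version of any rule resamples the $(X_j, y_j)$
pairs with replacement $B$ times (case resampling, preserving the joint
row structure), evaluates the rule on each resample, sorts the replicates
$\hat k^{*(1)} \le \dots \le \hat k^{*(B)}$, and replaces the full-sample
value by an empirical quantile $\hat k^*_\gamma$. The intuition: on
collinear data the sampling distribution of every rule is strongly
right-skewed, and values deeper in its upper tail — larger than the rule
itself dares to pick — usually buy more variance reduction than the bias
they cost.

**Quantile convention.** No interpolation: $\hat k^*_\gamma$ is the order
statistic with index $\lceil \gamma B \rceil$. This satisfies the defining
inequality $P(\hat k^* < \hat k^*_\gamma) \le \gamma \le P(\hat k^* \le
\hat k^*_\gamma)$ on the empirical distribution, returns an actually
realised value, and is exactly reproducible.

**Choosing the level.** A "best" $\gamma$ cannot be defined through the
true MSE on real data, since the true $(\alpha, \sigma^2)$ are unknown; the
package therefore makes the choice explicit as three strategies:

* `fixed` — the user supplies $\gamma$;
* `min_estimated_mse` — evaluate the MSE formula with plug-in
  $(\hat\alpha_{OLS}, \hat\sigma^2, \lambda)$ at each candidate quantile
  over the default grid $\gamma \in \{0.50, 0.55, \dots, 0.95\}$ and take
  the minimiser (the real-data default, used by `fit_report()`);
* `oracle` — the same search with the true $(\alpha, \sigma^2)$, available
  only in simulations, where it isolates how much the bootstrap
  distribution itself could deliver under an ideal level choice.

The grid covers the upper half of the unit interval because upper
quantiles are where improvement is found in practice; ties in the
criterion break toward the largest $\gamma$. Degenerate resamples are
redrawn with a counted budget of $10B$; the count is reported. Within a
simulation replication the same $B$ resamples are shared by all five
rules, so between-rule comparisons are not polluted by independent
resampling noise.

In `fit_report()` the candidate set additionally contains the baseline
$\hat k$ itself, so the reported BQR row is never worse than its baseline
in plug-in MSE; when the baseline wins, the reported $\gamma$ is `NA`.

## What the synthetic-data generator emulates

`generate_design()` builds collinear Gaussian predictors from a shared
extra latent column,

$$ x_{jw} = (1-\rho^2)^{1/2} z_{jw} + \rho\, z_{j,p+1},
   \qquad z \sim \text{iid } N(0,1), $$

the standard construction of the ridge simulation literature (McDonald &
Galarneau 1975; Kibria 2003). Every column has unit variance and every
pair of columns has correlation $\rho^2$, so $\rho = 0.99$ produces
pairwise correlations of about $0.98$ and a condition number in the
thousands at $n = 25$. A `self_referential` variant, in which the shared
component is the last design column itself (so the off-diagonal structure
mixes $\rho^2$ and $\rho$ and the last column has inflated variance),
appears in print in parts of the applied literature and is provided for
comparison; the shared-extra form is the default because its exchangeable
structure is what the classical simulation designs define and what the
large-sample OLS risk values of those designs correspond to.

The true coefficient vector is the unit-norm eigenvector of the realised
$X'X$ for $\lambda_{\max}$ — again the convention of that literature — so
$\beta'\beta = 1$ and the canonical truth is $\alpha = (1, 0, \dots, 0)$:
all signal sits in the best-conditioned direction and the ill-conditioned
directions carry pure noise. This is the configuration in which ridge
shrinkage is most clearly beneficial; results under a different $\beta$
convention (e.g. the $\lambda_{\min}$ eigenvector) would be less
favourable to heavy shrinkage, and the package accepts any fixed `truth`
through the oracle interface.

Error laws: `normal` is $N(0, \sigma^2)$; `t2` is a raw $t(2)$ draw — its
variance is infinite, so no variance standardisation exists and the
nominal $\sigma^2$ is ignored; `f4_16` is $F(4,16)$ standardised
analytically to mean $0$, variance $1$ (mean $16/14$, variance
$2\cdot16^2\cdot18/(4\cdot14^2\cdot12)$), a strongly right-skewed error.

What the generator does **not** emulate: fixed or non-Gaussian designs,
heteroscedastic or autocorrelated errors, model misspecification, and
signal spread across several canonical directions. Passing simulation
tests therefore demonstrate correct behaviour under this specific
exchangeable-collinearity model, not robustness on arbitrary real data.

## The Monte Carlo engine and evaluation criteria

`run_scenario()` repeats, $M$ times: fresh design, fresh truth, fresh
errors; canonical OLS; the five baseline ridge fits; and (optionally) the
five BQR fits from one shared set of $B$ bootstrap resamples. It reports
the empirical MSE
$\frac1M \sum_v \sum_w (\hat\alpha_{vw} - \alpha_{vw})^2$ per estimator,
its Monte Carlo standard error (so that differences can be judged against
resampling noise), and the percentage reduction
$P_{MSE} = 100\,(\text{MSE} - \text{MSE}^*_\gamma)/\text{MSE}$ of each BQR
version over its baseline. Every replication derives its own seed from the
scenario seed, so results are independent of execution order and exactly
reproducible. `run_case_grid()` expands the standard evaluation grids:
$(n,p) \in \{(25,4), (50,8), (100,10)\}$ crossed with
$\sigma^2 \in \{0.5, 1, 5\}$ and $\rho \in \{0.70, 0.80, 0.90, 0.99\}$,
plus a large-sample grid $n = 200$, $\rho = 0.99$,
$p \in \{4, 8, 10, 16, 32\}$.

Default study sizes are $M = 1000$ Monte Carlo replications and $B = 200$
bootstrap resamples. The test suite runs the full small-sample grid at
$M = 200$, which it states explicitly; the headline scenarios are run at
the full $M = 1000$.

Two empirical regularities are worth recording. First, with oracle level
choice every BQR estimator beats its baseline in every cell of the
small-sample grid — the central claim, and a property the test suite
asserts strictly. The size of the gain is grid-limited, however: at
$\rho = 0.99$, $n = 25$, the oracle-over-grid BQR version of HK removes
roughly 35--45% of the baseline MSE, because even the $0.95$ quantile of
the HK bootstrap distribution rarely reaches the $k$ that the true MSE
curve would prefer; levels nearer $1$ (or wider candidate sets) would be
needed for reductions in the 80--90% range. Second, the AM rule is an
outlier in the noiseless limit: because $k_{AM}$ is an average of ratios
whose numerators and denominators both vanish with $\sigma^2$, it does not
collapse to OLS as noise disappears, and its baseline MSE is dominated by
occasional extreme over-shrinkage; its BQR version repairs exactly this
instability, which is why AM shows the largest relative gains.

## Real-data workflow

`load_regression_csv()` ingests a numeric CSV, refuses missing or
non-numeric entries naming the offending cell, and by default centres the
response and centres + unit-length-scales the predictors. That puts
$X'X$ in correlation form, removes the intercept, and makes $k$ values
comparable across datasets; the preprocessing record is kept so
predictions return to the original scale. Diagnostics are the classical
ones: the condition number $\lambda_{\max}/\lambda_{\min}$ of $X'X$ and
variance inflation factors $1/(1 - R_w^2)$ (infinite, not an error, under
perfect collinearity). `fit_report()` prints, for OLS, the five baselines
and their BQR versions, the ridge parameter (2 decimals displayed, full
precision retained), the plug-in estimated MSE — the only MSE available
when the truth is unknown, and therefore an optimistic, model-trusting
quantity — and the coefficients on the preprocessing scale.

## Known limitations

* The plug-in MSE criterion inherits the noise of $\hat\alpha_{OLS}$ and
  $\hat\sigma^2$; on severely ill-conditioned data it can misrank
  candidate levels. The oracle strategy brackets what better level
  selection could achieve.
* The pairs bootstrap assumes exchangeable rows; it is not a wild
  bootstrap and offers no protection under heteroscedasticity.
* Empirical MSEs under $t(2)$ errors average a statistic whose population
  counterpart is infinite-variance; Monte Carlo summaries are then
  heavy-tailed and seed-sensitive, and their standard errors should be
  read with caution.
* Scalar $k$ only: the per-coordinate rule is exposed as a utility, but
  generalised ridge with a data-driven diagonal $K$ is out of scope.
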