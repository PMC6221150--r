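---
title: "Threshold analysis for network meta-analysis: models, influence and decision-invariant regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold analysis for network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threshnma)
```

## Why thresholds

Network meta-analysis (NMA) synthesises randomised trials on K treatments
into a coherent set of relative effects, and a recommendation is read off
the joint posterior: the treatment with the best expected effect. Qualitative
risk-of-bias assessment cannot say whether a suspect study actually matters
for that recommendation. Threshold analysis asks the converse question: for
each piece of evidence, how large an additive bias adjustment would be
needed to change the recommended treatment, and to what? Evidence with huge
thresholds can be deprioritised in quality assessment no matter how flawed;
evidence with thresholds inside its own confidence interval makes the
decision sensitive to mere sampling noise.

This vignette records the package's own account of the method: the models,
the influence algebra, the contrast-level reconstruction, and every
numerical and design choice a maintainer might want to revisit.

## Models and assumptions

Relative-effect data are stacked study by study: a study with $A_j$ arms
contributes $A_j - 1$ effects against its baseline arm, giving
$y \sim N(\delta, V)$ with $V$ block diagonal (studies independent; within
a multi-arm study the shared baseline induces the off-diagonal covariance,
which must be supplied or induced from arm-level data — the package never
approximates it). Treatment 1 is the network reference; the basic
parameters are $d = (d_2, \dots, d_K)$ with $d_1 = 0$ and any contrast
$d_{ab} = d_b - d_a$ by consistency. Two fittable likelihood structures:

* **Fixed effect (FE):** $\delta = Xd$ with signed-incidence design $X$.
* **Random effects (RE):** $\delta \mid d, \tau^2 \sim N(Xd,
  \Sigma_{\tau^2})$, where $\Sigma_{\tau^2}$ is block diagonal with
  $\tau^2$ on the diagonal and $0.5\tau^2$ off it inside multi-arm blocks
  (homogeneous between-study variance; the algebra is unchanged for a
  generic user-supplied heterogeneity covariance).

With a normal prior $d \sim N(d_0, \Sigma_d)$ both posteriors are available
in closed form; the RE model keeps $\tau^2$ **known and fixed, unchanged by
bias adjustment** — the assumption that preserves conjugacy. This is an
approximation to the usual hierarchical analysis with a prior on $\tau$; it
should be checked by rerunning at plausible values (`tau2_sensitivity()`
accepts, e.g., the limits of the credible interval for $\tau$ from the
original analysis). There is empirical evidence that heterogeneity is larger
in biased evidence, so values below the lower credible limit are also worth
probing.

The frequentist GLS fit is the $\Sigma_d^{-1} = 0$ limit (the
`improper = TRUE` prior); the default proper prior is $d_0 = 0$,
$\Sigma_d = 10^6 I$, the conventional diffuse choice on a log-odds or
standardised-mean-difference scale.

Extended models add parameters $\mu$ (study baselines for arm-level data,
covariate effects) with designs $L$, $M$:
$y \mid \delta, \mu \sim N(L\delta + M\mu, V)$. Class-effect models
($d \mid z \sim N(Zz, \Sigma_{class})$) are handled by two reductions: for
exchangeable classes the hierarchical prior marginalises to the normal
prior $N(Zz_0, \Sigma_{class} + Z\Sigma_z Z^\top)$; for fixed classes
($\Sigma_{class} = 0$) the model is fitted in class space with design $XZ$
and mapped back through $d = Zz$. Both routes are verified against the
refit oracle, as the influence-equivalence of class models predicts. The
between-treatment covariance is called `Sigma_class` throughout to keep it
distinct from the prior covariance $\Sigma_d$.

## Thresholds and the influence matrix

Every supported model satisfies the exact linear identity
$\tilde E(d) = E(d) + H\beta$ for bias-adjusted data $\tilde y = y + \beta$.
The candidate solutions $u_{ak^*,m}$, thresholds, invariant intervals and
new optima follow as described in the README; the new optimum at a
threshold is read directly from the contrast whose expectation changes sign
there, which the test suite confirms empirically by refitting just beyond
every finite threshold.

Decision-rule conventions:

* `lower_better` outcomes are handled by negating $(E, H)$ internally and
  applying the higher-better formulas; the resulting $u$ are adjustments to
  the data on their original scale, so no back-transformation is applied.
* The minimal clinically important difference $\rho$ enters the numerator
  as $-E(d_{ak^*}) - \rho$ off the reference branch and $-E(d_{1a}) + \rho$
  on it; $\rho = 0$ reproduces the plain analysis exactly (tested as an
  identity).
* A candidate solution of exactly 0 means the decision is tied at the
  observed data; it is reported as a zero threshold with a warning rather
  than as an error.
* A zero influence difference makes a treatment unreachable through that
  datum: $u = \pm\infty$, and a side with no finite solution is an open
  ("NT") side of the invariant interval. Printed intervals use two decimals
  with signed zero preserved, so a threshold of $-0.004$ prints as
  $-0.00$.
* Ties in the argmax are broken to the lowest treatment code and flagged.

A common bias applied to an index set $M$ sums the individual influences,
so solutions combine harmonically,
$u_{a,M} = (\sum_{m \in M} u_{a,m}^{-1})^{-1}$ with $\infty^{-1} = 0$;
singleton sets reduce to the per-datum analysis (tested as an identity).

## Contrast-level analysis from a reported posterior

When only the posterior mean and covariance of $d$ are available — the
typical situation with a published NMA fitted by MCMC — no study-level
influence matrix exists, and the package deliberately refuses to guess one:
`nma_influence()` on an external posterior directs the user to the
contrast-level pathway. There, a hypothetical data set of one *independent*
point per contrast with direct evidence is constructed such that its FE
pooling approximates the reported posterior. Only the variances matter:
thresholds never need the hypothetical data values themselves.

Numerical choices in the reconstruction:

* The weight system $\sum_c w_c x_c x_c^\top = \Sigma^{-1} - \Sigma_d^{-1}$
  is half-vectorised with $\sqrt 2$ scaling of off-diagonal entries so the
  least-squares objective equals the Frobenius matrix residual, and solved
  by non-negative least squares (`pracma::lsqnonneg`).
* Weights below $10^{-12}$ of the largest are truncated to zero (infinite
  variance) to avoid absurd pseudo-evidence from numerical dust.
* A target precision that is not positive semi-definite (tolerance
  $10^{-8}$ relative) means the assumed prior is more informative than the
  posterior; the error says to supply a flatter prior.
* The KL adequacy diagnostic is computed as KL(reconstructed ∥ true).
  The reconstruction matches covariances only, so the mean term is taken as
  zero ($\hat\eta := \eta$); with `verbose = TRUE`, `kl_diagnostic()` also
  reports the reverse direction, since either reading of "divergence of the
  reconstructed posterior from the true posterior" is defensible and the
  two differ in general. Verdicts follow the log-Bayes-factor bands: good
  below 1, fair in $[1, 3]$, poor above 3.
* Invariant intervals at contrast level are anchored at the posterior
  contrast means $E(d_{ab})$ (the natural display when the hypothetical
  data are unknown), with 95% credible intervals from the posterior
  covariance.

On a complete network the reconstruction is exact, and contrast-level
thresholds coincide with study-level thresholds when each edge carries
exactly one study — both facts are enforced by tests.

## Simultaneous adjustments

Allowing $r$ components of $\beta$ to be non-zero replaces threshold points
with hyperplanes $\beta^\top w_a = 1$, $[w_a]_i = u_{a,i}^{-1}$. In two
dimensions the invariant region is the intersection of the half-planes
containing the origin, computed by Sutherland–Hodgman clipping of a large
bounding box (no computational-geometry dependency is needed for convex
clipping); edges are labelled with the new optimum whose constraint is
active, the region is flagged open when box edges survive, and treatments
with all-infinite solutions are dropped as unreachable. Axis crossings of
the region reproduce the one-dimensional invariant intervals exactly
(restriction consistency), and convexity holds by construction.
Visualisation stops at two dimensions; for larger $r$, `beta_min()` reports
the closest point of each hyperplane to the origin,
$\beta^{min}_a = w_a / \|w_a\|^2$ — the smallest overall simultaneous
adjustment that makes $a$ optimal — sorted by norm.

## What the generator emulates — and what it does not

`sim_spec()`/`generate()` draw data *exactly* from the stated hierarchy:
random connected networks (redrawn until connected) of two- and three-arm
studies, per-arm variances uniform on a chosen range inducing proper
multi-arm covariance blocks with the shared-baseline off-diagonals, study
effects with the $0.5\tau^2$ multi-arm correlation, and normal sampling
error. Defaults — 3–6 treatments, 5–20 studies, a quarter of studies
three-arm, arm variances 0.05–0.3 on the linear-predictor scale — are
typical of moderate evidence bases of log-odds-ratio or SMD data. The
acceptance run uses a 6-treatment, 14-study network (one in ten studies
three-arm) as its standing example of a realistic decision problem, and a
4-treatment, 10-study configuration replicated 150 times for coverage
calibration; test networks go up to $K = 6$, $N \approx 25$.

Because the generator *is* the model, passing tests demonstrate the
algebra, not robustness to real-data pathologies: no skewness or
non-normality of effect estimates, no small-study effects, no inconsistency
between direct and indirect evidence, no misreported or missing
covariances, and binary outcomes are not simulated at the arm level (the
package works on the normal approximation throughout, as NMA practice does
after transformation). Conclusions about real data rest on the adequacy of
those standard approximations, not on anything tested here.

## Numerical choices

* All symmetric positive-definite solves go through one Cholesky helper;
  a condition number above $10^{10}$ triggers a warning, and singular
  systems are rejected with the approximate null-space direction named so
  disconnected-parameter problems are actionable.
* The RE joint posterior is obtained by inverting the assembled
  $(d, \delta)$ precision; its independent check in the tests is the
  analytically distinct marginal route $y \mid d \sim N(Xd, V +
  \Sigma_{\tau^2})$.
* The bisection oracle (`numerical_threshold_oracle()`) — the expensive
  numerical route the influence algebra replaces — grows a bracket
  geometrically from $10^{-6}$ to $10^{6}$ and bisects to a relative width
  of $10^{-10}$; the acceptance suite requires agreement with the algebraic
  thresholds to $10^{-6}$ relative on 50 random FE and RE networks.
  Algebraic thresholds beyond $10^{5}$ are treated as operationally
  open-sided when compared with the oracle, since no plausible bias
  adjustment reaches them.
* Influence matrices are computed once per fitted model and reused across
  all data points; thresholds never trigger refits.
* CSV serialisation writes floats with 17 significant digits so a
  write/read round trip reproduces $y$ and $V$ bit-for-bit; missing
  covariance cells in multi-arm blocks default to zero with a warning,
  since real data extractions routinely omit them.

## Interface choices

The package follows the classic R modelling idiom — `nma_fit()` returns a
classed object with `coef`/`vcov`/`print`/`summary`, analyses return
classed tables with `print`/`plot` — rather than providing a shell
executable; evidence-synthesis practitioners work in R, and scripted use
is a one-liner (`run_study_level(read_network("data.csv"), ...)` followed
by `render_forest()`, which writes CSV, markdown or a plot). Both data
pathways (relative effects with explicit covariance columns, and arm-level
estimates differenced against the study baseline) are exposed because the
literature reports both and neither can be recovered from the other.

## Known limitations

* $\tau^2$ is never estimated and its own sensitivity to bias adjustment
  is ignored (the fixed-$\tau^2$ approximation); use the sensitivity
  sweep.
* Exact binomial/Poisson likelihoods are out of scope; everything works on
  the normal approximation.
* The contrast-level reconstruction can be poor (KL > 3) for highly
  irregular posteriors; the diagnostic is reported precisely so that such
  analyses are not trusted silently.
* Threshold hyperplanes beyond $r = 2$ are computed but not visualised;
  interpretation in high dimensions is genuinely hard and is better
  approached by targeted subsets or by modelling bias explicitly within
  the NMA.
* Decision rules beyond maximal expected effect (with optional MCID) —
  net-benefit, equivalence-margin recommendations — are not implemented,
  though the solution-set interface (`solution_set()`,
  `common_bias_solution_set()`) exposes the building blocks they would
  need.
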