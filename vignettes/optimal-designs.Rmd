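---
title: "G- and D-optimal designs for hierarchical models with a competitive swarm optimizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G- and D-optimal designs for hierarchical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The design problem

csodesign computes approximate experimental designs for hierarchical
(random-coefficient) linear models

$$y_{ij} = f(x_j)^T \beta_i + \varepsilon_{ij}, \qquad
  j = 1, \dots, m, \; i = 1, \dots, n,$$

where each of $n$ individuals is observed $m$ times under a common
regime, the individual coefficient vectors $\beta_i$ have mean $\beta$
and covariance $\sigma^2 D$ (with $D$ known and possibly singular), and
the errors are homoscedastic with variance $\sigma^2$.  An approximate
design $\xi$ is a probability measure on a compact box
$\mathcal{X}$ — support points $x_l$ with weights $w_l$ — and is stored
here as a tibble with columns `x1..xd` and `weight`, so designs pipe
directly through the criterion, certification, and plotting functions.

Two prediction criteria are implemented.  Writing
$M(\xi) = \sum_l w_l f(x_l) f(x_l)^T$ for the standardized information
matrix, $\Delta = mD$, and
$N(\xi, \Delta) = \Delta - \Delta (M^{-1}(\xi) + \Delta)^{-1} \Delta$
(a form that stays valid when $D$ is singular), the prediction variance
function is

$$\phi(x, \xi) = f(x)^T M^{-1}(\xi) f(x)
  + (n - 1)\, f(x)^T N(\xi, \Delta) f(x),$$

and the **G-criterion** is $\psi_G(\xi) = \max_{x \in \mathcal{X}}
\phi(x, \xi)$: the worst-case summed squared error of the individual
response predictions.  A G-optimal design minimizes it.  The criterion
obeys the lower bound
$\psi_G(\xi) \ge p + (n-1)\,\mathrm{tr}\{(M^{-1} + \Delta)^{-1}\Delta\}$
(`g_lower_bound()`); a design attaining the bound at its support points
is optimal, and the reported `gap` is a useful convergence diagnostic.

The **prediction D-criterion** (`d_pred_criterion()`) is

$$\psi_D(\xi) = \frac{1}{m}\Big[\ln\det M^{-1}(\xi)
  + (n-1) \ln \prod_{l=1}^{q} \lambda_l(\xi, \Delta)\Big],$$

with $\lambda_1 \ge \dots \ge \lambda_q$ the $q = \mathrm{rank}(D)$
largest eigenvalues of $N(\xi, \Delta)$; these are exactly the
log-volumes of the prediction MSE matrix restricted to its
$(n-1)q + p$ informative eigendirections.  The $1/m$ factor is a
deliberate standardization: it is the scale on which the worked
examples this package reproduces report their criterion values, and
being a positive constant for a fixed model it changes neither the
optimal design nor the ordering of designs.  `pred_efficiency()`
converts criterion differences into efficiencies:
$\psi_G(\xi_{ref})/\psi_G(\xi)$ for G, and
$\exp\{m[\psi_D(\xi_{ref}) - \psi_D(\xi)]/((n-1)q + p)\}$ for D — the
latter is a package convention (a volume ratio per informative
dimension), since no standard definition exists for mixed-model
prediction efficiency.

## Certifying G-optimality

G-optimality has a first-order certificate even though the criterion is
non-differentiable.  The *answering set* $A(\xi)$ collects the points
where $\phi(\cdot, \xi)$ attains its maximum; a design $\xi^*$ is
G-optimal if and only if some probability measure $\mu^*$ on
$A(\xi^*)$ makes the sensitivity function

$$s(x) = f^T M^{-1} M_A(\mu) M^{-1} f
  + (n-1) f^T N M_A(\mu) N f
  - \mathrm{tr}\{M_A(\mu) M^{-1} + (n-1) M N M_A(\mu) N\}$$

nonpositive on all of $\mathcal{X}$, where
$M_A(\mu) = \sum_j w_{\mu j} f(a_j) f(a_j)^T$.  At the optimum the
support points of $\xi^*$ are roots of $s$.  `verify_g_optimality()`
automates the pipeline:

1. `answering_set()` locates $A(\xi)$ by splitting the box into
   sub-boxes (2 per axis, doubling until the set size is stable for two
   rounds), maximizing $\phi$ on each, and keeping points with
   $\phi \ge \bar\phi(1 - 10^{-4})$, merged within `1e-4` of the factor
   range.
2. `find_mu()` searches for $\mu^*$ over the weight simplex with the
   swarm optimizer (64 particles, social factor 0.05), first minimizing
   the design-weighted squared residuals of $s$ at the support points —
   which is cheap because $s$ is *linear* in the weights of $\mu$, so
   the residuals are precomputed coefficient matrices times the weight
   vector — then the full loss that adds the squared supremum of $s$,
   followed by a deterministic local polish.
3. The certificate passes when $\sup_x s \le \mathrm{tol}\cdot\bar\phi$
   and $|s| \le \mathrm{tol}\cdot\bar\phi$ at every support point.  The
   default `tol = 0.02` reflects what designs reported to three
   decimals can achieve; machine-precision designs certify at far
   tighter tolerances, as the closed-form examples in the test suite
   show.

```{r}
library(csodesign)
mod <- hlm_model(poly_basis(2), D = diag(c(0.2, 0.2, 0.3)),
                 n = 10, m = 5, space = design_space(0, 2))
fit <- find_g_optimal(mod, seed = 1)
fit$report          # certificate: answering set, mu, max sensitivity
autoplot(fit)       # sensitivity curve with roots at the support
```

## The competitive swarm optimizer

The G-criterion requires nested min–max optimization, which defeats
classical exchange algorithms.  The package uses a competitive swarm
optimizer (CSO): at every iteration the swarm is randomly paired, each
pair compares objective values, winners are left untouched, and each
loser is updated by

$$v \leftarrow R_1 \circ v + R_2 \circ (x_{win} - x)
  + \gamma R_3 \circ (\bar{x} - x), \qquad x \leftarrow x + v,$$

with fresh uniform $R_1, R_2, R_3$ and the swarm center $\bar{x}$.
Defaults follow the tuning the method is known to work well with at
these dimensions: $\gamma = 0$, 128 particles, at most 350 iterations,
convergence when the best value changes by less than $10^{-6}$ (for
robustness we require 50 such consecutive iterations rather than one).
Choices the method's description leaves open are fixed as follows, for
reproducibility: initial velocities are zero (uniform random available
via `velocity_init`), positions are clipped to the box with the
violating velocity component zeroed, and design weights are
parameterized as raw coordinates $r_l \in [0,1]$ mapped to the simplex
by $w_l = r_l / \sum_j r_j$ (an all-zero vector falls back to uniform
weights).  Searches are multi-restart (`restarts`, each run drawing
from one seeded stream) because a swarm can stall on hard landscapes;
every result is certified rather than trusted.

## Numerical choices that matter

**Honest inner maximization.**  Evaluating
$\max_x \phi$ by taking the best point of a dense grid — even with one
local polish — is not good enough here, for an instructive reason: the
outer minimizer will park designs so that the sharp peaks of $\phi$
fall *between* grid nodes, "optimizing" an underestimate.  The
fractional-polynomial models make this visible: $\phi$ near its peaks
is sharp enough that third-decimal movements of a support point shift
the criterion in its second decimal (compare the acceptance artifacts'
evaluations at three-decimal rounded designs with the certified search
optima).  `g_criterion()` therefore
refines *every* local maximum of the grid (parabolic interpolation of
the three neighboring nodes, then exact re-evaluation at the refined
points, then a bounded local polish of the winner).  For one- and
two-factor spaces this is deterministic; three or more factors use a
seeded inner swarm with local polish.

**Regularization only where it belongs.**  During the swarm phase,
information matrices are stabilized as $M + 10^{-7} I$ so that
transient singular candidates do not derail the search.  The final
Nelder–Mead polish and all certification run *unregularized*: a ridge
biases the criterion downward precisely in the near-singular
configurations a minimizer likes, and polishing against it chases that
bias instead of the optimum.  Singular candidates simply score
$+\infty$ and lose their competitions.

**Other fixed choices.** $\mathrm{rank}(D)$ uses an eigenvalue
threshold of $10^{-10}$ times the largest eigenvalue.  Designs are
cleaned by merging support points within $10^{-4}$ of the factor range
and pruning weights below $10^{-4}$, matching three-decimal reporting
precision.  `round_to_exact()` converts weights to $N$ replicates by
largest-remainder apportionment (ties to the larger weight, then the
earlier point) because naive per-point rounding need not sum to $N$.
Fractional-polynomial powers are validated against the conventional set
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (power 0 is $\ln x$; repeated
powers multiply by $\ln x$), with arbitrary reals admitted via
`strict = FALSE`.  $\sigma^2$ defaults to 1; it scales all criteria
monotonically and never changes an optimal design.

## Closed forms as oracles

For the simple linear model with a random slope on $[0, 1]$ the
G-optimal design is known exactly: two points $\{0, 1\}$ with weight

$$w^* = \frac{\sqrt{\delta^2 n^2 + 4\delta + 4} + n\delta - 2}
  {2\delta(n+1)}, \qquad \delta = m d,$$

at 1, together with closed forms for $\phi$, the certifying measure
weight $w_\mu$, and the sensitivity function whose maximum
$(1 - w_\mu)/(w^* - 1)^2$ equals the equivalence-theorem trace term
(`random_slope_*()`).  The $\delta \to 0$ limits ($w^* = w_\mu = 1/2$)
are returned analytically since the printed expressions are $0/0$
there.  For models with only a random intercept the G-criterion of the
fixed-effects D-optimal design equals the design-free bound
$p + (n-1)\delta/(1+\delta)$ (`random_intercept_g_bound()`), so D- and
G-optimality coincide — the test suite verifies both facts numerically
and uses the closed forms as independent oracles for the swarm
pipeline.  Whether that equivalence extends beyond random intercepts is
open; the package computes cross-efficiencies but claims no theorem.

## Poisson mixed models

For count data the package finds locally D-optimal designs for
$Y_{ij} \sim \mathrm{Poisson}(\lambda_{ij})$ with
$\log \lambda_{ij} = f(x_{ij})^T b_i$ and random coefficients
$b_i \sim (\beta, D)$.  With normal random effects the marginal
intensity is $\mu(x) = \exp(f^T\beta + f^T D f / 2)$ and two
observations of the same individual at $x$ and $x'$ are correlated
through $e(x, x') = \exp(f(x)^T D f(x'))$; the quasi-likelihood
information of a design is the grouped expression

$$M(\xi) = F^T \big(\mathrm{diag}(1/(w \mu)) + E - J\big)^{-1} F,$$

where $F$ stacks $f(x_l)^T$, $E_{ll'} = e(x_l, x_{l'})$, and $J$ is the
all-ones matrix.  When $D = 0$ this collapses to the familiar Poisson
GLM information $\sum_l w_l \lambda(x_l) f f^T$ — the reduction, and
the published two-factor worked examples, are the correctness anchors
for the implementation (the acceptance artifacts record two
higher-dimensional published values that this definition does *not*
reproduce; they are reported as computed, not adjusted).  Linear
predictors are capped at magnitude 50, beyond which an error names the
offending support point rather than silently overflowing.

The D-optimality sensitivity in variance-function form residualizes
$f(x)$ on the correlated support,
$g(x) = f(x) - F^T A^{-1} c(x)$ with $c(x)_l = e(x_l, x) - 1$ and
$A$ the matrix inverted above, giving
$d(x, \xi) = \mu(x) g^T M^{-1} g + p - T(\xi)$ with
$T = \sum_l w_l \mu_l g_l^T M^{-1} g_l$; at a D-optimal design
$d \le p$ with equality on the support.  The Atwood-type bound
$p / \max_x d$ (`d_efficiency_lower_bound()`) grades any candidate
without knowing the optimum, and
`find_locally_d_optimal_poisson()` reports the *minimum* bound across
restarts — a deliberately conservative summary for a stochastic
search.

## What the synthetic generator does and does not emulate

`random_hlm()` draws polynomial-basis hierarchical models with
$D = A A^T$ (optionally with a zeroed row/column to exercise singular
dispersion), counts in modest ranges, and a design space bounded away
from zero so fractional terms stay finite; `random_design()` draws
supports uniformly with exponential weights.  These fixtures exercise
the linear-algebra identities (the $\phi$-integral trace identity, the
two algebraic forms of $N$, the MSE eigenstructure, the Theorem-type
lower bound) across hundreds of seeds.  They do *not* emulate real
longitudinal data: individuals always share one regime with equal
$m_i$, $D$ is treated as known rather than estimated, there is no
missingness, and errors are exactly homoscedastic.  Passing tests
therefore validate the design mathematics, not the robustness of the
resulting designs to violations of those modeling assumptions.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
to finish comfortably on one CPU: inner maximization grids of 2001
points per axis (201 during search iterations), outer swarms of 128
particles for 200 iterations with 2 restarts for the published
examples, a $(n, \delta)$ closed-form sweep of 9 combinations at 64
particles, 200 random model/design pairs for the bound property, and a
two-point exhaustive oracle on a 0.005 grid.  All published-example
quantities re-derive in a few minutes; individual criterion evaluations
are milliseconds.

## Known limitations

Design spaces are axis-aligned boxes; exact designs are supported only
through apportionment of an approximate design; response surfaces are
univariate.  The mixed-model efficiency definitions and the $1/m$
criterion standardization are package conventions, documented above.
Certification tolerances are relative to $\bar\phi$, so a pathological
model with $\bar\phi$ near zero would need a manual tolerance.  For
three or more factors the answering-set search and sensitivity sweeps
rely on seeded stochastic maximization; certificates there are
numerical evidence, not proof.
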