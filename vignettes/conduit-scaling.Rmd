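---
title: "Methods: conduit scaling, balanced resampling, and the collapse limit"
author: "xylemtaper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conduit scaling, balanced resampling, and the collapse limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `xylemtaper`, the
assumptions behind them, the numerical choices that were genuinely open,
and what the synthetic-data tests do and do not establish about real data.

## 1. The two scaling laws and how they are estimated

Conduit diameters are modelled as power laws in two predictors: distance
from the leaf tip, $d = d_0 L^{\alpha}$, and organ external diameter,
$d = d_0 D^{\beta}$. Both are fitted after $\log_{10}$ transformation, so
the slope is the exponent and the intercept is $\log_{10} d_0$. All
logarithms in the package are base 10.

The primary estimator is the standardized major axis (SMA, model II):
$|\hat b| = s_y / s_x$ with the sign of the correlation, the standard
choice for allometric exponents because residual variation exists in both
variables. Its 95% interval uses
$\hat b\,(\sqrt{B+1} \pm \sqrt{B})$ with
$B = F_{0.95;1,n-2}(1-r^2)/(n-2)$, and the association $p$-value is the
two-sided Pearson test. OLS fits are provided on the same interface; on
noisy data the OLS slope is attenuated by the factor $|r|$, and both are
reported where slopes are compared. $p$-values below $2.22\times10^{-16}$
are printed as `< 2.22e-16`.

Slope hypothesis tests use the residual-axis correlation: under
$b = b_0$, $(y - b_0 x)$ and $(y + b_0 x)$ are uncorrelated. The
correlation is computed from second moments rather than from the residual
vectors, because at $b_0 = \hat b$ the covariance is analytically zero and
the vector form loses it to cancellation. Two-sample slope and elevation
comparisons are large-sample Wald tests with
$\mathrm{SE}(\hat b) = |\hat b|\sqrt{(1-r^2)/(n-2)}$; the elevation test
conditions on an inverse-variance-weighted common slope and propagates its
uncertainty through the difference in mean predictors.

Curvature in log–log space is the quadratic coefficient of an OLS fit of
$y$ on $\{1, x, x^2\}$; functional-form comparison fits power,
exponential, logarithmic, quadratic and single-breakpoint models **on the
same response scale** $\log_{10} y$, so that $\mathrm{AIC} =
n\ln(\mathrm{RSS}/n) + 2k$ values are comparable ($k$ counts the
breakpoint as a parameter). This common-scale convention is a deliberate
simplification: it avoids Jacobian corrections across response scales at
the cost of fitting the logarithmic candidate by nonlinear least squares
($\log_{10} y = \log_{10}(a + b\ln x)$, which can legitimately fail where
$a + b \ln x \le 0$ — such candidates are reported as unavailable, not
fatal). Breakpoints are located by exhaustive search over 200 interior
x-quantiles (1%–99%), minimizing RSS with ties broken toward the smaller
breakpoint, which makes the fit deterministic.

Thickness-to-span ratios are fitted against *relative* position $L/H$
(exponential decay, i.e. SMA of $\log_{10}(t/b)^2$ on $L/H$), because sap
tension depends on both position and total path length; $L/H$ makes trees
of different heights comparable. A generating decay rate $k$ appears as a
slope of $-k/\ln 10$.

## 2. Bin-balanced resampling

Conduit tables are extremely unbalanced: under the default generator (as
in real sampling designs) a single trunk section contributes the count cap
of 5,000 conduits while a leaf section contributes tens, so raw counts per
log-predictor bin differ by more than an order of magnitude. Balancing
proceeds in three steps:

1. **Binning** (`plan_bins`): equally spaced $\log_{10}$ bins; the number
   of bins is the *largest* value (capped at 30) for which every occupied
   bin holds at least `min_count = 100` observations. Taking the largest
   feasible number gives the finest resolution consistent with the
   constraint; the cap and minimum are configurable. Values on an interior
   edge fall right; the last bin is closed. Empty interior bins (gappy
   predictors, e.g. the gap between branch bases and trunk) are treated as
   absent and excluded from the minimum-count constraint, and their count
   is flagged in the plan.
2. **Balancing**: *subsampling* draws the smallest occupied-bin count from
   every bin without replacement; *bootstrapping* keeps all raw records
   and augments every bin with replacement up to the largest bin. Both are
   exactly conservative (bin counts are exact by construction) and
   seeded.
3. **Iteration** (`iterate_fit`): the balance-and-fit cycle repeats
   (defaults: 1,000 bootstrap or 10,000 subsample iterations, within the
   ranges the procedure was designed for; tests use fewer), recording each
   slope. A running mean forms the stability trace; the run is declared
   converged when the trace moves less than `stability_tol = 1e-3` over
   its second half. The aggregate slope is the mean of per-iteration
   slopes; the aggregate CI is the 2.5/97.5 percentile of per-iteration
   slopes, and per-iteration parametric CIs are stored as well.

**Why two CIs, and a warning.** Under bootstrap augmentation the fitted
sample has $n_{\max}\times$(bins) rows, so per-iteration parametric CIs
reflect an inflated sample size and are anti-conservative. Less obviously,
the *across-iteration percentile CI is anti-conservative too*: because
every raw record is retained in every iteration, the only variation across
iterations comes from the augmentation draws — per bin a variance of order
$\sigma_b^2/(n_{\max}-n_b)$, whereas the sampling variance of the
underlying data is $\sigma_b^2/n_b$. For strongly imbalanced data
($n_b \ll n_{\max}$ in the bins that dominate the fit) the percentile
interval is therefore several-fold narrower than the actual seed-to-seed
sampling error of the aggregate slope. The acceptance test that re-fits 20
independently generated datasets makes this visible: the aggregate
exponents land within $\pm 0.02$ of truth in essentially all runs, while
the percentile CIs, a few $10^{-4}$ wide, rarely contain the true value.
Subsample-mode percentile CIs do not share this defect (iterations are
genuinely independent small draws) and straddle the bootstrap point
estimate in the cross-mode test. Users who need calibrated intervals
should use subsample mode or treat the bootstrap intervals as
repeatability, not confidence, statements.

## 3. The collapse-limit model

The hydraulic path is a series of vertically stacked pipes widening as
$d = d_0 L^{\alpha}$ from tip to base, discretized into segments of
$\Delta l = 100\,\mu m$ over $H = 30$ m by default. Per segment,
Hagen–Poiseuille resistance $r_i = 128\eta\,\Delta l/(\pi d_i^4)$; in
series, $R = \sum r_i$; Darcy flow
$Q = (\psi_{soil} - \psi_{leaf})/R$; the potential at the proximal node of
segment $i$ is $\psi_i = \psi_{leaf} + Q\sum_{j\le i} r_j$, which rises
monotonically from exactly $\psi_{leaf}$ at the tip boundary to exactly
$\psi_{soil}$ at the base (an algebraic identity, asserted in tests). Sap
tension is $P_i = |\psi_i|$ and the critical thickness-to-span ratio is
$(t/b)^2_{crit} = P_i\,\beta/\sigma$.

Defaults and their meaning:

| parameter | default | meaning |
|---|---|---|
| $\psi_{leaf}$ | −4.7 MPa | measured drought minimum leaf water potential |
| $\psi_{soil}$ | −1.5 MPa | typical wilting-point soil water potential |
| $\beta$ | 0.25 | plate-bending coefficient for span-to-length ≤ 0.5, always satisfied by conduit walls |
| $\sigma$ | 41.6 MPa | mean modulus of rupture of green cell-wall material; per-species values supported |
| $\eta$ | 1.002e-9 MPa·s | sap viscosity — cancels (below) |
| $d_0$ | any | normalization — cancels (below) |
| $\Delta l$ | 1e-4 m | segment length |
| $H$ | 30 m | path length; endpoint limits are H-independent |

Two structural properties make the simulation desk-checkable. First,
$d_0$ and $\eta$ enter $Q$ and every $r_j$ as a common factor and cancel
in $\psi_i$, so the potential and critical-limit profiles are invariant to
rescaling either (tested to $10^{-9}$ relative). Second, the endpoint
limits are analytic: $|\psi_{leaf}|\beta/\sigma \approx 0.028$ at the tip
and $|\psi_{soil}|\beta/\sigma \approx 0.009$ at the base — a roughly
threefold decline — regardless of $\alpha$ or $H$.

**Numerical quadrature.** The resistance density $L^{-4\alpha}$ is nearly
non-integrable at the tip for realistic exponents ($4\alpha = 0.92$ at
$\alpha = 0.23$): roughly 40% of the continuum resistance of a 30 m path
lies within the first 100 µm. A midpoint-rule diameter evaluation
converges only as $\Delta l^{\,1-4\alpha}$, i.e. visibly (percent-level)
on grid halving. Segment resistances therefore use the *exact* cell
integral of the density, equivalently a power-mean effective diameter
$d_\mathrm{eff} = d_0(\Delta l / \int_{cell} L^{-4\alpha}dL)^{1/4}$; node
potentials then equal the continuum solution
$\psi(L) = \psi_{leaf} + \Delta\psi\,(L/H)^{1-4\alpha}$ for any grid
(grid-halving changes nothing beyond rounding error, and $\alpha = 0$
reproduces the linear pipe-model profile exactly). For $\alpha \ge 1/4$
the continuum tip integral diverges; the first cell then falls back to the
midpoint diameter, a regularization equivalent to capping conduit
narrowing below the first half-cell, and grid independence is documented
only for $\alpha < 1/4$. The gravitational head (~0.01 MPa m⁻¹) is
omitted — at these heights it is small against the 3.2 MPa driving
difference — and there is deliberately no configuration hook pretending
otherwise.

**Safety factors.** Observed $(t/b)^2$ is divided by the critical value at
the conduit's $L/H$, interpolated linearly over the profile nodes
*including the exact tip boundary node* ($\psi = \psi_{leaf}$ at
$L/H = 0$). Because the widening law is a pure power law, the potential
profile depends on position only through $L/H$, so a single profile serves
trees of any height — per-tree profiles would be identical. A conduit
exactly at the limit counts as safe (the collapse flag uses strict
inequality). Species-specific limits rescale the critical profile by each
species' modulus of rupture, which enters only as $1/\sigma$.

## 4. The synthetic-data generator

The generator emulates the statistical structure the analysis must cope
with, not the biology of any particular stand:

* Each tree draws a total path length $H \sim U(15, 30)$ m and contributes
  tissue samples for all seven organ classes: leaves at
  $L \in (0.005, 0.05]$ m, twigs in $(0.05, 0.3]$, branch bases near 1 m,
  the trunk base at $L = H$, and coarse/fine/very-fine roots (external
  diameters 3–60, 0.8–3, 0.2–0.8 mm) placed at the base of the path.
  Roots are driven by their own external diameters and are excluded from
  $L$-based fits; they never receive $L > H$.
* Conduit diameters follow $d_0 L^{\alpha}$ through the shoot
  ($\alpha = 0.23$, $d_0 = 6$ µm by default) and
  $d_0 D^{\beta}$ in roots ($\beta = 0.42$, $d_0 = 2.19$). Stem external
  diameters follow $L = a D^{\gamma}$ with $\gamma$ chosen so the implied
  stem exponent $\alpha\gamma$ is 0.32.
* Conduit counts per sample scale with organ cross-sectional area
  (`coef * D_mm^2`, default coefficient 20, floor 20, cap 5,000; leaves
  draw 20–100), reproducing the order-of-magnitude bin imbalance that
  motivates the resampling module.
* Thickness-to-span targets decay exponentially in $L/H$ (intercept 0.8,
  rate 1.5) with $\log_{10}$-normal scatter (sd 0.2); a configurable share
  (81%) of conduits is latewood and receives a ×4 reinforcement
  multiplier. Walls are synthesized so the drawn target is reproduced
  exactly: span $b = d$, double wall $t = b\sqrt{(t/b)^2}$, tangential
  single walls $t/2$, radial walls +10% so the tangential wall is the
  deterministic minimum; the radial lumen diameter is back-computed from a
  drawn Mork's index target on the correct side of 1, so the wood-type
  label and the index never disagree.
* A single root seed spawns per-tree substreams, so identical
  configurations yield byte-identical tables and individual trees can be
  regenerated independently.

**Noise placement — a deliberate choice.** Diameter scatter is
$\log_{10}$-normal with sd `sigma_log_d = 0.05`. Two considerations fix
this default and its structure. First, with response-side noise only, the
SMA population slope is $\sqrt{\alpha^2 + \sigma^2/s_x^2}$, not $\alpha$:
an sd of 0.15 would inflate the recovered exponent by about +0.03 given
the generator's log-$L$ spread, i.e. the generator itself would defeat the
estimator it exists to validate; 0.05 keeps that structural inflation
below ~0.005. Second, recorded organ external diameters carry matched
scatter (sd $\sigma/\beta$) around the latent organ size — the
error-in-both-variables structure that is the textbook justification for
SMA and under which it is a consistent estimator of the generating
exponent. This scatter is applied per conduit row rather than per tissue
sample. Both points are departures from realism worth naming: real tables
have wider within-position diameter spread (earlywood/latewood
dimorphism), one constant $D$ per section, and no guarantee that the SMA
error model holds. Passing recovery tests therefore demonstrate that the
*pipeline* is calibrated under the error model SMA assumes — they do not
show that real-data exponents are free of the inflation that asymmetric
noise produces. The generator also does not simulate ring structure,
within-ring position, image coordinates, or climate-driven interannual
variation.

## 5. Degenerate inputs and tie-breaks

* SMA on zero-variance input is a degenerate-fit error; OLS on a constant
  response returns slope 0 by convention, as does the $(t/b)^2$ decay fit
  on constant ratios (a zero decay rate, not an error).
* Mork's index exactly 1 classifies as earlywood (latewood is strictly
  $M > 1$).
* Breakpoint ties resolve to the smaller breakpoint; a pure line is
  flagged `no_meaningful_break` when the break improves RSS by less than
  $10^{-10}$ relative.
* Generated draws are rejected-and-redrawn only where a truncated support
  requires it (branch placement); log-normal draws are positive by
  construction. Configurations implying $(t/b)^2$ targets above 100
  (walls an order of magnitude thicker than their span) are config
  errors.
* AIC ties resolve to the earlier candidate in the fixed order power,
  exponential, logarithmic, quadratic, piecewise.

## 6. Problem sizes used by the test suite

Tests trade size for coverage: unit fixtures use 1–2 trees with the count
cap lowered to a few hundred conduits per sample (the imbalance *shape* is
preserved; the default cap of 5,000 is exercised where imbalance itself is
asserted). Exponent-recovery runs use 9 trees, a cap of 800, and 200
bootstrap iterations across 20 generator seeds; CI calibration uses 500
simulated datasets of $n = 200$. The collapse model always runs at full
resolution (300,000 segments for the default path) since it is vectorized
and cheap. The full suite completes in well under a minute of compute for
everything except the 20-seed recovery experiment, which takes tens of
seconds.

## 7. Known limitations

* The collapse model is quasi-static: one fixed worst-case
  ($\psi_{leaf}$, $\psi_{soil}$) pair, no transpiration dynamics, no
  embolism, and a single unbranched flow path.
* The balanced-bootstrap percentile CI is anti-conservative (Section 2);
  this is a property of the resampling design, reported rather than
  repaired.
* Exponent comparisons assume independent fits; conduits from the same
  tree are correlated, so cross-organ test $p$-values on real data will be
  somewhat optimistic.
* The logarithmic AIC candidate depends on a nonlinear fit that can fail
  on data incompatible with its domain; it is reported as unavailable in
  that case.
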