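---
title: "Thermodynamics of cooperative transcriptional activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of cooperative transcriptional activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promothermo)
```

## The model

`promothermo` implements the equilibrium statistical-thermodynamic picture of
transcription initiation. A promoter regulated by $N$ transcription factors
plus RNA polymerase (RNAP) occupies one of $2^{N+1}$ mutually exclusive
states, each a combination of the polymerase flag $\sigma \in \{0, 1\}$ and a
subset $S$ of bound factors. Each state carries an unnormalized Boltzmann
weight

$$
W(\sigma, S) \;=\; x_P^{\sigma} \prod_{i \in S} x_i
  \prod_{\substack{i<j \\ i,j \in S}} \omega_{ij}
  \left( \prod_{i \in S} w_i
  \prod_{\substack{i<j \\ i,j \in S}} \omega^{(3)}_{ij} \right)^{\sigma},
$$

where all concentrations are dimensionless ratios to dissociation constants
($x_i = c_i / K_i$, $x_P = [\mathrm{RNAP}]/K_P$) and the interaction
parameters are multiplicative *cooperativity factors*:

* $w_i > 1$ — a two-body factor; transcription factor $i$ lowers the RNAP
  binding energy by $-RT \log w_i$ (an activator);
* $\omega_{ij}$ — a factor-factor coupling that does not involve RNAP;
* $\omega^{(3)}_{ij}$ — a three-body coupling active only when both factors
  *and* polymerase are bound (DNA looping, assembly of an activation
  complex).

Factors are the primary internal representation. Energies enter only through
the Boltzmann map $f = e^{-\Delta E/(RT)}$ (`factors_from_energies()`), with
the sign convention that activating shifts are negative and map to factors
above 1. The equivalent energy formulation is recovered with
`energies_from_factors()`; the two orderings — by state probability and by
degeneracy-corrected free energy — are provably identical, and the test suite
checks this on random draws. Temperature defaults to 298.15 K with the gas
constant chosen by the energy unit tag (kcal/mol or J/mol).

State probabilities are weights over the partition sum. The occupancy
probability $p = V_{on}/(V_{on} + V_{off})$ sums the polymerase-bound block;
the transcription rate is taken proportional to $p$ with a free scale
(`transcription_rate()`). All weight accumulation happens in log space with a
single log-sum-exp per block, so saturating doses (up to at least $10^{12}$)
never overflow; this matters because every boundary result below probes the
saturation limit.

## Two activators and the synergy measure

For two activators the closed form is

$$
p(x_A, x_B) = \frac{x_P \left( 1 + x_A w_A + x_B w_B +
  x_A x_B w_A w_B\, \omega_{AB}\, \omega_3 \right)}
  {x_P(\cdot) + 1 + x_A + x_B + x_A x_B\, \omega_{AB}},
$$

monotone non-decreasing in each dose whenever all factors are $\ge 1$.
Synergy is quantified by the difference

$$
D = p(x_A, x_B) - p(x_A, 0) - p(0, x_B),
$$

positive for greater-than-additive (synergistic) responses and negative for
less-than-additive ones. **We use raw occupancies, with no basal
subtraction.** This choice is forced by two facts: at zero doses
$D = -p_{basal} < 0$, which is exactly the catalogued low-concentration
regime, and the double-site analysis compares the two-site curve against
*twice* the single-site activity, not against baseline-subtracted activity.
The alternative convention (adding $p(0,0)$ back) is available via
`synergy_difference(..., include_basal = TRUE)` but is not the default.
`D` always lies in $(-2, 1)$; an additive band of width $10^{-9}$ (absolute,
probability units) separates the two sign classes.

## Closed-form boundaries

With $u = (1 + x_A w_A)/(1 + x_A)$ and $v$ defined likewise, the sign of $D$
at neutral interaction factors equals the sign of the quadratic

$$
(uv - u - v) \;-\; 2\,uv\,x_P \;-\; (uv)^2 x_P^2 ,
$$

which underlies every boundary in the package:

* **Equal activators at saturation** ($u = v = w$):
  $x_P^{crit}(w) = (w-2)/w^2$, rising from 0 at $w = 2$ to a peak of $1/8$ at
  $w = 4$ and decaying thereafter (`critical_xp_equal_activators()`, and
  `critical_xp_vs_energy()` for the energy parameterization $w = e^g$).
  Scanning $w$ at fixed $x_P$ inside $(0, 1/8)$ therefore produces the
  re-entrant sign pattern $-,+,-$: activators must be neither too weak nor
  too strong.
* **High-polymerase ceiling.** Because both non-constant coefficients of the
  quadratic are negative, the synergistic window in $x_P$ is an interval
  anchored at zero. Maximizing over $u = v$ shows the window closes at
  $x_P = 1/8$ on the symmetric slice, comfortably below the catalogued bound
  of $1/2$; the acceptance suite verifies by grid search that no positive $D$
  exists at $x_P = 1/2$ and that the measured supremum is below $1/2$.
* **Strong activation, low polymerase** ($u \to w_A$, $v \to w_B$,
  $x_P \to 0$): the sign of $D$ follows
  $w_A w_B \omega_3 - w_A - w_B$ (`limiting_synergy_statistic()`; the
  factor-factor coupling $\omega_{AB}$ cancels in this limit). With
  $\omega_3 = 1$ this yields the hyperbola $(w_A - 1)(w_B - 1) = 1$
  (`two_body_hyperbola()`), with general $\omega_3$ the hyperbola
  $w_B = w_A / (\omega_3 w_A - 1)$ (`three_body_hyperbola()`).
* **Universal three-body threshold.** The infimum $\omega_3$ that makes the
  limiting statistic positive on the whole activator domain
  $w_A, w_B > 1$ is 2, attained as $w_A = w_B \to 1^+$
  (`minimal_universal_three_body_factor()`). We compute it by bisection of
  the everywhere-positive predicate on a 200-point-per-axis log grid over
  $(1, 100]$; the grid's lower edge is $1 + 10^{-4}$, close enough to the
  open boundary that the bisection lands within $10^{-3}$ of 2.

`classify_regime()` assembles these results into the catalogue of analytic
cases (low doses; weak activators; high polymerase; weak activation;
nonlinearity-driven synergy at saturation; strong activation with and
without three-body coupling). The asymptotic conditions are translated into
documented numeric cutoffs — "low" dose $\le 0.01$, "low" polymerase
$\le 0.01$, "strong" activation $x w \ge 100$, "weak" factor within 5% of
1 — all adjustable via the `thresholds` argument; cases are matched in a
fixed priority order (1, 2, 3, 4, 7b, 7a, 6, 5b, 5a) so overlapping
preconditions resolve deterministically, and ties on a boundary report
`"either"`/additive. Every sign prediction is validated in the tests against
`sign_scan_oracle()`, a brute-force grid evaluation of $D$.

## Dose response of a double-binding-site promoter

Setting $x_A = x_B = x$ and $w_A = w_B = w$ describes a promoter with two
identical sites for one activator. The reference is a single-site promoter
with the same $x_P$ and $w$, $p_{SS} = x_P(1 + xw) / (x_P(1 + xw) + 1 + x)$,
and the dose-resolved synergy is $D(x) = p_{DS}(x) - 2 p_{SS}(x)$.

Two closed-form results organize the dose axis:

* **Nonlinearity-driven crossovers** ($\omega_{tf} = \omega_3 = 1$): $D(x)$
  changes sign exactly where $r(x) = (1 + xw)/(1 + x)$ crosses a root of
  $x_P r^2 - r + 2 = 0$. Real roots require $x_P \le 1/8$, and mapping them
  back through $r$ yields 0, 1 or 2 crossover doses — the three catalogued
  response patterns (pure less-than-additive, single crossover, re-entrant).
  The normative implementation is numeric (sign-change bracketing on 400
  log-spaced doses in $[10^{-6}, 10^6]$ refined by bisection to $10^{-12}$
  in log dose, `critical_doses_nonlinearity()`); the closed form serves as
  the independent cross-check in the tests, with agreement to $10^{-8}$.
* **Three-body-driven crossover** ($w = \omega_{tf} = 1$): the single-site
  reference is then dose-independent and the unique crossover dose is the
  positive root of $[(1 - x_P)\omega_3 - 2]x^2 - 2(1 + x_P)x - (1 + x_P)$
  (`critical_dose_three_body()`), which exists iff
  $\omega_3 (1 - x_P) > 2$. The existence frontier
  $x_P^{crit} = 1 - 2/\omega_3$ (`critical_xp_line_three_body()`) approaches
  1 as $\omega_3 \to \infty$: once polymerase reaches its dissociation
  constant, no three-body interaction, however strong, produces synergy.

`synergy_ratio()` provides the ratio measure $p_{DS}/(2 p_{SS})$ used in
multi-site reporter experiments; it exceeds 1 exactly where $D > 0$, and in
the re-entrant regime rises to a single interior peak before decaying
monotonically below 1. Unequal sites ("near"/"far") are handled by routing
through the general two-activator model with $w_A \neq w_B$ and a shared
dose; their crossover doses are found numerically, as no closed form is
available.

## Estimation from saturation fold changes

Reporter studies typically publish three saturation fold changes over basal
activity: $F_A$, $F_B$ (single stimulation) and $F_{AB}$ (dual). Since the
rate is linear in occupancy, fold changes of rates equal fold changes of
occupancies; no basal subtraction is applied. In the low-polymerase limit
$F_A \to w_A$, $F_B \to w_B$, $F_{AB} \to w_A w_B \omega_3$, giving the
default estimator $\hat w_A = F_A$, $\hat w_B = F_B$,
$\hat \omega_3 = F_{AB} / (F_A F_B)$. With a known $x_P$, the exact relation
$F = w(1 + x_P)/(1 + x_P w)$ is inverted instead ($F$ must stay below
$(1 + x_P)/x_P$). Because $\omega_{AB}$ cancels at joint saturation, the
three readouts identify only the product reported as `omega3`; the output
records this explicitly. Estimates for specific published promoters are not
hard-coded; users supply the source fold changes.

**Accuracy of the low-polymerase mode.** The estimator's relative residual
is exact and instructive:
$\hat\omega_3/\omega_3 = (1 + x_P w_A)(1 + x_P w_B) /
\big((1 + x_P)(1 + x_P W)\big)$ with $W = w_A w_B \omega_3$, i.e. a relative
bias of order $x_P W$ — the *joint* fold change, not $x_P$, sets the error
scale. At $x_P = 10^{-6}$ the mode is accurate to $10^{-3}$ only while
$W \lesssim 10^3$; panels drawn from the generator's full ranges (two-body
factors up to 50, $\omega_3$ up to 20) reach $W = 5 \times 10^4$ and a bias
of several percent. The unit tests assert the exact bias law; the exact-mode
inversion is accurate to $10^{-10}$ regardless. $x_P$ itself is not
identifiable from three saturation fold changes, so no estimator in this
design can remove the bias.

`synergy_domain_contour()` converts estimates into a prediction: the locus
$D(x_A, x_B) = 0$ in the dose plane, traced by root bracketing along rays
from the origin (the origin side is always less-than-additive) with each
point refined until $|D| < 10^{-9}$. Axes can be rescaled to the dose
inducing a stated fraction (e.g. 80%) of the single-stimulation saturation
occupancy (`dose_for_saturation_fraction()`); occupancy, not
baseline-subtracted activity, defines the anchor, and a fraction below the
basal share of saturation is reported as unreachable.

## Synthetic data generator

`generate_fixtures()` emulates a panel of saturation reporter assays: truth
parameters drawn log-uniformly ($w_A, w_B \in [1, 50]$,
$\omega_3 \in [0.5, 20]$ — spanning weak to strong activators and
antagonistic to strongly cooperative three-body coupling, the range over
which published estimates for bacterial and nuclear-receptor promoters
fall), noiseless fold changes computed from the forward model at
$x_P = 10^{-6}$ and saturating doses, then multiplicative lognormal noise
(default sd 0.1 on the log scale, a typical reporter-assay spread). It is
the package's only source of randomness; the seed is recorded in the
manifest and identical seeds reproduce identical tables. What the generator
does *not* emulate: finite (non-saturating) doses, additive background,
replicate structure, or uncertainty in the basal readout — passing recovery
tests therefore demonstrates correctness of the inversion under the model's
own assumptions, not robustness to real-assay artifacts.

## Numerical choices

* Log-space weights with one log-sum-exp per on/off block; probabilities via
  a softmax. Zero doses contribute $-\infty$ log terms and drop out exactly.
* Saturation limits are evaluated analytically, never by plugging in huge
  doses — except inside test oracles, where dose $10^9$ with log-space
  weights is the deliberate cross-check.
* Root finding: sign-change bracketing on log-spaced grids refined by
  bisection (tolerance $10^{-12}$ in log dose); the synergy difference is
  smooth with at most two roots in every regime examined.
* Bisection brackets: $x_P \in (10^{-12}, 1)$ for polymerase boundaries,
  factor grids open at 1 (offset $10^{-4}$); exact boundary hits are
  classified additive.
* Problem sizes: the widest search in the test suite maximizes $D$ over
  $50^4$ grid points (doses $[10^{-3}, 10^3]$, factors $[1, 10^3]$, both
  log-spaced) per polymerase level, chunked over factor pairs to bound
  memory; 1000-draw property checks cover normalization, monotonicity and
  the closed-form/enumeration identity.

## Known limitations

* Equilibrium only: no kinetic or stochastic dynamics of binding.
* Interactions are pairwise (factor-factor) and pairwise-with-polymerase;
  higher-order terms among triples of factors are not represented for
  $N \ge 3$.
* Classification and pattern analysis are defined for activators
  ($w \ge 1$); the core weights accept $w < 1$ but repressor-specific
  regimes are out of scope.
* Boundary surfaces are derived for two activators; for more factors only
  the general state-space machinery applies.
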