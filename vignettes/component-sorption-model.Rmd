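---
title: "Predicting and fitting moisture sorption isotherms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and fitting moisture sorption isotherms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocomp)
```

## Scope and model

A moisture sorption isotherm links the water activity $a_w$ of ambient
air to the equilibrium moisture content $M$ (% dry basis) of a material
at fixed temperature. `isocomp` provides (i) a *component model* that
predicts the isotherm of a plant material from its proximate composition,
and (ii) least-squares fitting and comparison of seven classical isotherm
equations to measured or simulated EMC/$a_w$ data.

The component model assumes that dry matter can be partitioned into
vacuole solutes (sugar + ash), fiber, starch, protein and oil; that each
component equilibrates *independently* with the surrounding air (no
component interactions); and that oil sorbs a negligible amount of water.
The total moisture is then the composition-weighted sum

$$H_t(a_w) = w_v H_v + w_f H_f + w_s H_s + w_p H_p,$$

with weights normalized over non-oil dry matter and $w_v$ the combined
sugar-plus-ash fraction. The independence assumption is the model's main
physical limitation: at high humidity the components interact, and the
model is empirically trustworthy mainly below $a_w \approx 0.7$ — which
is, fortunately, the range that matters for drying, storage and
microbial stability.

### The vacuole (solution) component

Sugars and ash are treated as a mixed aqueous solution. Each solute
alone would give water activity of the Norrish form
$a_{w,i} = x_i \cdot 10^{-k_i (1-x_i)^2}$, where $x_i$ is the water mole
fraction $x_i = X_v / (X_v + c_i W_i)$, $X_v$ the vacuole water content
(g water / g vacuole solids), $W_i$ the solute's weight fraction within
vacuole solids, and $(c_i, k_i)$ empirical constants (glucose
$c = 0.08326$, $k = 0.858$; sucrose $c = 0.08764$, $k = 2.772$; ash
$c = 0.16981$, $k = 0.716$). The mixture activity is the Ross product
$a_{w,v} = a_{w,g}\, a_{w,s}\, a_{w,a}$, a standard approximation for
multicomponent solutions. Two conventions are worth stating:

- **Absent solutes contribute activity 1.** When $W_i = 0$ the mole
  fraction is 1 and the factor is $10^0 = 1$: a solute that is not there
  cannot depress water activity. This keeps the Ross product continuous
  in the composition.
- **The glucose/sucrose split.** Composition tables report a single
  "sugar" fraction, but the solution model needs glucose and sucrose
  separately. The split is exposed as `glucose_share` (default 0.5,
  i.e. an equal split) — an honest free parameter, not a fitted one.
  Predictions are only mildly sensitive to it because the two mole
  coefficients are close; the activity coefficients differ more, so
  users with sugar-profile data should set it.

Note that the mole coefficients are used exactly as published even
though $c_i = M_w/M_i$ would give $18.02/180.16 \approx 0.100$ for
glucose rather than 0.08326; they are empirical constants of the source
model, not molecular-weight ratios.

Because all three factors increase strictly from 0 towards 1 as $X_v$
grows, the forward map is strictly monotone and $X_v(a_w)$ is computed
by bracketing root search (see *Numerical choices*). Near $a_w = 0$ the
vacuole moisture scales like $a_w^{1/3}$ — the product of three
near-proportional mole fractions — so convergence to zero is genuine but
slow.

### The fiber component

Fiber follows Kelsey's empirical water–cellulose–moist-air correction:
an auxiliary bound-water variable

$$y = \frac{0.076 + X_f - \sqrt{(0.076 + X_f)^2 - 0.28546\,X_f}}{1.878}$$

and $a_w = \frac{X_f - y}{X_f}\,
\exp\!\left(\frac{0.16137}{X_f + 0.43684}\right)$, clamped to $[0, 1]$.

The sign of the exponential argument is typographically ambiguous in the
sources this form circulates in, so both readings are implemented and
the choice is exposed (`exp_sign`, default `"pos"`). The shipped default
is the positive sign, for two reasons. First, it is the form as printed.
Second, it is the physically plausible one: at $X_f = 0.2$ (20 % d.b.)
it gives $a_w \approx 0.82$, consistent with cellulose holding roughly
20–30 % d.b. near saturation, whereas the negative sign would imply
fiber holding ~60 % d.b. at $a_w = 0.9$, far above any reported
cellulose isotherm. With the positive sign the map increases strictly
until it reaches $a_w = 1$ at $X_f \approx 0.454$ and is clamped
afterwards; every $a_w \in (0,1)$ therefore has a unique pre-image and
inversion is well-posed. The discriminant under the square root is
verified non-negative before evaluation (it is positive on the whole
operating range).

### Starch and protein

Starch uses a Henderson-form fit to classical starch sorption data,
$H_s = 18.19182\,(-\ln(1 - a_w))^{0.41181}$ in % d.b.; protein a power
law $H_p = 0.090614\,(-\ln a_w)^{-0.62}$ in decimal d.b. Both are
strictly increasing with closed forms, needing no inversion. Their
low-$a_w$ tails vanish only logarithmically slowly — at $a_w = 10^{-3}$
starch still predicts ~1 % d.b. — which is why the package's
zero-water-limit checks probe $a_w$ down to $10^{-6}$ rather than
asserting near-zero moisture at $10^{-2}$.

### Units

All user-facing moisture values are % dry basis. Internally the vacuole,
fiber and protein equations work in decimal d.b. and are scaled by 100;
starch is already in %. Water activity is always decimal.

## The seven fitted equations

| model | form | parameters |
|---|---|---|
| henderson | $a_0(-\ln(1-a_w))^{a_1}$ | $a_0, a_1 > 0$ |
| chung_pfost | $b_0 + b_1 \ln(-\ln a_w)$ | free |
| halsey | $c_0(-1/\ln a_w)^{c_1}$ | $c_0, c_1 > 0$ |
| oswin | $d_0(a_w/(1-a_w))^{d_1}$ | $d_0, d_1 > 0$ |
| white_eirig | $1/(e_0 + e_1 a_w)$ | free |
| caurie | $f_0 e^{f_1 a_w}$ | $f_0 > 0$ |
| gab | $\frac{ABC\,a_w}{(1-Ba_w)(1-Ba_w+BCa_w)}$ | $A, C > 0$, $0 < B \le 1.2$ |

Default starting values (`default_init`) are round numbers at the
magnitudes typical of published herb and grain fits: henderson (10, 1),
chung_pfost (5, −6), halsey (6, 0.7), oswin (7, 0.6), white_eirig
(0.25, −0.2), caurie (2, 3), gab (8, 0.7, 10). The GAB bound
$B \le 1.2$ keeps the singularity $B a_w = 1$ controllable while still
admitting fits with $B$ slightly above 1 when the data stop below
$a_w = 1/B$. All seven have closed-form inverses $a_w(M)$; GAB's is the
root in $(0, 1)$ of a quadratic in $u = B a_w$.

## Fitting and comparison criteria

Parameters minimize $\sum_i (y_i - M(a_{w,i}; \theta))^2$ by bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`; maximum 2000
function evaluations, relative tolerances $10^{-10}$). Out-of-domain
predictions during a trial step are replaced by a large finite penalty
so the optimizer backs away rather than crashing. If the default start
does not converge, five deterministically jittered starts (fixed
multiplicative factors, no RNG) are tried and the best kept; the
`converged` flag reports the optimizer status.

The four criteria follow the conventions of the sorption literature:

- $R^2 = 1 - SSE/SST$ with $SST$ about the mean (the usual pseudo-$R^2$
  convention for nonlinear fits);
- $s = \sqrt{SSE/(n-2)}$, with the divisor held at $n - 2$ for **all**
  models, including three-parameter GAB, because a single formula is
  the convention this toolkit mirrors — $s$ values across models are
  then directly comparable at equal $n$;
- $MRE = \frac{100}{n}\sum |y_i - \hat y_i| / y_i$ with the *measured*
  value in the denominator (fits under ~10 % are conventionally "good");
- $PRESS = \sum_i (y_i - \hat y_{-i})^2$, each $\hat y_{-i}$ from a
  genuine leave-one-out refit warm-started at the full-data parameters.
  Warm starting is a speed/stability choice only; the test suite checks
  it against cold-started refits and, for the linear-in-parameters
  Chung–Pfost model, against the exact hat-matrix identity
  $PRESS = \sum (r_i/(1-h_{ii}))^2$.

`compare_models()` ranks by PRESS ascending (ties: MRE, then $s$),
because PRESS is the only one of the four that measures *prediction*
rather than fit.

### The residual-pattern verdict

The literature judges adequacy by eye: residual plots should look
"uniform", not systematically patterned. The package operationalizes
this with a Wald–Wolfowitz runs test on residual signs ordered by
$a_w$: lack of fit manifests as sign *clustering* (too few runs), so the
verdict is `"pattern"` when the lower-tail probability of the observed
run count falls below $\alpha = 0.05$, and when all residuals share one
sign (a gross misfit the conditional-on-signs test cannot see). The
exact conditional null distribution is used below 20 residuals, the
continuity-corrected normal approximation above. Too *many* runs
(alternation) is not treated as a pattern: it indicates negative
autocorrelation, not the monotone misfit that residual plots are read
for; a `two.sided` alternative remains available on `runs_test()`. This
is a reproducible convention, deliberately flagged as such — it is not a
claim about what any human judge would decide.

## Numerical choices

- **Inversion** of the vacuole and fiber isotherms uses bracketing
  (Brent) root search: the bracket upper end doubles from 1 until it
  encloses the target, and the solution is accepted only if the forward
  map reproduces $a_w$ to $10^{-8}$ absolute. Derivative-free bracketing
  is robust here because both forward maps are strictly monotone.
- **Degenerate inputs** fail loudly with named errors: a vacuole with
  neither water nor solutes, compositions whose non-oil fractions are
  all zero, water activities outside each equation's domain, moisture
  values outside an equation's range.
- **Printed compositions that do not sum to 1** (they rarely do; one
  bundled product sums to 0.43 because the table reports per-total
  rather than per-dry-matter fractions) are accepted with a warning and
  renormalized over non-oil dry matter, so the component weights always
  sum to 1.
- **Zero-weight components** contribute exactly zero and their
  sub-models are never evaluated, so a starch-free product does not
  trip the starch domain checks.

## The synthetic-data generator

`simulate_isotherm()` and `simulate_from_composition()` emulate
hygrometric (equilibrium-relative-humidity) measurements: a known curve
plus additive homoscedastic Gaussian noise on the moisture axis,
truncated at 0.01 % d.b. to preserve positivity. Defaults, chosen once
as realistic study conditions: 15 points evenly spaced on
$a_w \in [0.1, 0.9]$ (ERH studies typically report 8–20 points) and
`noise_sd = 0.3` % d.b., the moisture-axis scatter a calibrated
hygrometer (about ±0.7 % RH) induces through a typical mid-range
isotherm slope of ~0.3–0.5 % d.b. per % RH.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: temperature drift and sensor
calibration error, sorption–desorption hysteresis, heteroscedastic
error growth near saturation, and error in $a_w$ itself. Conclusions
about estimator bias and model ranking transfer to real measurements
only insofar as those effects are small.

## Problem sizes

The test suite and acceptance script run at the scales the methods are
designed for: 9–15-point isotherms, 200-replicate bias studies at
$\sigma = 0.3$ % d.b., 500-replicate noise-calibration checks, and
50-point grids for monotonicity. These are the sizes at which the
methods are used on real sorption data; everything completes in seconds
on one core.

## Known limitations

- The component model ignores component interactions and so
  systematically underpredicts above $a_w \approx 0.7$ for
  vacuole-poor products (and overshoots for sugar-rich ones, where the
  solution term diverges as dilution becomes unbounded).
- No temperature dependence is modelled: published fits at 5–45 °C
  differ only marginally for the bundled products, and the equations
  carry no temperature term. Fits at different temperatures are simply
  separate fits.
- GAB fits with $B a_w \ll 1$ over the data range are non-identifiable:
  the model degenerates to $\approx ABC\,a_w$ and only the product is
  estimable. Several published GAB sets are of this kind (e.g.
  $A \sim 10^5$, $B \sim 0.007$); the package reproduces their *curves*
  but no optimizer can recover such parameter triples from 15 points,
  and the recovery tests use identifiable sets.
- Desorption hysteresis is out of scope; all curves are adsorption-style
  monotone isotherms.
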