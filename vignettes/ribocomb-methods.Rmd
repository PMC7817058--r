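---
title: "Predicting antibiotic interactions from growth laws: model and methods"
author: "ribocomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antibiotic interactions from growth laws: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When two antibiotics are combined, the observed growth inhibition can be
stronger (synergy) or weaker (antagonism) than the additive expectation in
which the drugs merely substitute for each other.  For ribosome-targeting
antibiotics (translation inhibitors), the physiological feedback between
translation and growth is quantitatively captured by the bacterial *growth
laws*, which makes a predictive, essentially parameter-free biophysical
model of combined drug action possible.  `ribocomb` implements that model:
from the response parameters of the individual drugs it predicts entire
two-drug dose-response surfaces, classifies the interaction with the Loewe
interaction score, extends to three drugs in a tractable limit, and covers
two biologically important refinements — starvation-mimicking antibiotics
and constitutively expressed resistance genes.

## The model

### Growth laws

Two empirical linear relations anchor the model.  Under nutrient variation
the concentration of unperturbed (translating) ribosomes grows linearly
with growth rate,

$$r_u = r_{min} + \lambda/\kappa_t,$$

while under translation inhibition at fixed nutrients the cell upregulates
total ribosome content,

$$r_{tot} = r_u + r_b = r_{max} - \lambda\,\Delta r\,
  [1/\lambda_0 - 1/(\kappa_t \Delta r)],$$

with $\Delta r = r_{max} - r_{min}$ and $\lambda_0$ the drug-free growth
rate set by the medium.  The defaults are the standard published constants
for *E. coli*: $\kappa_t = 0.06\,\mu M^{-1}h^{-1}$, $r_{min} = 19.3\,\mu M$,
$r_{max} = 65.8\,\mu M$ (hence $\Delta r = 46.5\,\mu M$ and
$\lambda_{max} = \kappa_t\Delta r = 2.79\,h^{-1}$).

### Single translation inhibitor

A drug at external concentration $a_{ex}$ enters the cell with first-order
transport $J = p_{in} a_{ex} - p_{out} a$, binds translating ribosomes with
mass-action kinetics ($k_{on}$, $k_{off}$), and every species is diluted by
growth.  In balanced growth the system reduces to a cubic in the relative
growth rate $y = \lambda/\lambda_0$:

$$4y^3 - 4y^2 + [\alpha^2 + c(\alpha^2+1)]\,y - \alpha^2 = 0,$$

where $c$ is the concentration in IC50 units and the single dimensionless
*response parameter* $\alpha = \lambda_0^*/\lambda_0$, with
$\lambda_0^* = 2\sqrt{p_{out}\kappa_t K_D}$, controls the curve shape:
large $\alpha$ gives shallow curves, small $\alpha$ steep ones.  The
relation inverts in closed form,

$$c(y) = \frac{(1-y)(4y^2+\alpha^2)}{y(\alpha^2+1)},$$

which is the computational backbone of the package: steady states, fold
points, the bistable window, and Loewe references are all obtained from it
without iteration on the ODEs.  For
$\alpha < \alpha_{crit} = 2/(3\sqrt3) \approx 0.385$ the relation is
non-monotonic and two stable growth rates coexist over a window of
concentrations; the package reports the *upper branch* (the largest stable
root), which is what batch-culture experiments observe, with the
discontinuous drop at the fold.

An important numerical subtlety, discovered while validating the solver
and documented here deliberately: the cubic above is the *fast
transport/binding limit* of the kinetic system.  Exact elimination of the
ODE steady state gives

$$p_{in}a_{ex} = \Delta r(1-y)\left[\lambda +
  \frac{\kappa_t(\lambda+p_{out})(\lambda+k_{off})}{k_{on}\lambda}\right],$$

which reduces to the cubic's
$[\lambda + \kappa_t p_{out}k_{off}/(k_{on}\lambda)]$ only when
$k_{off}, p_{out} \gg \lambda$ and $\kappa_t/k_{on}$ is small — accurate to
a few percent for typical kinetics.  `ribocomb` therefore carries both
descriptions: `inverse_dose_response()`/`steady_state_growth()` implement
the reduced closed form, and `aex_of_y()` implements the exact inverse of
the full kinetic system (including, optionally, a resistance enzyme).  The
two agree in the fast-kinetics regime; consistency-critical constructions
(surface axes, Loewe references for full-model surfaces) always use the
exact inverse so that reference-model mismatch can never masquerade as a
drug interaction.

### Two drugs

With two drugs each ribosome can be unbound, single-bound (either drug) or
double-bound ($r_d$).  The second binding step is scaled by dimensionless
modifiers $\delta_{on,i}$, $\delta_{off,i}$: all ones for independent
binding, $\delta_{on}=0$ for competitive binding (shared site), values
above one for mutual stabilisation on the ribosome.  A short proof shows
that without double-bound ribosomes the isoboles are exactly straight
lines — competitive binding is additive whatever the curve shapes, and a
drug combined with itself is additive automatically.
`additivity_certificate()` turns that theorem into a numerical check
(coefficients $\xi_i$, $\Upsilon_i$ and the traced isobole's deviation from
linearity, typically $10^{-13}$).

Double-bound ribosomes break additivity: for independently binding drugs
the interaction runs from antagonism (steep pairs, where irreversibly
blocked ribosomes act as a sponge for the second drug) to synergy (shallow
pairs), and `phase_diagram()` maps the Loewe score over
$(\alpha_A, \alpha_B)$.  Stabilising direct interactions
($\delta_{on} > 1$) amplify whatever interaction is present; destabilising
ones weaken it towards additivity, with a mildly synergistic overshoot
possible on the way for steep pairs.

### Interaction scoring

The Loewe interaction score is the log-ratio of the volumes under the
model (or measured) surface and the additive reference,
$LI = \log(\int y \, / \int y_{add})$, negative for synergy and positive
for antagonism.  The additive reference solves
$c_A/C_A(y) + c_B/C_B(y) = 1$ per concentration pair, where $C_i$ is drug
$i$'s inverse dose-response; for bistable drugs the analytic inverse
(defined on all of $(0,1]$) is used with the largest-$y$ solution, which
keeps the reference well defined and makes self-combination exactly
additive including the discontinuous drop.  Integration is trapezoidal on
the stored grid — the surfaces are smooth except along the fold line, and
the default $121 \times 121$ grid over $[0,3]^2$ IC50 units resolves the
volumes to well below the $|LI| < 0.01$ additive band.  The natural
logarithm is used; only sign and zero matter for classification.

### Slow-growth limits and three drugs

For reversibly binding drugs with fast kinetics at low growth rates the
system linearises and yields closed forms: a Bliss-like product of
Langmuir terms for independent binding, a Loewe form
$\propto 1/(1+c_A'+c_B')$ for competitive binding, and the general
expression with $\Phi$ factors for arbitrary symmetric or asymmetric
$\delta$, all in the rescaled concentrations
$c_i' = c_i(\alpha_i^2+1)\lambda_{max}/(\alpha_i^2\lambda_0)$
(`slow_growth_surface()`, `c_prime()`).  These limits carry a
$\lambda_{max}/\lambda_0$ prefactor — they approximate the low-growth part
of the surface, not the drug-free corner, so their value lies in shape
comparisons (the Pearson correlation with the full surface rises steadily
with $\alpha$).

The same assumptions make three drugs tractable: `triple_slow_growth()`
builds the steady-state balance over the eight ribosome occupancy states
(fewer under competitive exclusions) and solves the linear system, rather
than hard-coding the product forms — reproducing them to machine precision
is a genuine test of the diagram.  The mechanism-independent
maximum-entropy formula
$y_{ABC} = y_A y_{BC} + y_B y_{AC} + y_C y_{AB} - 2y_Ay_By_C$
(`maxent_triple()`) is consistent with this mechanistic limit;
`consistency_report()` verifies the identity over random concentration
triples.  Because the printed marginal responses drop the
$\lambda_{max}/\lambda_0$ prefactor, the consistency check normalises all
responses by the drug-free value — the identity is quadratic in the
responses on one side and linear on the other, so it can only hold on the
normalised scale.

### Starvation-mimicking antibiotics

An SMA (e.g. mupirocin) blocks tRNA charging and thereby mimics a poor
nutrient environment: its sole effect in the model is to rescale the
drug-free growth rate by its own dose-response $g(c_s)$.  The translation
inhibitor's response parameter becomes $\alpha_F/g$ and its IC50 changes
by the fold-factor

$$\psi = \frac{\alpha_F^2 + g^2}{(\alpha_F^2+1)g},$$

monotonically increasing with SMA inhibition when $\alpha_F > 1$ and
dipping to a minimum $2\alpha_F/(1+\alpha_F^2)$ at $g = \alpha_F$ when
$\alpha_F \le 1$ — so the combined surface
$y(c, c_s) = g \cdot f(\alpha_F/g,\, c/\psi)$ is *not* a product of the
individual responses.  $g(c_s)$ is supplied as data: a tabulated curve
(monotone Hyman spline interpolation) or a parametric single-drug curve
with its own $\alpha$.  The shipped presets $\alpha_F = 1.04$
(chloramphenicol-like) and $\alpha_F = 0.46$ (streptomycin-like) reproduce
the two qualitative $\psi$ shapes.

### Constitutive resistance genes

An unregulated resistance enzyme is expressed in proportion to
$(1-\lambda_0/\lambda_{max})$ across nutrient environments and to
$\lambda/\lambda_0$ under translation inhibition, giving the removal flux

$$j_{rem} = V'_{max}\,\frac{\lambda}{\lambda_0}\,\frac{a}{a+K_{rem}},
\qquad V'_{max} = V_{max}(1-\lambda_0/\lambda_{max}).$$

The $\lambda/\lambda_0$ factor closes a positive feedback (less growth →
less enzyme → less removal → even less growth) that is evaluated
self-consistently inside the steady-state solve.  It steepens dose-response
curves, raises the IC50, and can create bistability even for drugs whose
enzyme-free response is monostable; for very large $K_{rem}$ the flux is
linear in $a$ and the feedback loses its teeth.  The enzyme pool is not a
dynamic variable — its quasi-steady expression law is folded into the flux.
For drug pairs (one specific enzyme per drug, no cross-resistance), growing
resistance shifts the interaction towards antagonism, more strongly for
competitively binding drugs; concentration axes of resistant surfaces are
rescaled by the numerically recomputed resistant IC50s so surfaces remain
comparable.

## Numerical methods

**Two-drug steady states.** At fixed $\lambda$ the first growth law pins
$r_u$, the three bound-ribosome pools solve a linear system in closed form
(all denominators provably positive), and the problem reduces to a 2-D
root find in the intracellular concentrations $(a_A, a_B)$ — handled by a
finite-difference Newton iteration with strict-descent backtracking, backed
by a coordinate-bisection fallback that cannot fail (each drug balance is
positive at zero and negative for large $a$).  The ribosome-balance
residual $g(\lambda) = r_u + r_{bA} + r_{bB} + r_d - r_{tot}(\lambda)$ then
defines the fixed points; the *largest* root on $(0, \lambda_0]$ — found by
a downward scan (400 panels) with golden-section refinement of positive
dips (which detects fold pairs about to annihilate) and bisection — is the
upper-branch, population-observable state.  Grid evaluations warm-start
from the neighbouring dose (continuation).  The inner tolerance is
$10^{-13}$ relative to the dominant flux; every reported fixed point is
checked against the full six-equation right-hand side
($|\mathrm{rhs}| < 10^{-8}$) and, in the tests, against `deSolve` time
integration from a drug-free inoculum.  The double-bound pool is counted in
$r_{tot}$ — double-bound ribosomes are still ribosomes.  The grid solver is
implemented in C++ (via Rcpp); everything else is plain R.

**Branch policy and $\alpha = 0$.** The largest stable root is "the"
response everywhere; all roots with stability labels remain available via
`steady_state_growth()` for bistability studies.  Stability uses the 1-D
criterion (sign of $dc/dy$, middle root of three unstable), cross-checked
in the tests against the eigenvalues of the dynamical Jacobian at the fixed
points.  The irreversible-binding limit $\alpha = 0$ is handled by its
exact quadratic factorisation rather than a degenerate cubic, and
$IC_{50} = \Delta r\lambda_0(\alpha^2+1)/(4p_{in})$ is used for all
$\alpha \ge 0$ (it is the continuous extension of the usual
$(\alpha^2+1)/2\alpha$ form).

**Concrete kinetics behind a given $\alpha$.** Steady-state curves depend
on the kinetics only through $\alpha$, but the dynamical and two-drug
systems need a concrete parameter set; figure-style presets are stated as
$\alpha$ only.  `shape_to_kinetics()` fixes
$k_{on} = 1000\,\mu M^{-1}h^{-1}$, $p_{out} = 10\,h^{-1}$,
$p_{in} = 100\,h^{-1}$ — mid-range typical values for translation
inhibitors — and solves $K_D = (\alpha\lambda_0)^2/(4\kappa_t p_{out})$.
The default nutrient setting is $\lambda_0 = 1\,h^{-1}$, a moderately rich
medium well below $\lambda_{max}$.  These choices were made once; all
two-drug results in the documentation and tests use them.

**Loewe reference solving.** The additive reference is found per
concentration pair by scanning a dense descending $y$ grid (4096 points
plus a logarithmic tail near zero) for the largest crossing of
$c_A/C_A(y)+c_B/C_B(y)=1$ and refining with `uniroot` to $10^{-13}$.  For
grids that straddle a fold this matches the branch convention of the
surface solver; lattice points closer to a fold than the $y$-grid
resolution squared could in principle be assigned the lower branch one
grid cell early, a set of measure small enough that it never affects the
trapezoidal volumes at the default resolution.

**Problem sizes.** The package's own validation uses $121\times121$
surfaces (the resolution at which surface–approximation correlations are
quoted) for the headline checks and $41\times61$-scale grids for
property-style sweeps; the consistency checks use $10^2$–$10^3$ random
draws under fixed seeds.  A full $121\times121$ surface solves in roughly
ten seconds on one core.

## What the checks do and do not show

All quantitative statements in the tests concern the *model*: printed
constants ($\Delta r = 46.5\,\mu M$, $\alpha_{crit} \approx 0.385$), exact
limits ($y = 1/(1+c)$ at large $\alpha$, $(1+\sqrt{1-c})/2$ at small
$\alpha$), exact theorems (competitive additivity, maxent consistency) and
qualitative orderings (phase-diagram signs, $\delta$ amplification, CERG
steepening and antagonism shifts).  Passing them shows the implementation
is faithful to the model and its analytic structure, not that the model
describes any particular organism or drug pair.  Real dose-response data
carry measurement noise, growth-rate estimation artefacts and
drug-specific mechanisms (most notably suppression, where one drug's
potency is destroyed by the other) that are outside this model's scope by
construction.  Also out of scope: fitting $\alpha$ to measured curves,
translation-cycle/ribosome-assembly detail, target-modification or decoy
resistance mechanisms, and kinetic systems of more than two drugs (the
three-drug module lives entirely in the slow-growth limit).

## Worked example

```{r example}
library(ribocomb)
laws <- growth_laws()           # published constants, lambda0 = 1/h

# single-drug curve, steep regime with its bistable window
bistable_window(0.2)
crv <- dose_response_curve(response_shape(0.2), seq(0, 2, 0.01))

# full two-drug surface and interaction score, shallow pair
res <- pair_interaction(4, 4, binding_modifiers(), laws)
res$score                       # negative LI: synergy

# competitive binding is additive whatever the shapes
pair_interaction(4, 4, binding_modifiers(0, 0, 1, 1), laws)$score

# resistance enzymes shift interactions towards antagonism
enz <- list(resistance_enzyme(950, 0.1, "A"), resistance_enzyme(950, 0.1, "B"))
cerg_pair_interaction(list(1, 1), binding_modifiers(), enz, laws)$score
```
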