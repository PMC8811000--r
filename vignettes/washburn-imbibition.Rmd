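---
title: "Washburn modelling of liquid imbibition in wood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Washburn modelling of liquid imbibition in wood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodimbibe)
library(dplyr)
```

## The problem

When a dry wood sample touches a liquid reservoir, capillarity pulls the
liquid up the conducting tissue against viscous drag and gravity. Which
tissue conducts depends on the liquid and the species: a non-polar oil rises
in poplar vessels and in spruce latewood tracheids; water is blocked at the
scars between vessel cells, rises instead through the dense latewood band of
each growth ring, and from there slowly invades the surrounding earlywood
through ray cells and connected tracheids. The package models this at two
levels:

* a one-dimensional porous-medium Washburn model for a single conducting
  pathway (`washburn1d` functions), and
* a dual-scale two-dimensional network model in which a fast latewood column
  feeds slow lateral spreading at every wetted height (`washburn2d`
  functions),

together with the data-reduction chain for gravimetric (microbalance)
imbibition recordings and a synthetic-data generator that emulates such
recordings so that the whole pipeline can be exercised and tested without
any experimental download.

## The 1D model

For a porous pathway with active porosity $\varepsilon_g$ (referred to the
full sample cross-section), superficial permeability $K$, and equivalent
pore radius $R_{eq}$, the meniscus height $h$ obeys

$$\varepsilon_g \frac{dh}{dt} =
  \left(\frac{2\sigma\cos\theta}{R_{eq}} - \rho g h\right)\frac{K}{\mu h},$$

which integrates to the implicit closed form

$$t(h) = -\frac{\mu\,\varepsilon_g}{\rho g K}
  \left(h + h_{max}\ln\!\left(1 - \frac{h}{h_{max}}\right)\right),
  \qquad h_{max} = \frac{2\sigma\cos\theta}{\rho g R_{eq}}.$$

`analytic_time()` evaluates this form, `height_at_time()` inverts it by
bracketed root finding, and `integrate_1d()` solves the ODE with an explicit
two-stage second-order (Heun) scheme. A gravimetric experiment sees the
*equivalent height* $h_{eq} = \varepsilon_g h$ (absorbed volume spread over
the full section, `to_equivalent_height()`). Two conventions matter and are
used consistently everywhere:

* porosities and permeabilities are sample-section effective values, so all
  volumetric fluxes use the full cross-section $S$ and front speeds divide
  by $\varepsilon_g$;
* all internal units are SI; millimetres and hours appear only in printing
  and plotting.

The rise is stopped once $h$ reaches the sample length $\ell$ (100 mm by
default) and the curve is flagged `capped`. When $\ell \ge h_{max}$ the cap
is never reached and integration simply runs to `t_end`, matching the
asymptotic physics.

Numerical choices in `integrate_1d()`:

* the start is singular ($dh/dt \to \infty$ at $h = 0$), so the first point
  is taken from the gravity-free closed form
  $h^2 = (4\sigma\cos\theta K / (R_{eq}\varepsilon_g\mu))\,t$ at a small
  fraction of the step cap, removing the singularity without an arbitrary
  seed height;
* steps then grow geometrically (at most 0.5% of elapsed time per step)
  until they reach `dt_max`, which defaults to `t_end/1e5`; each step is
  also limited to a front advance of $\ell/1000$;
* the scheme is second order; the tests measure an observed convergence
  order above 1.5 on a tall sample where neither cap interferes, and
  pointwise agreement with the closed form below one part in $10^3$ on all
  four study scenarios.

```{r one-d}
water <- builtin_fluids()$water
latewood <- builtin_tissues()$latewood
analytic_time(0.1, water, latewood) / 3600 # hours for water to climb latewood
```

## Parameters and presets

`builtin_fluids()` provides the two working fluids (water and silicone oil)
with one representative contact angle each (50 and 18 degrees, the values
measured along the grain on solid wood); `builtin_tissues()` provides the
four effective tissues (poplar vessels, spruce latewood, a generic fibre
tissue, and the "cross-section" tissue standing for lateral earlywood
invasion). The vessel preset sits between literature values and the
straight-tube-bundle bound $K = (\varepsilon_g/\tau) R_{eq}^2/8$
(`tube_bundle_permeability()`), which evaluates to $3\times 10^{-11}$ m²
for the vessel geometry.

Two points where the sources leave room, decided once here:

* the oil density preset is 1010 kg m⁻³ (the tabulated modelling value;
  the running text's 1000 kg m⁻³ is not used), and
* porosities are interpreted as fractions of the *total* sample
  cross-section — the only reading under which the equivalent-height
  conversion $h_{eq} = \varepsilon_g h$ is self-consistent.

`validate_setup()` returns invariant violations as messages (an empty
character vector for every preset); solvers raise the same checks as
`wi_invalid_parameter` conditions. Setups round-trip through a YAML config
(`write_imbibition_config()` / `read_imbibition_config()`) bit-exactly for
all presets. Gravity defaults to 9.81 m s⁻² and may be set to zero to work
in the gravity-free limit (used by the square-root-law tests), a deliberate
relaxation of the "strictly positive" reading of that setting.

## The dual-scale 2D model

For water in spruce the 1D picture fails: lateral invasion of earlywood
consumes part of the supply. `run_2d()` discretises the sample height into
`n_elements` elements (100 by default, 1 mm each). The state is the latewood
meniscus height $h_{L}$ plus one lateral penetration depth $y_i \le W$ per
element ($W$ = 4 mm ring width). Each step:

1. `solve_pressures()` assembles the Kirchhoff flux-conservation system for
   the wetted nodes — base node at gauge pressure 0, longitudinal Darcy
   conductances $K_{lw} S / (\mu \Delta z)$ acting on
   $(P_i - P_j - \rho g \Delta z)$, a meniscus suction boundary
   $P = -2\sigma\cos\theta/R_{lw}$ referenced through the last partial
   segment (length $h_L \bmod \Delta z$, floored at $\Delta z/10$), and one
   lateral sink per wetted element,
   $$Q_i = \frac{K_{cs}}{\mu}\,
     \frac{P_i + 2\sigma\cos\theta/R_{cs}}{y_i}\,\frac{S\,\Delta z}{W},$$
   with no gravity along the (horizontal) lateral direction. The linear
   system is tridiagonal plus diagonal and is solved directly each step.
   Elements whose nodal pressure cannot sustain lateral suction are
   deactivated for the step by fixed-point iteration on the active set, so
   lateral fronts never recede.
2. `advance_fronts()` moves the meniscus by the front flux over
   $S\,\varepsilon_{lw}$ and each active lateral front by the exact
   frozen-pressure closed form $y \mapsto \sqrt{y^2 + 2 K_{cs}\,d_i\,\Delta t
   /(\mu\,\varepsilon_{cs})}$ with $d_i$ the sink drive. This is the Euler
   rule in the small-step limit but is free of the $1/y$ stiffness right
   after activation; the volume ledger integrates lateral uptake with the
   same closed form, so the conservation check compares independently
   accumulated inflow against stored volume. Steps whose front advance
   would exceed `front_cfl` (default 0.5) element heights — laterally, ring
   widths — are rejected and retried at half the step.

`run_2d()` wraps the two in a two-stage (Heun) update with adaptive steps
capped at `dt_max` (default `t_end/2000`). Newly wetted elements activate
their lateral front at $y = 10^{-6}$ m (the lateral analogue of the 1D
startup step; the seeded volume is charged to the ledger). Lateral storage
uses the minimal ring geometry consistent with the section-effective
porosities: element $i$ holds $S\,\Delta z\,\varepsilon_{cs}\,(y_i/W)$ of
earlywood liquid, and the recorded equivalent height generalises the 1D
conversion,
$h_{eq} = \varepsilon_{lw} h_L + (\varepsilon_{cs}/W)\sum_i y_i \Delta z$.
The immersion-depth hydrostatic offset is ignored, as in the 1D model.
`moisture_field()` snapshots are sharp-front saturation grids over one
growth ring.

```{r two-d, eval = FALSE}
ts <- builtin_tissues()
res <- run_2d(water, ts$latewood, ts$cross_section,
              t_end = 10 * 3600, stop_at_cap = TRUE)
glance(res)
```

### What this closure can and cannot reproduce

The nodal sink law above is the flux-conserving reading of the dual-scale
coupling, and it carries a structural bound worth knowing. The meniscus pins
the top of the column at $-2\sigma\cos\theta/R_{lw}$; with the preset radii
($R_{lw} = 10\,\mu$m, $R_{cs} = 20\,\mu$m) the lateral suction is exactly
half the longitudinal one, so the nodal drive $P_i + 2\sigma\cos\theta/R_{cs}$
is extinguished wherever the column pressure drops below mid-suction —
roughly the upper half of the wetted column. However strong the sinks
become, the front flux can therefore never fall below
$K_{lw} S\,(2\sigma\cos\theta(1/R_{lw} - 1/R_{cs}) - \rho g h)/(\mu h)$,
about 44% of its 1D value, bounding the achievable slowdown of the rise at
roughly a factor 2.1 (a cap time of about 3.4 h for the water presets). In
practice the realised slowdown is smaller still, because the active sinks
sit low in the column where they draw mostly through the short path to the
reservoir: the default run caps at about 1.9 h versus 1.6 h for the
uncoupled 1D model, with the lateral uptake continuing long after the front
arrives. Closures that instead reference the lateral drive to the static
column pressure sustain demand at every height but overshoot in the other
direction (cap times beyond 12 h at unit exchange area). The package ships
the flux-conserving nodal law because it is the self-consistent one; the
bound above is the honest statement of what it implies for the rise time.

## Balance reduction

A hanging sample gains mass as liquid enters it; the reservoir level drops
as liquid leaves the container, reducing the buoyancy on the immersed mouth,
so raw readings overstate uptake. With container section $A_c$ and sample
section $S$, a true uptake $u$ lowers the level by $u/(\rho(A_c - S))$ and
the closure is $u = m_{raw}\,(A_c - S)/A_c$ (`buoyancy_correct()`): linear,
contractive, identity as $A_c \to \infty$. The experimental container
geometry is not part of the record, so $A_c$ is a required input; synthetic
work uses $A_c/S = 50$. `reduce_kinetics()` converts to
$h_{eq} = \Delta m/(\rho S)$, `sqrt_time_slope()` fits the early
$\sqrt{t}$ regime by ordinary least squares, and `fit_permeability()`
performs one-parameter least squares of the closed-form curve over
$\log_{10} K$ on a $[10^{-20}, 10^{-8}]$ m² bracket
(`stats::optimize()`; the curve is inverted on a 2000-point height grid,
uniform in $\sqrt t$ where the kinetics are steep). Model-data distance is
RMSE on $h_{eq}$ (not mass), so fluids are comparable; the model curve must
span the data window or a `wi_no_overlap` condition is raised.

## Synthetic recordings and what they do (not) show

`generate_balance_series()` runs a scenario's forward model, maps
$h_{eq}(t)$ to uptake mass, applies the inverse buoyancy map, samples every
10 s, and adds linear drift plus i.i.d. Gaussian reading noise (default
σ = 5 mg, a plausible figure for a microbalance carrying a ~100 g sample;
the study reports no noise model, so these are declared defaults, not
inferred ones). Generation is bit-reproducible given a seed
(`withr::with_seed`). The five preset scenarios (`scenario_presets()`) wire
the four 1D cases and the 2D water case to the built-in parameters and
default geometry. `recovery_experiment()` closes the loop: generate, reduce,
refit $K$, report relative errors across replicates.

The generator emulates the *statistical structure* of microbalance
recordings (smooth Washburn kinetics, buoyancy coupling, additive reading
noise, optional drift). It does not emulate swelling-induced apparent-mass
artifacts, evaporation, autocorrelated noise, or the biological variability
between samples — so a passing recovery experiment demonstrates that the
reduction-and-fitting chain is correct and noise-stable, not that field
recordings of real wood will identify $K$ to the same accuracy.

## Sizes and tolerances used by the test suite

The suite runs the 2D reference case (100 elements, steps capped at
`t_end/2000`) once to its cap, four 1D scenarios at $2\times 10^4$ steps,
a convergence ladder at 4–64 steps on a tall sample, and a 20-replicate
recovery experiment at σ = 5 mg — a few minutes end to end on one core.
Key tolerances: numeric-vs-analytic $10^{-3}$ relative; gravity-free
square-root slope 0.5%; volume conservation 0.5%; decoupled-limit agreement
0.5%; grid-doubling drift 1%; median recovery error 10%.

## Known limitations

* Fluid inertia (short times) and gas-phase viscosity are neglected.
* One homogeneous ring is modelled; per-ring heterogeneity, pit-aspiration
  statistics, and trapped-air effects are outside scope.
* Temperature dependence of the fluid properties is not modelled.
* The buoyancy closure assumes a rigid, non-evaporating bath; swelling is
  not corrected.
* The dual-scale rise-time bound discussed above: the printed behaviour of
  strongly coupled systems may require closures beyond the flux-conserving
  nodal law.
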