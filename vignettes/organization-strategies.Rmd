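---
title: "Modeling spatial organization strategies for two-enzyme pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatial organization strategies for two-enzyme pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgflux)
```

## The model and its assumptions

`orgflux` treats a bacterial cell as a sphere of radius $R_b$ with a single
concentric organizing volume of radius $R_c$ — an equivalent representation
of the cell's microcompartments or scaffold puncta collapsed into one
sphere holding **all** per-cell enzyme copies. The pathway is two
sequential enzymes: substrate $S_1$ is converted to intermediate $S_2$
(reaction 1), and $S_2$ to product (reaction 2). Product is not tracked:
with irreversible kinetics the rate of reaction 2 fully determines
production.

Assumptions, in decreasing order of importance:

1. **Steady state.** Cultures are analyzed at a quasi-stationary operating
   point; no transients.
2. **Constant external concentrations.** The medium is an infinite bath at
   $S_{1,\mathrm{out}}$ (and $S_{2,\mathrm{out}}$, normally zero).
3. **Irreversible Michaelis–Menten kinetics** by default,
   $R_i = V_i S_i/(K_i+S_i)$ with $V_i = k_{cat,i} N_i/(N_A V_{region})$.
4. **Spherical symmetry**, with transport as Fickian diffusion
   (diffusivity $D$) plus mass-transfer (Robin) conditions at the membrane
   ($k_m$, cm/s) and compartment boundary ($k_c$, cm/s).
5. For the organized strategies, the organizing volume is treated as
   **well mixed** (see the correction below).

The unit system is fixed package-wide: cm, s, µM, cm²/s, cm/s, and
µmol/cell/s for per-cell fluxes, matching how these systems are tabulated
in the microcompartment literature. A scaffold is modeled as an organelle
whose boundary permeability is set to $10^3$ cm/s, a value high enough
that the boundary is indistinguishable from free diffusion; the
`"none"` strategy distributes the enzymes over the whole cell volume, so
$V_i$ is computed over $\tfrac43\pi R_b^3$ instead of
$\tfrac43\pi R_c^3$.

## The organized solver: resistances in series

In the reaction-free cytosol shell each species satisfies Laplace's
equation, so $S_i(r) = a_i + b_i/r$ and the total diffusive flow through
any concentric sphere is constant. Membrane, shell and compartment
boundary therefore act as three resistances in series, and the flow
between medium and compartment is $J_i = G_i (S_{i,\mathrm{out}} -
S_{i,c})$ with

$$ G_i^{-1} = \frac{1}{4\pi R_b^2 k_m^i} +
   \frac{1/R_c - 1/R_b}{4\pi D} +
   \frac{1}{4\pi R_c^2 k_c^i} + \frac{1}{20\pi D R_c}. $$

The last term is this package's refinement of the plain well-mixed
picture: a sphere with a uniform volumetric reaction supports a parabolic
internal profile, and relating the *volume-mean* concentration (at which
the rates are evaluated) to the inner-surface value adds the spreading
resistance $1/(20\pi D R_c)$. For a barrier-dominated organelle this term
is $\sim 10^{-6}$ of the total and changes nothing; in the free-diffusion
scaffold limit it is what keeps the closed-form solution within 0.1% of
the full spatial solution (without it the flux error is ~4% for the Pdu
scaffold). The compartment-boundary conservation diagnostic uses the same
interface law, so the three-way flow identity holds exactly at
convergence.

Steady state closes the system with two mass balances: substrate inflow
equals compartment consumption, $G_1(S_{1,\mathrm{out}} - S_{1,c}) =
V_c R_1(S_{1,c})$, and intermediate outflow equals net production,
$G_2(S_{2,c} - S_{2,\mathrm{out}}) = V_c\,(R_1 - R_2(S_{2,c}))$. With
irreversible kinetics $R_1$ does not depend on $S_{2,c}$, so the system
is triangular and each balance is strictly monotone in its unknown: each
is solved by bracketed Brent root finding on the physical interval
(starting at $[0, S_{1,\mathrm{out}}]$, with geometric bracket expansion
for the intermediate). This converges for every physical parameter set and
is independent of initialization, which is why it was preferred over a
damped Newton iteration on the joint system. With the reversible rate law
the balances couple and a nested bracketed root find (outer in $S_{2,c}$,
inner in $S_{1,c}$) is used instead. Default tolerance $10^{-10}$
(relative residual), iteration cap 200.

## The finite-volume solver

The unorganized case has reactions everywhere, so no closed form exists;
it is solved on a radial grid, which also provides full-resolution
validation of the well-mixed solution for the organized cases. Three
numerical choices matter:

* **Conservative (vertex-centred finite-volume) discretization.** Unknowns
  sit at nodes $0 = r_1 < \dots < r_n = R_b$ with a node placed exactly at
  $R_c$; each internal face flow is computed once and enters the two
  adjacent control volumes with opposite signs. Summing the converged
  residuals therefore telescopes exactly: membrane influx matches the
  volume-integrated reaction rates to the solver tolerance, not merely to
  discretization error. Robin conditions enter as face flows; in the
  organized case the node at $R_c$ is duplicated and the two copies are
  coupled through the permeability $k_c$ (the concentration is
  discontinuous across the shell). The scheme is second-order on uniform
  spacing; grids are uniform within the compartment and within the
  cytosol, with nodes allocated proportionally ($\ge 10$ inside). Default
  $n = 400$ nodes; halving the spacing moves the Pdu flux by
  $<10^{-3}$ relative, and `check_grid = TRUE` automates that check.

* **Bath-referenced deviation variables.** The solver iterates on
  $u = S_{ref} - S$ with the bath value as the default reference. The
  interesting fields here are often a large constant ($5.5\times10^4$ µM)
  carrying gradients ten orders of magnitude smaller; in absolute
  variables the face flows would hit a double-precision floor around
  $10^{-4}$ relative, breaking the $10^{-6}$ conservation requirement.
  In deviation variables the flows retain full precision. When a nearly
  sealed compartment decouples the interior from the bath (interior
  concentrations near zero rather than near the bath), the interior is
  re-referenced to zero and the solve retried — the two regimes are
  detected automatically.

* **Safeguarded Newton.** The Jacobian is the constant transport operator
  plus the diagonal reaction derivative. Saturated Michaelis–Menten terms
  make naive Newton overshoot to negative concentrations, so steps are
  capped so no nodal concentration falls more than 99% per iteration, and
  halved while the residual fails to decrease. With irreversible kinetics
  the $S_1$ system is solved first and its reaction field enters the
  (then decoupled) $S_2$ system as a source.

The reversible rate law is supported by the analytic organized solver
only; the compartment is where reversibility matters (it caps the
intermediate concentration a selectively permeable shell can accumulate),
and the opposing-Michaelis–Menten form — forward rate on $S_1$ minus
reverse rate on $S_2$ — was chosen for its limit properties: it reduces
exactly to the irreversible law at zero reverse rate, is negative under
pure back-reaction, and vanishes at the balance point.

## Metrics and the strategy comparison

* **Pathway flux**: per-cell rate of reaction 2 (product formation),
  $V_c R_2(S_{2,c})$ or the volume integral of $R_2$, in µmol/cell/s. At
  steady state it also equals substrate influx minus intermediate leakage;
  both routes are computed and their agreement is part of the test suite.
  (Substrate *consumption* differs from product formation exactly by the
  leakage term; this package defines "flux" as product formation.)
* **Intermediate leakage**: membrane efflux
  $4\pi R_b^2 k_m^{S2} (S_2(R_b) - S_{2,\mathrm{out}})$. Losses to
  hypothetical competing cytosolic reactions are out of scope.
* **Cytosol gradient**: $(S(R_b) - S(R_c))/S(R_b)$ per species, the
  diagnostic for the constant-far-field assumption (at the Pdu baseline it
  is $<10^{-5}$ for substrate).

`compare_strategies()` solves all three strategies with shared parameters
and reports the optimum. Objectives within $10^{-3}$ relative are treated
as tied and resolved toward the least engineering effort (none, then
scaffold, then organelle). The tolerance is deliberately coarser than the
solver accuracy: strategy landscapes contain genuinely flat regions —
e.g. for slow, abundant enzymes a scaffold outperforms no organization by
only $\sim 3\times10^{-4}$ relative, and at vanishing enzyme activity the
organelle's leakage advantage is $\sim 10^{-4}$ — and differences that
small are below any practical significance (and below the ~1%
cross-solver validation accuracy), so recommending the simpler
construction is the defensible engineering default. Callers who want
strict arg-max behavior can pass a smaller `tie_tol`; the per-strategy
objective values are always reported alongside `best`.

## Design-space analysis

`sweep_1d()` and `optimal_strategy_map()` evaluate the comparison along
one parameter or over a 2D grid addressed by dotted parameter paths
(`"conditions.S1_out"`, `"transport.k_m_S2"`, …). The composite path
`"enzyme2.k_cat_E0"` addresses the activity product $k_{cat} E_0$ (enzyme
concentration referred to the organizing volume, µM/s) by scaling
$k_{cat}$ at fixed copy number — the axis on which organization design
spaces are conventionally drawn. Grids are typically log-spaced
(`log_grid()` spans ±3 decades around a baseline with 25 points per axis
by default); map cells are mutually independent, and cells where no
strategy converges are labelled `"unconverged"` rather than interpolated.
Axis ranges are user-configurable; the defaults span the preset baselines.

## Calibration of literature observations

Two conversions compare model predictions with experiments, both exactly
linear in their observable. A growth observation (doubling time $t_d$ on
the pathway substrate as sole carbon source) implies
$\Phi = (m_{cell}/t_d)/f/M$, with cell mass $m_{cell}$ (default 0.3 pg),
$f$ the fraction of pathway mass flux usable for growth (default 0.5) and
$M$ the substrate molar mass (default 76.09 g/mol, 1,2-propanediol — not
a tabulated model parameter but required by the mass-to-mole conversion).
The mass accumulation rate is taken as $m_{cell}/t_d$ without a
$\ln 2$ factor; this convention reproduces the published per-cell flux
scale from the published inputs, and the two conventions agree to well
within the precision of such estimates. A titer observation converts as
$\Phi = \mathrm{titer}/(\mathrm{duration}\cdot\mathrm{cell\ density})$.

```{r calibration}
flux_from_growth(growth_observation(doubling_time = 7.5 * 3600))
flux_from_titer(titer_observation(1e4, 2 * 86400, 2e9))
```

## Problem sizes and verification

The test suite and the acceptance script run entirely from the two
built-in presets; there are no external data. Verification is by
independent oracles rather than by comparison with any particular code:
the organized solver against the finite-volume solver (≤1% on fluxes for
both presets and both organized strategies), the finite-volume solver
against the closed-form solution of the linearized equations
(modified-spherical-Bessel $\sinh(\phi r)/r$ modes) in the
$S \ll K_M$ regime (≤0.5%), Richardson-style grid refinement, exact
conservation identities ($<10^{-6}$ relative on every converged solve),
and enzyme-capacity bounds $k_{cat}N/N_A$. Routine solves use $n = 400$
finite-volume nodes; sweeps in the tests use 6–10 point ladders and maps
a handful of cells, sizes at which the full analysis runs in seconds on a
laptop while remaining grid-converged to well below the tolerances being
asserted.

## Known limitations

* The spreading-resistance correction assumes a roughly uniform reaction
  density inside the organizing volume; at very high Thiele modulus
  (strong intra-compartment gradients) the closed form degrades and the
  finite-volume solver should be used directly.
* One equivalent compartment: effects of the number, size distribution and
  subcellular position of multiple discrete organelles are out of scope.
* No cofactor balances, enzyme inhibition, competing cytosolic reactions,
  or product export; time-dependent dynamics are out of scope.
* Membrane and shell permeabilities are taken as given parameters, not
  estimated from chemical structure.
* The reversible rate law is a phenomenological opposing-MM form validated
  by its limits, and is available in the well-mixed organized solver only.
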