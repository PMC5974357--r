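# orgflux

Steady-state flux of spatially organized two-enzyme pathways in bacteria.

## The problem

Metabolic engineers can organize a heterologous pathway in three ways:
encapsulate the enzymes in a protein-bound organelle (a bacterial
microcompartment such as the Pdu MCP), co-localize them on a scaffold
(protein, lipid or nucleic acid, without a diffusion barrier), or leave them
free in the cytosol. Which choice maximizes pathway flux — or minimizes loss
of a toxic or valuable intermediate to the medium — depends on enzyme
kinetics, membrane and shell transport, and culture conditions. `orgflux`
answers that question quantitatively with a spatially resolved steady-state
kinetic model of a sequential two-enzyme pathway (substrate S1 →
intermediate S2 → product) in a spherical cell, and maps the optimal
strategy across parameter space.

## The model

A spherical cell of radius R_b contains a concentric organizing volume of
radius R_c (the organelle or scaffold region holding all enzyme copies; for
the unorganized case the enzymes fill the whole cell). At steady state,

- cytosol (no reaction): `D ∇²S_i(r) = 0`
- organizing volume: `D ∇²S1 − R1 = 0`, `D ∇²S2 + R1 − R2 = 0`

with irreversible Michaelis–Menten kinetics
`R_i = V_i S_i / (K_i + S_i)`, `V_i = k_cat,i N_i / (N_A V_region)`.
Boundary conditions: Robin (mass-transfer) conditions at the cell membrane,
`D dS_i/dr(R_b) = k_m^i (S_i,out − S_i(R_b))`, an analogous permeability
condition with coefficient `k_c^i` at the compartment boundary, and
symmetry at the origin. A scaffold is an organelle whose boundary
permeability approximates free diffusion (k_c = 10³ cm/s).

For the organized strategies the cytosol profiles are `a + b/r` (Laplace)
and, treating the organizing volume as well mixed, the model collapses to
series transport resistances closed by two monotone mass balances, solved
by bracketed root finding. The unorganized case (and full-resolution
validation of the organized cases) uses a conservative finite-volume
Newton solver on a radial grid. Outputs per cell: pathway flux (product
formation, µmol/cell/s), intermediate leakage across the membrane, radial
concentration profiles, and conservation diagnostics.

Parameter presets reproduce two reference systems: native Pdu
microcompartment metabolism (PduCDE → PduP/Q, 1,2-propanediol →
propionaldehyde) and heterologous mevalonate biosynthesis (HMGS → HMGR).

## Worked example

```r
library(orgflux)
sol <- solve_organized(preset("pdu"))
print(sol)
#> <steady_state_solution> strategy: organelle  method: analytic  converged: TRUE
#>   compartment: S1 = 3318.99 uM, S2 = 38596 uM
#>   at membrane: S1 = 54997.9 uM, S2 = 1.54376 uM
#>   pathway flux:         1.64423e-13 umol/cell/s
#>   intermediate leakage: 4.84988e-13 umol/cell/s
#>   residual: 3.82e-11 after 17 iterations
```

With 55 mM external 1,2-propanediol, substrate drops only ~6% from the
membrane into the microcompartment (3319 µM there), while the
propionaldehyde intermediate accumulates to ~38.6 mM inside — above the
15 mM Michaelis constant of PduP/Q — which is what drives the flux benefit
of encapsulation. The cell converts 1.6e-13 µmol/cell/s to product and
leaks 4.8e-13 µmol/cell/s of intermediate; their sum equals substrate
uptake (mass conservation).

```r
compare_strategies(preset("pdu"), "max_flux")
#> <strategy_comparison> objective: max_flux
#>   organelle  flux 1.64423e-13  leakage 4.84988e-13 umol/cell/s
#>   scaffold   flux 4.48464e-17  leakage 7.40466e-13 umol/cell/s
#>   none       flux 3.62304e-17  leakage 7.40474e-13 umol/cell/s
#>   best: organelle
```

The organelle out-produces the scaffold and the unorganized cell by more
than three orders of magnitude for this pathway, and leaks the least
intermediate. Design-space maps over any two parameters
(`optimal_strategy_map()`), 1D sweeps (`sweep_1d()`), and calibration of
literature observations to per-cell fluxes (`flux_from_growth()`,
`flux_from_titer()`) complete the analysis. A command-line interface is
installed at `exec/orgflux` (subcommands `solve`, `sweep`, `map`,
`calibrate`).

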