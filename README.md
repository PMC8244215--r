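# rspaths

Movement of real animals is neither a blind random walk nor a perfectly
informed least-cost march — it sits somewhere in between, and *where* it
sits matters for conservation: corridor maps drawn under the wrong
assumption protect the wrong places. `rspaths` implements a complete
workflow for inferring the randomness level of animal movement from GPS
telemetry and turning it into corridor networks, built around the
randomized-shortest-path (RSP) model of landscape connectivity. It is
aimed at movement ecologists and connectivity modellers who want the
whole chain — habitat model, routing model, validation, corridors — in
one tested, scriptable package.

## The model

A conductance raster (each cell's permeability to movement, in (0,1))
becomes a sparse 8-neighbour graph with edge conductance
`g_ij = mean(c_i, c_j)/d_ij`, reference walk `p_ij = g_ij / Σ_k g_ik`
and cost `κ_ij = 1/g_ij`. Under RSP, a path `℘` from source to
destination has probability ∝ `π_ref(℘) · exp(−θ·c(℘))`: the single
parameter θ interpolates from circuit theory (θ = 0) to the least-cost
path (θ → ∞). Passage surfaces come from two sparse linear solves
(forward visits `u`, backward absorption weights `z`), expected edge
flows `η_ij = u_i w_ij z_j / z_s`, and per-cell net throughflow
`½ Σ_j |f_ij|`.

θ is calibrated by scoring the passage surfaces of an 11-value grid
(0 … 0.01) against held-out fixes with four validation statistics —
Brownian-bridge MSE, representation in percentile corridors, logistic
AIC, and rank percentile of used vs available points — and taking each
method's optimum. Corridors are the top decile of the summed
inter-nuclei flux, excluding nucleus areas, compared against circuit
and LCP baselines by shared area and surface correlation.

The habitat side is a point selection function: used composition =
3×3-window class proportions at each fix; available composition =
generalized-Pareto distance-weighted mean within the 99th-percentile
displacement radius; weighted logistic contrast with a reference cover
class (conditional-likelihood variant included); prediction used
directly as conductance.

Because suitable telemetry is not openly available, the package ships a
first-class synthetic module: autocorrelated categorical landscapes
with known selection coefficients, population nuclei, territorial
(Ornstein–Uhlenbeck) fixes, and exploratory trajectories sampled
*exactly* from the RSP path distribution at a known θ* — so every
downstream stage has a recoverable ground truth.

## Worked example

```r
library(rspaths)

# a synthetic study: 100x100 landscape, 5 nuclei, 30 trajectories at
# theta* = 5e-4
sim <- simulate_study(simulation_config(seed = 1))
sim$conductance
#> raster2d: 100 x 100 cells, res 125, extent x [0, 12500] y [0, 12500]
#>   values in [0.0192252, 0.951601], 0 nodata cells

# calibrate theta with all four validation methods (a few minutes)
rep <- run_calibration(sim$ts, sim$trajs, delta = 25, seed = 1)
rep$optimal
#>            method percentile best_theta
#>   brownian_bridge         NA      0e+00
#>         corridors         85      0e+00
#>         corridors         90      1e-04
#>         corridors         95      1e-03
#>         corridors         99      1e-05
#>          logistic         NA      0e+00
#>           ranking         NA      1e-03
```

The corridor-representation (percentile 90) and ranking methods land
within one grid step of the generating θ* = 5e-4; the Brownian-bridge
and logistic statistics drift to the random extreme at this domain size
(see the vignette for why). Every surface ranks used points above
chance — the minimum ranking score across the grid is 53.7 (> 50).

```r
cmp <- run_corridor_comparison(sim$ts, sim$nuclei, reference_theta = 1e-4,
                               rsp_thetas = c(0, 0.01))
cmp$table
#>        approach  method theta shared_area_pct surface_correlation
#>   rsp_reference     rsp 1e-04       100.00000           1.0000000
#>     rsp_theta_0     rsp 0e+00        92.11066           0.9982962
#>  rsp_theta_0.01     rsp 1e-02        73.87295           0.9482836
#>         circuit circuit    NA        92.11066           0.9982962
#>             lcp     lcp    NA        38.01230           0.4576885
```

The θ = 0 network is exactly the circuit-theory network, and the LCP
network differs most from the optimised reference — deterministic
routing draws narrower, different corridors.

The same pipeline runs as a narrative workflow in `analysis/`:
`01_simulate.R` → `02_habitat.R` → `03_calibrate.R` → `04_corridors.R`,
each writing its tables and rasters under `results/`.

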