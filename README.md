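# nppimpact

Urbanization changes vegetation net primary productivity (NPP) in two very
different ways. Replacing vegetated land with impervious surface removes
productive area outright — a **direct** impact that is always a loss. At the
same time, the altered urban environment (most visibly urban-heat-island
warming) changes how the *remaining* vegetation grows — an **indirect**
impact that can be positive. `nppimpact` separates the two on a regular
fishnet grid, tests how strongly each field clusters in space, and maps
where land surface temperature (LST) helps or hurts the indirect component,
using geographically weighted regression (GWR). It is aimed at landscape
ecologists and urban carbon-cycle analysts working with co-registered
NPP / impervious-fraction / LST rasters.

## The model

Let `β(x, t) ∈ [0, 1]` be the impervious-surface fraction of cell `x` at
time `t` (the urbanization intensity), and `NPP_fv(x)` the productivity the
cell would have under ideal full vegetation cover, assumed constant in time.
The hypothetical productivity if urbanization acted only through land cover
is

    NPP_h(x, t) = [1 − β(x, t)] · NPP_fv(x)

With a baseline year `t0` and a later year `t1`, the decomposition is

    NPP_dir(x, t1) = [β(x, t0) − β(x, t1)] · NPP_fv(x)
    NPP_ind(x, t1) = NPP(x, t1) − [1 − β(x, t1)] · NPP_fv(x)

Wherever the baseline is land-cover controlled
(`NPP(x, t0) = NPP_h(x, t0)`), these satisfy
`NPP_dir + NPP_ind = NPP(t1) − NPP(t0)` exactly.

Spatial structure is quantified with global Moran's I
(`E(I) = −1/(n−1)` under the null; normality, randomization and permutation
inference) and local Moran's I with LISA classes HH / LL / LH / HL / NS from
conditional permutation. The effect of LST on `NPP_ind` is estimated
globally by OLS and locally by GWR,

    y_i = β_0(u_i, v_i) + Σ_k β_k(u_i, v_i) x_ik + ε_i
    β̂(u_i, v_i) = (Xᵀ W_i X)⁻¹ Xᵀ W_i y

with bi-square kernel weights `w = (1 − (d/b)²)²` for `d < b`, an adaptive
bandwidth (distance to the k-th nearest cell) selected by corrected AIC, and
model comparison on a common Gaussian AIC scale (a difference larger than 3
is decisive).

Because the imagery behind any particular city is rarely redistributable,
the package ships a synthetic-city generator with known ground truth
(logistic urban core, UHI-shaped LST, a spatially varying LST coefficient
surface `γ(x)`), so the whole chain is testable end to end.

## Worked example

```r
library(nppimpact)

city <- generate_city(city_config(grid_n = 60, seed = 1))   # 15 x 15 km city
grid <- aggregate_to_fishnet(c(city$layers, city$truth), cell_size = 500)
grid$cells$npp_fv <- grid$cells$npp_fv_true                  # truth baseline
grid <- decompose_impacts(grid, npp_fv_mode = "supplied")

w <- build_weights(grid)                                     # queen, row-std
moran_permutation_test(grid$cells$npp_ind, w, n_perm = 999, seed = 10)
#> Global Moran's I = 0.7894  (E[I] = -0.0011, n = 900)
#>   normality:     z =   45.995, p = 0
#>   randomization: z =   46.005, p = 0
#>   permutation:   p = 0.001 (999 permutations)

ols <- fit_ols(grid, "npp_ind", "lst_t1")
bw  <- select_bandwidth(grid, "npp_ind", "lst_t1")           # AICc, golden
gwr <- gwr_fit(grid, "npp_ind", "lst_t1",
               kernel_spec("bisquare", "adaptive", bw$bandwidth))
compare_models(ols, gwr)$table
#>   model adj_r_squared      aic
#> 1   OLS     0.5383256 5906.338
#> 2   GWR     0.8258683 5027.030
```

The indirect impact clusters strongly (I = 0.79, permutation p at the
0.001 floor). Globally, one degree of LST adds ~6.0 gC m⁻² yr⁻¹ of
indirect NPP, but the GWR surface shows that average hides strong spatial
heterogeneity: the local LST coefficient runs from −7.5 to +21.5 with
positive values concentrated in the urban core (79.8% of cells positive
here), and the fit improves decisively (ΔAIC = −879, "GWR preferred").
Against the generator's truth, the estimated coefficient surface correlates
with `γ(x)` at r = 0.976. The same chain runs from a single config via
`run_pipeline()`, which writes all tables (grid, Moran summary, LISA maps,
OLS/GWR coefficients, model comparison) plus a manifest, and
`pipeline_report()` renders them as one markdown report.

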