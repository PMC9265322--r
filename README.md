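# econetr

Rapidly urbanising regions fragment their natural habitat: woodland,
grassland, rivers and farmland survive as disconnected patches inside an
expanding construction matrix. Landscape ecologists respond by designing
**ecological networks** — systems of *sources* (large, well-connected
habitat patches), *corridors* (least-cost routes along which organisms and
material can move between sources) and *nodes* (point locations where flows
concentrate or are obstructed). `econetr` implements that workflow as a
tested, fully scriptable R pipeline for categorical land-cover rasters plus
terrain, of the kind used in metropolitan-scale planning studies (the
running example emulates a Yellow-River-basin metropolitan area: high
fragmented terrain in the west, a long narrow river corridor, a central
urban block, paddy-field plains in the east).

The stages, each usable on its own:

1. **MSPA** — morphological spatial pattern analysis of the binary
   foreground (habitat classes) into `core`, `islet`, `edge`,
   `perforation`, `bridge`, `loop`, `branch`, by chamfer-distance erosion
   and connectivity rules. Core patches are candidate sources.
2. **Connectivity screening** — graph-theoretic indices over patches with a
   dispersal-distance threshold *d* and dispersal probability
   *p(d)* = exp(*k·d*) calibrated to 0.5 at the threshold:

   - LCP = Σ (Δᵢ/SL)² over components,
   - IIC = [Σᵢⱼ aᵢaⱼ/(1+nlᵢⱼ)] / SL²,
   - PC = [Σᵢⱼ aᵢaⱼ μ*ᵢⱼ] / SL²,

   with per-patch importance dΦ = 100·(Φ − Φ₋ₓ)/Φ. Patches with dPC > 1
   become ecological sources; a threshold sweep (default 100–2000 m)
   supports choosing *d*.
3. **Resistance surface** — per-layer resistance coefficients (MSPA class,
   land cover, elevation, slope; defaults on a 1–100 ladder) combined by
   AHP-weighted sum (default weights 0.5638/0.2634/0.1178/0.055, consistency
   ratio checked).
4. **Corridors** — exact Dijkstra cost distance over the 8-connected grid
   (move cost = mean endpoint resistance × step length), least-cost paths
   between all source pairs, a 10 km length floor and duplicate removal,
   then the gravity model G = L²ₘₐₓ ln(aᵢ)ln(aⱼ)/L²ᵢⱼ with tiers
   level 1 (>100), level 2 (10–100], level 3 (1–10], excluded (≤1).
5. **Nodes** — sink-filled D8 flow over the resistance surface extracts
   valley lines (top accumulation quantile) and ridge lines (same on the
   negated surface); intersections yield strategic (ridge × max-cost
   corridor), natural (persistent corridor crossings) and artificial
   (valley × roads/rivers/paddy) nodes.
6. **Network evaluation** — α = (L−V+1)/(2V−5), β = L/V, γ = L/(3(V−2))
   and cost ratio = 1 − L/C per corridor–node subnetwork.
7. **Markov–CA projector** — transition matrices estimated from raster
   pairs, Markov demand projection with exact count conservation, and a
   cellular-automaton allocator (suitability × neighbourhood density ×
   demand-driven inertia) with kappa/overall-accuracy validation.
8. **Synthetic landscapes** — a seeded generator (fractal DEM with a
   west-high trend, autocorrelated land cover, river + urban overlays,
   multi-date series with known transition probabilities) so the entire
   pipeline is reproducible without external data.

## Worked example

```r
library(econetr)

spec <- synth_spec()                      # 150 x 150 cells, 600 m
demo <- make_demo_landscape(spec)
cfg  <- pipeline_config(seed = 1L)

res <- run_pipeline(cfg,
                    list(landcover = demo$landcover[[1]],
                         dem = demo$dem, slope = demo$slope),
                    out_dir = "demo-run")

res$sources$importance |> dplyr::filter(selected)
#> # A tibble: 10 × 6
#>       id area_km2  dLCP  dIIC   dPC selected
#>    <int>    <dbl> <dbl> <dbl> <dbl> <lgl>
#>  1     4    145.  20.2  20.6  20.5  TRUE
#>  2     8     37.8  1.37  1.40  1.39 TRUE
#>  3     9     39.6  1.51  1.53  1.53 TRUE
#>  4    15     90    7.78  7.91  7.89 TRUE
#>  5    17     32.8  1.03  1.05  1.05 TRUE
#>  6    43    222.  47.4  48.2  48.1  TRUE
#>  7    48     56.9  3.11  3.16  3.15 TRUE
#>  8    57     56.5  5.10  4.16  4.34 TRUE
#>  9    65     18.7  2.37  1.38  1.57 TRUE
#> 10    66     79.2  6.41  6.32  6.34 TRUE

dplyr::count(res$corridors$corridors, level)
#> # A tibble: 2 × 2
#>   level     n
#> 1     1     7
#> 2     2     2

dplyr::count(res$nodes$nodes, node_type)
#> # A tibble: 3 × 2
#>   node_type      n
#> 1 artificial    16
#> 2 natural        6
#> 3 strategic      2
```

Ten patches clear the dPC > 1 bar and anchor the network (the two largest,
145 and 222 km², carry dPC ≈ 20 and 48: removing either would cost a fifth
to a half of the landscape's probability of connectivity). Between the 45
source pairs, nine corridors survive the 10 km floor and duplicate
removal with gravity above 1 — seven of them strong level-1 links. The
node stage finds 2 strategic ridge crossings, 6 natural corridor
crossings and 16 artificial obstruction points. `demo-run/` then holds the
full artifact set: `mspa.asc`, `sources.csv`, `resistance.asc`,
`corridors.csv`/`corridors.geojson`, `nodes.geojson`,
`network_metrics.csv` and a `params.yaml` log of every setting; rerunning
with the same seed reproduces the tables byte for byte.

`autoplot()` methods draw the rasters (`autoplot(res$mspa)`,
`autoplot(res$resistance)`), `plot_network()` overlays corridors and nodes
on the resistance surface, and `tidy()`/`glance()` methods expose patch
graphs, transition matrices and CA runs as tibbles.

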