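# airnet

Aerial connectivity networks from backward air-mass trajectories.

Airborne microorganisms — plant-pathogen spores, pollen, bacteria — travel
long distances on moving air masses, and any air-sampling campaign has to
decide *where* and *when* to sample a territory it cannot cover
exhaustively. `airnet` turns archives of hourly-resolved backward air-mass
trajectories (e.g. HYSPLIT endpoint output) into spatio-temporal contact
networks that reveal which regions are recurrently connected by the
atmosphere, in which season, and which cells act as strong sources
(spreaders) or sinks (receptors). It is aimed at aerobiologists and
epidemiologists designing surveillance layouts for airborne propagules.

## The model

The territory is divided into `N` grid cells whose centroids are the
network nodes. For each day `t`, a 48-h backward trajectory arrives at each
cell; the daily contact network is the binary directed adjacency

    E_t(j, i) = 1  iff the trajectory arriving at cell i on day t
                    passed over cell j during the preceding 48 h

(edge direction = source → arrival; self-loops excluded). Daily networks
are averaged over any day subset `S` (the whole period, a year, a month, a
season):

    E_S(i, j) = Σ_{t ∈ S} E_t(i, j) / |S|

so a weight is the fraction of days of `S` on which the connection
occurred. On these weighted digraphs the package computes:

* **General metrics** — density, weighted transitivity, in/out-strength
  correlation, and diameter / average shortest path after converting
  weights to *effective distances* `ED(i, j) = 1 − ln P(i, j)` on the
  row-standardized adjacency `P` (Dijkstra on the ED digraph).
* **Cut distance** between same-node-set networks — the maximum over node
  bipartitions `(Q, Q̄)` of `|Σ_{i∈Q, j∉Q} (A_ij − B_ij)| / N²`, by exact
  enumeration for `N ≤ 20` or a seeded memetic genetic algorithm beyond;
  hierarchical clustering of the 12 monthly networks on this distance
  identifies the seasons of the connectivity pattern.
* **Pareto-front edge selection** — among all non-null edges, those that
  jointly maximize edge weight and great-circle distance (the stable
  long-range connections worth sampling), plus the fraction of edges
  nearest the front in the min–max-normalized weight–distance plane.
* **Node relevance** — betweenness, closeness, coreness, eigenvector
  centrality, in/out-strength and strength.
* **Threshold SI epidemics** — a deterministic susceptible–infected model
  (a susceptible cell becomes infected when some infected in-neighbour is
  connected with weight above a threshold, default 0.1, for 6 synchronous
  steps), yielding the *SI persistence* `P(i)` (percentage of cells
  infected by an epidemic seeded at `i`; spreader strength) and the *SI
  frequency* `F(i)` (percentage of the `N` seed-varied epidemics that end
  up infecting `i`; receptor strength).

A synthetic trajectory generator with season-dependent wind regimes
(direction the air comes from, speed, hourly jitter) makes the entire
pipeline runnable and testable without meteorological data.

## Worked example

A 4×4 lattice with 74-km cells off the Gulf of Lion, one year of synthetic
trajectories with summer westerlies (May–September) and winter easterlies:

```r
library(airnet)
grid <- make_lattice_grid(4, 4, 74, c(5, 43))
cal  <- synth_calendar("2015-01-01", "2015-12-31", list(
  wind_regime(5:9,            270, 40, dir_noise_deg = 15, speed_noise_kmh = 5),
  wind_regime(c(10:12, 1:4),   90, 40, dir_noise_deg = 15, speed_noise_kmh = 5)))
ts      <- generate_trajectories(grid, cal, seed = 42)
dailies <- build_daily_networks(ts, grid)
seasons <- project_periods(dailies, "seasonal")

seasons$summer
#> <agg_network> 'summer': 16 nodes, 59 non-null edges (mean of 153 days)
network_metrics(seasons$summer)
#>    label diameter   density transitivity strength_correlation average_shortest_path
#> 1 summer 17.87712 0.1029684    0.7587317             -0.99817              5.438318
```

The diameter and average shortest path are in effective-distance units; a
density of 0.103 means the average cell pair is connected on ~10 % of
summer days. The strength correlation is strongly negative because, under
a single prevailing wind, upwind border cells are pure sources and
downwind ones pure sinks. Weights decay with distance, Tobler-style:

```r
weight_distance_correlation(seasons$summer)
#> [1] -0.21
```

The SI indices mirror the west→east summer flow — western cells spread,
eastern cells receive (node ids are row-major from the south-west corner):

```r
si <- si_indices(seasons$summer)   # threshold 0.1, 6 steps
round(head(si$persistence, 8), 1)
#>    1    2    3    4    5    6    7    8
#> 25.0 18.8 12.5  6.2 31.2 18.8 12.5  6.2
round(head(si$frequency, 8), 1)
#>    1    2    3    4    5    6    7    8
#>  6.2 12.5 18.8 31.2  6.2 12.5 18.8 25.0
```

Pareto selection of the persistent long-range connections:

```r
cl <- edge_cloud(seasons$summer)       # 59 non-null edges
head(select_near_front(cl, fraction = 0.05), 3)
#>    src dst distance_km weight score
#> 15   5   6    74.41335      1     0
#> 22   6   7    74.41335      1     0
#> 59  15  16    72.74347      1     0
```

`run_pipeline(config, out_dir)` chains all stages (synthesis → daily
networks → aggregation → metrics → cut-distance clustering → Pareto →
node/SI indices) from one YAML configuration and writes CSV outputs plus a
reproducibility manifest; see
`system.file("extdata", "toy_config.yaml", package = "airnet")` and the
thin command-line wrapper `inst/cli/airnet.R`.

## Trajectory file format

One trajectory per plain-text file, laid out as
`<node_id>/<YYYYMMDD>.tdump`. Byte-exact example (3-h trajectory):

```
AIRNET-TDUMP node 1 date 2015-06-01 duration 3
0 5.000000 43.000000 500.0
-1 4.508139 42.998947 500.0
-2 4.016286 42.997894 500.0
-3 3.524442 42.996841 500.0
```

Header: arrival node id, arrival date, duration (hours). Records: hour
offset (0 down to −duration), longitude, latitude (decimal degrees, 6
decimals), altitude (m). Native HYSPLIT tdump endpoint files map onto this
dialect by keeping the endpoint records' hour-offset, lon, lat and height
columns and writing one file per (arrival point, arrival day).

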