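# nodeloc

Localization of radio-tagged animals from **node networks** — grids of
fixed, omnidirectional radio receivers that continuously log the received
signal strength (RSS) of animal-borne VHF transmitters.  Such automated
radio tracking systems can follow many small animals at once at fine
spatial scales, but turning raw RSS logs into accurate positions requires
careful analysis: signal strength attenuates rapidly and unpredictably in
structurally complex outdoor environments, and far-away receivers
contribute noise, not information.

`nodeloc` implements the full analysis chain:

1. **RSS–distance calibration.**  The decay of signal strength with
   distance is modelled as

   `RSS(d) = a · exp(−S · d) + K`

   with intercept term `a` (dB), decay rate `S` (per metre) and horizontal
   asymptote `K` (dB, effectively the noise floor), fitted to stationary
   test-transmitter data by nonlinear least squares (`rss_decay()`).

2. **Detection processing.**  Raw detection logs are trimmed and averaged
   per node and time window (`trim_window()`, `average_by_node()`,
   `window_detections()`), damping multipath outliers.

3. **Filtering and trilateration.**  Only informative nodes are kept —
   either those with RSS above a cutoff (`rss_filter()`) or those within a
   radius of the strongest-signal node (`distance_filter()`) — then each
   retained node's mean RSS is inverted to a distance estimate and the
   planar position minimizing the range residuals
   `Σᵢ (‖p − nodeᵢ‖ − dᵢ)²` is found by a safeguarded Gauss–Newton
   iteration (`localize()`, `trilaterate()`).

4. **Design evaluation by simulation.**  `run_experiment()` draws noisy
   RSS realizations (parametric noise with distance-dependent detection
   dropout, or empirical resampling of a calibration table) over simulated
   node configurations, and `summarize_errors()` / `edge_profile()`
   produce error tables with cluster-bootstrap confidence intervals and
   error-vs-network-edge profiles.  This is how to choose node spacing and
   filters *before* building a network.

## Worked example

```r
library(nodeloc)

# 1. calibrate: fit the decay curve to stationary test-transmitter data
set.seed(42)
d   <- runif(500, 1, 2500)
rss <- pmin(pmax(47.23 * exp(-0.005 * d) - 105.16 + rnorm(500, 0, 3), -120), -30)
fit <- rss_decay(d, rss)
print(fit)
#> Exponential RSS-distance decay model
#>   RSS = 48.062 * exp(-0.00506174 * distance) + (-105.332)  [dB, metres]
#>   residual SD 2.942 dB on 500 observations

# 2. localize a tag from a one-minute detection window (3 s pulse interval)
nw    <- make_network(spacing_m = 250, extent_m = 1250)   # 6 x 6 nodes
truth <- c(830, 410)
dv    <- sqrt((nw$nodes$x - truth[1])^2 + (nw$nodes$y - truth[2])^2)
t0    <- as.POSIXct("2022-06-01 05:00:00", tz = "UTC")
log   <- do.call(rbind, lapply(seq(0, 57, by = 3), function(s) {
  pulse <- generate_rss(dv, fit, noise_model())
  hit   <- !is.na(pulse)
  data.frame(tag_id = "bird01", node_id = nw$nodes$node_id[hit],
             rss = pulse[hit], timestamp = t0 + s)
}))
obs <- average_by_node(log, tag_id = "bird01")
est <- localize(obs, nw, fit, filter = distance_filter(radius_m = 315))
print(est)
#> Location estimate: (831.19, 427.69) m  [5 nodes, 5 iterations, residual norm 43.333]
localization_error(truth, est)
#> 17.7 m

# 3. quantify expected error for this network design by simulation
res <- run_experiment(nw, fit, noise_model(),
                      list(no_filter(), distance_filter(radius_m = 315)),
                      n_locations = 25, n_reps = 40, seed = 1)
summarize_errors(res)[, c("filter", "pct_location_loss", "mean_n_nodes",
                          "mean_error_m", "median_error_m")]
#>       filter pct_location_loss mean_n_nodes mean_error_m median_error_m
#> 1       none               0.0    16.517000     154.4405      140.38769
#> 2 dist 315 m               1.4     4.464503      90.0213       75.62103
```

The decay fit recovers the generating curve within sampling error.  The
single-window estimate lands 17.7 m from the truth using only the five
nodes around the strongest signal.  The simulation shows why filtering
matters on this 250 m grid: keeping all ~17 detecting nodes gives a median
error of ~140 m (estimates get dragged toward the network centre), while
the 315 m distance filter roughly halves it — with essentially no loss of
estimable locations.

## Command line

A thin CLI over the same functions is installed at
`inst/cli/nodeloc`:

```sh
nodeloc fit      --calibration cal.csv --out model.json
nodeloc localize --nodes nodes.csv --detections det.csv --model model.json \
                 --filter dist:1.25 --out estimates.csv
nodeloc simulate --config sim.yaml --out results.csv
nodeloc evaluate --results results.csv --out summary.csv --edge-profile edge.csv
```

Every run writes a JSON manifest (inputs, checksums, seed, package
version) next to its output.  `make_fixtures()` generates a synthetic
calibration/nodes/detections set for trying the commands offline.

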