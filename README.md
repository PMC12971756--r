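# pollenscape

Functional landscape connectivity metrics for pollinator-mediated gene
flow in fragmented landscapes.

Hummingbird-pollinated understory plants depend on traplining,
habitat-specialist hummingbirds to carry pollen between forest
remnants. `pollenscape` quantifies how much *functionally connected*
habitat surrounds each sampling site — habitat discounted by the
pollinator's movement behaviour — and asks which notion of connectivity
best explains realised pollen-mediated gene flow. It is aimed at
landscape geneticists and pollination ecologists working with
raster landcover, maternal-plant/seed microsatellite genotypes, and
site-level pollinator capture data.

## The model

All metrics derive from an incidence function model redefined over
10 m raster cells. For a sampling site on pixel *i*,

    S_i = sum_{j != i} exp(-alpha * d_ij) * A_j * p_j

summed over trapliner-habitat pixels *j* within the local landscape
(1 km radius, the pollinator's maximum daily movement range), where
`alpha = 1/282 m^-1` is the inverse mean home-range length of the
dominant trapliner, `A_j` is the pixel area (0.01 ha) and `p_j` is a
patch-level gap-crossing term. Crossing a factorial of

* habitat definition — *narrow* (mature forest) vs *broad* (mature +
  regenerating forest + narrow forest elements),
* distance weighting — kernel on/off,
* gap-crossing mode — *unlimited* (`p = 1`), *threshold* (`p = 1` iff
  the patch's gap chain to the focal patch stays within 50 m, stepping
  stones allowed), *probabilistic* (`p = exp(-lambda * d_k)` with
  `lambda = log(2)/50 m^-1`: crossing odds halve every 50 m of summed
  open gap `d_k`)

gives 12 local-scale metrics, plus 3 intra-patch metrics (total,
radius-limited, and distance-weighted focal patch area). Gene-flow
responses — pollen-pool haplotype diversity from maternal-genotype
subtraction, the shrinkage-corrected proportion of high-mobility
hummingbird captures, and supplied biparental inbreeding — are each
regressed on each standardised metric, and the models are ranked by
AICc, Akaike weights, and summed factor weights. A fully seeded
synthetic generator (`simulate_study()`) supplies landscapes,
genotypes and pollination events with known ground truth.

## Worked example

Simulate a complete study (3 x 3 km landscape, 30 sites, 5 mothers x
10 seeds each, 11 microsatellite loci), measure the 15-metric suite,
build the responses, and compare models:

```r
library(pollenscape)

cfg   <- synthetic_config(rng_seed = 42)
study <- simulate_study(cfg)

site  <- sampling_site(study$sites$site_id[1], study$sites$x[1],
                       study$sites$y[1], study$landscape)
suite <- compute_metric_suite(study$landscape, site)
suite[c(1, 10, 12), c("metric", "habitat_def", "gap_mode", "value_ha")]
#>              metric habitat_def      gap_mode value_ha
#>    focal_patch_area      NARROW          <NA>   0.7600
#>  local_connectivity       BROAD     UNLIMITED  86.5300
#>  local_connectivity       BROAD PROBABILISTIC  15.6648
```

Site S01 sits in a 0.76 ha mature remnant; 86.5 ha of broad habitat
lies within its 1 km disk, but only 15.7 ha of it remains after
discounting by the gap-crossing probabilities — a strongly fragmented
neighbourhood.

```r
metrics <- do.call(rbind, lapply(seq_len(nrow(study$sites)), function(i) {
  s <- sampling_site(study$sites$site_id[i], study$sites$x[i],
                     study$sites$y[i], study$landscape)
  compute_metric_suite(study$landscape, s)
}))
responses <- build_response_table(study$genotypes, study$captures,
                                  study$responses)
head(responses, 3)
#>  site_id prop_high_mobility     h tm_minus_ts
#>      S01              0.432 0.824       0.375
#>      S02              0.486 0.777       0.432
#>      S03              0.429 0.803       0.148

cmp   <- compare_all(responses, metrics)
loc_h <- cmp[cmp$response == "h" & cmp$scale == "LOCAL", ]
head(loc_h[order(loc_h$delta_aicc),
           c("habitat_def", "weighting", "gap_mode", "beta", "r2",
             "delta_aicc", "weight")], 2)
#>  habitat_def  weighting      gap_mode  beta    r2 delta_aicc weight
#>        BROAD UNWEIGHTED PROBABILISTIC 0.573 0.328      0.000 0.4839
#>        BROAD UNWEIGHTED     THRESHOLD 0.563 0.316      0.519 0.3733

round(summed_factor_weights(loc_h, "gap_mode"), 3)
#> PROBABILISTIC     THRESHOLD     UNLIMITED
#>         0.523         0.427         0.050
```

Pollen haplotype diversity across the 30 simulated sites is best
explained by the broad-habitat probabilistic gap-crossing metric
(Akaike weight 0.48, standardised slope 0.57), and summing weights
over the gap-crossing factor puts most support on the probabilistic
mode — the analysis recovers the movement model that generated the
data. `run_pipeline()` performs the same steps from files on disk
(ASCII-grid landcover plus CSV tables) and writes the metric,
response and comparison tables, the factor-weight JSON, and a run
manifest.

See the vignette `vignettes/connectivity-methods.Rmd` for the model
assumptions, parameter choices and limitations.

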