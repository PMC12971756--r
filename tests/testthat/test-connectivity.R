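# helper: a patch graph built directly from a gap matrix
graph_from_gaps <- function(gap, focal = 1L, areas = NULL) {
  ids <- seq_len(nrow(gap))
  structure(list(ids = ids,
                 areas = if (is.null(areas)) rep(1, length(ids)) else areas,
                 gap = gap, focal = as.integer(focal)),
            class = "patch_graph")
}

sym <- function(...) {
  v <- c(...)
  k <- (1 + sqrt(1 + 8 * length(v))) / 2
  m <- matrix(0, k, k)
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("intra-patch metrics give exact areas and kernel values", {
  # 100-pixel patch -> 1 ha, log = 0
  m <- matrix(LANDCOVER_CODES[["PASTURE"]], 20, 20)
  m[6:15, 6:15] <- LANDCOVER_CODES[["MATURE"]]
  r <- lc(m)
  pm <- label_patches(classify_habitat(r, "NARROW"))
  site <- sampling_site("s", 105, 105, r)
  fpa <- focal_patch_area(pm, site)
  expect_equal(fpa$value_ha, 1)
  expect_equal(fpa$transformed, 0)
  # 1000-pixel patch -> 10 ha, log(10); 1-pixel patch -> 0.01 ha
  m2 <- matrix(LANDCOVER_CODES[["PASTURE"]], 30, 60)
  m2[6:25, 6:55] <- LANDCOVER_CODES[["MATURE"]]
  pm2 <- label_patches(classify_habitat(lc(m2), "NARROW"))
  s2 <- sampling_site("s", 105, 105, lc(m2))
  expect_equal(focal_patch_area(pm2, s2)$value_ha, 10)
  expect_equal(focal_patch_area(pm2, s2)$transformed, log(10))
  m3 <- matrix(LANDCOVER_CODES[["PASTURE"]], 5, 5)
  m3[3, 3] <- LANDCOVER_CODES[["MATURE"]]
  pm3 <- label_patches(classify_habitat(lc(m3), "NARROW"))
  s3 <- sampling_site("s", 25, 25, lc(m3))
  expect_equal(focal_patch_area(pm3, s3)$value_ha, 0.01)
  expect_equal(focal_patch_area(pm3, s3)$transformed, log(0.01))
})

test_that("focal patch area within radius clips by the distance oracle", {
  m <- matrix(LANDCOVER_CODES[["PASTURE"]], 30, 60)
  m[14:16, 2:59] <- LANDCOVER_CODES[["MATURE"]]  # long ribbon patch
  r <- lc(m)
  pm <- label_patches(classify_habitat(r, "NARROW"))
  site <- sampling_site("s", 55, 155, r)
  full <- focal_patch_area(pm, site)
  clipped <- focal_patch_area_within_radius(pm, site, radius = 200)
  expect_lt(clipped$value_ha, full$value_ha)
  # exhaustive patch-membership AND distance oracle
  idx <- which(pm$labels == 1, arr.ind = TRUE)
  ctr_x <- 55; ctr_y <- 155
  n_in <- 0
  for (i in seq_len(nrow(idx))) {
    x <- (idx[i, 2] - 0.5) * 10
    y <- (30 - idx[i, 1] + 0.5) * 10
    if (sqrt((x - ctr_x)^2 + (y - ctr_y)^2) <= 200) n_in <- n_in + 1
  }
  expect_equal(clipped$value_ha, n_in * 0.01)
  # patch entirely inside the radius: equals total patch area
  all_in <- focal_patch_area_within_radius(pm, site, radius = 10000)
  expect_equal(all_in$value_ha, full$value_ha)
})

test_that("distance-weighted focal patch area evaluates the kernel", {
  # site pixel with a single habitat neighbour 10 m away
  m <- matrix(LANDCOVER_CODES[["PASTURE"]], 5, 5)
  m[3, 3:4] <- LANDCOVER_CODES[["MATURE"]]
  r <- lc(m)
  pm <- label_patches(classify_habitat(r, "NARROW"))
  site <- sampling_site("s", 25, 25, r)
  v <- distance_weighted_focal_patch_area(pm, site)
  expect_equal(v$value_ha, 0.01 * exp(-10 / 282), tolerance = 1e-12)
  # ring symmetry: four orthogonal neighbours all at 10 m
  m2 <- matrix(LANDCOVER_CODES[["PASTURE"]], 5, 5)
  m2[3, 2:4] <- LANDCOVER_CODES[["MATURE"]]
  m2[2:4, 3] <- LANDCOVER_CODES[["MATURE"]]
  pm2 <- label_patches(classify_habitat(lc(m2), "NARROW"))
  v2 <- distance_weighted_focal_patch_area(pm2,
                                           sampling_site("s", 25, 25, lc(m2)))
  expect_equal(v2$value_ha, 0.04 * exp(-10 / 282), tolerance = 1e-12)
  # an elongated patch scores below a round patch of equal area
  sq <- matrix(LANDCOVER_CODES[["PASTURE"]], 31, 31)
  sq[14:18, 14:18] <- LANDCOVER_CODES[["MATURE"]]         # 5 x 5
  ln <- matrix(LANDCOVER_CODES[["PASTURE"]], 31, 31)
  ln[16, 4:28] <- LANDCOVER_CODES[["MATURE"]]             # 1 x 25
  s_mid <- function(m) sampling_site("s", 155, 155, lc(m))
  v_sq <- distance_weighted_focal_patch_area(
    label_patches(classify_habitat(lc(sq), "NARROW")), s_mid(sq))
  v_ln <- distance_weighted_focal_patch_area(
    label_patches(classify_habitat(lc(ln), "NARROW")), s_mid(ln))
  expect_lt(v_ln$value_ha, v_sq$value_ha)
})

test_that("distance-weighted intra metric is invariant under 90-degree rotation", {
  set.seed(5)
  n <- 21
  g <- matrix(0L, n, n)
  g[11, 11] <- 1L
  g[cbind(sample(1:n, 40, TRUE), sample(1:n, 40, TRUE))] <- 1L
  # keep only the component containing the centre pixel
  rot <- t(g[n:1, ])   # 90-degree rotation about the grid centre
  v <- function(gr) {
    pm <- label_patches(hab(gr))
    site <- sampling_site("s", 105, 105, hab(gr))
    distance_weighted_focal_patch_area(pm, site)$value_ha
  }
  expect_equal(v(g), v(rot), tolerance = 1e-12)
})

test_that("threshold connectivity includes stepping stones", {
  # chain: focal - B (40 m) - C (45 m from B, 120 m direct)
  gap <- sym(40, 120, 45)
  g <- graph_from_gaps(gap)
  expect_setequal(connected_patches_threshold(g, 50), c(1, 2, 3))
  # isolated patch at 60 m from everything is excluded
  gap2 <- sym(60, 60, 60)
  expect_equal(connected_patches_threshold(graph_from_gaps(gap2), 50), 1)
  # reachability equals brute-force transitive closure on random graphs
  set.seed(9)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    m <- matrix(0, k, k)
    m[lower.tri(m)] <- runif(k * (k - 1) / 2, 0, 100)
    m <- m + t(m)
    conn <- connected_patches_threshold(graph_from_gaps(m), 50)
    # oracle: repeated boolean matrix closure
    adj <- (m <= 50) & !diag(k)
    reach <- adj | diag(k) > 0
    for (s in 1:k) reach <- reach | (reach %*% reach) > 0
    expect_setequal(conn, which(reach[1, ]))
  }
})

test_that("minimum summed gap distance equals exhaustive path enumeration", {
  gap <- sym(30, 80, 25)   # focal-B 30, focal-C 80, B-C 25
  d <- min_summed_gap_distance(graph_from_gaps(gap))
  expect_equal(unname(d), c(0, 30, 55))
  expect_lte(max(d - gap[1, ]), 0)  # d_k never exceeds the direct gap
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    m <- matrix(0, k, k)
    m[lower.tri(m)] <- runif(k * (k - 1) / 2, 0, 200)
    m <- m + t(m)
    expect_equal(unname(min_summed_gap_distance(graph_from_gaps(m))),
                 oracle_min_summed_gap(m, 1), tolerance = 1e-9)
  }
})

test_that("gap-crossing probability halves every 50 m", {
  expect_equal(gap_crossing_probability(0), 1)
  expect_equal(gap_crossing_probability(50), 0.5)
  expect_equal(gap_crossing_probability(100), 0.25)
  expect_error(gap_crossing_probability(-1), "non-negative")
  # the default decay rate is log(2)/50 per metre (printed rounded down
  # to 0.013)
  expect_equal(formals(gap_crossing_probability)$lambda, quote(log(2) / 50))
  expect_equal(floor(eval(formals(gap_crossing_probability)$lambda) * 1e3) / 1e3,
               0.013)
})

test_that("metric spec validates the factorial structure", {
  sp <- metric_spec("LOCAL", habitat_def = "BROAD", weighting = "KERNEL",
                    gap_mode = "PROBABILISTIC")
  expect_equal(sp$alpha, 1 / 282)
  expect_error(metric_spec("LOCAL", gap_threshold = 60, buffer = 25),
               "twice")
  expect_error(metric_spec("LOCAL", variant = "TOTAL_AREA"), "intra-patch")
  sp_intra <- metric_spec("INTRA_PATCH", variant = "TOTAL_AREA",
                          habitat_def = "BROAD")
  expect_equal(sp_intra$habitat_def, "NARROW")  # intra metrics force NARROW
})

# shared layout: 3x3 focal block plus a 2-ha patch across a 50 m gap
two_patch_layout <- function() {
  m <- matrix(LANDCOVER_CODES[["PASTURE"]], 20, 40)
  m[9:11, 2:4] <- LANDCOVER_CODES[["MATURE"]]
  m[1:20, 10:19] <- LANDCOVER_CODES[["MATURE"]]
  r <- lc(m)
  list(r = r, site = sampling_site("s", 25, 105, r))
}

test_that("local connectivity combines kernel and gap-crossing terms", {
  ly <- two_patch_layout()
  habc <- clip_local_landscape(classify_habitat(ly$r, "NARROW"), ly$site,
                               1000)
  spec <- function(gm, wt = "UNWEIGHTED")
    metric_spec("LOCAL", habitat_def = "NARROW", weighting = wt,
                gap_mode = gm)
  # unlimited + unweighted: all habitat pixels except the site pixel
  v_unl <- local_connectivity(habc, ly$site, spec("UNLIMITED"))
  expect_equal(v_unl$value_ha, (sum(habc$grid) - 1) * 0.01)
  # probabilistic: focal remainder + 0.5 x 2 ha across the 50 m gap
  v_prob <- local_connectivity(habc, ly$site, spec("PROBABILISTIC"))
  expect_equal(v_prob$value_ha, 0.08 + 0.5 * 2, tolerance = 1e-12)
  # threshold: gap of exactly 50 m is still connected
  v_thr <- local_connectivity(habc, ly$site, spec("THRESHOLD"))
  expect_equal(v_thr$value_ha, 0.08 + 2, tolerance = 1e-12)
  # scale mismatch is rejected
  expect_error(
    local_connectivity(habc, ly$site,
                       metric_spec("INTRA_PATCH", variant = "TOTAL_AREA")),
    "LOCAL")
})

test_that("probabilistic mode recovers its limiting cases", {
  ly <- two_patch_layout()
  habc <- clip_local_landscape(classify_habitat(ly$r, "NARROW"), ly$site,
                               1000)
  spec_l <- function(lam)
    metric_spec("LOCAL", habitat_def = "NARROW", gap_mode = "PROBABILISTIC",
                lambda = lam)
  # lambda -> infinity: only the focal patch remains
  expect_equal(local_connectivity(habc, ly$site, spec_l(1e3))$value_ha,
               0.08, tolerance = 1e-6)
  # lambda -> 0: converges to unlimited gap-crossing
  unl <- local_connectivity(
    habc, ly$site, metric_spec("LOCAL", habitat_def = "NARROW",
                               gap_mode = "UNLIMITED"))
  expect_equal(local_connectivity(habc, ly$site, spec_l(1e-9))$value_ha,
               unl$value_ha, tolerance = 1e-6)
})

test_that("the metric suite enumerates 3 intra + the 2x2x3 local factorial", {
  cfg <- synthetic_config(rng_seed = 21, extent = 1000, radius = 400,
                          n_sites = 1)
  landscape <- generate_landscape(cfg)
  placed <- place_sites(landscape, cfg)
  site <- sampling_site(placed$sites$site_id[1], placed$sites$x[1],
                        placed$sites$y[1], landscape)
  suite <- compute_metric_suite(landscape, site, radius = cfg$radius)
  expect_equal(nrow(suite), 15)
  expect_equal(sum(suite$scale == "INTRA_PATCH"), 3)
  local <- suite[suite$scale == "LOCAL", ]
  expect_equal(nrow(unique(local[, c("habitat_def", "weighting",
                                     "gap_mode")])), 12)
  expect_true(all(table(local$habitat_def) == 6))
  expect_true(all(table(local$gap_mode) == 4))
})

test_that("gap modes coincide on a single solid patch", {
  m <- block_landcover(30, 10:20, 10:20)
  r <- lc(m)
  site <- sampling_site("s", 155, 155, r)
  suite <- compute_metric_suite(r, site)
  local <- suite[suite$scale == "LOCAL", ]
  for (wt in c("UNWEIGHTED", "KERNEL")) {
    for (def in c("NARROW", "BROAD")) {
      v <- local$value_ha[local$weighting == wt & local$habitat_def == def]
      expect_equal(max(v) - min(v), 0)
    }
  }
})

test_that("dominance holds across random synthetic landscapes", {
  set.seed(31)
  n_checked <- 0
  for (i in 1:20) {
    cfg <- synthetic_config(rng_seed = 300 + i, extent = 800, radius = 350,
                            n_sites = 1, mother_scatter = 50)
    landscape <- generate_landscape(cfg)
    placed <- place_sites(landscape, cfg)
    site <- sampling_site(placed$sites$site_id[1], placed$sites$x[1],
                          placed$sites$y[1], landscape)
    suite <- compute_metric_suite(landscape, site, radius = cfg$radius)
    local <- suite[suite$scale == "LOCAL", ]
    val <- function(def, wt, gm)
      local$value_ha[local$habitat_def == def & local$weighting == wt &
                       local$gap_mode == gm]
    for (def in c("NARROW", "BROAD")) for (wt in c("UNWEIGHTED", "KERNEL")) {
      expect_gte(val(def, wt, "UNLIMITED"), val(def, wt, "THRESHOLD"))
      expect_gte(val(def, wt, "UNLIMITED"), val(def, wt, "PROBABILISTIC"))
    }
    for (def in c("NARROW", "BROAD")) for (gm in unique(local$gap_mode)) {
      expect_gte(val(def, "UNWEIGHTED", gm), val(def, "KERNEL", gm))
    }
    for (wt in c("UNWEIGHTED", "KERNEL")) {
      expect_gte(val("BROAD", wt, "UNLIMITED"), val("NARROW", wt, "UNLIMITED"))
    }
    expect_true(all(local$value_ha >= 0))
    expect_lte(max(local$value_ha),
               sum(clip_local_landscape(
                 classify_habitat(landscape, "BROAD"), site,
                 cfg$radius)$grid) * 0.01)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 20)
})
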