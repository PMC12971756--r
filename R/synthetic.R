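#' Configuration for the synthetic landscape / pollination generator
#'
#' Bundles every parameter of the synthetic study: landscape composition,
#' sampling design, microsatellite panel, pollen movement kernel, and the
#' noise structure of the capture and inbreeding responses. Defaults
#' emulate the study conditions: a 3 x 3 km fragmented premontane mosaic
#' at 10 m resolution with roughly 20% mature forest cover, 30 sampling
#' sites in distinct mature patches, 5 maternal plants per site, 10 seeds
#' per mother, and an 11-locus microsatellite panel.
#'
#' @param rng_seed Integer seed; every generator output is a pure function
#'   of (config, seed).
#' @param extent Side length of the square landscape, metres.
#' @param cell_size Raster cell size, metres.
#' @param mature_cover,mature_radius_meanlog,mature_radius_sdlog Requested
#'   mature-forest cover fraction of the extent, reached by adding
#'   quasi-elliptical patches whose major semi-axis is log-normal
#'   (metres); placement stops once the realised cover reaches the
#'   request.
#' @param n_patch_clusters,patch_cluster_sd Optional clustered
#'   (Thomas-type) placement of mature patch centres: `n_patch_clusters`
#'   uniform parent points, each patch displaced from a random parent by
#'   an isotropic Gaussian with this standard deviation (metres). 0
#'   (default) places patch centres uniformly.
#' @param regen_cover,regen_radius_meanlog,regen_radius_sdlog Requested
#'   regenerating-forest cover fraction; regenerating patches are seeded
#'   against mature patch edges, emulating succession on cleared margins
#'   adjacent to remnants.
#' @param n_arable_patches Small arable inclusions in the pasture matrix.
#' @param n_narrow_elements,element_width Straight narrow forest elements
#'   (fencerows/riparian strips) and their width in metres.
#' @param n_sites,n_mothers_per_site,mother_scatter Sampling design: number
#'   of sites (each in a distinct mature patch where possible), maternal
#'   plants per site, and the scatter radius (m) of plants around the site
#'   anchor.
#' @param n_seeds_per_mother Seeds genotyped per maternal plant.
#' @param n_loci,alleles_per_locus,freq_concentration Microsatellite panel:
#'   number of loci, alleles per locus, and the symmetric Dirichlet
#'   concentration of the population allele frequencies.
#' @param donor_density Pollen-donor plants per hectare of (broad) habitat.
#' @param donors_min_per_site Flowering conspecific neighbours guaranteed
#'   within `mother_scatter` of every site (maternal plants were found at
#'   every real site, so nearby flowering conspecifics always exist).
#' @param alpha,lambda Movement kernel of the siring process: distance
#'   decay (1/m) and gap-crossing decay (1/m); identical in form to the
#'   analysis metrics' probabilistic kernel.
#' @param radius,neighbourhood Local landscape radius (m) and patch
#'   labelling connectivity.
#' @param n_captures_mean Mean mist-netting captures per site (Poisson).
#' @param capture_intercept,capture_slope Logit-scale coefficients linking
#'   the standardised true donor accessibility to the probability that a
#'   capture is a high-mobility trapliner.
#' @param tm_intercept,tm_slope,response_noise_sd Linear model for the
#'   simulated biparental inbreeding response
#'   `tm = tm_intercept - tm_slope * z + N(0, response_noise_sd)`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(rng_seed = 1L,
                             extent = 3000, cell_size = 10,
                             mature_cover = 0.20,
                             mature_radius_meanlog = log(55),
                             mature_radius_sdlog = 0.25,
                             n_patch_clusters = 0,
                             patch_cluster_sd = 250,
                             regen_cover = 0.085,
                             regen_radius_meanlog = log(60),
                             regen_radius_sdlog = 0.5,
                             n_arable_patches = 2,
                             n_narrow_elements = 3,
                             element_width = 10,
                             n_sites = 30,
                             n_mothers_per_site = 5,
                             mother_scatter = 100,
                             n_seeds_per_mother = 10,
                             n_loci = 11,
                             alleles_per_locus = 12,
                             freq_concentration = 1,
                             donor_density = 0.25,
                             donors_min_per_site = 2,
                             alpha = 1 / 282,
                             lambda = log(2) / 50,
                             radius = 1000,
                             neighbourhood = 8,
                             n_captures_mean = 30,
                             capture_intercept = 0,
                             capture_slope = 1,
                             tm_intercept = 0.2,
                             tm_slope = 0.1,
                             response_noise_sd = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$extent > 0, cfg$cell_size > 0,
            cfg$extent %% cfg$cell_size == 0,
            cfg$n_sites >= 1, cfg$n_loci >= 1, cfg$alleles_per_locus >= 1)
  structure(cfg, class = "synthetic_config")
}

# fill a rotated ellipse into `grid`, overwriting only codes in `over`
fill_ellipse <- function(grid, r0, c0, a_cells, b_cells, theta, code,
                         over) {
  nr <- nrow(grid); nc <- ncol(grid)
  half <- ceiling(max(a_cells, b_cells)) + 1L
  r_lo <- max(1L, floor(r0 - half)); r_hi <- min(nr, ceiling(r0 + half))
  c_lo <- max(1L, floor(c0 - half)); c_hi <- min(nc, ceiling(c0 + half))
  if (r_lo > r_hi || c_lo > c_hi) return(grid)  # entirely off the extent
  rr <- r_lo:r_hi
  cc <- c_lo:c_hi
  dy <- rr - r0
  dx <- cc - c0
  u <- outer(dy, dx, function(y, x) x * cos(theta) + y * sin(theta))
  v <- outer(dy, dx, function(y, x) -x * sin(theta) + y * cos(theta))
  inside <- (u / a_cells)^2 + (v / b_cells)^2 <= 1
  block <- grid[rr, cc, drop = FALSE]
  repl <- inside & block %in% over
  block[repl] <- code
  grid[rr, cc] <- block
  grid
}

#' Generate a synthetic landcover raster
#'
#' Pasture matrix with randomly placed quasi-elliptical mature-forest
#' patches, regenerating-forest patches seeded against mature patch edges,
#' small arable inclusions, and straight narrow forest elements. Fully
#' deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A [landcover_raster()].
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed + 1L)
  cs <- config$cell_size
  n <- as.integer(config$extent / cs)
  if (exp(config$mature_radius_meanlog) / cs > n / 2)
    stop("generation failure: mature patch radius does not fit the extent",
         call. = FALSE)
  g <- matrix(LANDCOVER_CODES["PASTURE"], n, n)
  for (i in seq_len(config$n_arable_patches)) {
    a <- stats::rlnorm(1, log(80), 0.4) / cs
    g <- fill_ellipse(g, stats::runif(1, 1, n), stats::runif(1, 1, n),
                      a, a * stats::runif(1, 0.5, 1),
                      stats::runif(1, 0, pi), LANDCOVER_CODES["ARABLE"],
                      over = LANDCOVER_CODES["PASTURE"])
  }
  parents <- if (config$n_patch_clusters > 0)
    cbind(stats::runif(config$n_patch_clusters, 1, n),
          stats::runif(config$n_patch_clusters, 1, n))
  target_mature <- round(config$mature_cover * n * n)
  guard <- 0L
  while (sum(g == LANDCOVER_CODES["MATURE"]) < target_mature) {
    if ((guard <- guard + 1L) > 5000L)
      stop("generation failure: could not reach the requested mature ",
           "cover", call. = FALSE)
    a <- stats::rlnorm(1, config$mature_radius_meanlog,
                       config$mature_radius_sdlog) / cs
    if (is.null(parents)) {
      r0 <- stats::runif(1, 1, n); c0 <- stats::runif(1, 1, n)
    } else {
      p <- parents[sample.int(nrow(parents), 1), ]
      sd_cells <- config$patch_cluster_sd / cs
      r0 <- p[1] + stats::rnorm(1, 0, sd_cells)
      c0 <- p[2] + stats::rnorm(1, 0, sd_cells)
    }
    g <- fill_ellipse(g, r0, c0, a, a * stats::runif(1, 0.4, 1),
                      stats::runif(1, 0, pi), LANDCOVER_CODES["MATURE"],
                      over = LANDCOVER_CODES[c("PASTURE", "ARABLE")])
  }
  mature_idx <- which(g == LANDCOVER_CODES["MATURE"])
  target_regen <- round(config$regen_cover * n * n)
  guard <- 0L
  while (sum(g == LANDCOVER_CODES["REGEN"]) < target_regen) {
    if ((guard <- guard + 1L) > 5000L)
      stop("generation failure: could not reach the requested ",
           "regenerating cover", call. = FALSE)
    a <- stats::rlnorm(1, config$regen_radius_meanlog,
                       config$regen_radius_sdlog) / cs
    if (length(mature_idx) > 0) {
      # seed against a mature edge: centre offset from a random mature cell
      anchor <- mature_idx[sample.int(length(mature_idx), 1)]
      r0 <- ((anchor - 1L) %% n) + 1L + stats::rnorm(1, 0, a)
      c0 <- ((anchor - 1L) %/% n) + 1L + stats::rnorm(1, 0, a)
    } else {
      r0 <- stats::runif(1, 1, n); c0 <- stats::runif(1, 1, n)
    }
    g <- fill_ellipse(g, r0, c0, a, a * stats::runif(1, 0.4, 1),
                      stats::runif(1, 0, pi), LANDCOVER_CODES["REGEN"],
                      over = LANDCOVER_CODES[c("PASTURE", "ARABLE")])
  }
  w_cells <- max(1L, round(config$element_width / cs))
  for (i in seq_len(config$n_narrow_elements)) {
    x0 <- stats::runif(1, 0, n); y0 <- stats::runif(1, 0, n)
    theta <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 300, 1200) / cs
    t <- seq(0, len, by = 0.5)
    rr <- round(y0 + t * sin(theta)); cc <- round(x0 + t * cos(theta))
    for (off in seq_len(w_cells) - 1L) {
      r2 <- rr + off
      ok <- r2 >= 1 & r2 <= n & cc >= 1 & cc <= n
      lin <- (cc[ok] - 1L) * n + r2[ok]
      lin <- lin[g[lin] %in% LANDCOVER_CODES[c("PASTURE", "ARABLE")]]
      g[lin] <- LANDCOVER_CODES["NARROW_ELEM"]
    }
  }
  if (!any(g == LANDCOVER_CODES["MATURE"]) && config$mature_cover > 0)
    stop("generation failure: no mature forest was placed", call. = FALSE)
  landcover_raster(g, cell_size = cs, origin = c(0, 0),
                   crs = "synthetic-metric")
}

#' Place sampling sites and maternal plants
#'
#' Selects up to `n_sites` distinct mature patches (at least 0.6 ha),
#' drops an anchor pixel in each, scatters `n_mothers_per_site` maternal
#' plants on mature pixels of the same patch within `mother_scatter`
#' metres of the anchor, and sets the site centre to the component-wise
#' median of the plant coordinates (snapped to the nearest habitat pixel
#' of the patch if the median itself falls off-patch).
#'
#' @param landscape A [landcover_raster()].
#' @param config A [synthetic_config()].
#' @return List with `sites` (data frame `site_id`, `x`, `y`) and `plants`
#'   (data frame `plant_id`, `site_id`, `x`, `y`).
#' @export
place_sites <- function(landscape, config) {
  stopifnot(inherits(landscape, "landcover_raster"),
            inherits(config, "synthetic_config"))
  set.seed(config$rng_seed + 2L)
  habitat <- classify_habitat(landscape, "NARROW")
  if (sum(habitat$grid) == 0)
    stop("generation failure: no mature habitat to place sites in",
         call. = FALSE)
  patches <- label_patches(habitat, config$neighbourhood)
  eligible <- as.integer(names(patches$patch_areas)[patches$patch_areas >= 0.6])
  if (length(eligible) == 0)
    eligible <- as.integer(names(which.max(patches$patch_areas)))
  chosen <- if (length(eligible) > config$n_sites)
    sample(eligible, config$n_sites) else eligible
  nr <- nrow(patches$labels)
  sites <- NULL; plants <- NULL
  for (i in seq_along(chosen)) {
    id <- chosen[i]
    idx <- which(patches$labels == id)
    ctr <- pixel_centre(patches, ((idx - 1L) %% nr) + 1L,
                        ((idx - 1L) %/% nr) + 1L)
    anchor <- sample.int(length(idx), 1)
    d <- sqrt((ctr[, "x"] - ctr[anchor, "x"])^2 +
                (ctr[, "y"] - ctr[anchor, "y"])^2)
    near <- which(d <= config$mother_scatter)
    pick <- near[sample.int(length(near), config$n_mothers_per_site,
                            replace = length(near) < config$n_mothers_per_site)]
    jit <- landscape$cell_size * 0.4
    px <- ctr[pick, "x"] + stats::runif(length(pick), -jit, jit)
    py <- ctr[pick, "y"] + stats::runif(length(pick), -jit, jit)
    med <- median_site_coordinate(cbind(px, py))
    mpx <- point_to_pixel(patches, med["x"], med["y"])
    if (patches$labels[mpx[1, "row"], mpx[1, "col"]] != id) {
      # median fell off-patch (concave patch): snap to nearest patch pixel
      dm <- sqrt((ctr[, "x"] - med["x"])^2 + (ctr[, "y"] - med["y"])^2)
      med <- c(x = unname(ctr[which.min(dm), "x"]),
               y = unname(ctr[which.min(dm), "y"]))
    }
    sid <- sprintf("S%02d", i)
    sites <- rbind(sites, data.frame(site_id = sid, x = unname(med["x"]),
                                     y = unname(med["y"]),
                                     stringsAsFactors = FALSE))
    plants <- rbind(plants, data.frame(
      plant_id = sprintf("%s_M%d", sid, seq_along(pick)), site_id = sid,
      x = px, y = py, stringsAsFactors = FALSE))
  }
  list(sites = sites, plants = plants)
}

# draw n diploid genotypes in Hardy-Weinberg proportions; returns a
# data frame with two columns per locus
draw_genotypes <- function(n, allele_freqs) {
  out <- list()
  for (L in names(allele_freqs)) {
    p <- allele_freqs[[L]]
    a1 <- sample(names(p), n, replace = TRUE, prob = p)
    a2 <- sample(names(p), n, replace = TRUE, prob = p)
    out[[paste0(L, "_1")]] <- a1
    out[[paste0(L, "_2")]] <- a2
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate population allele frequencies, maternal genotypes and donors
#'
#' Draws per-locus allele frequencies from a symmetric Dirichlet prior,
#' assigns Hardy-Weinberg genotypes to the supplied maternal plants, and
#' scatters pollen-donor plants uniformly over (broad) habitat pixels at
#' the configured density, also with Hardy-Weinberg genotypes.
#'
#' @param config A [synthetic_config()].
#' @param plants Maternal-plant data frame from [place_sites()].
#' @param landscape A [landcover_raster()].
#' @return List with `allele_freqs` (per-locus named frequency vectors),
#'   `mothers` (plants + genotype columns) and `donors` (`donor_id`, `x`,
#'   `y` + genotype columns).
#' @export
simulate_population_genotypes <- function(config, plants, landscape) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed + 3L)
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  allele_freqs <- lapply(loci, function(L) {
    gam <- stats::rgamma(config$alleles_per_locus,
                         shape = config$freq_concentration)
    if (sum(gam) == 0) gam <- rep(1, length(gam))
    stats::setNames(gam / sum(gam),
                    sprintf("%03d", seq_len(config$alleles_per_locus)))
  })
  names(allele_freqs) <- loci
  mothers <- cbind(plants, draw_genotypes(nrow(plants), allele_freqs))
  habitat <- classify_habitat(landscape, "BROAD")
  idx <- which(habitat$grid == 1L)
  area_ha <- length(idx) * landscape$cell_size^2 / 1e4
  n_donors <- max(1L, round(area_ha * config$donor_density))
  pick <- idx[sample.int(length(idx), n_donors,
                         replace = n_donors > length(idx))]
  nr <- nrow(habitat$grid)
  ctr <- pixel_centre(habitat, ((pick - 1L) %% nr) + 1L,
                      ((pick - 1L) %/% nr) + 1L)
  jit <- landscape$cell_size * 0.4
  dx <- ctr[, "x"] + stats::runif(n_donors, -jit, jit)
  dy <- ctr[, "y"] + stats::runif(n_donors, -jit, jit)
  # guarantee a few flowering neighbours around every site
  hx <- pixel_centre(habitat, ((idx - 1L) %% nr) + 1L,
                     ((idx - 1L) %/% nr) + 1L)
  for (sid in unique(plants$site_id)) {
    pp <- plants[plants$site_id == sid, , drop = FALSE]
    med <- median_site_coordinate(pp[, c("x", "y")])
    near <- which(sqrt((hx[, "x"] - med["x"])^2 +
                         (hx[, "y"] - med["y"])^2) <= config$mother_scatter)
    if (length(near) == 0) next
    pick2 <- near[sample.int(length(near), config$donors_min_per_site,
                             replace = TRUE)]
    dx <- c(dx, hx[pick2, "x"] + stats::runif(length(pick2), -jit, jit))
    dy <- c(dy, hx[pick2, "y"] + stats::runif(length(pick2), -jit, jit))
  }
  donors <- data.frame(
    donor_id = sprintf("D%05d", seq_along(dx)),
    x = dx, y = dy, stringsAsFactors = FALSE)
  donors <- cbind(donors, draw_genotypes(nrow(donors), allele_freqs))
  list(allele_freqs = allele_freqs, mothers = mothers, donors = donors)
}

#' Simulate pollination and seed genotypes for one site
#'
#' Fathers are sampled among the discrete donor plants of the clipped
#' local landscape with probability proportional to
#' `exp(-alpha * d(mother, donor)) * exp(-lambda * d_k)`, where `d_k` is
#' the minimum summed gap distance from the donor's (broad-definition)
#' habitat patch to the focal patch. Each seed receives one random
#' maternal and one random paternal allele per locus.
#'
#' @param landscape A [landcover_raster()].
#' @param site One row of the `sites` data frame from [place_sites()].
#' @param mothers Rows of the genotyped maternal-plant table for the site.
#' @param donors Genotyped donor table from
#'   [simulate_population_genotypes()].
#' @param config A [synthetic_config()].
#' @param site_index Integer making the per-site RNG stream unique.
#' @return List with `seeds` (genotype data frame with `individual_id`,
#'   `mother_id`, `site_id`, `year` and locus columns), `fathers` (donor
#'   id per seed) and `accessibility` (the summed siring kernel over
#'   donors, evaluated from the site centre: the generative ground truth
#'   for donor accessibility).
#' @export
simulate_pollination <- function(landscape, site, mothers, donors, config,
                                 site_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed + 1000L + site_index)
  habitat <- classify_habitat(landscape, "BROAD")
  s <- sampling_site(site$site_id, site$x, site$y, habitat)
  clipped <- clip_local_landscape(habitat, s, config$radius)
  patches <- label_patches(clipped, config$neighbourhood)
  focal <- focal_patch_of(patches, s)
  graph <- build_patch_graph(patches, focal)
  dk <- min_summed_gap_distance(graph)
  # donors usable by this site: within the radius and on habitat pixels
  ok <- sqrt((donors$x - site$x)^2 + (donors$y - site$y)^2) <= config$radius
  dsub <- donors[ok, , drop = FALSE]
  if (nrow(dsub) > 0) {
    px <- point_to_pixel(patches, dsub$x, dsub$y)
    lab <- patches$labels[cbind(px[, "row"], px[, "col"])]
    dsub <- dsub[lab > 0, , drop = FALSE]
    lab <- lab[lab > 0]
  }
  if (nrow(dsub) == 0)
    stop("generation failure: no reachable pollen donor for site ",
         site$site_id, call. = FALSE)
  p_gap <- gap_crossing_probability(unname(dk[as.character(lab)]),
                                    config$lambda)
  d_site <- sqrt((dsub$x - site$x)^2 + (dsub$y - site$y)^2)
  accessibility <- sum(exp(-config$alpha * d_site) * p_gap)
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  seed_list <- vector("list", nrow(mothers))
  fathers <- character(0)
  ns <- config$n_seeds_per_mother
  for (mi in seq_len(nrow(mothers))) {
    m <- mothers[mi, ]
    d <- sqrt((dsub$x - m$x)^2 + (dsub$y - m$y)^2)
    w <- exp(-config$alpha * d) * p_gap
    if (sum(w) == 0)
      stop("generation failure: no reachable pollen donor for mother ",
           m$plant_id, call. = FALSE)
    f_idx <- sample.int(nrow(dsub), ns, replace = TRUE, prob = w)
    block <- data.frame(
      individual_id = sprintf("%s_S%04d", m$plant_id, seq_len(ns)),
      mother_id = m$plant_id, site_id = site$site_id, year = 1L,
      stringsAsFactors = FALSE)
    for (L in loci) {
      m_all <- c(m[[paste0(L, "_1")]], m[[paste0(L, "_2")]])
      f1 <- dsub[[paste0(L, "_1")]][f_idx]
      f2 <- dsub[[paste0(L, "_2")]][f_idx]
      block[[paste0(L, "_1")]] <- m_all[1 + (stats::runif(ns) < 0.5)]
      block[[paste0(L, "_2")]] <- ifelse(stats::runif(ns) < 0.5, f1, f2)
    }
    seed_list[[mi]] <- block
    fathers <- c(fathers, dsub$donor_id[f_idx])
  }
  list(seeds = do.call(rbind, seed_list), fathers = fathers,
       accessibility = accessibility)
}

#' Simulate capture counts and the biparental inbreeding response
#'
#' High-mobility capture counts are Binomial with success probability
#' `plogis(capture_intercept + capture_slope * z)` where `z` is the
#' standardised driver (true donor accessibility); biparental inbreeding
#' is `tm_intercept - tm_slope * z` plus Gaussian noise, reflecting more
#' mating among relatives where fewer donors are accessible.
#'
#' @param site_ids Character vector of site ids.
#' @param driver Numeric driver per site (standardised internally).
#' @param config A [synthetic_config()].
#' @return List with `captures` (long data frame `site_id`, `mobility`,
#'   `count`) and `responses` (`site_id`, `tm_minus_ts`).
#' @export
simulate_captures_and_responses <- function(site_ids, driver, config) {
  stopifnot(inherits(config, "synthetic_config"),
            length(site_ids) == length(driver))
  set.seed(config$rng_seed + 5L)
  z <- if (stats::sd(driver) > 0) standardize(driver) else driver * 0
  n_cap <- stats::rpois(length(site_ids), config$n_captures_mean)
  p_high <- stats::plogis(config$capture_intercept +
                            config$capture_slope * z)
  n_high <- stats::rbinom(length(site_ids), n_cap, p_high)
  captures <- rbind(
    data.frame(site_id = site_ids, mobility = "high", count = n_high,
               stringsAsFactors = FALSE),
    data.frame(site_id = site_ids, mobility = "low",
               count = n_cap - n_high, stringsAsFactors = FALSE))
  tm <- config$tm_intercept - config$tm_slope * z +
    stats::rnorm(length(site_ids), 0, config$response_noise_sd)
  list(captures = captures,
       responses = data.frame(site_id = site_ids, tm_minus_ts = tm,
                              stringsAsFactors = FALSE))
}

#' Run the full synthetic study
#'
#' Generates a landscape, sampling sites and maternal plants, population
#' genotypes and donors, pollination (seed genotypes) per site, and the
#' capture/inbreeding responses driven by each site's true donor
#' accessibility. The output bundle feeds the analysis pipeline
#' unmodified.
#'
#' @param config A [synthetic_config()].
#' @return List with `landscape`, `sites`, `plants`, `genotypes` (mothers
#'   and seeds stacked), `captures`, `responses` and `truth` (per-site
#'   generative donor accessibility).
#' @export
simulate_study <- function(config = synthetic_config()) {
  landscape <- generate_landscape(config)
  placed <- place_sites(landscape, config)
  pop <- simulate_population_genotypes(config, placed$plants, landscape)
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  mother_rows <- data.frame(
    individual_id = pop$mothers$plant_id, mother_id = NA_character_,
    site_id = pop$mothers$site_id, year = 1L, stringsAsFactors = FALSE)
  for (L in loci) {
    mother_rows[[paste0(L, "_1")]] <- pop$mothers[[paste0(L, "_1")]]
    mother_rows[[paste0(L, "_2")]] <- pop$mothers[[paste0(L, "_2")]]
  }
  seeds_all <- NULL
  access <- numeric(nrow(placed$sites))
  for (i in seq_len(nrow(placed$sites))) {
    site <- placed$sites[i, ]
    res <- simulate_pollination(
      landscape, site,
      pop$mothers[pop$mothers$site_id == site$site_id, , drop = FALSE],
      pop$donors, config, site_index = i)
    seeds_all <- rbind(seeds_all, res$seeds)
    access[i] <- res$accessibility
  }
  cr <- simulate_captures_and_responses(placed$sites$site_id, access,
                                        config)
  list(landscape = landscape, sites = placed$sites, plants = placed$plants,
       genotypes = rbind(mother_rows, seeds_all),
       captures = cr$captures, responses = cr$responses,
       truth = data.frame(site_id = placed$sites$site_id,
                          accessibility = access,
                          stringsAsFactors = FALSE))
}

#' Correlation structure of the metric suite over simulated landscapes
#'
#' Generates `n_landscapes` independent synthetic landscapes (one site
#' each), computes the 15-metric suite for every site, and returns the
#' Pearson correlation matrix across landscapes. Metrics that are constant
#' across the ensemble yield `NA` rows/columns (flagged, not an error).
#'
#' @param config A [synthetic_config()]; its seed anchors the ensemble.
#' @param n_landscapes Number of landscapes (>= 2).
#' @return 15 x 15 correlation matrix, rows/columns named by metric.
#' @export
metric_correlation_study <- function(config = synthetic_config(),
                                     n_landscapes = 20) {
  stopifnot(n_landscapes >= 2)
  vals <- NULL
  for (i in seq_len(n_landscapes)) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + i * 13L
    cfg$n_sites <- 1L
    landscape <- generate_landscape(cfg)
    placed <- place_sites(landscape, cfg)
    site <- sampling_site(placed$sites$site_id[1], placed$sites$x[1],
                          placed$sites$y[1], landscape)
    suite <- compute_metric_suite(landscape, site, alpha = cfg$alpha,
                                  lambda = cfg$lambda, radius = cfg$radius,
                                  neighbourhood = cfg$neighbourhood)
    v <- stats::setNames(suite$transformed, metric_key(suite))
    vals <- rbind(vals, v)
  }
  sds <- apply(vals, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(vals))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- 1
  cm
}
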