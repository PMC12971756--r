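#' Specification of a connectivity metric
#'
#' Captures the factorial levels and movement parameters that define one of
#' the 15 connectivity metrics: 3 intra-patch variants plus the 2 x 2 x 3
#' factorial of local landscape metrics (habitat definition x
#' distance-weighting x gap-crossing mode).
#'
#' @param scale `"INTRA_PATCH"` or `"LOCAL"`.
#' @param variant Intra-patch variant: `"TOTAL_AREA"`,
#'   `"AREA_WITHIN_RADIUS"` or `"DISTANCE_WEIGHTED"` (intra scale only).
#' @param habitat_def `"NARROW"` or `"BROAD"`; intra-patch metrics always
#'   use `"NARROW"` (discrete patches are not delineable under the broad
#'   definition because narrow forest elements connect everything).
#' @param weighting `"UNWEIGHTED"` or `"KERNEL"` (negative exponential
#'   distance kernel from the sampling pixel).
#' @param gap_mode `"UNLIMITED"`, `"THRESHOLD"` or `"PROBABILISTIC"`.
#' @param alpha Kernel decay rate, 1/metres; default `1/282`, the inverse
#'   mean home-range length of *Phaethornis guy*.
#' @param lambda Gap-crossing decay rate, 1/metres; default `log(2)/50`
#'   (50% odds reduction at a 50 m gap).
#' @param gap_threshold Gap threshold in metres (default 50; equals twice
#'   the 25 m patch buffer).
#' @param buffer Patch buffer in metres (default 25).
#' @param radius Local landscape radius in metres (default 1000).
#' @param neighbourhood Patch-labelling connectivity, 4 or 8 (default 8).
#' @param log_transform Whether the metric value is log-transformed
#'   (default `TRUE` for intra-patch metrics, `FALSE` for local metrics).
#' @return An object of class `metric_spec`.
#' @export
metric_spec <- function(scale = c("LOCAL", "INTRA_PATCH"),
                        variant = NULL,
                        habitat_def = c("NARROW", "BROAD"),
                        weighting = c("UNWEIGHTED", "KERNEL"),
                        gap_mode = c("UNLIMITED", "THRESHOLD", "PROBABILISTIC"),
                        alpha = 1 / 282, lambda = log(2) / 50,
                        gap_threshold = 50, buffer = 25, radius = 1000,
                        neighbourhood = 8,
                        log_transform = NULL) {
  scale <- match.arg(scale)
  habitat_def <- match.arg(habitat_def)
  weighting <- match.arg(weighting)
  gap_mode <- match.arg(gap_mode)
  stopifnot(alpha > 0, lambda > 0, gap_threshold > 0, radius > 0)
  if (abs(gap_threshold - 2 * buffer) > 1e-9)
    stop("`gap_threshold` must equal twice the patch `buffer`",
         call. = FALSE)
  if (scale == "INTRA_PATCH") {
    variant <- match.arg(variant,
                         c("TOTAL_AREA", "AREA_WITHIN_RADIUS",
                           "DISTANCE_WEIGHTED"))
    habitat_def <- "NARROW"
  } else if (!is.null(variant)) {
    stop("`variant` applies only to intra-patch metrics", call. = FALSE)
  }
  if (is.null(log_transform)) log_transform <- scale == "INTRA_PATCH"
  structure(list(scale = scale, variant = variant,
                 habitat_def = habitat_def, weighting = weighting,
                 gap_mode = gap_mode, alpha = alpha, lambda = lambda,
                 gap_threshold = gap_threshold, buffer = buffer,
                 radius = radius, neighbourhood = neighbourhood,
                 log_transform = log_transform),
            class = "metric_spec")
}

# distance (m) from the site pixel centre to the centres of the given
# linear grid indices
site_pixel_distances <- function(raster, site, idx) {
  g <- grid_of(raster)
  nr <- nrow(g)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  p <- pixel_centre(raster, rows, cols)
  ctr <- pixel_centre(raster, site$pixel["row"], site$pixel["col"])
  sqrt((p[, "x"] - ctr[1, "x"])^2 + (p[, "y"] - ctr[1, "y"])^2)
}

metric_value <- function(site, scale, metric, habitat_def, weighting,
                         gap_mode, value_ha, transformed) {
  data.frame(site_id = site$site_id, scale = scale, metric = metric,
              habitat_def = habitat_def, weighting = weighting,
              gap_mode = gap_mode, value_ha = value_ha,
              transformed = transformed, stringsAsFactors = FALSE)
}

#' Focal patch area
#'
#' Total area (ha) of the entire focal patch on the full raster extent
#' (narrow habitat definition), log-transformed: the purely structural
#' intra-patch connectivity metric.
#'
#' @param patches_full_extent Patch map labelled on the unclipped extent.
#' @param site A [sampling_site()].
#' @return One-row metric data frame (`value_ha`, `transformed`).
#' @export
focal_patch_area <- function(patches_full_extent, site) {
  focal <- focal_patch_of(patches_full_extent, site)
  a <- unname(patches_full_extent$patch_areas[as.character(focal)])
  metric_value(site, "INTRA_PATCH", "focal_patch_area", "NARROW",
               NA_character_, NA_character_, a, log(a))
}

#' Focal patch area within the local landscape radius
#'
#' Area (ha) of the part of the focal patch whose pixel centres lie within
#' `radius` of the sampling site, log-transformed: a simple functional
#' metric imposing the pollinator's maximum daily movement range.
#'
#' @inheritParams focal_patch_area
#' @param radius Radius in metres (default 1000).
#' @return One-row metric data frame.
#' @export
focal_patch_area_within_radius <- function(patches_full_extent, site,
                                           radius = 1000) {
  focal <- focal_patch_of(patches_full_extent, site)
  idx <- which(patches_full_extent$labels == focal)
  d <- site_pixel_distances(patches_full_extent, site, idx)
  a <- sum(d <= radius) * patches_full_extent$cell_size^2 / 1e4
  metric_value(site, "INTRA_PATCH", "focal_patch_area_within_radius",
               "NARROW", NA_character_, NA_character_, a, log(a))
}

#' Distance-weighted focal patch area
#'
#' Negative exponential dispersal kernel summed over focal-patch pixels
#' within `radius` of the sampling site (excluding the site pixel itself),
#' log-transformed. An elongated patch scores lower than a round patch of
#' equal area because distant pixels contribute less.
#'
#' @inheritParams focal_patch_area_within_radius
#' @param alpha Kernel decay rate, 1/metres (default `1/282`).
#' @return One-row metric data frame.
#' @export
distance_weighted_focal_patch_area <- function(patches_full_extent, site,
                                               alpha = 1 / 282,
                                               radius = 1000) {
  focal <- focal_patch_of(patches_full_extent, site)
  idx <- which(patches_full_extent$labels == focal)
  d <- site_pixel_distances(patches_full_extent, site, idx)
  d <- d[d > 0 & d <= radius]   # j != i, within the local landscape
  a <- sum(exp(-alpha * d)) * patches_full_extent$cell_size^2 / 1e4
  metric_value(site, "INTRA_PATCH", "distance_weighted_focal_patch_area",
               "NARROW", NA_character_, NA_character_, a, log(a))
}

# core local landscape sum: S_i = sum_{j != i} k_ij * p_patch(j) * pixel ha
local_S <- function(patches, graph, site, alpha, lambda, gap_threshold,
                    weighting, gap_mode) {
  idx <- which(patches$labels > 0)
  site_lin <- (site$pixel["col"] - 1L) * nrow(patches$labels) +
    site$pixel["row"]
  idx <- idx[idx != site_lin]
  if (length(idx) == 0) return(0)
  k_ij <- if (weighting == "KERNEL")
    exp(-alpha * site_pixel_distances(patches, site, idx)) else 1
  p_patch <- rep(1, length(graph$ids))
  names(p_patch) <- graph$ids
  if (gap_mode == "THRESHOLD") {
    conn <- connected_patches_threshold(graph, gap_threshold)
    p_patch[] <- as.numeric(graph$ids %in% conn)
  } else if (gap_mode == "PROBABILISTIC") {
    dk <- min_summed_gap_distance(graph)
    p_patch[] <- gap_crossing_probability(unname(dk[as.character(graph$ids)]),
                                          lambda)
    p_patch[as.character(graph$focal)] <- 1
  }
  labs <- patches$labels[idx]
  sum(k_ij * p_patch[as.character(labs)]) * patches$cell_size^2 / 1e4
}

#' Local landscape connectivity (raster-cell incidence function model)
#'
#' Computes `S_i = sum_{j != i} exp(-alpha * d_ij)^[kernel] * p_j * A_j`
#' over all habitat pixels j of the clipped local landscape, where `A_j`
#' is the pixel area (0.01 ha for 10 m cells) and `p_j` is the patch-level
#' gap-crossing term of the spec's `gap_mode`: 1 everywhere (unlimited),
#' membership of the focal 50 m-threshold component (threshold), or
#' `exp(-lambda * d_k)` of the patch's minimum summed gap distance
#' (probabilistic; focal patch p = 1).
#'
#' @param habitat_clipped Habitat raster already clipped to the local
#'   landscape (see [clip_local_landscape()]), under `spec$habitat_def`.
#' @param site A [sampling_site()] whose pixel is habitat.
#' @param spec A [metric_spec()] with `scale = "LOCAL"`.
#' @return One-row metric data frame (`value_ha`; `transformed` equals
#'   `value_ha` unless `spec$log_transform`).
#' @export
local_connectivity <- function(habitat_clipped, site, spec) {
  stopifnot(inherits(habitat_clipped, "habitat_raster"),
            inherits(site, "sampling_site"), inherits(spec, "metric_spec"))
  if (spec$scale != "LOCAL")
    stop("`spec` must have scale = \"LOCAL\"", call. = FALSE)
  if (habitat_clipped$definition != spec$habitat_def)
    stop("habitat raster definition does not match `spec$habitat_def`",
         call. = FALSE)
  patches <- label_patches(habitat_clipped, spec$neighbourhood)
  focal <- focal_patch_of(patches, site)
  graph <- build_patch_graph(patches, focal)
  s <- local_S(patches, graph, site, spec$alpha, spec$lambda,
               spec$gap_threshold, spec$weighting, spec$gap_mode)
  metric_value(site, "LOCAL", "local_connectivity", spec$habitat_def,
               spec$weighting, spec$gap_mode, s,
               if (spec$log_transform) log(s) else s)
}

#' Compute the full suite of 15 connectivity metrics for a site
#'
#' Three intra-patch metrics (narrow habitat definition, full-extent focal
#' patch) plus the 12 local landscape metrics of the 2 x 2 x 3 factorial
#' (habitat definition x distance-weighting x gap-crossing mode), all
#' expressed in hectares of functionally connected trapliner habitat.
#'
#' @param landcover A [landcover_raster()].
#' @param site A [sampling_site()] on a mature-forest pixel.
#' @param alpha,lambda,gap_threshold,radius,neighbourhood Movement and
#'   geometry parameters; see [metric_spec()].
#' @return Data frame of 15 rows with columns `site_id`, `scale`,
#'   `metric`, `habitat_def`, `weighting`, `gap_mode`, `value_ha`,
#'   `transformed`.
#' @export
compute_metric_suite <- function(landcover, site, alpha = 1 / 282,
                                 lambda = log(2) / 50, gap_threshold = 50,
                                 radius = 1000, neighbourhood = 8) {
  stopifnot(inherits(landcover, "landcover_raster"),
            inherits(site, "sampling_site"))
  narrow_full <- classify_habitat(landcover, "NARROW")
  patches_full <- label_patches(narrow_full, neighbourhood)
  out <- rbind(
    focal_patch_area(patches_full, site),
    focal_patch_area_within_radius(patches_full, site, radius),
    distance_weighted_focal_patch_area(patches_full, site, alpha, radius))
  for (def in c("NARROW", "BROAD")) {
    hab <- clip_local_landscape(classify_habitat(landcover, def), site,
                                radius)
    patches <- label_patches(hab, neighbourhood)
    focal <- focal_patch_of(patches, site)
    graph <- build_patch_graph(patches, focal)
    for (wt in c("UNWEIGHTED", "KERNEL")) {
      for (gm in c("UNLIMITED", "THRESHOLD", "PROBABILISTIC")) {
        s <- local_S(patches, graph, site, alpha, lambda, gap_threshold,
                     wt, gm)
        out <- rbind(out, metric_value(site, "LOCAL", "local_connectivity",
                                       def, wt, gm, s, s))
      }
    }
  }
  rownames(out) <- NULL
  out
}

# short factorial label used in comparison tables, e.g. "BROAD.KERNEL.PROBABILISTIC"
metric_key <- function(metrics) {
  ifelse(metrics$scale == "INTRA_PATCH", metrics$metric,
         paste(metrics$habitat_def, metrics$weighting, metrics$gap_mode,
               sep = "."))
}
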