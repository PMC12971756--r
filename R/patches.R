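#' Label contiguous habitat patches
#'
#' Connected-component labelling of the binary habitat grid. Labels are
#' assigned in row-major first-seen order, so the labelling is deterministic
#' for a given grid and neighbourhood.
#'
#' @param habitat A [habitat_raster()].
#' @param neighbourhood 8 (default; diagonal habitat cells are traversable
#'   by a flying pollinator) or 4.
#' @return An object of class `patch_map` with fields `labels` (integer
#'   matrix, 0 = non-habitat), `neighbourhood`, `patch_areas` (hectares,
#'   named by patch id), and the source geometry.
#' @export
label_patches <- function(habitat, neighbourhood = 8) {
  stopifnot(inherits(habitat, "habitat_raster"))
  if (!neighbourhood %in% c(4, 8))
    stop("`neighbourhood` must be 4 or 8", call. = FALSE)
  g <- habitat$grid
  nr <- nrow(g); nc <- ncol(g)
  hab <- which(g == 1L)
  labels <- matrix(0L, nr, nc)
  if (length(hab) > 0) {
    node <- integer(nr * nc)
    node[hab] <- seq_along(hab)
    rows <- ((hab - 1L) %% nr) + 1L
    cols <- ((hab - 1L) %/% nr) + 1L
    offs <- list(c(1L, 0L), c(0L, 1L))
    if (neighbourhood == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
    from <- integer(0); to <- integer(0)
    for (o in offs) {
      r2 <- rows + o[1]; c2 <- cols + o[2]
      ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
      lin2 <- (c2[ok] - 1L) * nr + r2[ok]
      sel <- g[lin2] == 1L
      from <- c(from, node[hab[ok]][sel])
      to <- c(to, node[lin2[sel]])
    }
    gr <- igraph::make_empty_graph(n = length(hab), directed = FALSE)
    if (length(from) > 0)
      gr <- igraph::add_edges(gr, rbind(from, to))
    memb <- igraph::components(gr)$membership
    # relabel components by first appearance in row-major order
    ord <- order(rows, cols)
    seen <- memb[ord][!duplicated(memb[ord])]
    newid <- integer(max(memb))
    newid[seen] <- seq_along(seen)
    labels[hab] <- newid[memb]
  }
  n_patch <- if (length(hab)) max(labels) else 0L
  areas <- if (n_patch > 0)
    stats::setNames(tabulate(labels[labels > 0], n_patch) *
                      habitat$cell_size^2 / 1e4, seq_len(n_patch))
  else stats::setNames(numeric(0), character(0))
  structure(list(labels = labels, neighbourhood = neighbourhood,
                 patch_areas = areas, cell_size = habitat$cell_size,
                 origin = habitat$origin, crs = habitat$crs,
                 definition = habitat$definition),
            class = "patch_map")
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf("<patch_map> %d patches, %.1f ha habitat (%d-neighbourhood)\n",
              length(x$patch_areas), sum(x$patch_areas), x$neighbourhood))
  invisible(x)
}

#' Focal patch containing a sampling site
#'
#' @param patches A [label_patches()] result.
#' @param site A [sampling_site()].
#' @return The patch id at the site pixel.
#' @export
focal_patch_of <- function(patches, site) {
  stopifnot(inherits(patches, "patch_map"), inherits(site, "sampling_site"))
  lab <- patches$labels[site$pixel["row"], site$pixel["col"]]
  if (lab == 0L)
    stop("focal patch undefined: site '", site$site_id,
         "' does not lie on a habitat pixel (site/landcover mismatch?)",
         call. = FALSE)
  unname(lab)
}

# boundary pixels of a patch: habitat pixels with a 4-neighbour outside the
# patch (or on the raster edge); the nearest pixel of a patch to any
# external point always lies on this set
patch_boundary <- function(patches, id) {
  lab <- patches$labels
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab == id)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  inside <- rep(TRUE, length(idx))
  for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    off_grid <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
    lin2 <- (pmax(pmin(c2, nc), 1L) - 1L) * nr + pmax(pmin(r2, nr), 1L)
    inside <- inside & !off_grid & lab[lin2] == id
  }
  cbind(row = rows[!inside], col = cols[!inside])
}

# minimum Euclidean distance between two point sets, chunked to bound memory
min_cross_distance <- function(xa, ya, xb, yb, chunk_cells = 4e6) {
  na <- length(xa)
  step <- max(1L, floor(chunk_cells / max(1L, length(xb))))
  best <- Inf
  i <- 1L
  while (i <= na) {
    j <- min(na, i + step - 1L)
    d2 <- outer(xa[i:j], xb, `-`)^2 + outer(ya[i:j], yb, `-`)^2
    best <- min(best, min(d2))
    i <- j + 1L
  }
  sqrt(best)
}

#' Edge-to-edge gap distance between two patches
#'
#' Raster surrogate for the edge-to-edge distance of (vector) patches:
#' the minimum centre-to-centre Euclidean distance over all pixel pairs,
#' minus one cell width, floored at zero. Symmetric in its arguments.
#'
#' @param patches A [label_patches()] result.
#' @param a,b Distinct patch ids.
#' @return Gap distance in metres.
#' @export
patch_gap_distance <- function(patches, a, b) {
  stopifnot(inherits(patches, "patch_map"))
  ids <- as.integer(names(patches$patch_areas))
  if (!(a %in% ids) || !(b %in% ids))
    stop("unknown patch id", call. = FALSE)
  if (a == b) stop("`a` and `b` must be distinct patches", call. = FALSE)
  ba <- patch_boundary(patches, a)
  bb <- patch_boundary(patches, b)
  pa <- pixel_centre(patches, ba[, "row"], ba[, "col"])
  pb <- pixel_centre(patches, bb[, "row"], bb[, "col"])
  d <- min_cross_distance(pa[, "x"], pa[, "y"], pb[, "x"], pb[, "y"])
  max(0, d - patches$cell_size)
}

#' Build the complete patch gap-distance graph
#'
#' Materialises pairwise edge-to-edge gap distances between all patches of
#' a (typically clipped) patch map, with the focal patch recorded. This is
#' the input for both gap-crossing modes that restrict connectivity.
#'
#' @param patches A [label_patches()] result.
#' @param focal Focal patch id.
#' @return An object of class `patch_graph` with fields `ids`, `areas`
#'   (ha), `gap` (symmetric matrix of gap distances, metres) and `focal`.
#' @export
build_patch_graph <- function(patches, focal) {
  stopifnot(inherits(patches, "patch_map"))
  ids <- as.integer(names(patches$patch_areas))
  if (length(ids) == 0) stop("no patches to build a graph from", call. = FALSE)
  if (!(focal %in% ids)) stop("unknown focal patch id", call. = FALSE)
  k <- length(ids)
  gap <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k > 1) {
    bnds <- lapply(ids, function(id) {
      b <- patch_boundary(patches, id)
      pixel_centre(patches, b[, "row"], b[, "col"])
    })
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d <- min_cross_distance(bnds[[i]][, "x"], bnds[[i]][, "y"],
                                bnds[[j]][, "x"], bnds[[j]][, "y"])
        gap[i, j] <- gap[j, i] <- max(0, d - patches$cell_size)
      }
    }
  }
  structure(list(ids = ids, areas = unname(patches$patch_areas),
                 gap = gap, focal = as.integer(focal)),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %d patches, focal = %d\n",
              length(x$ids), x$focal))
  invisible(x)
}

#' Patches connected to the focal patch under a gap threshold
#'
#' Two patches are directly connected when their gap distance is at most
#' `gap_threshold` (equivalently, when their 25 m buffers overlap for the
#' default 50 m threshold). Connection is transitive through stepping-stone
#' patches: the result is the connected component containing the focal
#' patch in the thresholded graph.
#'
#' @param graph A [build_patch_graph()] result.
#' @param gap_threshold Gap threshold in metres (default 50).
#' @return Sorted integer vector of connected patch ids (always includes
#'   the focal patch).
#' @export
connected_patches_threshold <- function(graph, gap_threshold = 50) {
  stopifnot(inherits(graph, "patch_graph"))
  k <- length(graph$ids)
  adj <- (graph$gap <= gap_threshold)
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(gr)$membership
  focal_pos <- match(graph$focal, graph$ids)
  sort(graph$ids[memb == memb[focal_pos]])
}

#' Minimum summed gap distance to the focal patch
#'
#' For every patch k, the minimum over all patch sequences from the focal
#' patch to k of the summed gap distances along the sequence (habitat
#' traversal within patches costs nothing). Stepping stones can therefore
#' shorten the effective non-forested distance below the direct gap.
#'
#' @param graph A [build_patch_graph()] result.
#' @return Named numeric vector of d_k in metres, one per patch id;
#'   the focal patch has d = 0.
#' @export
min_summed_gap_distance <- function(graph) {
  stopifnot(inherits(graph, "patch_graph"))
  k <- length(graph$ids)
  if (k == 1)
    return(stats::setNames(0, graph$ids))
  # graph_from_adjacency_matrix drops zero entries; distinct raster patches
  # always have gap > 0, but guard touching patches with a negligible weight
  wmat <- graph$gap
  off <- row(wmat) != col(wmat) & wmat == 0
  wmat[off] <- 1e-9
  gr <- igraph::graph_from_adjacency_matrix(wmat, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  focal_pos <- match(graph$focal, graph$ids)
  d <- igraph::distances(gr, v = focal_pos)[1, ]
  stats::setNames(as.numeric(d), graph$ids)
}

#' Gap-crossing probability
#'
#' Probability that a traplining hummingbird crosses a summed non-forested
#' gap of `d` metres, modelled as a negative exponential
#' `exp(-lambda * d)`. The default `lambda = log(2)/50` encodes a 50%
#' reduction in crossing odds at a 50 m gap, the midpoint of the
#' radio-tracking estimate (46-63 m).
#'
#' @param d Gap distance(s) in metres, non-negative.
#' @param lambda Decay rate per metre.
#' @return Probabilities in (0, 1]; exactly 1 at `d = 0`.
#' @export
gap_crossing_probability <- function(d, lambda = log(2) / 50) {
  if (any(d < 0)) stop("gap distance must be non-negative", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0)
    stop("`lambda` must be positive", call. = FALSE)
  exp(-lambda * d)
}
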