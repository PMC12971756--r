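# Independent brute-force oracles used to pin expected values. These are
# deliberately naive and share no code with the package internals.

# connected-component labelling by queue-based flood fill
oracle_label <- function(grid, neighbourhood = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  labels <- matrix(0L, nr, nc)
  nb <- if (neighbourhood == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  lab <- 0L
  for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
    if (grid[rr, cc] == 1L && labels[rr, cc] == 0L) {
      lab <- lab + 1L
      queue <- list(c(rr, cc))
      labels[rr, cc] <- lab
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in nb) {
          r2 <- p[1] + o[1]; c2 <- p[2] + o[2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              grid[r2, c2] == 1L && labels[r2, c2] == 0L) {
            labels[r2, c2] <- lab
            queue[[length(queue) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  labels
}

# gap distance by exhaustive pixel pairs (centre-to-centre minus one cell,
# floored at zero); grid rows are top-down like the package rasters
oracle_gap_distance <- function(labels, a, b, cell_size = 10) {
  pa <- which(labels == a, arr.ind = TRUE)
  pb <- which(labels == b, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    d <- sqrt(sum(((pa[i, ] - pb[j, ]) * cell_size)^2))
    best <- min(best, d)
  }
  max(0, best - cell_size)
}

# minimum summed gap distance by exhaustive enumeration of simple paths
oracle_min_summed_gap <- function(gap, focal) {
  k <- nrow(gap)
  best <- rep(Inf, k)
  best[focal] <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  others <- setdiff(seq_len(k), focal)
  for (target in others) {
    thru <- setdiff(others, target)
    for (m in 0:length(thru)) {
      subsets <- if (m == 0) list(integer(0)) else
        utils::combn(thru, m, simplify = FALSE)
      for (ss in subsets) for (ord in perms(ss)) {
        path <- c(focal, ord, target)
        len <- sum(gap[cbind(path[-length(path)], path[-1])])
        best[target] <- min(best[target], len)
      }
    }
  }
  best
}

# Akaike weights as a plain softmax over -delta/2
oracle_softmax_weights <- function(a) {
  e <- exp(-(a - min(a)) / 2)
  e / sum(e)
}

# OLS slope/intercept by solving the normal equations directly
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], beta = beta[2], se = se, r2 = r2)
}

# probability two draws (with replacement) from the allele multiset differ
oracle_pair_diversity <- function(alleles) {
  n <- length(alleles)
  diff <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    diff <- diff + (alleles[i] != alleles[j])
  diff / n^2
}

# tiny landcover raster from a code matrix (rows top-down)
lc <- function(m, cell_size = 10) {
  landcover_raster(m, cell_size = cell_size, origin = c(0, 0))
}

# habitat raster from a binary matrix
hab <- function(m, definition = "NARROW", cell_size = 10) {
  habitat_raster(m, definition, cell_size = cell_size, origin = c(0, 0))
}

# a small landcover matrix: one solid mature block in pasture
block_landcover <- function(n = 20, block_rows = 5:10, block_cols = 5:10) {
  m <- matrix(LANDCOVER_CODES[["PASTURE"]], n, n)
  m[block_rows, block_cols] <- LANDCOVER_CODES[["MATURE"]]
  m
}
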