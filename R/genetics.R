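#' Infer the paternal (pollen) haplotype of a seed
#'
#' Subtracts the maternal genetic contribution from a seed's diploid
#' multilocus genotype, locus by locus. Per locus the outcome is:
#' \describe{
#'   \item{resolved}{exactly one seed allele is absent from the mother
#'     (that allele is paternal), or the seed is homozygous for an allele
#'     the mother carries (the father contributed the same allele).}
#'   \item{ambiguous}{seed and mother are the same heterozygote, so either
#'     allele could be paternal.}
#'   \item{missing}{either genotype is missing at the locus.}
#' }
#' A seed sharing no allele with its mother at a locus indicates a
#' mislabelled family or a genotyping error.
#'
#' @param mother,seed Named lists mapping locus name to a length-2 vector
#'   of allele labels, or `NULL`/`NA` for missing.
#' @param on_incompatible `"error"` (default) or `"missing"` (downgrade the
#'   locus to missing with a warning).
#' @return An object of class `pollen_haplotype`: a named list per locus of
#'   `list(status = "resolved"|"ambiguous"|"missing", alleles = chr)`.
#' @export
infer_pollen_haplotype <- function(mother, seed,
                                   on_incompatible = c("error", "missing")) {
  on_incompatible <- match.arg(on_incompatible)
  loci <- names(mother)
  if (!setequal(loci, names(seed)))
    stop("mother and seed must be genotyped at the same loci", call. = FALSE)
  out <- lapply(loci, function(L) {
    m <- mother[[L]]; s <- seed[[L]]
    if (is.null(m) || is.null(s) || anyNA(m) || anyNA(s))
      return(list(status = "missing", alleles = character(0)))
    m <- as.character(m); s <- as.character(s)
    if (length(m) != 2 || length(s) != 2)
      stop("diploid genotypes must have two alleles at locus ", L,
           call. = FALSE)
    non_maternal <- s[!(s %in% m)]
    if (length(non_maternal) == 2 ||
        (length(unique(s)) == 1 && length(non_maternal) == 2)) {
      # no seed allele is carried by the mother
      if (on_incompatible == "error")
        stop("seed incompatible with mother at locus ", L,
             " (no shared allele)", call. = FALSE)
      warning("seed incompatible with mother at locus ", L,
              "; set to missing", call. = FALSE)
      return(list(status = "missing", alleles = character(0)))
    }
    if (length(non_maternal) == 1)
      return(list(status = "resolved", alleles = non_maternal))
    # both seed alleles occur in the mother
    if (length(unique(s)) == 1)
      return(list(status = "resolved", alleles = unique(s)))
    if (setequal(s, m) && length(unique(m)) == 2)
      return(list(status = "ambiguous", alleles = sort(unique(s))))
    # seed heterozygous, mother homozygous for one of the seed's alleles:
    # the allele the mother lacks is paternal -- already covered above;
    # reaching here means seed = {A,B}, mother carries both but is
    # homozygous, which is impossible for a diploid; defensive error
    stop("unresolvable subtraction at locus ", L, call. = FALSE)
  })
  names(out) <- loci
  structure(out, class = "pollen_haplotype")
}

#' Pool pollen haplotypes at the sampling-site level
#'
#' Combines the pollen haplotypes inferred from all seeds of a site's
#' maternal plants (across sampling years when `merge_years`) into one
#' pollen pool with per-locus allele frequency tables. Resolved alleles
#' count 1; each allele of an ambiguous heterozygote counts 1/2 (or the
#' haplotype is dropped at that locus under `ambiguous = "exclude"`).
#'
#' @param haplotypes List of [infer_pollen_haplotype()] results.
#' @param site_id Site identifier for the pool.
#' @param ambiguous `"half"` (default) or `"exclude"`.
#' @return An object of class `pollen_pool` with fields `site_id`, `n`
#'   (number of haplotypes), `freq` (per-locus named frequency vectors)
#'   and `counts` (per-locus contributing haplotype counts).
#' @export
pool_pollen <- function(haplotypes, site_id = "site",
                        ambiguous = c("half", "exclude")) {
  ambiguous <- match.arg(ambiguous)
  if (length(haplotypes) == 0)
    stop("empty pollen pool for site ", site_id, call. = FALSE)
  loci <- names(haplotypes[[1]])
  freq <- list(); counts <- integer(0)
  for (L in loci) {
    w <- list()
    n_contrib <- 0L
    for (h in haplotypes) {
      entry <- h[[L]]
      if (is.null(entry) || entry$status == "missing") next
      if (entry$status == "resolved") {
        w[[length(w) + 1L]] <- stats::setNames(1, entry$alleles)
        n_contrib <- n_contrib + 1L
      } else if (ambiguous == "half") {
        w[[length(w) + 1L]] <- stats::setNames(c(0.5, 0.5), entry$alleles)
        n_contrib <- n_contrib + 1L
      }
    }
    tot <- unlist(w)
    if (length(tot) == 0) {
      freq[[L]] <- stats::setNames(numeric(0), character(0))
      counts[L] <- 0L
    } else {
      f <- tapply(tot, names(tot), sum)
      freq[[L]] <- stats::setNames(as.numeric(f / sum(f)), names(f))
      counts[L] <- n_contrib
    }
  }
  structure(list(site_id = site_id, n = length(haplotypes), freq = freq,
                 counts = counts, ambiguous = ambiguous),
            class = "pollen_pool")
}

#' @export
print.pollen_pool <- function(x, ...) {
  cat(sprintf("<pollen_pool> site %s: %d haplotypes, %d loci\n",
              x$site_id, x$n, length(x$freq)))
  invisible(x)
}

#' Nei haplotype diversity of a pollen pool
#'
#' Per locus, `h_L = 1 - sum(p_a^2)` over the pool's allele frequencies;
#' the pool diversity is the mean of `h_L` across loci with data. This is
#' the probability, averaged over loci, that the paternal alleles of two
#' randomly chosen seeds differ.
#'
#' @param pool A [pool_pollen()] result.
#' @param unbiased Apply the small-sample factor `n/(n-1)` per locus
#'   (default `FALSE`).
#' @return Diversity `h` in `[0, 1]`.
#' @export
haplotype_diversity <- function(pool, unbiased = FALSE) {
  stopifnot(inherits(pool, "pollen_pool"))
  usable <- names(pool$freq)[pool$counts >= 2]
  if (length(usable) == 0)
    stop("haplotype diversity undefined: no locus with >= 2 contributing ",
         "haplotypes", call. = FALSE)
  hL <- vapply(usable, function(L) {
    p <- pool$freq[[L]]
    h <- 1 - sum(p^2)
    if (unbiased) h <- h * pool$counts[L] / (pool$counts[L] - 1)
    h
  }, numeric(1))
  mean(hL)
}

#' Proportion of high-mobility hummingbirds with shrinkage correction
#'
#' Capture-based proportion of high-mobility (traplining) hummingbirds at a
#' site with the four-pseudo-observation small-sample correction: two
#' successes and two failures are added, so
#' `p = (n_high + 2) / (n_total + 4)`. The estimate is strictly inside
#' (0, 1) and shrinks towards 0.5 as the number of captures goes to zero.
#'
#' @param n_high Number of high-mobility captures.
#' @param n_low Number of low-mobility captures.
#' @return Corrected proportion.
#' @export
proportion_high_mobility <- function(n_high, n_low) {
  if (any(c(n_high, n_low) < 0))
    stop("capture counts must be non-negative", call. = FALSE)
  (n_high + 2) / (n_high + n_low + 4)
}

# genotype table helpers -----------------------------------------------

# split a genotype data frame row into a named list of allele pairs
genotype_loci <- function(row, loci) {
  out <- lapply(loci, function(L) {
    a <- c(row[[paste0(L, "_1")]], row[[paste0(L, "_2")]])
    a <- as.character(a)
    if (anyNA(a) || any(a == "")) return(NULL)
    a
  })
  names(out) <- loci
  out
}

# locus names from a genotype table's paired columns
locus_names <- function(genotypes) {
  cols <- grep("_1$", names(genotypes), value = TRUE)
  loci <- sub("_1$", "", cols)
  missing2 <- setdiff(paste0(loci, "_2"), names(genotypes))
  if (length(missing2) > 0)
    stop("genotype table missing paired column(s): ",
         paste(missing2, collapse = ", "), call. = FALSE)
  loci
}

#' Build the site-level response table
#'
#' Runs pollen haplotype subtraction for every mother-seed pair, pools the
#' haplotypes per site (merging sampling years when `merge_years`),
#' computes haplotype diversity, joins the corrected proportion of
#' high-mobility hummingbirds from capture counts, and passes through the
#' externally estimated biparental inbreeding values.
#'
#' @param genotypes Data frame with columns `individual_id`, `mother_id`
#'   (empty/NA for maternal plants), `site_id`, `year`, then two columns
#'   per locus (`<locus>_1`, `<locus>_2`; empty = missing).
#' @param captures Data frame with columns `site_id`, `mobility`
#'   (`"high"`/`"low"`), `count`. May cover a subset of sites.
#' @param responses Data frame with columns `site_id`, `tm_minus_ts`.
#' @param merge_years Pool haplotypes across years per site (default
#'   `TRUE`).
#' @param on_incompatible,ambiguous Passed to [infer_pollen_haplotype()]
#'   and [pool_pollen()].
#' @return Data frame with one row per site: `site_id`,
#'   `prop_high_mobility`, `h`, `tm_minus_ts` (NA where an input does not
#'   cover the site).
#' @export
build_response_table <- function(genotypes, captures = NULL,
                                 responses = NULL, merge_years = TRUE,
                                 on_incompatible = "error",
                                 ambiguous = "half") {
  loci <- locus_names(genotypes)
  is_mother <- is.na(genotypes$mother_id) | genotypes$mother_id == ""
  mothers <- genotypes[is_mother, , drop = FALSE]
  seeds <- genotypes[!is_mother, , drop = FALSE]
  mother_rows <- stats::setNames(seq_len(nrow(mothers)),
                                 mothers$individual_id)
  group <- if (merge_years) seeds$site_id else
    paste(seeds$site_id, seeds$year, sep = ":")
  site_ids <- unique(seeds$site_id)
  h <- stats::setNames(rep(NA_real_, length(site_ids)), site_ids)
  for (sid in site_ids) {
    sel <- which(seeds$site_id == sid)
    haps <- lapply(sel, function(i) {
      mi <- mother_rows[[seeds$mother_id[i]]]
      if (is.null(mi))
        stop("seed ", seeds$individual_id[i], " references unknown mother ",
             seeds$mother_id[i], call. = FALSE)
      infer_pollen_haplotype(genotype_loci(mothers[mi, ], loci),
                             genotype_loci(seeds[i, ], loci),
                             on_incompatible = on_incompatible)
    })
    pool <- pool_pollen(haps, sid, ambiguous = ambiguous)
    h[sid] <- haplotype_diversity(pool)
  }
  out <- data.frame(site_id = site_ids, prop_high_mobility = NA_real_,
                    h = unname(h), tm_minus_ts = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(captures)) {
    for (sid in unique(captures$site_id)) {
      cc <- captures[captures$site_id == sid, ]
      p <- proportion_high_mobility(sum(cc$count[cc$mobility == "high"]),
                                    sum(cc$count[cc$mobility == "low"]))
      out$prop_high_mobility[out$site_id == sid] <- p
    }
  }
  if (!is.null(responses)) {
    m <- match(out$site_id, responses$site_id)
    out$tm_minus_ts <- responses$tm_minus_ts[m]
  }
  out
}
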