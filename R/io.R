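#' Write a landcover raster as an Esri ASCII grid
#'
#' Plain-text single-band raster with integer codes 1-5 and a NODATA
#' value; row 1 of the grid is the northernmost row, per the format.
#'
#' @param raster A [landcover_raster()].
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_landcover <- function(raster, path) {
  stopifnot(inherits(raster, "landcover_raster"))
  g <- raster$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(g)),
    paste("nrows", nrow(g)),
    paste("xllcorner", format(raster$origin[1], scientific = FALSE)),
    paste("yllcorner", format(raster$origin[2], scientific = FALSE)),
    paste("cellsize", format(raster$cell_size, scientific = FALSE)),
    "NODATA_value -9999"), con)
  g[is.na(g)] <- -9999L
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a landcover raster from an Esri ASCII grid
#'
#' @param path File written by [write_landcover()] or any integer-coded
#'   ASCII grid with codes 1-5.
#' @param crs CRS label to record (the format itself carries none).
#' @return A [landcover_raster()].
#' @export
read_landcover <- function(path, crs = "local-metric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("unsupported raster format: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (any(vals != floor(vals), na.rm = TRUE))
    stop("unsupported raster format: non-integer cell values", call. = FALSE)
  g <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols,
              byrow = TRUE)
  if (!is.null(hdr$nodata_value)) g[g == hdr$nodata_value] <- NA_integer_
  origin <- c(if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
              if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner)
  landcover_raster(g, cell_size = hdr$cellsize, origin = origin, crs = crs)
}

# fail fast with the table name when an input file is absent
check_exists <- function(path, what) {
  if (!file.exists(path))
    stop("cannot read ", what, " table: file not found: ", path,
         call. = FALSE)
  invisible(path)
}

# validate that a data frame has the named columns
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(what, " table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Read the typed CSV tables of the pipeline
#'
#' Schema-validated readers for the genotype, capture, response, site and
#' metric tables. Empty fields become `NA` (missing).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_genotypes <- function(path) {
  check_exists(path, "genotype")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  check_columns(df, c("individual_id", "mother_id", "site_id", "year"),
                "genotype")
  locus_names(df)  # errors if locus columns are not paired
  df
}

#' @rdname read_tables
#' @export
read_captures <- function(path) {
  check_exists(path, "captures")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "mobility", "count"), "captures")
  if (!all(df$mobility %in% c("high", "low")))
    stop("captures `mobility` must be 'high' or 'low'", call. = FALSE)
  df
}

#' @rdname read_tables
#' @export
read_responses <- function(path) {
  check_exists(path, "responses")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "tm_minus_ts"), "responses")
  df
}

#' @rdname read_tables
#' @export
read_sites <- function(path) {
  check_exists(path, "sites")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "x", "y"), "sites")
  df
}

#' Write a pipeline table to CSV
#'
#' Stable column order, floats at 6 significant digits, missing values as
#' empty fields.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the complete analysis pipeline
#'
#' classify -> clip -> label -> metrics -> responses -> model comparison.
#' Reads the landcover raster, site coordinates, genotypes, captures and
#' biparental inbreeding values; writes the metric table, response table,
#' model comparison table, summed factor weights (JSON) and a run
#' manifest into `out_dir`.
#'
#' @param landcover_path Esri ASCII grid of landcover codes.
#' @param sites_path Sites CSV (`site_id`, `x`, `y`).
#' @param genotypes_path Genotype CSV (see [read_genotypes()]).
#' @param captures_path,responses_path Optional capture and inbreeding
#'   CSVs; `NULL` drops the corresponding responses.
#' @param out_dir Output directory (created if needed).
#' @param alpha,lambda,gap_threshold,radius,neighbourhood Metric
#'   parameters; see [metric_spec()].
#' @param merge_years,on_incompatible,ambiguous Genetic options; see
#'   [build_response_table()].
#' @return Invisible list with `metrics`, `responses`, `comparison`,
#'   `factor_weights`.
#' @export
run_pipeline <- function(landcover_path, sites_path, genotypes_path,
                         captures_path = NULL, responses_path = NULL,
                         out_dir = ".", alpha = 1 / 282,
                         lambda = log(2) / 50, gap_threshold = 50,
                         radius = 1000, neighbourhood = 8,
                         merge_years = TRUE, on_incompatible = "error",
                         ambiguous = "half") {
  landcover <- read_landcover(landcover_path)
  sites <- read_sites(sites_path)
  genotypes <- read_genotypes(genotypes_path)
  captures <- if (!is.null(captures_path)) read_captures(captures_path)
  responses_in <- if (!is.null(responses_path)) read_responses(responses_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  metrics <- NULL
  for (i in seq_len(nrow(sites))) {
    s <- sampling_site(sites$site_id[i], sites$x[i], sites$y[i], landcover)
    metrics <- rbind(metrics, compute_metric_suite(
      landcover, s, alpha = alpha, lambda = lambda,
      gap_threshold = gap_threshold, radius = radius,
      neighbourhood = neighbourhood))
  }
  responses <- build_response_table(genotypes, captures, responses_in,
                                    merge_years = merge_years,
                                    on_incompatible = on_incompatible,
                                    ambiguous = ambiguous)
  comparison <- compare_all(responses, metrics)
  fw <- list()
  for (resp in unique(comparison$response[comparison$scale == "LOCAL"])) {
    rows <- comparison[comparison$response == resp &
                         comparison$scale == "LOCAL", ]
    fw[[resp]] <- lapply(
      stats::setNames(nm = c("habitat_def", "weighting", "gap_mode")),
      function(f) as.list(summed_factor_weights(rows, f)))
  }
  write_table(metrics, file.path(out_dir, "metrics.csv"))
  write_table(responses, file.path(out_dir, "responses.csv"))
  write_table(comparison, file.path(out_dir, "comparison.csv"))
  jsonlite::write_json(fw, file.path(out_dir, "factor_weights.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "pollenscape",
    version = as.character(utils::packageVersion("pollenscape")),
    parameters = list(alpha = alpha, lambda = lambda,
                      gap_threshold = gap_threshold, radius = radius,
                      neighbourhood = neighbourhood,
                      merge_years = merge_years,
                      on_incompatible = on_incompatible,
                      ambiguous = ambiguous),
    inputs = list(landcover = landcover_path, sites = sites_path,
                  genotypes = genotypes_path,
                  captures = captures_path, responses = responses_path),
    n_sites = nrow(sites), n_metric_rows = nrow(metrics),
    n_comparison_rows = nrow(comparison))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, responses = responses,
                 comparison = comparison, factor_weights = fw))
}
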