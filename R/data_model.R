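# Domain tables: detections, deployments, site covariates.
#
# All three tables are plain data frames with documented columns; readers
# validate invariants on the way in, writers emit the same CSV schema so a
# read-write round trip is lossless.

CAMERA_FEATURES <- c("waterhole", "riverbed", "track", "trail")
MANAGEMENT_TYPES <- c("conservancy", "concession")

# Declared ranges for bounded site covariates (inclusive).
COVARIATE_RANGES <- list(
  visibility      = c(1, 4),
  cover           = c(1, 3.5),
  water_proximity = c(0, 3),
  human_use       = c(0, 4),
  lion_longterm   = c(0, 2)
)

#' Species configuration
#'
#' Declares which species play which role in the analysis: focal herbivores
#' (the response species), apex predators (the exposure species), and any
#' additional species whose detection rates enter models as co-occurrence
#' covariates. Predator and herbivore lists must be disjoint.
#'
#' @param focal_herbivores Character vector of herbivore species codes.
#' @param predators Character vector of predator species codes.
#' @param co_detection_species Character vector of co-occurring species
#'   whose detection rates are used as covariates. Default none.
#' @return An object of class `species_config`.
#' @examples
#' species_config(c("gemsbok", "springbok"), c("lion", "spotted_hyena"))
#' @export
species_config <- function(focal_herbivores, predators,
                           co_detection_species = character()) {
  focal_herbivores <- as.character(focal_herbivores)
  predators <- as.character(predators)
  if (length(intersect(focal_herbivores, predators)) > 0)
    stop_fearscape("focal herbivore and predator lists must be disjoint: ",
                   paste(intersect(focal_herbivores, predators), collapse = ", "),
                   class = "fearscape_config_error")
  structure(list(focal_herbivores = focal_herbivores,
                 predators = predators,
                 co_detection_species = as.character(co_detection_species)),
            class = "species_config")
}

#' @export
print.species_config <- function(x, ...) {
  cat("Species configuration\n")
  cat("  focal herbivores:", paste(x$focal_herbivores, collapse = ", "), "\n")
  cat("  predators:       ", paste(x$predators, collapse = ", "), "\n")
  if (length(x$co_detection_species))
    cat("  co-detection:    ", paste(x$co_detection_species, collapse = ", "), "\n")
  invisible(x)
}

#' Read camera-trap detection records
#'
#' Reads a detections CSV (`camera_id,species,timestamp`, timestamps in ISO
#' 8601 `YYYY-MM-DDTHH:MM:SS` local clock time), drops exact duplicate rows,
#' optionally filters to a species set, and returns rows sorted by
#' (`camera_id`, `species`, `timestamp`).
#'
#' @param path Path to the CSV file.
#' @param species_filter Optional character vector; if given only these
#'   species are retained.
#' @return A data frame with columns `camera_id`, `species` (character) and
#'   `timestamp` (POSIXct, naive local time).
#' @seealso [write_detections()], [filter_independent()]
#' @export
read_detections <- function(path, species_filter = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("camera_id", "species", "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fearscape("detections file is missing column(s): ",
                   paste(miss, collapse = ", "),
                   class = "fearscape_schema_error")
  ts <- parse_timestamp(df$timestamp)
  if (anyNA(ts) && nrow(df) > 0) {
    bad <- which(is.na(ts))
    stop_fearscape("unparseable timestamp(s) at data line(s): ",
                   paste(head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) " ..." else "",
                   class = "fearscape_parse_error")
  }
  out <- data.frame(camera_id = df$camera_id, species = df$species,
                    timestamp = ts, stringsAsFactors = FALSE)
  out <- unique(out)
  if (!is.null(species_filter))
    out <- out[out$species %in% species_filter, , drop = FALSE]
  out <- out[order(out$camera_id, out$species, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write detection records
#'
#' @param detections Data frame as returned by [read_detections()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  df <- data.frame(camera_id = detections$camera_id,
                   species = detections$species,
                   timestamp = format_timestamp(detections$timestamp))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read camera deployments
#'
#' Reads a deployment CSV (`camera_id,x,y,feature,start,end`; one row per
#' active date range). Coordinates are planar metres (use
#' [latlon_to_planar()] for geographic input). Validates that features are
#' known, coordinates finite, `start <= end`, and that the active ranges of
#' each camera do not overlap.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `camera_id`, `x`, `y`, `feature`
#'   (character), `start`, `end` (Date).
#' @export
read_deployments <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera_id", "x", "y", "feature", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fearscape("deployments file is missing column(s): ",
                   paste(miss, collapse = ", "),
                   class = "fearscape_schema_error")
  out <- data.frame(camera_id = as.character(df$camera_id),
                    x = as.numeric(df$x), y = as.numeric(df$y),
                    feature = as.character(df$feature),
                    start = parse_date(df$start), end = parse_date(df$end),
                    stringsAsFactors = FALSE)
  validate_deployments(out)
  out <- out[order(out$camera_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_deployments <- function(dep) {
  if (!all(is.finite(dep$x)) || !all(is.finite(dep$y)))
    stop_fearscape("non-finite coordinates in deployments",
                   class = "fearscape_validation_error")
  bad_feat <- setdiff(unique(dep$feature), CAMERA_FEATURES)
  if (length(bad_feat))
    stop_fearscape("unknown feature type(s): ", paste(bad_feat, collapse = ", "),
                   class = "fearscape_validation_error")
  if (anyNA(dep$start) || anyNA(dep$end))
    stop_fearscape("unparseable deployment dates", class = "fearscape_parse_error")
  rev <- dep$end < dep$start
  if (any(rev))
    stop_fearscape("active range with end < start for camera(s): ",
                   paste(unique(dep$camera_id[rev]), collapse = ", "),
                   class = "fearscape_validation_error")
  for (cam in unique(dep$camera_id)) {
    d <- dep[dep$camera_id == cam, , drop = FALSE]
    if (nrow(d) < 2) next
    d <- d[order(d$start), ]
    if (any(d$start[-1] <= d$end[-nrow(d)]))
      stop_fearscape("overlapping active ranges for camera ", cam,
                     class = "fearscape_validation_error")
    # per-camera coordinates must be constant across ranges
    if (length(unique(d$x)) > 1 || length(unique(d$y)) > 1)
      stop_fearscape("inconsistent coordinates across ranges for camera ", cam,
                     class = "fearscape_validation_error")
  }
  invisible(dep)
}

#' Write camera deployments
#' @param deployments Data frame as returned by [read_deployments()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deployments <- function(deployments, path) {
  df <- data.frame(camera_id = deployments$camera_id,
                   x = deployments$x, y = deployments$y,
                   feature = deployments$feature,
                   start = format(deployments$start, "%Y-%m-%d"),
                   end = format(deployments$end, "%Y-%m-%d"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site covariates
#'
#' Reads the cluster-by-survey covariate table
#' (`cluster_id,survey_id,<covariates>`). Bounded covariates (visibility
#' 1-4, cover 1-3.5, water proximity 0-3, human use 0-4, long-term lion
#' activity 0-2) are range-checked; `management`, when present, must be
#' `conservancy` or `concession`. Missing values are rejected: covariate
#' preparation assumes a complete table.
#'
#' @param path Path to the CSV file.
#' @return Data frame with `cluster_id`, `survey_id` as character plus the
#'   covariate columns.
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "survey_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fearscape("covariates file is missing column(s): ",
                   paste(miss, collapse = ", "),
                   class = "fearscape_schema_error")
  df$cluster_id <- as.character(df$cluster_id)
  df$survey_id <- as.character(df$survey_id)
  validate_covariates(df)
  df <- df[order(df$cluster_id, df$survey_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_covariates <- function(df) {
  if (anyNA(df))
    stop_fearscape("missing values in covariate table",
                   class = "fearscape_validation_error")
  for (nm in intersect(names(COVARIATE_RANGES), names(df))) {
    r <- COVARIATE_RANGES[[nm]]
    v <- df[[nm]]
    if (any(v < r[1] | v > r[2]))
      stop_fearscape("covariate '", nm, "' outside declared range [",
                     r[1], ", ", r[2], "]",
                     class = "fearscape_validation_error")
  }
  if ("management" %in% names(df)) {
    bad <- setdiff(unique(df$management), MANAGEMENT_TYPES)
    if (length(bad))
      stop_fearscape("unknown management type(s): ", paste(bad, collapse = ", "),
                     class = "fearscape_validation_error")
  }
  invisible(df)
}

#' Write site covariates
#' @param covariates Data frame as returned by [read_covariates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project longitude/latitude to local planar metres
#'
#' Equirectangular approximation about an origin: adequate over the tens of
#' kilometres a camera survey spans, and keeps the clustering radius a plain
#' Euclidean distance.
#'
#' @param lon,lat Numeric vectors of degrees.
#' @param origin Optional `c(lon, lat)` of the projection origin; defaults
#'   to the centroid of the input.
#' @return Data frame with columns `x`, `y` in metres.
#' @export
latlon_to_planar <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  R <- 6371008.8
  x <- (lon - origin[1]) * pi / 180 * R * cos(origin[2] * pi / 180)
  y <- (lat - origin[2]) * pi / 180 * R
  data.frame(x = x, y = y)
}
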