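# Event preparation: camera clusters, effort accounting, the 30-min
# independence rule, detection rates, covariate transforms.

#' Group cameras into clusters
#'
#' Cameras sharing a landscape feature and lying within `radius` metres of a
#' common central point are treated as one sampling unit ("camera cluster")
#' to limit pseudo-replication. The partition is built by deterministic
#' greedy agglomeration within each feature class: cameras are visited in
#' `camera_id` order; each unassigned camera seeds a new cluster, which then
#' absorbs any unassigned same-feature camera within `radius` of the running
#' centroid, recomputing the centroid after every absorption.
#'
#' A user-supplied map (`camera_id`, `cluster_id`) overrides the algorithm,
#' mirroring field practice where clusters are drawn by the deployment team.
#'
#' @param deployments Deployment table ([read_deployments()]); multiple
#'   active ranges per camera are allowed.
#' @param radius Clustering radius in metres (default 150).
#' @param cluster_map Optional data frame with columns `camera_id`,
#'   `cluster_id` assigning cameras to clusters directly.
#' @return An object of class `camera_clusters`: a data frame with columns
#'   `camera_id`, `cluster_id`, `feature`, with a `centroids` attribute
#'   (data frame `cluster_id`, `x`, `y`, `feature`, `n_cameras`).
#'   Clusters with more than 9 members trigger a warning.
#' @export
cluster_cameras <- function(deployments, radius = 150, cluster_map = NULL) {
  cams <- unique(deployments[, c("camera_id", "x", "y", "feature")])
  cams <- cams[order(cams$camera_id), , drop = FALSE]
  if (nrow(cams) == 0)
    stop_fearscape("no cameras to cluster", class = "fearscape_config_error")

  if (!is.null(cluster_map)) {
    idx <- match(cams$camera_id, as.character(cluster_map$camera_id))
    if (anyNA(idx))
      stop_fearscape("cluster_map is missing camera(s): ",
                     paste(cams$camera_id[is.na(idx)], collapse = ", "),
                     class = "fearscape_config_error")
    cams$cluster_id <- as.character(cluster_map$cluster_id)[idx]
  } else {
    cams$cluster_id <- NA_character_
    k <- 0L
    for (feat in unique(cams$feature)) {
      sel <- which(cams$feature == feat)
      assigned <- rep(FALSE, length(sel))
      for (i in seq_along(sel)) {
        if (assigned[i]) next
        k <- k + 1L
        members <- sel[i]
        assigned[i] <- TRUE
        cx <- cams$x[sel[i]]; cy <- cams$y[sel[i]]
        repeat {
          grew <- FALSE
          for (j in seq_along(sel)) {
            if (assigned[j]) next
            d <- sqrt((cams$x[sel[j]] - cx)^2 + (cams$y[sel[j]] - cy)^2)
            if (d <= radius) {
              members <- c(members, sel[j])
              assigned[j] <- TRUE
              cx <- mean(cams$x[members]); cy <- mean(cams$y[members])
              grew <- TRUE
            }
          }
          if (!grew) break
        }
        cams$cluster_id[members] <- sprintf("C%03d", k)
      }
    }
  }

  cent <- do.call(rbind, lapply(split(cams, cams$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1], x = mean(d$x), y = mean(d$y),
               feature = d$feature[1], n_cameras = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(cent) <- NULL
  if (any(cent$n_cameras > 9))
    warning("cluster(s) with more than 9 cameras: ",
            paste(cent$cluster_id[cent$n_cameras > 9], collapse = ", "))
  out <- cams[, c("camera_id", "cluster_id", "feature")]
  rownames(out) <- NULL
  structure(out, centroids = cent, radius = radius,
            class = c("camera_clusters", "data.frame"))
}

#' @export
print.camera_clusters <- function(x, ...) {
  cent <- attr(x, "centroids")
  cat("Camera clusters:", nrow(cent), "clusters over", nrow(x), "cameras\n")
  cat("  members per cluster:", paste(range(cent$n_cameras), collapse = "-"), "\n")
  invisible(x)
}

cluster_of <- function(clusters, camera_id) {
  idx <- match(camera_id, clusters$camera_id)
  if (anyNA(idx))
    stop_fearscape("event(s) from camera(s) not in any cluster: ",
                   paste(unique(camera_id[is.na(idx)]), collapse = ", "),
                   class = "fearscape_config_error")
  clusters$cluster_id[idx]
}

#' Camera-night effort per cluster
#'
#' One camera-night is one operational calendar day for one camera; partial
#' first and last days count as whole days. Effort for a cluster is the sum
#' over member cameras of operational days intersected with `window`.
#'
#' @param clusters A `camera_clusters` object.
#' @param deployments Deployment table with active date ranges.
#' @param window Optional `c(start, end)` Date vector restricting the
#'   accounting window; default covers all deployments.
#' @return Data frame `cluster_id`, `camera_nights`.
#' @export
camera_nights <- function(clusters, deployments, window = NULL) {
  if (is.null(window)) {
    window <- c(min(deployments$start), max(deployments$end))
  } else {
    window <- as.Date(window)
    if (window[2] < window[1])
      stop_fearscape("empty effort window", class = "fearscape_config_error")
  }
  dep <- deployments
  dep$cluster_id <- cluster_of(clusters, dep$camera_id)
  lo <- pmax(dep$start, window[1])
  hi <- pmin(dep$end, window[2])
  nights <- pmax(as.numeric(hi - lo) + 1, 0)
  nights[hi < lo] <- 0
  agg <- aggregate(nights, by = list(cluster_id = dep$cluster_id), FUN = sum)
  names(agg)[2] <- "camera_nights"
  # clusters with no deployment rows in window keep zero effort
  all_cl <- attr(clusters, "centroids")$cluster_id
  missing <- setdiff(all_cl, agg$cluster_id)
  if (length(missing))
    agg <- rbind(agg, data.frame(cluster_id = missing, camera_nights = 0))
  agg <- agg[order(agg$cluster_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Independence-filter detections
#'
#' Within each (sampling unit, species) stream, a detection is retained only
#' if it falls at least `window_minutes` after the previously retained
#' detection of that species at that unit (the first detection is always
#' retained). This is the standard rule against pseudo-replicated bursts of
#' images of one animal. The filter is idempotent and its output shrinks
#' monotonically as the window grows.
#'
#' @param events Detection table ([read_detections()]).
#' @param clusters A `camera_clusters` object; every event's camera must be
#'   assigned (configuration error otherwise).
#' @param window_minutes Independence window in minutes (default 30).
#' @param by Grouping unit: `"cluster"` (default) or `"camera"` (the
#'   no-clustering sensitivity variant).
#' @return The retained events, with a `cluster_id` column added, sorted by
#'   (`cluster_id`, `species`, `timestamp`).
#' @export
filter_independent <- function(events, clusters, window_minutes = 30,
                               by = c("cluster", "camera")) {
  by <- match.arg(by)
  ev <- events
  ev$cluster_id <- cluster_of(clusters, ev$camera_id)
  unit <- if (by == "cluster") ev$cluster_id else ev$camera_id
  if (nrow(ev) == 0) {
    ev$cluster_id <- character(0)
    return(ev)
  }
  ord <- order(unit, ev$species, ev$timestamp)
  ev <- ev[ord, , drop = FALSE]
  unit <- unit[ord]
  key <- paste(unit, ev$species, sep = "\r")
  keep <- logical(nrow(ev))
  gap <- window_minutes * 60
  for (idx in split(seq_len(nrow(ev)), key)) {
    t <- as.numeric(ev$timestamp[idx])
    last <- -Inf
    for (i in seq_along(idx)) {
      if (t[i] - last >= gap) {
        keep[idx[i]] <- TRUE
        last <- t[i]
      }
    }
  }
  out <- ev[keep, , drop = FALSE]
  out <- out[order(out$cluster_id, out$species, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detection rate per 100 camera-nights
#'
#' @param events Independence-filtered detections (with `cluster_id`).
#' @param effort Effort table from [camera_nights()].
#' @param species Optional species subset; default every species present.
#' @return Data frame `cluster_id`, `species`, `n`, `camera_nights`, `rate`
#'   where `rate = 100 * n / camera_nights`. A cluster with zero effort and
#'   a nonzero count is an error; zero count with zero effort reports 0.
#' @export
detection_rate <- function(events, effort, species = NULL) {
  if (is.null(species)) species <- sort(unique(events$species))
  grid <- expand.grid(cluster_id = effort$cluster_id, species = species,
                      stringsAsFactors = FALSE)
  ev <- events[events$species %in% species, , drop = FALSE]
  if (nrow(ev)) {
    cnt <- aggregate(list(n = rep(1, nrow(ev))),
                     by = list(cluster_id = ev$cluster_id,
                               species = ev$species),
                     FUN = sum)
    out <- merge(grid, cnt, all.x = TRUE)
    out$n[is.na(out$n)] <- 0
  } else {
    out <- grid
    out$n <- if (nrow(grid)) 0 else numeric(0)
  }
  out <- merge(out, effort, by = "cluster_id")
  bad <- out$camera_nights <= 0 & out$n > 0
  if (any(bad))
    stop_fearscape("nonzero detections with zero effort in cluster(s): ",
                   paste(unique(out$cluster_id[bad]), collapse = ", "),
                   class = "fearscape_validation_error")
  out$rate <- as.numeric(
    ifelse(out$camera_nights > 0, 100 * out$n / out$camera_nights, 0))
  out <- out[order(out$cluster_id, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transform covariates for modelling
#'
#' Applies `log(1 + x)` to skewed columns and z-scores (centre/scale)
#' standardising columns, log-transforming before scaling when a column is
#' named in both. Transform metadata (which columns, centres, scales) is
#' attached so the mapping is invertible.
#'
#' @param rows Covariate table ([read_covariates()]).
#' @param log1p_columns Character vector of columns to `log1p`-transform.
#' @param zscore_columns Character vector of columns to standardise.
#' @return The transformed data frame with attribute `transforms`
#'   (list: `log1p`, `center`, `scale`).
#' @export
prepare_covariates <- function(rows, log1p_columns = character(),
                               zscore_columns = character()) {
  for (nm in unique(c(log1p_columns, zscore_columns))) {
    if (!nm %in% names(rows))
      stop_fearscape("column not found: ", nm, class = "fearscape_config_error")
    if (!is.numeric(rows[[nm]]))
      stop_fearscape("column not numeric: ", nm, class = "fearscape_config_error")
  }
  out <- rows
  for (nm in log1p_columns) {
    if (any(out[[nm]] < -1 + 1e-12))
      stop_fearscape("log1p undefined for column ", nm, " (values <= -1)",
                     class = "fearscape_validation_error")
    out[[nm]] <- log1p(out[[nm]])
  }
  centers <- scales <- setNames(numeric(0), character(0))
  for (nm in zscore_columns) {
    v <- out[[nm]]
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop_fearscape("cannot z-score constant column: ", nm,
                     class = "fearscape_validation_error")
    centers[nm] <- mean(v)
    scales[nm] <- s
    out[[nm]] <- (v - centers[nm]) / scales[nm]
  }
  attr(out, "transforms") <- list(log1p = log1p_columns,
                                  center = centers, scale = scales)
  out
}
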