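# Synthetic camera-trap detection streams with known ground truth. The
# generator reproduces the statistical structure the downstream stages
# assume: hourly Bernoulli detections with diel (von Mises mixture)
# activity, cluster- and survey-level random intercepts, covariate effects
# on the standardized scale, and short-term post-predator suppression with
# a configured odds ratio.

#' Diel activity profile
#'
#' A von Mises mixture on the 24-h circle, parameterised in hours.
#'
#' @param means_h Component mean activity times in hours.
#' @param kappas Component concentrations (> 0).
#' @param weights Component weights (summing to 1).
#' @return A `diel_profile` list.
#' @export
diel_profile <- function(means_h, kappas, weights = NULL) {
  weights <- weights %||% rep(1 / length(means_h), length(means_h))
  if (any(kappas <= 0))
    stop_fearscape("concentrations must be > 0", class = "fearscape_config_error")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_fearscape("weights must sum to 1", class = "fearscape_config_error")
  structure(list(means_h = means_h, kappas = kappas, weights = weights),
            class = "diel_profile")
}

#' True diel density of a profile
#' @param theta Angles in radians.
#' @param profile A `diel_profile`.
#' @return Density values (integrating to 1 over the circle).
#' @export
diel_density <- function(theta, profile) {
  mu <- profile$means_h * 2 * pi / 24
  out <- 0
  for (i in seq_along(mu))
    out <- out + profile$weights[i] * dvonmises(theta, mu[i], profile$kappas[i])
  out
}

#' Simulation configuration
#'
#' Defaults emulate a dry-season survey: strongly diurnal herbivores
#' (midday activity, concentration 3), nocturnal predators (early-morning
#' activity, concentration 2), moderate spatial heterogeneity, and
#' short-term herbivore suppression after predator passage at odds ratio
#' 0.33 with no delayed effect.
#'
#' @param n_clusters Number of camera clusters (default 20).
#' @param cameras_per_cluster Cameras per cluster, 1-9 (default 2).
#' @param n_surveys Number of survey periods (default 2).
#' @param days_per_survey Operational days per survey (default 120).
#' @param species Named list of species definitions; each a list with
#'   `role` (`"herbivore"`/`"predator"`), `diel` (a [diel_profile()]), and
#'   `base_logodds` (baseline hourly detection log-odds).
#' @param beta Named vector of covariate effects (applied to the z-scored
#'   covariate, herbivores only).
#' @param sigma_cluster,sigma_survey Random-intercept standard deviations.
#' @param or_short,or_delayed Avoidance odds ratios applied to herbivore
#'   detection in the hours after a predator detection at the cluster
#'   (lags 1-5 h and 6-23 h respectively; both > 0).
#' @param seed Integer seed.
#' @param start_date First deployment date.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clusters = 20, cameras_per_cluster = 2,
                       n_surveys = 2, days_per_survey = 120,
                       species = NULL,
                       beta = c(visibility = 0.5, temperature = -0.3),
                       sigma_cluster = 0.5, sigma_survey = 0.5,
                       or_short = 0.33, or_delayed = 1.0,
                       seed = 1L, start_date = "2022-06-01") {
  if (cameras_per_cluster < 1 || cameras_per_cluster > 9)
    stop_fearscape("cameras_per_cluster must be 1-9",
                   class = "fearscape_config_error")
  if (or_short <= 0 || or_delayed <= 0)
    stop_fearscape("odds ratios must be > 0", class = "fearscape_config_error")
  species <- species %||% list(
    gemsbok = list(role = "herbivore", base_logodds = -3.8,
                   diel = diel_profile(12.5, 3)),
    lion = list(role = "predator", base_logodds = -4.5,
                diel = diel_profile(2.2, 2)),
    spotted_hyena = list(role = "predator", base_logodds = -4.5,
                         diel = diel_profile(2.9, 2)))
  structure(list(n_clusters = n_clusters,
                 cameras_per_cluster = cameras_per_cluster,
                 n_surveys = n_surveys, days_per_survey = days_per_survey,
                 species = species, beta = beta,
                 sigma_cluster = sigma_cluster, sigma_survey = sigma_survey,
                 or_short = or_short, or_delayed = or_delayed,
                 seed = as.integer(seed), start_date = as.Date(start_date)),
            class = "sim_config")
}

#' Simulate a camera-trap survey
#'
#' For every operational cluster-hour and species, a detection is drawn as
#' `Bernoulli(plogis(alpha_s + x.beta + u_cluster + v_survey + diel + a))`
#' where `diel = log(2*pi*d_s(hour))` is the species' log diel density
#' offset (zero for uniform activity), and `a` adds `log(or_short)` /
#' `log(or_delayed)` to herbivores when any predator was detected at the
#' cluster 1-5 / 6-23 hours earlier. Covariate effects apply to the
#' z-scored covariate columns. Detection timestamps are jittered uniformly
#' within the hour and assigned to a random member camera. Fully
#' reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: writes `detections.csv`,
#'   `deployments.csv`, `covariates.csv` and `ground_truth.json` there.
#' @return List with `detections`, `deployments`, `covariates` data frames
#'   and `ground_truth` (all realized parameters).
#' @export
simulate_cameratrap <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  out <- with_seed(cfg$seed, simulate_cameratrap_impl(cfg))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_detections(out$detections, file.path(dir, "detections.csv"))
    write_deployments(out$deployments, file.path(dir, "deployments.csv"))
    write_covariates(out$covariates, file.path(dir, "covariates.csv"))
    jsonlite::write_json(out$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

simulate_cameratrap_impl <- function(cfg) {
  ncl <- cfg$n_clusters
  cluster_ids <- sprintf("C%03d", seq_len(ncl))
  survey_ids <- sprintf("S%d", seq_len(cfg$n_surveys))
  features <- sample(CAMERA_FEATURES, ncl, replace = TRUE,
                     prob = c(0.1, 0.2, 0.1, 0.6))
  # clusters on a widely spaced grid; member cameras jittered within 60 m
  gx <- ((seq_len(ncl) - 1) %% 5) * 2000
  gy <- ((seq_len(ncl) - 1) %/% 5) * 2000
  dep <- list(); k <- 0
  for (i in seq_len(ncl)) {
    for (j in seq_len(cfg$cameras_per_cluster)) {
      k <- k + 1
      cam <- sprintf("%s-cam%d", cluster_ids[i], j)
      for (s in seq_len(cfg$n_surveys)) {
        st <- cfg$start_date + (s - 1) * (cfg$days_per_survey + 30)
        dep[[length(dep) + 1]] <- data.frame(
          camera_id = cam, x = gx[i] + runif(1, -60, 60),
          y = gy[i] + runif(1, -60, 60), feature = features[i],
          start = st, end = st + cfg$days_per_survey - 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  deployments <- do.call(rbind, dep)
  # constant camera coordinates across survey ranges
  first <- !duplicated(deployments$camera_id)
  xy <- deployments[first, c("camera_id", "x", "y")]
  idx <- match(deployments$camera_id, xy$camera_id)
  deployments$x <- xy$x[idx]; deployments$y <- xy$y[idx]

  # covariates once per (cluster, survey)
  cov <- expand.grid(cluster_id = cluster_ids, survey_id = survey_ids,
                     stringsAsFactors = FALSE)
  cov <- cov[order(cov$cluster_id, cov$survey_id), , drop = FALSE]
  cov$visibility <- sample(1:4, nrow(cov), replace = TRUE)
  cov$temperature <- round(rnorm(nrow(cov), 28, 4), 2)
  rownames(cov) <- NULL

  u <- rnorm(ncl, 0, cfg$sigma_cluster)
  v <- rnorm(cfg$n_surveys, 0, cfg$sigma_survey)

  # covariate offset per (cluster, survey) row, on the z-scored scale
  covx <- rep(0, nrow(cov))
  for (nm in names(cfg$beta)) {
    z <- cov[[nm]]
    z <- (z - mean(z)) / (if (sd(z) > 0) sd(z) else 1)
    covx <- covx + cfg$beta[[nm]] * z
  }

  hours_per_survey <- cfg$days_per_survey * 24
  theta_hour <- (2 * pi * ((0:23) + 0.5)) / 24
  sp_names <- names(cfg$species)
  roles <- vapply(cfg$species, function(s) s$role, character(1))
  diel_off <- lapply(cfg$species, function(s)
    log(pmax(2 * pi * diel_density(theta_hour, s$diel), 1e-12)))

  det <- list()
  for (s in seq_len(cfg$n_surveys)) {
    st <- cfg$start_date + (s - 1) * (cfg$days_per_survey + 30)
    t0 <- as.POSIXct(paste0(format(st), "T00:00:00"), format = TIME_FMT,
                     tz = "UTC")
    hod <- rep(0:23, cfg$days_per_survey)           # hour of day sequence
    for (i in seq_len(ncl)) {
      ci_row <- which(cov$cluster_id == cluster_ids[i] &
                        cov$survey_id == survey_ids[s])
      base <- u[i] + v[s]
      # predators first: independent of herbivores
      pred_ind <- matrix(0L, hours_per_survey, sum(roles == "predator"),
                         dimnames = list(NULL, sp_names[roles == "predator"]))
      for (sp in sp_names[roles == "predator"]) {
        eta <- cfg$species[[sp]]$base_logodds + base + diel_off[[sp]][hod + 1]
        pred_ind[, sp] <- rbinom(hours_per_survey, 1, plogis(eta))
      }
      # per-predator lag since the most recent detection (strictly prior
      # hours); avoidance terms are additive across predators so the
      # case-crossover indicators identify each odds ratio exactly
      pos <- seq_len(hours_per_survey)
      avoid <- rep(0, hours_per_survey)
      for (sp in colnames(pred_ind)) {
        lastpos <- cummax(ifelse(pred_ind[, sp] == 1L, pos, 0L))
        prev <- c(0L, lastpos[-hours_per_survey])
        lag <- ifelse(prev > 0L, pos - prev, Inf)
        avoid <- avoid +
          ifelse(is.finite(lag) & lag < 6, log(cfg$or_short),
                 ifelse(is.finite(lag) & lag < 24, log(cfg$or_delayed), 0))
      }
      herb_ind <- matrix(0L, hours_per_survey, sum(roles == "herbivore"),
                         dimnames = list(NULL, sp_names[roles == "herbivore"]))
      for (sp in sp_names[roles == "herbivore"]) {
        eta <- cfg$species[[sp]]$base_logodds + base + covx[ci_row] +
          diel_off[[sp]][hod + 1] + avoid
        herb_ind[, sp] <- rbinom(hours_per_survey, 1, plogis(eta))
      }
      ind <- cbind(pred_ind, herb_ind)
      for (sp in colnames(ind)) {
        hit <- which(ind[, sp] == 1L)
        if (!length(hit)) next
        cam <- sprintf("%s-cam%d", cluster_ids[i],
                       sample.int(cfg$cameras_per_cluster, length(hit),
                                  replace = TRUE))
        ts <- t0 + (hit - 1) * 3600 + floor(runif(length(hit), 0, 3600))
        det[[length(det) + 1]] <- data.frame(
          camera_id = cam, species = sp, timestamp = ts,
          stringsAsFactors = FALSE)
      }
    }
  }
  detections <- if (length(det)) do.call(rbind, det) else
    data.frame(camera_id = character(0), species = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"))
  detections <- unique(detections)
  detections <- detections[order(detections$camera_id, detections$species,
                                 detections$timestamp), , drop = FALSE]
  rownames(detections) <- NULL

  ground_truth <- list(
    beta = as.list(cfg$beta),
    base_logodds = lapply(cfg$species, function(s) s$base_logodds),
    roles = as.list(roles),
    diel = lapply(cfg$species, function(s)
      list(means_h = s$diel$means_h, kappas = s$diel$kappas,
           weights = s$diel$weights)),
    sigma_cluster = cfg$sigma_cluster, sigma_survey = cfg$sigma_survey,
    or_short = cfg$or_short, or_delayed = cfg$or_delayed,
    u_cluster = setNames(as.list(u), cluster_ids),
    v_survey = setNames(as.list(v), survey_ids),
    seed = cfg$seed)

  surveys <- data.frame(
    survey_id = survey_ids,
    start = cfg$start_date + (seq_len(cfg$n_surveys) - 1) *
      (cfg$days_per_survey + 30),
    end = cfg$start_date + (seq_len(cfg$n_surveys) - 1) *
      (cfg$days_per_survey + 30) + cfg$days_per_survey - 1)

  list(detections = detections, deployments = deployments,
       covariates = cov, surveys = surveys, ground_truth = ground_truth)
}

#' True overlap between two configured species
#'
#' High-resolution quadrature of the pointwise minimum of the two true diel
#' densities; serves as the oracle for the overlap estimators.
#'
#' @param config A `sim_config` (or `NULL` when profiles are given).
#' @param species_a,species_b Species names in `config`, or
#'   [diel_profile()] objects.
#' @param grid_size Quadrature grid size (default 10000).
#' @return True overlap in `[0, 1]`.
#' @export
expected_overlap <- function(config, species_a, species_b,
                             grid_size = 10000) {
  prof <- function(s) {
    if (inherits(s, "diel_profile")) return(s)
    config$species[[s]]$diel
  }
  pa <- prof(species_a); pb <- prof(species_b)
  grid <- seq(0, 2 * pi, length.out = grid_size + 1)[seq_len(grid_size)]
  min(circ_integral(pmin(diel_density(grid, pa), diel_density(grid, pb))), 1)
}

#' Simulate a daily Bernoulli response panel
#'
#' Daily-scale companion generator for validating the hierarchical model
#' directly: `logit P(y=1) = intercept + x.beta + u[cluster] + v[survey]`
#' with covariates drawn standard normal per row (cluster-day).
#'
#' @param n_clusters,n_surveys,days Panel dimensions.
#' @param beta Named vector of covariate effects.
#' @param intercept Baseline log-odds.
#' @param sigma_cluster,sigma_survey Random-intercept standard deviations.
#' @param seed Integer seed.
#' @return Data frame with `cluster_id`, `survey_id`, `presence`, one
#'   column per covariate, and attribute `truth`.
#' @export
simulate_response_panel <- function(n_clusters = 25, n_surveys = 2,
                                    days = 60, beta = c(x1 = 1),
                                    intercept = -1, sigma_cluster = 1,
                                    sigma_survey = 0.5, seed = 1L) {
  with_seed(seed, {
    g <- expand.grid(cluster_id = sprintf("C%03d", seq_len(n_clusters)),
                     survey_id = sprintf("S%d", seq_len(n_surveys)),
                     day = seq_len(days), stringsAsFactors = FALSE)
    u <- rnorm(n_clusters, 0, sigma_cluster)
    v <- rnorm(n_surveys, 0, sigma_survey)
    eta <- intercept + u[as.integer(factor(g$cluster_id))] +
      v[as.integer(factor(g$survey_id))]
    for (nm in names(beta)) {
      g[[nm]] <- rnorm(nrow(g))
      eta <- eta + beta[[nm]] * g[[nm]]
    }
    g$presence <- rbinom(nrow(g), 1, plogis(eta))
    attr(g, "truth") <- list(beta = beta, intercept = intercept,
                             sigma_cluster = sigma_cluster,
                             sigma_survey = sigma_survey, u = u, v = v)
    g
  })
}
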