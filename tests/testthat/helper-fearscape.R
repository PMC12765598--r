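# Shared fixtures and independent oracles used across test files.

# von Mises sampler (Best & Fisher rejection algorithm), parameterised in
# hours on the 24-h clock; independent of the package's density code.
rvm_hours <- function(n, mean_h, kappa) {
  mu <- mean_h * 2 * pi / 24
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# Closed-form von Mises density (independent of package internals).
dvm_ref <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
}

# True overlap of two von Mises densities by fine Riemann sum.
true_overlap_vm <- function(mu1_h, k1, mu2_h, k2, m = 200000) {
  g <- seq(0, 2 * pi, length.out = m + 1)[seq_len(m)]
  f <- dvm_ref(g, mu1_h * 2 * pi / 24, k1)
  h <- dvm_ref(g, mu2_h * 2 * pi / 24, k2)
  mean(pmin(f, h)) * 2 * pi
}

# Brute-force re-statement of the greedy clustering rule with explicit
# loops and from-scratch distance computations.
greedy_cluster_oracle <- function(cams, radius) {
  cams <- cams[order(cams$camera_id), ]
  assign <- setNames(rep(NA_character_, nrow(cams)), cams$camera_id)
  k <- 0
  for (feat in unique(cams$feature)) {
    ids <- cams$camera_id[cams$feature == feat]
    for (id in ids) {
      if (!is.na(assign[id])) next
      k <- k + 1
      members <- id
      repeat {
        grew <- FALSE
        cx <- mean(cams$x[cams$camera_id %in% members])
        cy <- mean(cams$y[cams$camera_id %in% members])
        for (id2 in ids) {
          if (!is.na(assign[id2]) || id2 %in% members) next
          d <- sqrt((cams$x[cams$camera_id == id2] - cx)^2 +
                      (cams$y[cams$camera_id == id2] - cy)^2)
          if (d <= radius) {
            members <- c(members, id2)
            cx <- mean(cams$x[cams$camera_id %in% members])
            cy <- mean(cams$y[cams$camera_id %in% members])
            grew <- TRUE
          }
        }
        if (!grew) break
      }
      assign[members] <- paste0("O", k)
    }
  }
  assign
}

# Direct conditional log-likelihood evaluation, written independently of
# fit_clogit's internals: explicit loop over strata.
clogit_ll_ref <- function(strata, indicators, beta) {
  ll <- 0
  for (sid in unique(strata$stratum_id)) {
    d <- strata[strata$stratum_id == sid, , drop = FALSE]
    eta <- as.matrix(d[, indicators, drop = FALSE]) %*% beta
    ll <- ll + eta[d$role == "case"][1] - log(sum(exp(eta)))
  }
  ll
}

# Matched 1:1 strata with a single exposure indicator: n_ce strata where
# only the case is exposed and n_cc where only the control is.
discordant_pairs <- function(n_ce, n_cc) {
  rows <- list()
  for (i in seq_len(n_ce))
    rows[[length(rows) + 1]] <- data.frame(
      stratum_id = paste0("ce", i), role = c("case", "control"),
      x_short = c(1, 0), stringsAsFactors = FALSE)
  for (i in seq_len(n_cc))
    rows[[length(rows) + 1]] <- data.frame(
      stratum_id = paste0("cc", i), role = c("case", "control"),
      x_short = c(0, 1), stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# Minimal deployment table: one camera per row, one active range.
make_deployments <- function(x, y, feature = "trail",
                             start = as.Date("2022-06-01"),
                             end = as.Date("2022-08-31"),
                             ids = sprintf("cam%02d", seq_along(x))) {
  data.frame(camera_id = ids, x = x, y = y, feature = feature,
             start = start, end = end, stringsAsFactors = FALSE)
}

# Detection table from timestamp strings.
make_events <- function(camera_id, species, times) {
  data.frame(camera_id = camera_id, species = species,
             timestamp = as.POSIXct(times, format = "%Y-%m-%dT%H:%M:%S",
                                    tz = "UTC"),
             stringsAsFactors = FALSE)
}

# Small simulated survey shared by several test files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cameratrap(sim_config(
        n_clusters = 8, cameras_per_cluster = 2, n_surveys = 1,
        days_per_survey = 60, seed = 314))
    cache
  }
})
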