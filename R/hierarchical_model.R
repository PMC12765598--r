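# Hierarchical Bernoulli detection model: logit link, random intercepts for
# camera cluster and survey, weakly informative priors, fit by adaptive
# Metropolis-within-Gibbs. Posterior summaries feed the effect-strength
# tiers and the post hoc pruning rule.

#' Build the daily Bernoulli response table
#'
#' One row per operational (cluster, day): focal presence 0/1 that calendar
#' day, plus a daily presence indicator per predator — 1 when the predator
#' was detected at the cluster within the 24 h before the day starts (i.e.,
#' on the preceding calendar day; day boundary is midnight). Non-operational
#' days are excluded.
#'
#' @param events Independence-filtered detections (with `cluster_id`).
#' @param clusters A `camera_clusters` object.
#' @param deployments Deployment table (operational calendar).
#' @param focal Focal species.
#' @param predators Character vector of predator species.
#' @param surveys Optional data frame `survey_id`, `start`, `end` assigning
#'   days to surveys; default a single survey `"S1"`.
#' @return Data frame with `cluster_id`, `survey_id`, `day`, `presence` and
#'   one `<predator>_daily` column per predator.
#' @export
build_response <- function(events, clusters, deployments, focal, predators,
                           surveys = NULL) {
  dep <- deployments
  dep$cluster_id <- cluster_of(clusters, dep$camera_id)
  tabs <- lapply(split(dep, dep$cluster_id), function(d) {
    days <- seq(min(d$start), max(d$end), by = "day")
    op <- vapply(days, function(dd) any(dd >= d$start & dd <= d$end), logical(1))
    data.frame(cluster_id = d$cluster_id[1], day = days[op],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  if (is.null(surveys)) {
    tab$survey_id <- "S1"
  } else {
    tab$survey_id <- NA_character_
    for (i in seq_len(nrow(surveys)))
      tab$survey_id[tab$day >= surveys$start[i] & tab$day <= surveys$end[i]] <-
        as.character(surveys$survey_id[i])
    tab <- tab[!is.na(tab$survey_id), , drop = FALSE]
  }
  ev_day <- function(sp) {
    e <- events[events$species == sp, , drop = FALSE]
    paste(e$cluster_id, as.Date(e$timestamp, tz = "UTC"))
  }
  key <- paste(tab$cluster_id, tab$day)
  tab$presence <- as.integer(key %in% ev_day(focal))
  for (p in predators) {
    prev_key <- paste(tab$cluster_id, tab$day - 1)
    tab[[paste0(p, "_daily")]] <- as.integer(prev_key %in% ev_day(p))
  }
  tab <- tab[order(tab$cluster_id, tab$day), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Fit the hierarchical Bernoulli detection model
#'
#' Logistic regression of a 0/1 response on fixed effects with crossed
#' random intercepts for camera cluster and survey:
#' `logit P(y=1) = X b + u[cluster] + v[survey]`,
#' `u ~ N(0, sigma_cluster)`, `v ~ N(0, sigma_survey)`, with priors
#' `Normal(0, 2)` on fixed effects, `Normal(0, 5)` on the intercept, and
#' `Exponential(1)` on both group standard deviations.
#'
#' Sampling is adaptive Metropolis-within-Gibbs over blocks (each fixed
#' effect; all cluster intercepts jointly, accepted per cluster; all survey
#' intercepts; each log group-sd), with step sizes tuned during warmup to
#' ~44% acceptance. Interaction terms (`"a:b"`) require both parents in
#' `fixed`. A rank-deficient design is an error naming the collinear
#' columns. Convergence is assessed by split R-hat and bulk effective
#' sample size on the reported parameters.
#'
#' @param data Data frame with the response, covariates and grouping
#'   columns.
#' @param response Name of the 0/1 response column.
#' @param fixed Character vector of fixed-effect terms (column names and
#'   optional `"a:b"` interactions). May be empty for a null model.
#' @param cluster,survey Names of the grouping columns.
#' @param chains,iter,warmup MCMC configuration (total iterations per chain
#'   includes warmup; defaults 4 chains x 2000, 1000 warmup).
#' @param seed Integer seed; each chain derives its own substream.
#' @param priors List overriding `beta_sd` (2), `intercept_sd` (5),
#'   `sigma_rate` (1).
#' @return Object of class `hbm_fit`: post-warmup draws (one matrix per
#'   chain; columns: fixed effects, `sigma_cluster`, `sigma_survey`, group
#'   intercepts), the model frame pieces, and diagnostics.
#' @seealso [posterior_summary()], [bayes_r2()], [classify_effect()]
#' @export
fit_hier_bernoulli <- function(data, response, fixed = character(),
                               cluster = "cluster_id", survey = "survey_id",
                               chains = 4, iter = 2000, warmup = 1000,
                               seed = 1L, priors = list()) {
  if (iter <= warmup || warmup < 1)
    stop_fearscape("need iter > warmup >= 1", class = "fearscape_config_error")
  pr <- list(beta_sd = 2, intercept_sd = 5, sigma_rate = 1)
  pr[names(priors)] <- priors

  for (f in fixed[grepl(":", fixed, fixed = TRUE)]) {
    parents <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (!all(parents %in% fixed))
      stop_fearscape("interaction ", f, " without both main effects",
                     class = "fearscape_config_error")
  }
  n <- nrow(data)
  if (n > 0) {
    form <- if (length(fixed)) reformulate(fixed) else ~1
    X <- model.matrix(form, data)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
      stop_fearscape("rank-deficient design; collinear column(s): ",
                     paste(bad, collapse = ", "),
                     class = "fearscape_rank_error")
    }
    y <- as.numeric(data[[response]])
    cl <- factor(data[[cluster]])
    sv <- factor(data[[survey]])
  } else {
    X <- matrix(numeric(0), 0, length(fixed) + 1,
                dimnames = list(NULL, c("(Intercept)", fixed)))
    y <- numeric(0)
    cl <- factor(character(0))
    sv <- factor(character(0))
  }
  p <- ncol(X); K <- nlevels(cl); S <- nlevels(sv)
  cli <- as.integer(cl); svi <- as.integer(sv)
  prior_sd <- ifelse(colnames(X) == "(Intercept)", pr$intercept_sd, pr$beta_sd)

  par_names <- c(colnames(X), "sigma_cluster", "sigma_survey",
                 if (K) paste0("u.", levels(cl)),
                 if (S) paste0("v.", levels(sv)))
  n_keep <- iter - warmup

  run_chain <- function(chain_id) {
    with_seed(seed_from_key(seed, paste0("chain", chain_id)), {
      b <- rnorm(p, 0, 0.1)
      u <- rnorm(K, 0, 0.1); v <- rnorm(S, 0, 0.1)
      ls_u <- 0; ls_v <- 0                       # log sigmas
      step_u <- rep(0.5, max(K, 1)); step_v <- rep(0.5, max(S, 1))
      acc_u <- rep(0, max(K, 1)); acc_v <- rep(0, max(S, 1))
      eta <- if (n) drop(X %*% b) + (if (K) u[cli] else 0) +
        (if (S) v[svi] else 0) else numeric(0)
      ll_obs <- function(e) y * e - log1pexp(e)
      ll_cur <- ll_obs(eta)
      draws <- matrix(NA_real_, n_keep, length(par_names),
                      dimnames = list(NULL, par_names))
      batch <- 0L
      for (it in seq_len(iter)) {
        # fixed effects: univariate slice sampling (stepping-out), one
        # coordinate at a time
        for (j in seq_len(p)) {
          logf <- function(bj) {
            sum(ll_obs(eta + X[, j] * (bj - b[j]))) +
              dnorm(bj, 0, prior_sd[j], log = TRUE)
          }
          bj_new <- slice_1d(b[j], logf, w = 0.5)
          if (bj_new != b[j]) {
            eta <- eta + X[, j] * (bj_new - b[j])
            b[j] <- bj_new
            ll_cur <- ll_obs(eta)
          }
        }
        # cluster intercepts: joint proposal, per-cluster accept
        if (K) {
          su <- exp(ls_u)
          du <- step_u * rnorm(K)
          eta_new <- eta + du[cli]
          ll_new <- ll_obs(eta_new)
          dll <- drop(rowsum(ll_new - ll_cur, cli, reorder = TRUE))
          dpr <- dnorm(u + du, 0, su, log = TRUE) - dnorm(u, 0, su, log = TRUE)
          acc <- log(runif(K)) < dll + dpr
          if (any(acc)) {
            u[acc] <- u[acc] + du[acc]
            keepmask <- acc[cli]
            eta[keepmask] <- eta_new[keepmask]
            ll_cur[keepmask] <- ll_new[keepmask]
            acc_u[acc] <- acc_u[acc] + 1
          }
        }
        # survey intercepts
        if (S) {
          ss <- exp(ls_v)
          dv <- step_v * rnorm(S)
          eta_new <- eta + dv[svi]
          ll_new <- ll_obs(eta_new)
          dll <- drop(rowsum(ll_new - ll_cur, svi, reorder = TRUE))
          dpr <- dnorm(v + dv, 0, ss, log = TRUE) - dnorm(v, 0, ss, log = TRUE)
          acc <- log(runif(S)) < dll + dpr
          if (any(acc)) {
            v[acc] <- v[acc] + dv[acc]
            keepmask <- acc[svi]
            eta[keepmask] <- eta_new[keepmask]
            ll_cur[keepmask] <- ll_new[keepmask]
            acc_v[acc] <- acc_v[acc] + 1
          }
        }
        # translation moves: shift the intercept against a random-effect
        # vector (likelihood-invariant; accepted on the priors alone).
        # Breaks the intercept/group-mean confounding that otherwise stalls
        # mixing when a factor has few levels.
        has_int <- p > 0 && colnames(X)[1] == "(Intercept)"
        if (has_int && n > 0) {
          for (block in c("u", "v")) {
            re <- if (block == "u") u else v
            ns <- if (block == "u") exp(ls_u) else exp(ls_v)
            if (!length(re)) next
            dlt <- 0.3 * rnorm(1)
            lr <- dnorm(b[1] + dlt, 0, prior_sd[1], log = TRUE) -
              dnorm(b[1], 0, prior_sd[1], log = TRUE) +
              sum(dnorm(re - dlt, 0, ns, log = TRUE)) -
              sum(dnorm(re, 0, ns, log = TRUE))
            if (is.finite(lr) && log(runif(1)) < lr) {
              b[1] <- b[1] + dlt
              if (block == "u") u <- u - dlt else v <- v - dlt
            }
          }
        }
        # hypers on the log scale by slice sampling (the conditional
        # depends on the random effects only; Jacobian term for log scale)
        lp_sigma <- function(ls, re) {
          s <- exp(ls)
          sum(dnorm(re, 0, s, log = TRUE)) + dexp(s, pr$sigma_rate, log = TRUE) + ls
        }
        ls_u <- slice_1d(ls_u, function(z) lp_sigma(z, u), w = 1)
        ls_v <- slice_1d(ls_v, function(z) lp_sigma(z, v), w = 1)
        # random-effect step-size adaptation during warmup, batches of 50
        batch <- batch + 1L
        if (it <= warmup && batch == 50L) {
          tune <- function(s, a) s * exp(pmin(pmax((a / 50 - 0.44), -0.5), 0.5))
          step_u <- tune(step_u, acc_u); step_v <- tune(step_v, acc_v)
          acc_u[] <- 0; acc_v[] <- 0
          batch <- 0L
        }
        if (it > warmup)
          draws[it - warmup, ] <- c(b, exp(ls_u), exp(ls_v),
                                    if (K) u, if (S) v)
      }
      draws
    })
  }

  chains_list <- lapply(seq_len(chains), run_chain)
  report <- c(colnames(X), "sigma_cluster", "sigma_survey")
  diag <- data.frame(parameter = report,
                     rhat = vapply(report, function(pm)
                       split_rhat(lapply(chains_list, function(d) d[, pm])),
                       numeric(1)),
                     ess = vapply(report, function(pm)
                       ess_bulk(lapply(chains_list, function(d) d[, pm])),
                       numeric(1)),
                     row.names = NULL)
  structure(list(chains = chains_list, par_names = par_names,
                 fixed_names = colnames(X), diagnostics = diag,
                 X = X, y = y, cluster = cli, survey = svi,
                 cluster_levels = levels(cl), survey_levels = levels(sv),
                 config = list(chains = chains, iter = iter, warmup = warmup,
                               seed = seed, priors = pr),
                 converged = all(is.na(diag$rhat) | diag$rhat < 1.05)),
            class = "hbm_fit")
}

# Univariate slice sampler (Neal 2003, stepping-out with shrinkage).
slice_1d <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  z <- f0 - rexp(1)
  L <- x0 - w * runif(1)
  R <- L + w
  j <- floor(max_steps * runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && is.finite(fl <- logf(L)) && fl > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && is.finite(fr <- logf(R)) && fr > z) { R <- R + w; k <- k - 1 }
  for (i in seq_len(100)) {
    x1 <- L + runif(1) * (R - L)
    f1 <- logf(x1)
    if (is.finite(f1) && f1 > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

# All post-warmup draws stacked across chains.
draws_matrix <- function(fit) do.call(rbind, fit$chains)

# Split R-hat over a list of per-chain draw vectors.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars); B <- n * var(means)
  if (W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Bulk ESS via Geyer's initial positive sequence, summed over chains.
ess_bulk <- function(chains) {
  sum(vapply(chains, function(v) {
    n <- length(v)
    if (var(v) < 1e-12) return(n)
    ac <- acf_vec(v, lag.max = min(n - 2, 200))
    rho_sum <- 0
    k <- 1
    while (k + 1 <= length(ac)) {
      pair <- ac[k] + ac[k + 1]
      if (pair < 0) break
      rho_sum <- rho_sum + pair
      k <- k + 2
    }
    n / (1 + 2 * rho_sum)
  }, numeric(1)))
}

acf_vec <- function(v, lag.max) {
  v <- v - mean(v)
  denom <- sum(v^2)
  vapply(seq_len(lag.max), function(L)
    sum(v[seq_len(length(v) - L)] * v[(L + 1):length(v)]) / denom, numeric(1))
}

#' Posterior summary with effect-strength tiers
#'
#' Per-parameter posterior mean, sd, central 95% and 90% credible intervals,
#' directional mass `P(beta > 0)`, Monte-Carlo standard error of the mean,
#' split R-hat and bulk ESS, plus the effect-strength tier
#' ([classify_effect()]) for fixed effects.
#'
#' @param fit An `hbm_fit`.
#' @param error_type Posterior-error unit for the weak tier: `"mcse"`
#'   (default) or `"sd"`.
#' @return Data frame, one row per reported parameter.
#' @export
posterior_summary <- function(fit, error_type = c("mcse", "sd")) {
  error_type <- match.arg(error_type)
  d <- draws_matrix(fit)
  report <- c(fit$fixed_names, "sigma_cluster", "sigma_survey")
  rows <- lapply(report, function(pm) {
    v <- d[, pm]
    ess <- fit$diagnostics$ess[fit$diagnostics$parameter == pm]
    q <- quantile(v, c(0.025, 0.975, 0.05, 0.95), names = FALSE)
    data.frame(parameter = pm, mean = mean(v), sd = sd(v),
               ci95_low = q[1], ci95_high = q[2],
               ci90_low = q[3], ci90_high = q[4],
               p_gt0 = mean(v > 0),
               mcse = sd(v) / sqrt(max(ess, 1)),
               rhat = fit$diagnostics$rhat[fit$diagnostics$parameter == pm],
               ess = ess, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$error <- if (error_type == "mcse") out$mcse else out$sd
  is_fixed <- out$parameter %in% fit$fixed_names
  out$tier <- NA_character_
  out$tier[is_fixed] <- classify_effect(out[is_fixed, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Classify posterior effect strength
#'
#' Three-tier rules on a posterior summary: *strong* when the 95% credible
#' interval excludes zero; else *moderate* when at least 90% of the
#' posterior mass lies on one side of zero; else *weak* when the posterior
#' mean is at least 1.0 from zero and the CrI is asymmetric about zero —
#' the bound on the mean's side more than 2 posterior-error units from zero
#' and the bound on the other side within 2 error units; otherwise *none*.
#'
#' @param summary Data frame with columns `mean`, `ci95_low`, `ci95_high`,
#'   `p_gt0` and `error` (the posterior-error unit).
#' @return Character vector of tiers.
#' @export
classify_effect <- function(summary) {
  vapply(seq_len(nrow(summary)), function(i) {
    m <- summary$mean[i]
    lo <- summary$ci95_low[i]; hi <- summary$ci95_high[i]
    pg <- summary$p_gt0[i]; err <- summary$error[i]
    if (lo > 0 || hi < 0) return("strong")
    if (pg >= 0.90 || pg <= 0.10) return("moderate")
    near <- if (m >= 0) hi else -lo     # bound on the mean's side
    far <- if (m >= 0) -lo else hi      # bound on the other side
    if (abs(m) >= 1.0 && near > 2 * err && far < 2 * err) return("weak")
    "none"
  }, character(1))
}

#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the fitted probabilities (including
#' random effects) divided by itself plus the mean Bernoulli residual
#' variance `p(1-p)` over observations.
#'
#' @param fit An `hbm_fit` (fitted to nonempty data).
#' @param max_draws Cap on draws used (default 1000).
#' @return List with `mean`, `ci_low`, `ci_high` (95% CrI) and the per-draw
#'   vector `draws`.
#' @export
bayes_r2 <- function(fit, max_draws = 1000) {
  if (length(fit$y) == 0)
    stop_fearscape("Bayes R2 needs data", class = "fearscape_config_error")
  d <- draws_matrix(fit)
  if (nrow(d) > max_draws)
    d <- d[seq(1, nrow(d), length.out = max_draws), , drop = FALSE]
  p <- length(fit$fixed_names)
  K <- length(fit$cluster_levels); S <- length(fit$survey_levels)
  r2 <- apply(d, 1, function(dr) {
    eta <- drop(fit$X %*% dr[seq_len(p)])
    if (K) eta <- eta + dr[p + 2 + fit$cluster]
    if (S) eta <- eta + dr[p + 2 + K + fit$survey]
    ph <- plogis(eta)
    vfit <- var(ph)
    vfit / (vfit + mean(ph * (1 - ph)))
  })
  list(mean = mean(r2),
       ci_low = unname(quantile(r2, 0.025)),
       ci_high = unname(quantile(r2, 0.975)),
       draws = r2)
}

#' Prune predictors by near-zero posterior band
#'
#' Drops predictors whose posterior mean and 95% CrI midpoint both fall
#' inside `band` (default (-0.2, 0.2)); any main effect that parents a
#' retained interaction is re-added, so no interaction is retained without
#' its main effects.
#'
#' @param summary Posterior summary data frame ([posterior_summary()]);
#'   only fixed-effect rows (tier not `NA`) are considered, the intercept is
#'   always kept.
#' @param band Length-2 numeric band.
#' @return List with `keep`, `drop`, `readded` character vectors.
#' @export
prune_predictors <- function(summary, band = c(-0.2, 0.2)) {
  s <- summary[!is.na(summary$tier) & summary$parameter != "(Intercept)", ,
               drop = FALSE]
  mid <- (s$ci95_low + s$ci95_high) / 2
  inside <- s$mean > band[1] & s$mean < band[2] &
    mid > band[1] & mid < band[2]
  keep <- s$parameter[!inside]
  drop <- s$parameter[inside]
  readded <- character(0)
  for (f in keep[grepl(":", keep, fixed = TRUE)]) {
    for (par in strsplit(f, ":", fixed = TRUE)[[1]]) {
      if (par %in% drop) {
        drop <- setdiff(drop, par)
        keep <- c(keep, par)
        readded <- c(readded, par)
      }
    }
  }
  list(keep = unique(keep), drop = drop, readded = unique(readded))
}

#' @export
print.hbm_fit <- function(x, ...) {
  cfg <- x$config
  cat("Hierarchical Bernoulli detection model (logit link)\n")
  cat(sprintf("  %d obs; %d clusters, %d surveys; %d chains x %d iter (%d warmup)\n",
              length(x$y), length(x$cluster_levels), length(x$survey_levels),
              cfg$chains, cfg$iter, cfg$warmup))
  cat(sprintf("  converged (split R-hat < 1.05 on reported parameters): %s\n",
              x$converged))
  invisible(x)
}

#' @export
summary.hbm_fit <- function(object, ...) posterior_summary(object, ...)

#' @export
coef.hbm_fit <- function(object, ...) {
  d <- draws_matrix(object)
  colMeans(d[, object$fixed_names, drop = FALSE])
}
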