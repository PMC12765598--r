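# Time-stratified case-crossover analysis: hourly detection matrix,
# predator-exposure lags, matched strata, and a conditional logistic
# regression fitter.

#' Build the hourly detection matrix
#'
#' Floors independence-filtered detections to the hour and lays them on a
#' consecutive hourly grid per camera cluster, with an operational mask (a
#' cluster-hour is operational when at least one member camera is active on
#' that calendar day). Cluster-days are anchored at 12:00, running to 11:59
#' the next day, so a night belongs to one day. Detections falling in
#' non-operational hours are dropped with a warning.
#'
#' @param events Independence-filtered detections (with `cluster_id`, as
#'   returned by [filter_independent()]).
#' @param clusters A `camera_clusters` object.
#' @param deployments Deployment table (for the operational mask).
#' @param species Species to build indicator columns for; default all
#'   present in `events`.
#' @return Object of class `hourly_matrix`: a data frame with `cluster_id`,
#'   `hour` (POSIXct, on-the-hour), `cluster_day` (Date, noon-anchored),
#'   `operational` (logical) and one 0/1 column per species.
#' @export
build_hourly_matrix <- function(events, clusters, deployments,
                                species = NULL) {
  if (is.null(species)) species <- sort(unique(events$species))
  dep <- deployments
  dep$cluster_id <- cluster_of(clusters, dep$camera_id)

  mats <- lapply(split(dep, dep$cluster_id), function(d) {
    days <- seq(min(d$start), max(d$end), by = "day")
    op_day <- vapply(days, function(dd)
      any(dd >= d$start & dd <= d$end), logical(1))
    hours <- seq(as.POSIXct(paste0(format(min(days)), "T00:00:00"),
                            format = TIME_FMT, tz = "UTC"),
                 as.POSIXct(paste0(format(max(days)), "T23:00:00"),
                            format = TIME_FMT, tz = "UTC"),
                 by = "hour")
    data.frame(cluster_id = d$cluster_id[1], hour = hours,
               operational = rep(op_day, each = 24),
               stringsAsFactors = FALSE)
  })
  mat <- do.call(rbind, mats)
  rownames(mat) <- NULL
  mat$cluster_day <- as.Date(mat$hour - 12 * 3600, tz = "UTC")

  key <- paste(mat$cluster_id, format(mat$hour, "%Y-%m-%d %H", tz = "UTC"))
  for (sp in species) mat[[sp]] <- 0L
  dropped <- 0L
  ev <- events[events$species %in% species, , drop = FALSE]
  if (nrow(ev)) {
    ev_key <- paste(ev$cluster_id, format(ev$timestamp, "%Y-%m-%d %H", tz = "UTC"))
    idx <- match(ev_key, key)
    oob <- is.na(idx) | !mat$operational[pmax(idx, 1L)]
    if (any(oob)) {
      dropped <- sum(oob)
      warning(dropped, " detection(s) in non-operational hours dropped")
    }
    for (sp in species) {
      take <- idx[!oob & ev$species == sp]
      if (length(take)) mat[[sp]][take] <- 1L
    }
  }
  structure(mat, species = species, dropped_events = dropped,
            class = c("hourly_matrix", "data.frame"))
}

# Hours since the most recent predator indicator strictly before each row's
# hour, per cluster, assuming rows are the consecutive hourly grid.
# Returns Inf where no prior detection exists.
lag_since_last <- function(mat, predator) {
  out <- rep(Inf, nrow(mat))
  for (idx in split(seq_len(nrow(mat)), mat$cluster_id)) {
    z <- mat[[predator]][idx]
    pos <- seq_along(idx)
    lastpos <- cummax(ifelse(z == 1L, pos, 0L))
    prev <- c(0L, lastpos[-length(lastpos)])
    lag <- ifelse(prev > 0L, pos - prev, Inf)
    out[idx] <- lag
  }
  out
}

#' Time since last predator detection at a cluster-hour
#'
#' @param matrix An `hourly_matrix`.
#' @param predator Predator species column name.
#' @param cluster Cluster id.
#' @param hour POSIXct hour within the matrix coverage.
#' @return List with `hours_since` (numeric, `Inf` if never) and `window`
#'   (`"short"` for lags in `[0, 6)`, `"delayed"` for `[6, 24)`,
#'   `"reference"` otherwise).
#' @export
time_since_last <- function(matrix, predator, cluster, hour) {
  rows <- which(matrix$cluster_id == cluster)
  if (!length(rows))
    stop_fearscape("unknown cluster: ", cluster, class = "fearscape_config_error")
  i <- rows[match(as.numeric(hour), as.numeric(matrix$hour[rows]))]
  if (is.na(i))
    stop_fearscape("hour outside matrix coverage", class = "fearscape_config_error")
  lag <- lag_since_last(matrix, predator)[i]
  window <- if (is.finite(lag) && lag < 6) "short"
  else if (is.finite(lag) && lag < 24) "delayed"
  else "reference"
  list(hours_since = lag, window = window)
}

exposure_window_cols <- function(predators)
  as.vector(t(outer(predators, c("short", "delayed"), paste, sep = "_")))

# Exposure indicator columns for every row of the matrix (computed
# identically for cases and controls - the time-stratified referent).
exposure_indicators <- function(mat, predators) {
  out <- matrix(0L, nrow(mat), 2 * length(predators),
                dimnames = list(NULL, exposure_window_cols(predators)))
  for (p in predators) {
    lag <- lag_since_last(mat, p)
    out[, paste0(p, "_short")] <- as.integer(is.finite(lag) & lag < 6)
    out[, paste0(p, "_delayed")] <- as.integer(is.finite(lag) & lag >= 6 & lag < 24)
  }
  out
}

#' Build case-crossover strata
#'
#' Every operational hour with a focal-species detection is a case. Its
#' control pool is the operational hours at the same cluster, in the same
#' calendar month, at the same hour of day, without a focal detection; up to
#' `k_controls` controls are sampled without replacement. Sampling is keyed
#' by (`seed`, stratum id), so strata are reproducible regardless of
#' evaluation order. Strata with an empty pool are dropped and counted.
#'
#' Exposure indicators (`<predator>_short` for lags in `[0, 6)` hours,
#' `<predator>_delayed` for `[6, 24)`) are computed from the hourly grid,
#' strictly-before the focal hour. If `events` is supplied, a same-hour
#' predator detection whose raw timestamp precedes the case's earliest focal
#' detection in that hour counts as lag-0 short-term exposure for that case.
#'
#' @param matrix An `hourly_matrix` containing the focal and predator
#'   columns.
#' @param focal Focal species column name.
#' @param predators Character vector of predator column names.
#' @param k_controls Maximum controls per case (default 5).
#' @param seed Integer seed for control sampling.
#' @param events Optional raw (filtered) detections for the same-hour
#'   timestamp-ordering refinement.
#' @return Object of class `cc_strata`: long data frame with `stratum_id`,
#'   `role` (`"case"`/`"control"`), `cluster_id`, `hour` and the exposure
#'   columns; attributes `dropped_strata`, `focal`, `predators`.
#' @export
build_strata <- function(matrix, focal, predators, k_controls = 5,
                         seed = 1L, events = NULL) {
  mat <- matrix
  expo <- exposure_indicators(mat, predators)
  op <- mat$operational
  is_case <- op & mat[[focal]] == 1L
  if (!any(is_case))
    stop_fearscape("no focal detection hours for ", focal,
                   class = "fearscape_sample_error")
  pool_key <- paste(mat$cluster_id, format(mat$hour, "%Y-%m", tz = "UTC"),
                    format(mat$hour, "%H", tz = "UTC"))
  eligible <- op & mat[[focal]] == 0L
  pool_idx <- split(which(eligible), pool_key[eligible])

  case_rows <- which(is_case)
  out <- vector("list", length(case_rows))
  dropped <- 0L
  for (i in seq_along(case_rows)) {
    r <- case_rows[i]
    sid <- paste0(mat$cluster_id[r], "/", format(mat$hour[r], TIME_FMT, tz = "UTC"))
    pool <- pool_idx[[pool_key[r]]] %||% integer(0)
    if (!length(pool)) {
      dropped <- dropped + 1L
      next
    }
    k <- min(k_controls, length(pool))
    ctrl <- with_seed(seed_from_key(seed, sid),
                      pool[sample.int(length(pool), k)])
    rows <- c(r, ctrl)
    d <- data.frame(stratum_id = sid,
                    role = c("case", rep("control", k)),
                    cluster_id = mat$cluster_id[rows],
                    hour = mat$hour[rows],
                    stringsAsFactors = FALSE)
    out[[i]] <- cbind(d, as.data.frame(expo[rows, , drop = FALSE]))
  }
  kept <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(kept)) do.call(rbind, kept) else
    cbind(data.frame(stratum_id = character(0), role = character(0),
                     cluster_id = character(0),
                     hour = as.POSIXct(character(0), tz = "UTC")),
          as.data.frame(expo[0, , drop = FALSE]))
  rownames(res) <- NULL

  # same-hour refinement: predator raw timestamp before focal raw timestamp
  if (!is.null(events) && nrow(res)) {
    cases <- res$role == "case"
    for (p in predators) {
      pe <- events[events$species == p, , drop = FALSE]
      fe <- events[events$species == focal, , drop = FALSE]
      if (!nrow(pe) || !nrow(fe)) next
      for (j in which(cases)) {
        h0 <- res$hour[j]; cl <- res$cluster_id[j]
        f_in <- fe$timestamp[fe$cluster_id == cl &
                               fe$timestamp >= h0 & fe$timestamp < h0 + 3600]
        if (!length(f_in)) next
        p_in <- pe$timestamp[pe$cluster_id == cl &
                               pe$timestamp >= h0 & pe$timestamp < h0 + 3600]
        if (length(p_in) && min(p_in) < min(f_in))
          res[[paste0(p, "_short")]][j] <- 1L
      }
    }
  }
  structure(res, dropped_strata = dropped, focal = focal,
            predators = predators,
            class = c("cc_strata", "data.frame"))
}

#' Fit a conditional logistic regression to matched strata
#'
#' Maximises the conditional likelihood
#' `prod_s exp(x_case . beta) / sum_j exp(x_j . beta)` by Newton-Raphson
#' with step-halving (tolerance 1e-8 on the log-likelihood change, at most
#' `max_iter` iterations). Standard errors come from the inverse observed
#' information; Wald CIs use 1.96 and p-values are two-sided normal.
#' Indicators without within-stratum variation are dropped with a warning.
#' Quasi-complete separation (a coefficient drifting to infinity) is flagged
#' per coefficient when `|beta| > 10` or `SE > 100`; such coefficients are
#' reported but marked unstable.
#'
#' @param strata A `cc_strata` data frame (or any long data frame with
#'   `stratum_id`, `role` and indicator columns).
#' @param indicators Character vector of exposure columns; default every
#'   column ending in `_short` or `_delayed`.
#' @param max_iter Newton-Raphson iteration cap (default 50).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return Object of class `clogit_fit` with coefficients, `se`, `or`,
#'   `ci_low`/`ci_high` (OR scale), `p`, log-likelihoods, the likelihood
#'   ratio test, concordance, `n_events`, convergence and separation flags.
#' @seealso [lr_test()], [concordance_index()]
#' @export
fit_clogit <- function(strata, indicators = NULL, max_iter = 50,
                       tol = 1e-8) {
  if (is.null(indicators))
    indicators <- grep("_(short|delayed)$", names(strata), value = TRUE)
  if (!length(indicators))
    stop_fearscape("no exposure indicator columns found",
                   class = "fearscape_config_error")
  g <- factor(strata$stratum_id)
  y <- strata$role == "case"
  if (!any(y))
    stop_fearscape("no case rows in strata", class = "fearscape_config_error")
  X <- as.matrix(strata[, indicators, drop = FALSE])
  storage.mode(X) <- "double"

  # indicators must vary within at least one stratum to be estimable
  varies <- vapply(indicators, function(j) {
    rng <- tapply(X[, j], g, function(v) max(v) - min(v))
    any(rng > 0)
  }, logical(1))
  dropped_ind <- indicators[!varies]
  if (length(dropped_ind)) {
    warning("indicator(s) without within-stratum variation dropped: ",
            paste(dropped_ind, collapse = ", "))
    indicators <- indicators[varies]
    X <- X[, indicators, drop = FALSE]
  }
  p <- ncol(X)
  n_s <- as.integer(table(g))
  ll_null <- -sum(log(n_s))
  gi <- as.integer(g)

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    m <- ave(eta, gi, FUN = max)
    w <- exp(eta - m)
    W <- rowsum(w, gi)
    m_s <- rowsum(m, gi) / n_s
    sum(eta[y]) - sum(log(W) + m_s)
  }

  beta <- rep(0, p)
  ll <- loglik(beta)
  converged <- FALSE
  info <- NULL
  if (p > 0) {
    for (iter in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      m <- ave(eta, gi, FUN = max)
      w <- exp(eta - m)
      W <- drop(rowsum(w, gi))
      wn <- w / W[gi]
      xbar <- rowsum(X * wn, gi)            # one row per stratum
      grad <- colSums(X[y, , drop = FALSE]) - colSums(xbar)
      A <- crossprod(X * sqrt(wn))
      B <- crossprod(xbar)
      info <- A - B
      step <- tryCatch(solve(info, grad), error = function(e) NULL)
      if (is.null(step)) break
      ll_new <- loglik(beta + step)
      halvings <- 0
      while ((!is.finite(ll_new) || ll_new < ll) && halvings < 30) {
        step <- step / 2
        ll_new <- loglik(beta + step)
        halvings <- halvings + 1
      }
      beta <- beta + step
      if (is.finite(ll_new) && abs(ll_new - ll) < tol) {
        ll <- ll_new
        converged <- TRUE
        break
      }
      ll <- ll_new
    }
    # information at the optimum
    eta <- drop(X %*% beta)
    m <- ave(eta, gi, FUN = max)
    w <- exp(eta - m)
    W <- drop(rowsum(w, gi))
    wn <- w / W[gi]
    xbar <- rowsum(X * wn, gi)
    info <- crossprod(X * sqrt(wn)) - crossprod(xbar)
  }
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- names(se) <- indicators
  dimnames(vc) <- list(indicators, indicators)
  separation <- abs(beta) > 10 | se > 100
  z <- beta / se
  lp <- drop(X %*% beta)
  conc <- concordance_lp(lp, gi, y)
  lr_chisq <- max(0, 2 * (ll - ll_null))
  fit <- structure(list(
    coefficients = beta, se = se, vcov = vc,
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * pnorm(-abs(z)),
    loglik = c(null = ll_null, full = ll),
    lr_chisq = lr_chisq, lr_df = p,
    lr_p = pchisq(lr_chisq, df = max(p, 1), lower.tail = FALSE),
    concordance = conc,
    n_events = nlevels(g), n_strata = nlevels(g),
    converged = converged, separation = separation,
    dropped_indicators = dropped_ind,
    indicators = indicators,
    linear_predictors = lp, stratum = gi, case = y),
    class = "clogit_fit")
  fit
}

concordance_lp <- function(lp, gi, y) {
  num <- 0; den <- 0
  for (idx in split(seq_along(gi), gi)) {
    lc <- lp[idx][y[idx]]
    lk <- lp[idx][!y[idx]]
    if (!length(lc) || !length(lk)) next
    for (v in lc) {
      num <- num + sum(v > lk) + 0.5 * sum(v == lk)
      den <- den + length(lk)
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Concordance of a conditional logistic fit
#'
#' Over all (case, control) pairs within strata: the fraction of pairs where
#' the case's fitted linear predictor exceeds the control's, ties credited
#' 0.5.
#'
#' @param fit A `clogit_fit`.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(fit) {
  concordance_lp(fit$linear_predictors, fit$stratum, fit$case)
}

#' Likelihood ratio test of a conditional logistic fit
#'
#' `chisq = 2 (ll_full - ll_null)` against the null of all coefficients 0,
#' where the null log-likelihood is `-sum_s log(n_s)`.
#'
#' @param fit A `clogit_fit`.
#' @return List with `chisq`, `df`, `p`.
#' @export
lr_test <- function(fit) {
  list(chisq = fit$lr_chisq, df = fit$lr_df, p = fit$lr_p)
}

#' @export
coef.clogit_fit <- function(object, ...) object$coefficients

#' @export
vcov.clogit_fit <- function(object, ...) object$vcov

#' @export
confint.clogit_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste0(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("Conditional logistic regression (case-crossover)\n")
  cat(sprintf("  n events = %d strata; LR chisq = %.2f on %d df, p = %.3g; concordance = %.3f\n",
              x$n_events, x$lr_chisq, x$lr_df, x$lr_p, x$concordance))
  print(summary(x))
  invisible(x)
}

#' @export
summary.clogit_fit <- function(object, ...) {
  out <- data.frame(coef = object$coefficients, se = object$se,
                    OR = object$or, ci_low = object$ci_low,
                    ci_high = object$ci_high, p = object$p,
                    unstable = object$separation)
  out
}
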