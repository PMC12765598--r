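make_small_matrix <- function() {
  dep <- make_deployments(c(0, 2000), c(0, 0),
                          start = as.Date("2022-06-01"),
                          end = as.Date("2022-06-30"))
  cl <- cluster_cameras(dep)
  ev <- make_events(
    c("cam01", "cam01", "cam01", "cam02"),
    c("gemsbok", "gemsbok", "lion", "gemsbok"),
    c("2022-06-05T14:37:12", "2022-06-05T14:55:00",
      "2022-06-05T10:30:00", "2022-06-10T09:00:00"))
  ev$cluster_id <- fearscape:::cluster_of(cl, ev$camera_id)
  list(dep = dep, cl = cl, ev = ev,
       mat = build_hourly_matrix(ev, cl, dep))
}

test_that("hourly matrix floors to the hour with binary indicators", {
  x <- make_small_matrix()
  mat <- x$mat
  row14 <- mat[mat$cluster_id == "C001" &
                 format(mat$hour, "%Y-%m-%d %H") == "2022-06-05 14", ]
  expect_equal(row14$gemsbok, 1L)       # two detections, still 1
  expect_equal(sum(mat$gemsbok), 2L)    # one hour per cluster
  expect_equal(sum(mat$lion), 1L)
  # noon-anchored cluster-day: 10:30 belongs to the previous cluster-day
  expect_equal(unique(mat$cluster_day[format(mat$hour, "%H") == "00"]),
               unique(as.Date(mat$hour[format(mat$hour, "%H") == "00"],
                              tz = "UTC") - 1))
})

test_that("detections in non-operational hours are dropped with a warning", {
  dep <- make_deployments(0, 0, start = as.Date("2022-06-01"),
                          end = as.Date("2022-06-30"))
  dep2 <- rbind(dep, transform(dep, start = as.Date("2022-08-01"),
                               end = as.Date("2022-08-10")))
  cl <- cluster_cameras(dep2)
  ev <- make_events("cam01", "gemsbok", "2022-07-05T10:00:00") # in the gap
  ev$cluster_id <- fearscape:::cluster_of(cl, ev$camera_id)
  expect_warning(mat <- build_hourly_matrix(ev, cl, dep2), "non-operational")
  expect_equal(sum(mat$gemsbok), 0L)
})

test_that("time since last predator maps to the exposure windows", {
  x <- make_small_matrix()
  h <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  # lion at 10:00 on 2022-06-05 in cluster C001
  expect_equal(time_since_last(x$mat, "lion", "C001", h("2022-06-05T14:00:00")),
               list(hours_since = 4, window = "short"))
  expect_equal(time_since_last(x$mat, "lion", "C001", h("2022-06-05T22:00:00")),
               list(hours_since = 12, window = "delayed"))
  expect_equal(time_since_last(x$mat, "lion", "C001", h("2022-06-04T14:00:00")),
               list(hours_since = Inf, window = "reference"))
  expect_equal(time_since_last(x$mat, "lion", "C001", h("2022-06-08T14:00:00")),
               list(hours_since = 76, window = "reference"))
})

test_that("strata match on cluster, month and hour of day with up to five controls", {
  x <- make_small_matrix()
  st <- build_strata(x$mat, "gemsbok", "lion", seed = 7)
  for (sid in unique(st$stratum_id)) {
    d <- st[st$stratum_id == sid, ]
    case <- d[d$role == "case", ]
    ctrl <- d[d$role == "control", ]
    expect_gte(nrow(ctrl), 1)
    expect_lte(nrow(ctrl), 5)
    expect_equal(unique(d$cluster_id), case$cluster_id)
    expect_setequal(format(ctrl$hour, "%H"), format(case$hour, "%H"))
    expect_setequal(format(ctrl$hour, "%Y-%m"), format(case$hour, "%Y-%m"))
    # controls carry no focal detection
    key <- paste(x$mat$cluster_id, format(x$mat$hour))
    expect_true(all(x$mat$gemsbok[match(paste(ctrl$cluster_id,
                                              format(ctrl$hour)), key)] == 0))
  }
  # full month pool (30 eligible hours minus detections): exactly 5 controls
  expect_equal(sum(st$role == "control" &
                     st$stratum_id == st$stratum_id[1]), 5)
})

test_that("control sampling is reproducible and order-independent", {
  x <- make_small_matrix()
  st1 <- build_strata(x$mat, "gemsbok", "lion", seed = 11)
  st2 <- build_strata(x$mat, "gemsbok", "lion", seed = 11)
  expect_equal(st1, st2)
  st3 <- build_strata(x$mat, "gemsbok", "lion", seed = 12)
  expect_false(identical(st1$hour, st3$hour))
})

test_that("cases with empty control pools are dropped and counted", {
  # single camera operational one day: every eligible hour shares the month
  dep <- make_deployments(0, 0, start = as.Date("2022-06-01"),
                          end = as.Date("2022-06-01"))
  cl <- cluster_cameras(dep)
  # focal detected every hour of the day -> no eligible controls anywhere
  ev <- make_events(rep("cam01", 24), "gemsbok",
                    sprintf("2022-06-01T%02d:15:00", 0:23))
  ev$cluster_id <- fearscape:::cluster_of(cl, ev$camera_id)
  mat <- build_hourly_matrix(ev, cl, dep)
  st <- build_strata(mat, "gemsbok", character(0), seed = 1)
  expect_equal(nrow(st), 0)             # nothing buildable
  expect_equal(attr(st, "dropped_strata"), 24)
})

test_that("same-hour predator detections count as exposure only when earlier", {
  dep <- make_deployments(0, 0, start = as.Date("2022-06-01"),
                          end = as.Date("2022-06-30"))
  cl <- cluster_cameras(dep)
  ev <- make_events(rep("cam01", 4),
                    c("gemsbok", "lion", "gemsbok", "lion"),
                    c("2022-06-05T14:40:00", "2022-06-05T14:10:00",
                      "2022-06-10T09:10:00", "2022-06-10T09:40:00"))
  ev$cluster_id <- fearscape:::cluster_of(cl, ev$camera_id)
  mat <- build_hourly_matrix(ev, cl, dep)
  st <- build_strata(mat, "gemsbok", "lion", seed = 3, events = ev)
  case1 <- st[st$role == "case" & format(st$hour, "%d") == "05", ]
  case2 <- st[st$role == "case" & format(st$hour, "%d") == "10", ]
  expect_equal(case1$lion_short, 1L)    # lion 14:10 precedes gemsbok 14:40
  expect_equal(case2$lion_short, 0L)    # lion 09:40 follows gemsbok 09:10
})

test_that("matched-pair conditional MLE equals the discordant-pair closed form", {
  st <- discordant_pairs(10, 5)
  fit <- fit_clogit(st, indicators = "x_short")
  expect_equal(unname(coef(fit)), log(10 / 5), tolerance = 1e-6)
  expect_equal(unname(fit$or), 2.0, tolerance = 1e-6)
  expect_false(any(fit$separation))
  expect_true(fit$converged)
})

test_that("fitter matches the survival package on random strata", {
  skip_if_not_installed("survival")
  set.seed(21)
  d <- do.call(rbind, lapply(1:150, function(s) {
    k <- sample(2:6, 1)
    data.frame(stratum_id = sprintf("s%03d", s),
               role = c("case", rep("control", k - 1)),
               a_short = rbinom(k, 1, 0.3), a_delayed = rbinom(k, 1, 0.3),
               b_short = rbinom(k, 1, 0.2), b_delayed = rbinom(k, 1, 0.4))
  }))
  fit <- fit_clogit(d)
  d$y <- as.integer(d$role == "case")
  # clogit is exact conditional logistic via stratified Cox with ties=exact
  sf <- survival::coxph(
    survival::Surv(rep(1, nrow(d)), y) ~ a_short + a_delayed + b_short +
      b_delayed + survival::strata(stratum_id),
    data = d, ties = "exact")
  expect_equal(unname(coef(fit)), unname(coef(sf)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sf)))), tolerance = 1e-6)
  expect_equal(unname(fit$loglik["full"]), sf$loglik[2], tolerance = 1e-8)
  expect_equal(fit$concordance, unname(sf$concordance["concordance"]),
               tolerance = 1e-8)
})

test_that("complete separation is flagged rather than reported as stable", {
  st <- discordant_pairs(12, 0)         # all cases exposed, no controls
  fit <- suppressWarnings(fit_clogit(st, indicators = "x_short"))
  expect_true(any(fit$separation))
})

test_that("likelihood ratio matches direct re-evaluation and has the right df", {
  set.seed(22)
  d <- do.call(rbind, lapply(1:80, function(s) {
    k <- 4
    data.frame(stratum_id = sprintf("s%03d", s),
               role = c("case", rep("control", k - 1)),
               a_short = rbinom(k, 1, 0.4), a_delayed = rbinom(k, 1, 0.3),
               b_short = rbinom(k, 1, 0.3), b_delayed = rbinom(k, 1, 0.3))
  }))
  fit <- fit_clogit(d)
  lt <- lr_test(fit)
  expect_equal(lt$df, 4)
  ind <- fit$indicators
  ll_hat <- clogit_ll_ref(d, ind, coef(fit))
  ll_0 <- clogit_ll_ref(d, ind, rep(0, 4))
  expect_equal(lt$chisq, 2 * (ll_hat - ll_0), tolerance = 1e-8)
  expect_gte(lt$chisq, 0)
})

test_that("concordance: ties give 0.5, perfect separation gives 1, manual tally agrees", {
  expect_equal(fearscape:::concordance_lp(rep(0, 6), rep(1:2, each = 3),
                                          c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)),
               0.5)
  expect_equal(fearscape:::concordance_lp(c(1, 0, 0, 1, 0, 0),
                                          rep(1:2, each = 3),
                                          c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)),
               1.0)
  # hand-countable: stratum 1 case beats 1 of 2, ties 1 (1.5/2);
  # stratum 2 case beats 2 of 2; stratum 3 case loses both (0/2)
  lp <- c(2, 1, 2,   3, 0, 1,   0, 1, 2)
  gi <- rep(1:3, each = 3)
  y <- rep(c(TRUE, FALSE, FALSE), 3)
  expect_equal(fearscape:::concordance_lp(lp, gi, y), (1.5 + 2 + 0) / 6)
})

test_that("stratum-constant covariates do not change the estimates", {
  set.seed(23)
  d <- do.call(rbind, lapply(1:60, function(s) {
    k <- 3
    data.frame(stratum_id = sprintf("s%03d", s),
               role = c("case", "control", "control"),
               a_short = rbinom(k, 1, 0.4), b_delayed = rbinom(k, 1, 0.3))
  }))
  fit <- fit_clogit(d, indicators = c("a_short", "b_delayed"))
  d$const_short <- ave(seq_len(nrow(d)), d$stratum_id, FUN = function(i) i[1])
  fit2 <- suppressWarnings(
    fit_clogit(d, indicators = c("a_short", "b_delayed", "const_short")))
  expect_equal(coef(fit2)[c("a_short", "b_delayed")],
               coef(fit)[c("a_short", "b_delayed")], tolerance = 1e-10)
  expect_true("const_short" %in% fit2$dropped_indicators)
})

test_that("within-stratum label permutation centres the estimate on zero", {
  set.seed(24)
  d <- do.call(rbind, lapply(1:100, function(s) {
    data.frame(stratum_id = sprintf("s%03d", s),
               role = c("case", "control"),
               x_short = rbinom(2, 1, 0.4))
  }))
  betas <- replicate(200, {
    perm <- do.call(rbind, lapply(split(d, d$stratum_id), function(g) {
      g$role <- sample(g$role)
      g
    }))
    f <- tryCatch(suppressWarnings(fit_clogit(perm, indicators = "x_short")),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else unname(coef(f))
  })
  betas <- betas[is.finite(betas)]
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas)), 2 * mc_se + 1e-8)
})
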