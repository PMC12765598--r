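test_that("daily response table encodes presence and prior-day predator exposure", {
  dep <- make_deployments(0, 0, start = as.Date("2022-06-01"),
                          end = as.Date("2022-06-10"))
  cl <- cluster_cameras(dep)
  ev <- make_events(rep("cam01", 5),
                    c("gemsbok", "gemsbok", "gemsbok", "lion", "lion"),
                    c("2022-06-03T08:00:00", "2022-06-03T10:00:00",
                      "2022-06-03T15:00:00", "2022-06-02T22:00:00",
                      "2022-06-07T04:00:00"))
  ev$cluster_id <- fearscape:::cluster_of(cl, ev$camera_id)
  tab <- build_response(ev, cl, dep, "gemsbok", "lion")
  expect_equal(nrow(tab), 10)
  expect_equal(tab$presence[tab$day == as.Date("2022-06-03")], 1L)
  expect_equal(sum(tab$presence), 1L)
  # lion on the 2nd -> daily indicator on the 3rd; lion on the 7th -> the 8th
  expect_equal(tab$lion_daily[tab$day == as.Date("2022-06-03")], 1L)
  expect_equal(tab$lion_daily[tab$day == as.Date("2022-06-08")], 1L)
  expect_equal(sum(tab$lion_daily), 2L)
})

test_that("non-operational days are absent from the response table", {
  dep <- make_deployments(0, 0, start = as.Date("2022-06-01"),
                          end = as.Date("2022-06-05"))
  dep <- rbind(dep, transform(dep, start = as.Date("2022-06-10"),
                              end = as.Date("2022-06-12")))
  cl <- cluster_cameras(dep)
  ev <- make_events("cam01", "gemsbok", "2022-06-02T08:00:00")
  ev$cluster_id <- fearscape:::cluster_of(cl, ev$camera_id)
  tab <- build_response(ev, cl, dep, "gemsbok", character(0))
  expect_equal(nrow(tab), 8)
  expect_false(as.Date("2022-06-07") %in% tab$day)
})

test_that("survey windows assign days to surveys", {
  dep <- make_deployments(0, 0, start = as.Date("2022-06-01"),
                          end = as.Date("2022-06-10"))
  cl <- cluster_cameras(dep)
  ev <- make_events("cam01", "gemsbok", "2022-06-02T08:00:00")
  ev$cluster_id <- fearscape:::cluster_of(cl, ev$camera_id)
  sv <- data.frame(survey_id = c("S1", "S2"),
                   start = as.Date(c("2022-06-01", "2022-06-06")),
                   end = as.Date(c("2022-06-05", "2022-06-10")))
  tab <- build_response(ev, cl, dep, "gemsbok", character(0), surveys = sv)
  expect_equal(unname(table(tab$survey_id)[c("S1", "S2")]), c(5L, 5L),
               ignore_attr = TRUE)
})

test_that("model configuration is validated before sampling", {
  pan <- simulate_response_panel(n_clusters = 4, days = 10, seed = 1)
  expect_error(fit_hier_bernoulli(pan, "presence", fixed = "x1",
                                  iter = 100, warmup = 200),
               class = "fearscape_config_error")
  expect_error(fit_hier_bernoulli(pan, "presence", fixed = c("x1", "x1:x2")),
               class = "fearscape_config_error")
  pan$x2 <- pan$x1                      # perfectly collinear
  expect_error(fit_hier_bernoulli(pan, "presence", fixed = c("x1", "x2"),
                                  chains = 1, iter = 60, warmup = 20),
               class = "fearscape_rank_error")
})

test_that("the sampler recovers a known effect and shrinks absent heterogeneity", {
  pan <- simulate_response_panel(n_clusters = 20, n_surveys = 2, days = 40,
                                 beta = c(x1 = 1), intercept = -1,
                                 sigma_cluster = 0, sigma_survey = 0.3,
                                 seed = 55)
  fit <- fit_hier_bernoulli(pan, "presence", fixed = "x1",
                            chains = 2, iter = 800, warmup = 300, seed = 8)
  s <- posterior_summary(fit)
  b1 <- s[s$parameter == "x1", ]
  expect_gt(b1$mean, 0.7); expect_lt(b1$mean, 1.3)
  expect_true(b1$ci95_low < 1 && 1 < b1$ci95_high)
  # generator had no cluster heterogeneity: posterior mass near zero
  d <- fearscape:::draws_matrix(fit)
  expect_lt(median(d[, "sigma_cluster"]), 0.3)
})

test_that("fitted probabilities are proper and monotone in a covariate", {
  pan <- simulate_response_panel(n_clusters = 10, days = 20, seed = 66)
  fit <- fit_hier_bernoulli(pan, "presence", fixed = "x1",
                            chains = 2, iter = 500, warmup = 200, seed = 9)
  b <- coef(fit)
  x <- seq(-3, 3, 0.5)
  p <- plogis(b[["(Intercept)"]] + b[["x1"]] * x)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0) || all(diff(p) < 0))
})

test_that("effect tiers follow the strong/moderate/weak rules", {
  s <- data.frame(
    mean = c(0.66, 0.3, 0.05, 1.4, -1.4, -0.8),
    ci95_low = c(0.03, -0.2, -0.5, -0.05, -3.1, -2.4),
    ci95_high = c(1.39, 0.9, 0.6, 3.1, 0.05, 0.9),
    p_gt0 = c(0.98, 0.92, 0.55, 0.89, 0.11, 0.2),
    error = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.5))
  expect_equal(classify_effect(s),
               c("strong",    # CrI excludes zero
                 "moderate",  # 92% directional mass
                 "none",      # small and symmetric
                 "weak",      # |mean| >= 1, asymmetric CrI about zero
                 "weak",      # mirror image on the negative side
                 "none"))     # |mean| < 1
})

test_that("tier classification works on hand-built posterior draws", {
  set.seed(31)
  draws <- cbind(strong = rnorm(4000, 1, 0.3),
                 moderate = rnorm(4000, 0.5, 0.36),
                 none = rnorm(4000, 0.02, 0.5))
  s <- do.call(rbind, lapply(colnames(draws), function(nm) {
    v <- draws[, nm]
    data.frame(parameter = nm, mean = mean(v),
               ci95_low = unname(quantile(v, 0.025)),
               ci95_high = unname(quantile(v, 0.975)),
               p_gt0 = mean(v > 0), error = sd(v) / sqrt(1000))
  }))
  expect_equal(classify_effect(s), c("strong", "moderate", "none"))
})

test_that("pruning drops the near-zero band but preserves interaction parents", {
  s <- data.frame(
    parameter = c("(Intercept)", "ndvi", "lion_daily", "ndvi:lion_daily",
                  "temperature"),
    mean = c(0.5, 0.01, 0.05, 1.2, 1.1),
    ci95_low = c(0, -0.15, -0.1, 0.4, 0.2),
    ci95_high = c(1, 0.18, 0.19, 2.0, 2.0),
    tier = c(NA, "none", "none", "strong", "strong"))
  pr <- prune_predictors(s)
  expect_true("ndvi:lion_daily" %in% pr$keep)
  expect_true(all(c("ndvi", "lion_daily") %in% pr$keep))
  expect_setequal(pr$readded, c("ndvi", "lion_daily"))
  expect_true("temperature" %in% pr$keep)
  expect_length(pr$drop, 0)

  s2 <- s[c(1, 2, 5), ]                 # no interaction: band rule bites
  pr2 <- prune_predictors(s2)
  expect_equal(pr2$drop, "ndvi")
  expect_equal(pr2$keep, "temperature")
})

test_that("Bayes R2 is bounded, near zero for pure noise, higher with structure", {
  set.seed(32)
  noise <- data.frame(presence = rbinom(800, 1, 0.5),
                      cluster_id = "C1", survey_id = "S1")
  f0 <- fit_hier_bernoulli(noise, "presence", chains = 2, iter = 500,
                           warmup = 200, seed = 3)
  r0 <- bayes_r2(f0)
  expect_true(all(r0$draws >= 0 & r0$draws <= 1))
  expect_lt(r0$mean, 0.05)

  pan <- simulate_response_panel(n_clusters = 15, days = 30,
                                 beta = c(x1 = 1.5), seed = 44)
  f1 <- fit_hier_bernoulli(pan, "presence", fixed = "x1",
                           chains = 2, iter = 500, warmup = 200, seed = 3)
  fnull <- fit_hier_bernoulli(pan, "presence",
                              chains = 2, iter = 500, warmup = 200, seed = 3)
  expect_gt(bayes_r2(f1)$mean, bayes_r2(fnull)$mean)
})

test_that("credible intervals cover zero effects at the nominal rate", {
  set.seed(33)
  covered <- 0L; total <- 0L
  for (r in 1:15) {
    pan <- simulate_response_panel(n_clusters = 12, n_surveys = 2, days = 20,
                                   beta = c(x1 = 0, x2 = 0), intercept = -0.5,
                                   sigma_cluster = 0.5, sigma_survey = 0.3,
                                   seed = 700 + r)
    fit <- fit_hier_bernoulli(pan, "presence", fixed = c("x1", "x2"),
                              chains = 2, iter = 600, warmup = 200,
                              seed = 800 + r)
    s <- posterior_summary(fit)
    for (pm in c("x1", "x2")) {
      row <- s[s$parameter == pm, ]
      total <- total + 1L
      if (row$ci95_low <= 0 && 0 <= row$ci95_high) covered <- covered + 1L
    }
  }
  expect_gte(covered / total, 0.93)
})
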