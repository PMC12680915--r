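# Group-time ATT estimator: closed-form oracles, method agreement,
# aggregation, bootstrap properties, parameter recovery, and the
# contamination guard against naive two-way fixed effects.

test_that("a hand-computed 6-row toy panel gives the 2x2 DiD answer exactly", {
  p <- make_panel(list(
    list(g = 2, y = c(0, 0.3, NA)),
    list(g = 3, y = c(0, 0.1, NA)),
    list(g = 3, y = c(0, 0.1, NA))
  ), n_months = 3)
  expect_equal(nrow(p), 6)
  a <- att_gt(p, g = 2, t = 2, no_cov())
  expect_equal(a$att, 0.2, tolerance = 1e-12)
  # identical outcome paths in both groups: att is exactly zero
  p0 <- make_panel(list(
    list(g = 2, y = c(0, 0.4, NA)),
    list(g = 3, y = c(0, 0.4, NA))
  ), n_months = 3)
  expect_equal(att_gt(p0, 2, 2, no_cov())$att, 0)
})

test_that("no-covariate att equals the closed-form DiD of means on random panels", {
  set.seed(99)
  for (r in 1:25) {
    n <- sample(30:80, 1)
    gs <- sample(2:6, n, replace = TRUE)
    ent <- ifelse(stats::runif(n) < 0.5, sample(1:6, n, replace = TRUE),
                  NA_integer_)
    coh <- make_cohort(g = gs, entitlement_month = ent, n_months = 6)
    p <- build_panel(coh)
    g <- sample(2:5, 1)
    t <- sample(setdiff(1:5, g - 1), 1)
    a <- att_gt(p, g, t, no_cov())
    if (a$estimable) {
      expect_equal(a$att, did_2x2(p, g, t), tolerance = 1e-10)
    }
  }
})

test_that("dr, ipw and outcome-regression agree when covariates carry no information", {
  # identical covariate multisets in the treated and comparison groups make
  # the fitted propensity exactly constant and the three estimands coincide
  set.seed(7)
  n2 <- 30
  covs <- data.frame(
    age_band = rep(c("75-79", "85-89", "90-94"), each = 10),
    sex = rep(c("male", "female"), 15)
  )
  coh <- make_cohort(g = rep(c(3, 9), each = n2),
                     entitlement_month = ifelse(stats::runif(2 * n2) < 0.4,
                                                sample(2:8, 2 * n2, TRUE),
                                                NA),
                     n_months = 10)
  coh$age_band <- rep(covs$age_band, 2)
  coh$sex <- rep(covs$sex, 2)
  p <- build_panel(coh)
  st <- function(m) estimator_settings(estimand_method = m,
                                       covariates = c("age_band", "sex"))
  a_dr <- att_gt(p, 3, 4, st("dr"))$att
  a_ipw <- att_gt(p, 3, 4, st("ipw"))$att
  a_reg <- att_gt(p, 3, 4, st("reg"))$att
  expect_lt(abs(a_dr - a_ipw), 1e-8)
  expect_lt(abs(a_dr - a_reg), 1e-8)
})

test_that("cell bookkeeping: base period, first group and last group are not estimable", {
  coh <- simulate_cohort(quick_config(n = 1500, seed = 51))
  p <- build_panel(coh)
  st <- no_cov()
  expect_false(att_gt(p, 1, 5, st)$estimable)        # no base period
  expect_false(att_gt(p, 24, 23, st)$estimable)      # no not-yet-treated left
  expect_false(att_gt(p, 10, 24, st)$estimable)      # t beyond last comparison
  expect_true(att_gt(p, 10, 23, st)$estimable)
  res <- att_gt_all(p, st)
  expect_false(any(res$atts$t == res$atts$g - 1))    # base period skipped
  expect_true(all(!res$atts$estimable[res$atts$g == 1]))
})

test_that("aggregation is the treated-count weighted mean of cohort effects", {
  coh <- make_cohort(
    g = rep(c(2, 3, 4), c(100, 300, 100)),
    entitlement_month = c(
      ifelse(seq_len(100) <= 40, 2L, NA),              # g=2: +0.4 at k=0
      ifelse(seq_len(300) <= 60, 2L,                   # g=3: 20% pre-loss,
             ifelse(seq_len(300) <= 135, 3L, NA)),     #      +0.25 at k=0
      ifelse(seq_len(100) <= 20, 2L,
             ifelse(seq_len(100) <= 35, 3L, NA))       # g=4: control paths
    ),
    n_months = 5
  )
  p <- build_panel(coh)
  res <- att_gt_all(p, no_cov())
  a22 <- res$atts[res$atts$g == 2 & res$atts$t == 2, ]
  a33 <- res$atts[res$atts$g == 3 & res$atts$t == 3, ]
  expect_equal(a22$att, 0.2, tolerance = 1e-12)
  expect_equal(a33$att, 0.1, tolerance = 1e-12)
  curve <- aggregate_event_study(res)
  expect_equal(curve$theta[curve$k == 0], 100 * 0.125, tolerance = 1e-10)
  # normalization: exactly zero at k = -1 with zero uncertainty
  expect_identical(curve$theta[curve$k == -1], 0)
  expect_identical(curve$se[curve$k == -1], 0)
})

test_that("a single treatment cohort yields no estimable cells", {
  coh <- make_cohort(g = rep(5, 50),
                     entitlement_month = c(rep(6L, 10), rep(NA, 40)))
  p <- build_panel(coh)
  expect_warning(res <- att_gt_all(p, no_cov()), "fewer than two")
  expect_true(all(!res$atts$estimable))
  expect_error(aggregate_event_study(res), "no estimable")
})

test_that("under the null about 5% of cell z-statistics exceed 1.96", {
  coh <- simulate_cohort(null_config(n = 5000, seed = 52,
                                     death_hazard_not_entitled = 0,
                                     death_hazard_entitled = 0))
  res <- att_gt_all(build_panel(coh), no_cov())
  a <- res$atts[res$atts$estimable & res$atts$se > 0, ]
  rate <- mean(abs(a$att / a$se) > 1.96)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.13)
})

test_that("multiplier bootstrap is seed-reproducible and respects duplication", {
  coh <- simulate_cohort(quick_config(n = 2500, seed = 53))
  p <- build_panel(coh)
  st <- no_cov(bootstrap_reps = 499, seed = 5)
  cv1 <- multiplier_bootstrap(aggregate_event_study(att_gt_all(p, st)), st)
  cv2 <- multiplier_bootstrap(aggregate_event_study(att_gt_all(p, st)), st)
  expect_identical(cv1, cv2)
  expect_error(multiplier_bootstrap(cv1, no_cov(bootstrap_reps = 0)),
               "bootstrap_reps")
  # exact duplication of every individual: same curve, se shrinks by 1/sqrt(2)
  coh2 <- rbind(coh, coh)
  coh2$id <- seq_len(nrow(coh2))
  class(coh2) <- class(coh); attr(coh2, "config") <- attr(coh, "config")
  cvd <- multiplier_bootstrap(aggregate_event_study(
    att_gt_all(build_panel(coh2), st)), st)
  expect_equal(cvd$theta, cv1$theta, tolerance = 1e-10)
  free <- cv1$se > 0
  ratio <- cvd$se[free] / cv1$se[free]
  expect_lt(abs(median(ratio) - 1 / sqrt(2)), 0.06)
})

test_that("with mortality off the estimated curve recovers the configured truth", {
  cfg <- quick_config(n = 10000, seed = 54,
                      death_hazard_not_entitled = 0,
                      death_hazard_entitled = 0)
  coh <- simulate_cohort(cfg)
  st <- estimator_settings(bootstrap_reps = 199, seed = 2)
  res <- event_study_pipeline(coh, settings = st, correct = FALSE)
  cv <- res$curve
  tr <- true_event_study(cfg)
  lag <- cv$k >= 0
  z <- (cv$theta[lag] - tr[as.character(cv$k[lag])]) / cv$se[lag]
  expect_lt(max(abs(z)), 3.5)
  expect_lt(mean(abs(z)), 1.6)
  # leads are centred on zero (no anticipation configured)
  lead <- cv$k < -1
  expect_lt(max(abs(cv$theta[lead] / cv$se[lead])), 3.5)
})

test_that("the estimator resists the early/late contamination that biases naive TWFE", {
  # two adoption waves with different treatment dynamics: group-time
  # estimation with not-yet-treated controls recovers the cohort-weighted
  # truth, while the two-way fixed-effects event-study regression (the
  # test-only oracle below) mixes cohorts and is visibly biased
  M <- 12
  base <- list(n_months = M, baseline_rate = 0.02, calendar_trend = 1,
               death_hazard_not_entitled = 0, death_hazard_entitled = 0,
               age_hazard_ratio = c("75-79" = 1, "80-84" = 1.5, "85-89" = 2,
                                    "90-94" = 2.5, "95-100" = 3),
               homecare_hazard_ratio = c(no = 1, yes = 2), frailty_share = 0)
  profA <- c(8, 8 * (8:0) / 8)    # early adopters: strong, slowly decaying
  profB <- c(1, 1, 0)             # late adopters: weak and short-lived
  cfgA <- do.call(quick_config, c(list(
    n = 15000, seed = 141, effect_profile = profA,
    partner_death_distribution = c(rep(1 / 6, 6), rep(0, 6))), base))
  cfgB <- do.call(quick_config, c(list(
    n = 15000, seed = 241, effect_profile = profB,
    partner_death_distribution = c(rep(0, 6), rep(1 / 6, 6))), base))
  cohA <- simulate_cohort(cfgA)
  cohB <- simulate_cohort(cfgB)
  cohB$id <- cohB$id + nrow(cohA)
  coh <- rbind(cohA, cohB)
  class(coh) <- class(cohA)
  p <- build_panel(coh, n_months = M)
  res <- aggregate_event_study(att_gt_all(p, no_cov()))
  trA <- true_event_study(cfgA)
  trB <- true_event_study(cfgB)
  ng <- table(factor(coh$g, levels = 1:M))
  truth <- sapply(0:6, function(k) {
    gs <- 2:(M - 1)
    gs <- gs[gs + k <= M - 1]
    w <- ng[gs]
    sum(w * ifelse(gs <= 6, trA[as.character(k)],
                   trB[as.character(k)])) / sum(w)
  })

  # TWFE oracle: exact two-way within transformation (balanced panel) and
  # OLS on the saturated event-time dummies, k = -1 omitted
  ks <- setdiff(sort(unique(p$k)), -1)
  D <- sapply(ks, function(k) as.numeric(p$k == k))
  Z <- cbind(p$Y, D)
  fid <- match(p$id, unique(p$id))
  Zt <- Z - (rowsum(Z, fid) / as.vector(table(fid)))[fid, ] -
    (rowsum(Z, p$s) / as.vector(table(p$s)))[p$s, ] +
    matrix(colMeans(Z), nrow(Z), ncol(Z), byrow = TRUE)
  fit <- stats::lm.fit(Zt[, -1, drop = FALSE], Zt[, 1])
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  twfe <- 100 * cf[match(0:6, ks)]

  cs <- res$theta[match(0:6, res$k)]
  cs_dev <- max(abs(cs - truth))
  twfe_dev <- max(abs(twfe - truth))
  expect_lt(cs_dev, 0.8)
  expect_gt(twfe_dev, 1.0)
  expect_gt(twfe_dev, 2 * cs_dev)
})

test_that("stratified runs recover stratum-specific effects and partition the cohort", {
  cfg1 <- quick_config(n = 6000, seed = 55,
                       effect_profile = 2 * default_effect_profile(),
                       baseline_rate = 0.0025, calendar_trend = 1,
                       death_hazard_not_entitled = 0,
                       death_hazard_entitled = 0)
  cfg2 <- quick_config(n = 6000, seed = 56,
                       baseline_rate = 0.0025, calendar_trend = 1,
                       death_hazard_not_entitled = 0,
                       death_hazard_entitled = 0)
  c1 <- simulate_cohort(cfg1)
  c2 <- simulate_cohort(cfg2)
  c1$sex <- "male"
  c2$sex <- "female"
  c2$id <- c2$id + nrow(c1)
  coh <- rbind(c1, c2)
  class(coh) <- class(c1)
  st <- no_cov(bootstrap_reps = 99, seed = 3)
  out <- stratified_run(coh, strata = "sex", settings = st, correct = FALSE)
  expect_setequal(names(out), c("male", "female"))
  expect_equal(out$male$n + out$female$n, nrow(coh))
  th <- function(r, k) r$curve$theta[r$curve$k == k]
  se <- function(r, k) r$curve$se[r$curve$k == k]
  expect_lt(abs(th(out$male, 3) - 3.0), 3.5 * se(out$male, 3))
  expect_lt(abs(th(out$female, 3) - 1.5), 3.5 * se(out$female, 3))
  expect_gt(th(out$male, 3) - th(out$female, 3), 0.5)
  # trivial stratifier reproduces the unstratified run
  allres <- stratified_run(c2, strata = "all", settings = st, correct = FALSE)
  direct <- event_study_pipeline(c2, settings = st, correct = FALSE)
  expect_equal(allres$all$curve$theta, direct$curve$theta)
  # empty stratum is skipped with a warning
  f <- factor(rep("x", nrow(c2)), levels = c("x", "y"))
  expect_warning(stratified_run(c2, strata = f, settings = st,
                                correct = FALSE), "empty")
})

test_that("overlap failure is reported loudly with the offending cell", {
  # a covariate that perfectly predicts treatment-group membership
  coh <- make_cohort(g = rep(c(3, 6), each = 40),
                     entitlement_month = rep(c(4L, NA), 40))
  coh$homecare_self <- coh$g == 3
  p <- build_panel(coh)
  st <- estimator_settings(covariates = "homecare_self")
  expect_error(att_gt(p, 3, 4, st), "no overlap.*g = 3, t = 4")
  # the batch loop records such cells as not estimable instead of dying
  expect_warning(res <- att_gt_all(p, st), "without propensity overlap")
  bad <- res$atts[res$atts$g == 3 & res$atts$t == 4, ]
  expect_false(bad$estimable)
  expect_match(bad$reason, "no overlap")
})
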