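## Synthetic registry-style cohort generator.
##
## One row per surviving spouse. Treatment is the partner's death month g
## (staggered, by default uniform over the 24-month window); the outcome is an
## absorbing entitlement to institutional long-term care; own mortality occurs
## only after partner loss, with a higher hazard among the entitled. The
## bereavement effect is realised as an exact pull-forward timing shift of
## counterfactual entitlements, so the implied event-study profile Delta(k)
## equals the configured one and every downstream stage can be validated by
## parameter recovery.

#' Default true effect profile
#'
#' Additive lift, in percentage points, of the cumulative entitlement
#' probability at event times k = 0, 1, ... after partner loss. The default
#' rises to a 1.5 percentage-point peak 3 months after widowhood and decays
#' linearly to zero at 10 months, mirroring the short-lived entitlement
#' response typically reported for spousal bereavement.
#'
#' @param peak Peak lift in percentage points.
#' @param peak_at Event time (months) of the peak.
#' @param horizon Event time at which the profile returns to zero.
#' @return Numeric vector of length `horizon + 1`, element j is Delta(j - 1).
#' @export
default_effect_profile <- function(peak = 1.5, peak_at = 3, horizon = 10) {
  rise <- peak * c(1 / 3, 2 / 3, 0.9, 1)[seq_len(peak_at + 1)]
  if (peak_at != 3) rise <- peak * seq_len(peak_at + 1) / (peak_at + 1)
  decay <- peak * (horizon - seq(peak_at + 1, horizon)) / (horizon - peak_at)
  c(rise, decay)
}

#' Generator configuration for synthetic bereavement cohorts
#'
#' Assembles and validates all data-generating assumptions: covariate
#' marginals, the distribution of partner-death months, piecewise-constant
#' baseline entitlement hazards by covariate cell (age band and home-care use
#' dominate, with a two-point unobserved frailty multiplier and a mild
#' calendar decline), the true event-study effect profile, and post-loss
#' mortality hazards by current entitlement status. When `baseline_rate`,
#' `calendar_trend` or `death_hazard_not_entitled` are left `NULL` they are
#' calibrated numerically (see [calibrate_generator()]) so that the default
#' cohort reproduces the printed study marginals: 6.9% entitled before partner
#' loss, 5.2% at or after, and 6.6% dying before the end of the window.
#'
#' @param n_individuals Cohort size.
#' @param n_months Length of the observation window in months (default 24).
#' @param seed Integer master seed.
#' @param covariate_marginals Data frame as returned by [default_marginals()].
#' @param partner_death_distribution Probability vector over months
#'   `1..n_months`; default uniform ("roughly the same number of individuals
#'   lose their partner each month").
#' @param effect_profile True effect profile Delta(k), k = 0..horizon, in
#'   percentage points; must rise to a single peak and decay to exactly zero
#'   at its last element. See [default_effect_profile()].
#' @param pg_share Fraction of entitlements typed psycho-geriatric.
#' @param death_hazard_entitled,death_hazard_not_entitled Monthly post-loss
#'   mortality probabilities by current entitlement status. If
#'   `death_hazard_not_entitled` is `NULL` both are calibrated with their
#'   ratio fixed at 25/6.
#' @param anticipation_dip Probability that a counterfactual entitlement in
#'   the four months before partner loss is postponed to after the loss
#'   (default 0 = off), producing the pre-loss dip in leads.
#' @param age_hazard_ratio,homecare_hazard_ratio Relative baseline entitlement
#'   hazards across age bands and home-care use.
#' @param frailty_share,frailty_ratio Two-point unobserved frailty mixture:
#'   a `frailty_share` fraction carries hazard multiplier `frailty_ratio`, the
#'   rest a multiplier chosen so the mean multiplier is 1.
#' @param baseline_rate Baseline monthly entitlement hazard scale `b` (hazard
#'   of the reference cell in month 1); `NULL` = calibrate.
#' @param calendar_trend Monthly multiplicative calendar trend `d` on the
#'   baseline hazard; `NULL` = calibrate.
#' @param partner_homecare_share Fraction whose deceased partner used home
#'   care before death.
#' @return An object of class `ltc_config` (a list).
#' @export
#' @examples
#' cfg <- generator_config(n_individuals = 1000, seed = 1,
#'                         baseline_rate = 0.004, calendar_trend = 1,
#'                         death_hazard_not_entitled = 0.006,
#'                         death_hazard_entitled = 0.025)
#' round(true_event_study(cfg)[1:6], 2)
generator_config <- function(n_individuals = 48997,
                             n_months = 24,
                             seed = 1L,
                             covariate_marginals = default_marginals(),
                             partner_death_distribution = NULL,
                             effect_profile = default_effect_profile(),
                             pg_share = 0.60,
                             death_hazard_entitled = NULL,
                             death_hazard_not_entitled = NULL,
                             anticipation_dip = 0,
                             age_hazard_ratio = c("75-79" = 1, "80-84" = 2.2,
                                                  "85-89" = 4.5, "90-94" = 8,
                                                  "95-100" = 12),
                             homecare_hazard_ratio = c(no = 1, yes = 7),
                             frailty_share = 0.2,
                             frailty_ratio = 3,
                             baseline_rate = NULL,
                             calendar_trend = NULL,
                             partner_homecare_share = 0.68) {
  stopifnot(n_individuals >= 1, n_months >= 2)
  if (is.null(partner_death_distribution)) {
    partner_death_distribution <- rep(1 / n_months, n_months)
  }
  stopifnot(length(partner_death_distribution) == n_months,
            all(partner_death_distribution >= 0))
  partner_death_distribution <- partner_death_distribution /
    sum(partner_death_distribution)

  validate_effect_profile(effect_profile)
  stopifnot(pg_share >= 0, pg_share <= 1,
            anticipation_dip >= 0, anticipation_dip <= 1,
            partner_homecare_share >= 0, partner_homecare_share <= 1,
            frailty_share >= 0, frailty_share < 1, frailty_ratio >= 1)

  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_months = as.integer(n_months),
    seed = as.integer(seed),
    covariate_marginals = covariate_marginals,
    partner_death_distribution = partner_death_distribution,
    effect_profile = effect_profile,
    pg_share = pg_share,
    death_hazard_entitled = death_hazard_entitled,
    death_hazard_not_entitled = death_hazard_not_entitled,
    anticipation_dip = anticipation_dip,
    age_hazard_ratio = age_hazard_ratio,
    homecare_hazard_ratio = homecare_hazard_ratio,
    frailty_share = frailty_share,
    frailty_ratio = frailty_ratio,
    baseline_rate = baseline_rate,
    calendar_trend = calendar_trend,
    partner_homecare_share = partner_homecare_share
  ), class = "ltc_config")

  needs_cal <- is.null(cfg$baseline_rate) || is.null(cfg$calendar_trend) ||
    is.null(cfg$death_hazard_not_entitled)
  if (needs_cal) cfg <- calibrate_generator(cfg)
  if (is.null(cfg$death_hazard_entitled)) {
    cfg$death_hazard_entitled <- cfg$death_hazard_not_entitled * 25 / 6
  }
  stopifnot(cfg$death_hazard_entitled >= 0, cfg$death_hazard_entitled <= 1,
            cfg$death_hazard_not_entitled >= 0,
            cfg$death_hazard_not_entitled <= 1)
  validate_config_cells(cfg)
  cfg
}

#' @export
print.ltc_config <- function(x, ...) {
  cat("<ltc_config>\n")
  cat(sprintf("  n = %d persons, window = %d months, seed = %d\n",
              x$n_individuals, x$n_months, x$seed))
  cat(sprintf("  baseline hazard b = %.5f, calendar trend d = %.4f\n",
              x$baseline_rate, x$calendar_trend))
  cat(sprintf("  death hazards: entitled %.4f, not entitled %.4f per month\n",
              x$death_hazard_entitled, x$death_hazard_not_entitled))
  cat(sprintf("  effect profile: peak %.2f pp at k = %d, zero at k = %d\n",
              max(x$effect_profile), which.max(x$effect_profile) - 1L,
              length(x$effect_profile) - 1L))
  invisible(x)
}

validate_effect_profile <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) >= 1, all(is.finite(delta)),
            all(delta >= 0))
  if (all(delta == 0)) return(invisible(TRUE))
  pk <- which.max(delta)
  if (is.unsorted(delta[seq_len(pk)]) ||
      is.unsorted(rev(delta[pk:length(delta)]))) {
    stop("effect_profile must rise to a single peak and then decay")
  }
  if (delta[length(delta)] != 0) {
    stop("effect_profile must end at exactly zero (the decay horizon)")
  }
  invisible(TRUE)
}

## --- hazard cells -----------------------------------------------------------

## One row per (age band x home-care x frailty) cell with population weight
## and hazard multiplier. Only these covariates move the baseline hazard.
hazard_cells <- function(cfg) {
  pr <- marginal_probs(cfg$covariate_marginals)
  age_p <- pr$age_band
  hc_p <- pr$homecare_self
  stopifnot(identical(names(age_p), names(cfg$age_hazard_ratio)),
            identical(names(hc_p), names(cfg$homecare_hazard_ratio)))
  fr_ratio <- c(low = (1 - cfg$frailty_share * cfg$frailty_ratio) /
                  (1 - cfg$frailty_share),
                high = cfg$frailty_ratio)
  if (fr_ratio[["low"]] < 0) stop("frailty mixture has mean multiplier > 1")
  fr_p <- c(low = 1 - cfg$frailty_share, high = cfg$frailty_share)
  g <- expand.grid(age = names(age_p), hc = names(hc_p),
                   fr = names(fr_p), stringsAsFactors = FALSE)
  g$weight <- age_p[g$age] * hc_p[g$hc] * fr_p[g$fr]
  g$mult <- cfg$age_hazard_ratio[g$age] * cfg$homecare_hazard_ratio[g$hc] *
    fr_ratio[g$fr]
  g
}

## Extended monthly hazard matrix (cells x months 1..n_months + horizon):
## counterfactual entitlements are tracked past the window so that a loss late
## in the window still has a populated pull-forward pool.
hazard_matrix <- function(cfg, b = cfg$baseline_rate,
                          d = cfg$calendar_trend, check = FALSE) {
  cells <- hazard_cells(cfg)
  S <- cfg$n_months + length(cfg$effect_profile) - 1L
  lam <- outer(b * cells$mult, d^(seq_len(S) - 1))
  if (any(lam >= 1)) {
    if (check) {
      bad <- which(rowSums(lam >= 1) > 0)[1]
      stop(sprintf(
        "calibration error: monthly entitlement hazard >= 1 in cell (age %s, homecare %s, frailty %s)",
        cells$age[bad], cells$hc[bad], cells$fr[bad]))
    }
    lam <- pmin(lam, 0.95)   # probing far from the solution; capped silently
  }
  lam
}

validate_config_cells <- function(cfg) {
  invisible(hazard_matrix(cfg, check = TRUE)) # hazard validity, names cell
  invisible(effect_pull(cfg, check = TRUE))   # pull feasibility, names k
}

## --- pull-forward realisation of the effect profile ------------------------

## Cohort-specific event-time pull probabilities pi_j(g) for
## j = peak+1 .. horizon, and the rise distribution q over 0..peak. A
## counterfactual entitlement falling j months after partner loss of cohort g
## is advanced, with probability pi_j(g), to g + r, r ~ q. Within each cohort
## the implied event-study curve then equals the configured Delta exactly
## (sum_{j>k} pi_j(g) P_j(g) telescopes to Delta(k)), so any aggregation over
## any subset of cohorts is unbiased for the configured truth. For the latest
## cohorts, whose decay months fall beyond the observation window (g + j >
## n_months) and are never estimable, pi is capped at 1 where needed.
effect_pull <- function(cfg, lam = hazard_matrix(cfg), check = FALSE) {
  delta <- cfg$effect_profile / 100   # pp -> probability
  H <- length(delta) - 1L
  M <- cfg$n_months
  if (all(delta == 0)) {
    return(list(peak = 0L, horizon = H,
                pi = matrix(0, M, 0), q = numeric(0)))
  }
  peak <- which.max(delta) - 1L
  if (peak >= H) stop("effect_profile needs at least one decay month")
  cells <- hazard_cells(cfg)
  surv <- cbind(1, t(apply(1 - lam, 1, cumprod)))  # cells x (0..S)
  f <- surv[, seq_len(ncol(lam)), drop = FALSE] * lam  # P(e = s)
  ## P_j(g) = cohort-g probability of a counterfactual entitlement at event
  ## time j (population-weighted over hazard cells)
  jdec <- seq(peak + 1L, H)
  P <- vapply(jdec, function(j) {
    vapply(seq_len(M), function(g) sum(cells$weight * f[, g + j]), 0)
  }, numeric(M))                                   # M x length(jdec)
  drops <- delta[jdec] - delta[jdec + 1L]
  pi <- sweep(1 / P, 2, drops, `*`)
  inwin <- outer(seq_len(M), jdec, `+`) <= M
  if (check && any(pi[inwin] > 1 + 1e-12)) {
    bad <- which(pi > 1 + 1e-12 & inwin, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "calibration error: effect profile infeasible at event time k = %d for the cohort losing a partner in month %d (required pull probability %.2f > 1)",
      jdec[bad[2]], bad[1], max(pi[inwin])))
  }
  q <- (delta[seq_len(peak + 1)] - c(0, delta[seq_len(peak)])) / delta[peak + 1]
  list(peak = peak, horizon = H, pi = pmin(pi, 1), q = q)
}

#' True event-study curve implied by a generator configuration
#'
#' Ground truth for parameter-recovery tests: the additive lift, in
#' percentage points, of the treated cohort's cumulative entitlement
#' probability at each event time k after partner loss, before any mortality
#' selection.
#'
#' @param config An [generator_config()] object.
#' @return Named numeric vector Delta(k) for k = 0..`n_months - 1`.
#' @export
true_event_study <- function(config) {
  stopifnot(inherits(config, "ltc_config"))
  k <- 0:(config$n_months - 1)
  delta <- rep(0, length(k))
  prof <- config$effect_profile
  delta[seq_len(min(length(prof), length(k)))] <-
    prof[seq_len(min(length(prof), length(k)))]
  names(delta) <- k
  delta
}

## --- closed-form cohort expectations ----------------------------------------

#' Closed-form cohort-level expectations of a generator configuration
#'
#' Computes, by exact enumeration over hazard cells, partner-death months and
#' entitlement times, the population fractions the generator produces in
#' expectation: entitled before partner loss, entitled (and observed, i.e.
#' surviving to entitlement) at or after partner loss, and dying before the
#' end of the window. These are the quantities the calibration step matches
#' to the printed study marginals, and they double as an independent oracle
#' for the simulator in tests. The anticipation dip, when enabled, is not
#' part of this enumeration (calibration is defined at the default,
#' dip-off configuration).
#'
#' @param config An [generator_config()] object.
#' @param baseline_rate,calendar_trend,death_hazard_not_entitled Optional
#'   overrides of the corresponding config entries (used by the calibrator).
#' @return List with elements `pre_loss`, `post_loss`, `deaths` (fractions).
#' @export
cohort_expectations <- function(config,
                                baseline_rate = config$baseline_rate,
                                calendar_trend = config$calendar_trend,
                                death_hazard_not_entitled =
                                  config$death_hazard_not_entitled) {
  cfg <- config
  hN <- death_hazard_not_entitled
  hE <- if (is.null(cfg$death_hazard_entitled)) hN * 25 / 6 else
    cfg$death_hazard_entitled
  lam <- hazard_matrix(cfg, baseline_rate, calendar_trend)
  cells <- hazard_cells(cfg)
  M <- cfg$n_months
  pgdist <- cfg$partner_death_distribution
  pull <- effect_pull(cfg, lam)
  H <- pull$horizon

  surv <- cbind(1, t(apply(1 - lam, 1, cumprod)))
  f <- surv[, seq_len(ncol(lam)), drop = FALSE] * lam
  w <- cells$weight

  pre <- 0; post <- 0; death <- 0
  for (g in seq_len(M)) {
    pgw <- pgdist[g]
    if (pgw == 0) next
    Fpre <- 1 - surv[, g]                    # entitled before g
    jj <- 0:H
    fpost <- f[, g + jj, drop = FALSE]       # counterfactual, event times 0..H
    ## apply pulls: mass pi_j(g) moves from j in (peak, H] to r ~ q over 0..peak
    ft <- fpost
    if (length(pull$pi)) {
      moved_j <- seq(pull$peak + 1, H)
      moved <- sweep(fpost[, moved_j + 1, drop = FALSE], 2, pull$pi[g, ], `*`)
      ft[, moved_j + 1] <- ft[, moved_j + 1] - moved
      tot <- rowSums(moved)
      ft[, seq_len(pull$peak + 1)] <- ft[, seq_len(pull$peak + 1)] +
        outer(tot, pull$q)
    }
    ## event times H+1 .. M-g keep their counterfactual mass
    cap <- M - g
    extra_j <- if (cap > H) seq(H + 1, cap) else integer(0)
    fext <- if (length(extra_j)) f[, g + extra_j, drop = FALSE] else NULL

    ## observed post-loss entitlements: survive j months at hazard hN
    jin <- jj[jj <= cap]
    post_g <- rowSums(sweep(ft[, jin + 1, drop = FALSE], 2,
                            (1 - hN)^jin, `*`))
    if (length(extra_j)) {
      post_g <- post_g + rowSums(sweep(fext, 2, (1 - hN)^extra_j, `*`))
    }
    ## deaths by end of window: hazard hN for the first a = min(j, M-g)
    ## post-loss months, hE thereafter; pre-loss entitled have a = 0
    d_pre <- 1 - (1 - hE)^cap
    dh <- function(a) 1 - (1 - hN)^a * (1 - hE)^(cap - a)
    death_g <- Fpre * d_pre
    a_in <- pmin(jj, cap)
    death_g <- death_g + as.vector(ft %*% dh(a_in))
    if (length(extra_j)) {
      death_g <- death_g + as.vector(fext %*% dh(pmin(extra_j, cap)))
    }
    used <- Fpre + rowSums(ft) + if (length(extra_j)) rowSums(fext) else 0
    death_g <- death_g + (1 - used) * dh(cap)

    pre <- pre + pgw * sum(w * Fpre)
    post <- post + pgw * sum(w * post_g)
    death <- death + pgw * sum(w * death_g)
  }
  list(pre_loss = pre, post_loss = post, deaths = death)
}

#' Calibrate the generator to the printed study marginals
#'
#' Root-finding (Gauss-Seidel over three nested `uniroot` solves) for the
#' baseline hazard scale `b`, the monthly calendar trend `d` and the
#' non-entitled mortality hazard `h_N` (with the entitled hazard fixed at
#' 25/6 times `h_N`) such that the closed-form cohort expectations match the
#' target fractions: entitled before partner loss, entitled at or after, and
#' dead before the end of the window.
#'
#' @param config An `ltc_config` (possibly with `NULL` calibration slots).
#' @param targets Named vector with `pre`, `post`, `death` fractions.
#' @param tol Convergence tolerance on the target residuals.
#' @return The config with `baseline_rate`, `calendar_trend`,
#'   `death_hazard_not_entitled` and `death_hazard_entitled` filled in.
#' @export
calibrate_generator <- function(config,
                                targets = c(pre = 0.069, post = 0.052,
                                            death = 0.066),
                                tol = 1e-7) {
  cfg <- config
  key <- paste(deparse(targets), cfg$n_months, cfg$frailty_share,
               cfg$frailty_ratio, paste(cfg$age_hazard_ratio, collapse = ","),
               paste(cfg$homecare_hazard_ratio, collapse = ","),
               paste(round(cfg$effect_profile, 10), collapse = ","),
               paste(round(cfg$partner_death_distribution, 12), collapse = ","),
               sep = "|")
  free_b <- is.null(cfg$baseline_rate)
  free_d <- is.null(cfg$calendar_trend)
  free_h <- is.null(cfg$death_hazard_not_entitled)
  key <- paste(key, free_b, free_d, free_h,
               if (!free_b) cfg$baseline_rate, if (!free_d) cfg$calendar_trend,
               if (!free_h) cfg$death_hazard_not_entitled, sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) {
    cfg[names(hit)] <- hit
    return(cfg)
  }
  b <- if (free_b) 0.0007 else cfg$baseline_rate
  d <- if (free_d) 0.99 else cfg$calendar_trend
  hN <- if (free_h) 0.005 else cfg$death_hazard_not_entitled
  mrr <- max(hazard_cells(cfg)$mult)
  for (it in seq_len(40)) {
    if (free_b) b <- stats::uniroot(function(x)
      cohort_expectations(cfg, x, d, hN)$pre_loss - targets[["pre"]],
      c(1e-7, 0.9 / mrr / max(d, 1)^cfg$n_months), tol = 1e-11)$root
    if (free_d) d <- stats::uniroot(function(x)
      cohort_expectations(cfg, b, x, hN)$post_loss - targets[["post"]],
      c(0.85, 1.05), tol = 1e-10)$root
    if (free_h) hN <- stats::uniroot(function(x)
      cohort_expectations(cfg, b, d, x)$deaths - targets[["death"]],
      c(1e-6, 0.04), tol = 1e-11)$root
    e <- cohort_expectations(cfg, b, d, hN)
    res <- c(pre = e$pre_loss - targets[["pre"]],
             post = e$post_loss - targets[["post"]],
             death = e$deaths - targets[["death"]])
    res <- res[c(free_b, free_d, free_h)]
    if (!length(res) || max(abs(res)) < tol) break
  }
  if (length(res) && max(abs(res)) >= tol) {
    warning("generator calibration did not fully converge; residuals: ",
            paste(signif(res, 3), collapse = ", "))
  }
  out <- list(baseline_rate = b, calendar_trend = d,
              death_hazard_not_entitled = hN)
  if (is.null(cfg$death_hazard_entitled)) {
    out$death_hazard_entitled <- hN * 25 / 6
  }
  .calibration_cache[[key]] <- out
  cfg[names(out)] <- out
  cfg
}

.calibration_cache <- new.env(parent = emptyenv())

## --- simulation -------------------------------------------------------------

#' Simulate a synthetic bereavement cohort
#'
#' Draws one row per surviving spouse: baseline covariates from the
#' configured marginals, a partner-death month, an entitlement month (if any,
#' absorbing, possibly before partner loss), an entitlement type, and an own
#' death month (only ever after partner loss, with the hazard switching to
#' the entitled level once entitled). An entitlement pre-empted by death is
#' never observed and is recorded as absent. Identical seeds give identical
#' cohorts; each person's history depends only on their own row of draws.
#'
#' @param config An [generator_config()] object.
#' @return A data.frame of class `ltc_cohort` with columns `id`, `sex`,
#'   `age_band`, `ses_category`, `n_children_alive`, `has_daughter`,
#'   `homecare_self`, `homecare_partner`, `g` (partner-death month),
#'   `death_month` (NA if surviving the window), `entitlement_month` (NA if
#'   never entitled within the window), `entitlement_type`
#'   (`"PG"`/`"somatic"`/`"none"`). The config is attached as attribute
#'   `config`.
#' @export
#' @examples
#' cfg <- generator_config(n_individuals = 500, seed = 7,
#'                         baseline_rate = 0.004, calendar_trend = 1,
#'                         death_hazard_not_entitled = 0.006,
#'                         death_hazard_entitled = 0.025)
#' coh <- simulate_cohort(cfg)
#' table(coh$entitlement_type)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ltc_config"))
  cfg <- config
  n <- cfg$n_individuals
  M <- cfg$n_months
  pr <- marginal_probs(cfg$covariate_marginals)
  lam <- hazard_matrix(cfg)
  cells <- hazard_cells(cfg)
  pull <- effect_pull(cfg, lam)

  set.seed(cfg$seed)
  draw_cat <- function(p) {
    lv <- names(p)
    lv[findInterval(stats::runif(n), cumsum(p), left.open = TRUE) + 1L]
  }
  sex <- draw_cat(pr$sex)
  age_band <- draw_cat(pr$age_band)
  ses <- draw_cat(pr$ses_category)
  children_lv <- draw_cat(pr$n_children_alive)
  n_children <- as.integer(sub("\\+$", "", children_lv))
  has_daughter <- stats::runif(n) < 1 - 0.5^n_children
  homecare_self <- draw_cat(pr$homecare_self) == "yes"
  homecare_partner <- stats::runif(n) < cfg$partner_homecare_share
  frail <- stats::runif(n) < cfg$frailty_share
  g <- findInterval(stats::runif(n), cumsum(cfg$partner_death_distribution),
                    left.open = TRUE) + 1L

  ## counterfactual entitlement month from the cell's cumulative incidence
  cell_id <- match(paste(age_band, ifelse(homecare_self, "yes", "no"),
                         ifelse(frail, "high", "low")),
                   paste(cells$age, cells$hc, cells$fr))
  Fmat <- 1 - t(apply(1 - lam, 1, cumprod))   # cells x months, cum incidence
  u_e <- stats::runif(n)
  e <- rep(Inf, n)
  for (c_i in unique(cell_id)) {
    idx <- which(cell_id == c_i)
    pos <- findInterval(u_e[idx], Fmat[c_i, ], left.open = TRUE) + 1L
    e[idx] <- ifelse(pos > ncol(Fmat), Inf, pos)
  }

  u_pull <- stats::runif(n)
  u_q <- stats::runif(n)
  u_ant <- stats::runif(n)
  if (length(pull$pi)) {
    j <- e - g
    elig <- which(is.finite(e) & j > pull$peak & j <= pull$horizon)
    pij <- pull$pi[cbind(g[elig], j[elig] - pull$peak)]
    pulled <- elig[u_pull[elig] < pij]
    r <- findInterval(u_q, cumsum(pull$q), left.open = TRUE)
    e[pulled] <- g[pulled] + r[pulled]
  }
  if (cfg$anticipation_dip > 0 && length(pull$q)) {
    j <- e - g
    elig <- is.finite(e) & j >= -4 & j <= -1
    post <- elig & u_ant < cfg$anticipation_dip
    r <- findInterval(u_q, cumsum(pull$q), left.open = TRUE)
    e[post] <- g[post] + r[post]
  }

  ## mortality: only in months g+1..M; hazard h_N while not entitled at the
  ## start of the month, h_E from the month after entitlement
  hN <- cfg$death_hazard_not_entitled
  hE <- cfg$death_hazard_entitled
  a <- pmin(pmax(e - g, 0), M - g)            # post-loss months at h_N
  gN <- if (hN > 0) ceiling(log(stats::runif(n)) / log(1 - hN)) else
    rep(Inf, n)
  gE <- if (hE > 0) ceiling(log(stats::runif(n)) / log(1 - hE)) else
    rep(Inf, n)
  death <- ifelse(gN <= a, g + gN,
                  ifelse(a + gE <= M - g, g + a + gE, NA_real_))
  ## death at or before the entitlement month pre-empts the entitlement
  ent <- ifelse(is.finite(e) & e <= M & (is.na(death) | e < death), e,
                NA_real_)
  u_type <- stats::runif(n)
  type <- ifelse(is.na(ent), "none",
                 ifelse(u_type < cfg$pg_share, "PG", "somatic"))

  out <- data.frame(
    id = seq_len(n),
    sex = sex,
    age_band = age_band,
    ses_category = ses,
    n_children_alive = n_children,
    has_daughter = has_daughter,
    homecare_self = homecare_self,
    homecare_partner = homecare_partner,
    g = as.integer(g),
    death_month = as.integer(death),
    entitlement_month = as.integer(ent),
    entitlement_type = type,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- cfg
  class(out) <- c("ltc_cohort", "data.frame")
  out
}
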