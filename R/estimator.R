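## Staggered event-study estimator.
##
## Group-time average treatment effects ATT(g,t) with strictly
## not-yet-treated comparison groups and a universal base period g-1, doubly
## robust covariate adjustment (propensity score x outcome regression),
## aggregation to an event-study curve with weights proportional to treated
## group sizes, and multiplier-bootstrap inference on per-individual
## influence contributions.
##
## Because own mortality only occurs after partner loss, the comparison
## group for any cell is fully observed while the treated group is thinned
## by death at post-treatment outcome months. Each cell therefore contrasts
## per-period available-case means: the treated baseline mean is taken over
## the whole treatment cohort (complete by construction) and the treated
## follow-up mean over the survivors, so the selective-mortality bias of the
## lags has the closed-form level-composition form that the attrition module
## corrects. Calendar-time effects common to all individuals cancel within
## each (g,t) contrast and are not estimated as parameters.

#' Estimator settings
#'
#' @param estimand_method `"dr"` (doubly robust, the default), `"ipw"`
#'   (inverse probability weighting only) or `"reg"` (outcome regression
#'   only).
#' @param covariates Baseline covariate columns entering the propensity and
#'   outcome-regression models; `character(0)` gives the unadjusted
#'   difference of group means.
#' @param bootstrap_reps Number of multiplier-bootstrap draws.
#' @param bootstrap_weights `"rademacher"` or `"mammen"` external weights.
#' @param seed Seed for the bootstrap draws.
#' @param conf_level Level of the pointwise and simultaneous bands.
#' @return A list of class `ltc_settings`. The control group
#'   (not-yet-treated) and base period (universal, g-1) are fixed by design.
#' @export
estimator_settings <- function(estimand_method = c("dr", "ipw", "reg"),
                               covariates = c("age_band", "sex",
                                              "ses_category",
                                              "n_children_alive",
                                              "homecare_self"),
                               bootstrap_reps = 999L,
                               bootstrap_weights = c("rademacher", "mammen"),
                               seed = 1L,
                               conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  structure(list(
    estimand_method = match.arg(estimand_method),
    covariates = covariates,
    bootstrap_reps = as.integer(bootstrap_reps),
    bootstrap_weights = match.arg(bootstrap_weights),
    seed = as.integer(seed),
    conf_level = conf_level,
    control_group = "notyettreated",
    base_period = "universal"
  ), class = "ltc_settings")
}

## Person-level representation of the panel: wide outcome matrix Y (n x M,
## NA after death), group vector, covariate model matrix.
panel_prep <- function(panel, covariates) {
  stopifnot(inherits(panel, "ltc_panel") || is.data.frame(panel))
  M <- attr(panel, "n_months")
  if (is.null(M)) M <- max(panel$s)
  first <- !duplicated(panel$id)
  ids <- panel$id[first]
  n <- length(ids)
  Y <- matrix(NA_real_, n, M)
  Y[cbind(match(panel$id, ids), panel$s)] <- panel$Y
  per <- panel[first, , drop = FALSE]
  miss <- setdiff(covariates, names(per))
  if (length(miss)) {
    stop("covariates not present in the panel: ", paste(miss, collapse = ", "))
  }
  X <- if (length(covariates)) {
    stats::model.matrix(~ ., data = as.data.frame(per[, covariates,
                                                      drop = FALSE]))
  } else {
    matrix(1, n, 1)
  }
  list(ids = ids, n = n, M = M, Y = Y, g = per$g,
       death_month = per$death_month, X = X,
       adjusted = length(covariates) > 0)
}

not_estimable <- function(g, t, reason) {
  structure(list(g = g, t = t, att = NA_real_, se = NA_real_,
                 n_treated = NA_integer_, n_control = NA_integer_,
                 influence = NULL, estimable = FALSE, reason = reason),
            class = "gt_att")
}

## The (g,t) cell estimator on a prepared panel. Returns the point estimate,
## analytic standard error and the per-individual influence contributions on
## the full-cohort scale (zero outside the cell sample).
att_gt_core <- function(prep, g, t, settings, keep_influence = TRUE) {
  M <- prep$M
  if (g < 2) return(not_estimable(g, t, "no pre-treatment base period"))
  if (t < 1 || t > M) return(not_estimable(g, t, "outcome month outside window"))
  b0 <- g - 1L
  if (t == b0) return(not_estimable(g, t, "base period"))
  Tr <- prep$g == g
  Cp <- prep$g > max(t, b0) & prep$g != g   # untreated at both t and g-1
  if (!any(Tr)) return(not_estimable(g, t, "no treated"))
  if (!any(Cp)) return(not_estimable(g, t, "no not-yet-treated comparison"))
  Yb <- prep$Y[, b0]
  Yt <- prep$Y[, t]
  TrB <- Tr & !is.na(Yb)           # complete: deaths only after partner loss
  TrA <- Tr & !is.na(Yt)           # survivors at the outcome month
  Cok <- Cp & !is.na(Yb) & !is.na(Yt)
  if (!any(TrA) || !any(TrB)) return(not_estimable(g, t, "no observed treated"))
  if (!any(Cok)) return(not_estimable(g, t, "no observed comparison"))

  n <- prep$n
  dY <- Yt - Yb
  sub <- TrB | Cok
  if (prep$adjusted) {
    Xs <- prep$X[sub, , drop = FALSE]
    D <- as.numeric(Tr[sub])
    fit <- suppressWarnings(stats::glm.fit(Xs, D,
                                           family = stats::binomial()))
    ps <- numeric(n)
    ps[sub] <- fit$fitted.values
    if (any(ps[sub] > 0.999)) {
      stop(sprintf("no overlap: propensity score at 1 for cell (g = %d, t = %d)",
                   g, t))
    }
    orf <- stats::lm.fit(prep$X[Cok, , drop = FALSE], dY[Cok])
    cf <- orf$coefficients
    cf[is.na(cf)] <- 0
    mu <- as.vector(prep$X %*% cf)
  } else {
    ps <- rep(mean(Tr[sub]), n) * as.numeric(sub)
    mu <- rep(mean(dY[Cok]), n)
  }

  w <- numeric(n)
  w[Cok] <- ps[Cok] / (1 - ps[Cok])
  W <- sum(w)
  nA <- sum(TrA); nB <- sum(TrB)
  m1 <- sum(Yt[TrA]) / nA                      # treated follow-up mean
  m2 <- sum(Yb[TrB]) / nB                      # treated baseline mean
  m3 <- sum(mu[TrB]) / nB                      # OR trend at treated X
  m4 <- sum(w[Cok] * (dY[Cok] - mu[Cok])) / W  # reweighted OR residual
  m5 <- sum(w[Cok] * dY[Cok]) / W              # IPW trend

  method <- settings$estimand_method
  att <- switch(method,
                dr = m1 - m2 - (m3 + m4),
                reg = m1 - m2 - m3,
                ipw = m1 - m2 - m5)

  psi <- numeric(n)
  psi[TrA] <- psi[TrA] + n * (Yt[TrA] - m1) / nA
  psi[TrB] <- psi[TrB] - n * (Yb[TrB] - m2) / nB
  if (method %in% c("dr", "reg")) {
    psi[TrB] <- psi[TrB] - n * (mu[TrB] - m3) / nB
  }
  if (method == "dr") {
    psi[Cok] <- psi[Cok] - n * w[Cok] * (dY[Cok] - mu[Cok] - m4) / W
  } else if (method == "ipw") {
    psi[Cok] <- psi[Cok] - n * w[Cok] * (dY[Cok] - m5) / W
  }
  se <- sqrt(mean(psi^2) / n)

  structure(list(g = g, t = t, att = att, se = se,
                 n_treated = as.integer(sum(Tr)),
                 n_control = as.integer(sum(Cok)),
                 influence = if (keep_influence) psi else NULL,
                 estimable = TRUE, reason = NA_character_),
            class = "gt_att")
}

#' Group-time average treatment effect ATT(g, t)
#'
#' Doubly robust contrast of outcome changes from the universal base period
#' g-1 to month t between the cohort losing a partner in month g and the
#' strictly not-yet-treated comparison group (partner death after both
#' periods). With no covariates this reduces exactly to the 2x2
#' difference-in-differences of available-case group means.
#'
#' @param panel An `ltc_panel`.
#' @param g Treatment (partner-death) month of the cohort.
#' @param t Outcome month.
#' @param settings An [estimator_settings()] object.
#' @return An object of class `gt_att`: point estimate (`att`, on the
#'   probability scale), analytic `se`, group sizes, and per-individual
#'   influence contributions.
#' @export
att_gt <- function(panel, g, t, settings = estimator_settings()) {
  prep <- panel_prep(panel, settings$covariates)
  att_gt_core(prep, g, t, settings)
}

#' @export
print.gt_att <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("ATT(g=%d, t=%d): not estimable (%s)\n", x$g, x$t, x$reason))
  } else {
    cat(sprintf("ATT(g=%d, t=%d) = %.5f (se %.5f), %d treated, %d comparison\n",
                x$g, x$t, x$att, x$se, x$n_treated, x$n_control))
  }
  invisible(x)
}

#' All estimable group-time effects
#'
#' Computes ATT(g, t) for every observed treatment cohort g and outcome
#' month t (the pre-period cells, t < g-1, are the placebo/lead estimates
#' against the same universal base period). Cells without a base period,
#' without not-yet-treated comparisons, at the base period itself, or
#' without propensity overlap (with a warning) are
#' recorded as not estimable. Influence contributions are accumulated
#' directly at the event-time level with weights proportional to treated
#' cohort sizes, ready for [aggregate_event_study()].
#'
#' @inheritParams att_gt
#' @return An object of class `ltc_attset`: a data.frame of cell results
#'   (`$atts`) plus the event-time influence matrix.
#' @export
att_gt_all <- function(panel, settings = estimator_settings()) {
  prep <- panel_prep(panel, settings$covariates)
  groups <- sort(unique(prep$g))
  M <- prep$M
  if (length(groups) < 2) {
    warning("fewer than two treatment cohorts: no not-yet-treated comparison exists")
  }
  ks <- seq(-(M - 1L), M - 1L)
  inf_sum <- matrix(0, prep$n, length(ks), dimnames = list(NULL, ks))
  w_sum <- att_wsum <- setNames(numeric(length(ks)), ks)
  rows <- vector("list", length(groups) * M)
  ri <- 0L
  for (g in groups) {
    ng <- sum(prep$g == g)
    for (t in seq_len(M)) {
      if (t == g - 1L) next
      ## a single cell without covariate overlap (e.g. a rare factor level
      ## concentrated in one tiny group) is excluded and logged, not fatal
      cell <- tryCatch(att_gt_core(prep, g, t, settings),
                       error = function(e) {
                         if (!grepl("no overlap", conditionMessage(e))) stop(e)
                         not_estimable(g, t, conditionMessage(e))
                       })
      ri <- ri + 1L
      rows[[ri]] <- data.frame(g = g, t = t, k = t - g, att = cell$att,
                               se = cell$se, n_treated = cell$n_treated,
                               n_control = cell$n_control,
                               estimable = cell$estimable,
                               reason = cell$reason,
                               stringsAsFactors = FALSE)
      if (cell$estimable) {
        kc <- as.character(t - g)
        inf_sum[, kc] <- inf_sum[, kc] + ng * cell$influence
        att_wsum[kc] <- att_wsum[kc] + ng * cell$att
        w_sum[kc] <- w_sum[kc] + ng
      }
    }
  }
  atts <- do.call(rbind, rows[seq_len(ri)])
  dropped <- sum(grepl("no overlap", atts$reason))
  if (dropped > 0) {
    warning(dropped, " cell(s) without propensity overlap excluded; see the ",
            "'reason' column of the cell table")
  }
  keep <- w_sum > 0
  structure(list(
    atts = atts,
    influence = inf_sum[, keep, drop = FALSE],
    theta = att_wsum[keep] / w_sum[keep],
    weights = w_sum[keep],
    n = prep$n,
    ids = prep$ids,
    n_months = M,
    settings = settings
  ), class = "ltc_attset")
}

#' @export
print.ltc_attset <- function(x, ...) {
  est <- x$atts$estimable
  cat(sprintf("<ltc_attset> %d cells (%d estimable), %d persons, window %d months\n",
              nrow(x$atts), sum(est), x$n, x$n_months))
  invisible(x)
}

#' Aggregate group-time effects into an event-study curve
#'
#' For each event time k, the weighted mean of ATT(g, g+k) over the cohorts
#' g for which the cell is estimable, with weights proportional to the
#' number of treated individuals in each cohort; influence contributions are
#' aggregated with the same weights. The effect at k = -1 is identically
#' zero (the universal base period) and is included as the reference point.
#' Standard errors and confidence bands come from [multiplier_bootstrap()];
#' this function fills in analytic influence-function standard errors so
#' the curve is usable without bootstrapping.
#'
#' @param atts An `ltc_attset` from [att_gt_all()].
#' @param panel Optional; accepted for interface symmetry, unused (the
#'   attset carries everything needed).
#' @return An object of class `ltc_event_study`: a data.frame with columns
#'   `k`, `theta` (percentage points), `se`, `ci_lo`, `ci_hi`, `band_lo`,
#'   `band_hi`, `corrected`; the influence matrix rides along as an
#'   attribute.
#' @export
aggregate_event_study <- function(atts, panel = NULL) {
  stopifnot(inherits(atts, "ltc_attset"))
  if (!length(atts$theta)) {
    stop("no estimable group-time cells to aggregate")
  }
  k <- as.integer(names(atts$theta))
  inf <- sweep(atts$influence, 2, atts$weights, `/`)
  ## reference point k = -1: structurally zero
  if (!(-1L %in% k)) {
    k <- c(k, -1L)
    inf <- cbind(inf, `-1` = 0)
    theta <- c(atts$theta, `-1` = 0)
  } else {
    theta <- atts$theta
  }
  o <- order(k)
  k <- k[o]
  theta <- as.numeric(theta[o])
  inf <- inf[, o, drop = FALSE]
  se <- sqrt(colMeans(inf^2) / atts$n)
  z <- stats::qnorm(1 - (1 - atts$settings$conf_level) / 2)
  curve <- data.frame(
    k = k,
    theta = 100 * theta,
    se = 100 * se,
    ci_lo = 100 * (theta - z * se),
    ci_hi = 100 * (theta + z * se),
    band_lo = NA_real_,
    band_hi = NA_real_,
    corrected = FALSE
  )
  attr(curve, "influence") <- inf
  attr(curve, "n") <- atts$n
  attr(curve, "settings") <- atts$settings
  attr(curve, "crit_val") <- NA_real_
  class(curve) <- c("ltc_event_study", "data.frame")
  curve
}

#' Multiplier-bootstrap inference for an event-study curve
#'
#' Perturbs the aggregated per-individual influence contributions with
#' i.i.d. external weights (one draw per individual, not per person-month),
#' recomputing the whole curve for each draw. Standard errors use the
#' bootstrap interquartile range rescaled by the normal quantile spread
#' (robust to heavy-tailed draws); the simultaneous band uses the sup-t
#' statistic over event times. Reproducible under the settings seed.
#'
#' @param curve An `ltc_event_study` from [aggregate_event_study()].
#' @param settings An [estimator_settings()]; defaults to the settings the
#'   curve was built with.
#' @return The curve with `se`, `ci_lo`/`ci_hi` (pointwise) and
#'   `band_lo`/`band_hi` (simultaneous) replaced by bootstrap values, and
#'   the sup-t critical value in attribute `crit_val`.
#' @export
multiplier_bootstrap <- function(curve, settings = attr(curve, "settings")) {
  stopifnot(inherits(curve, "ltc_event_study"))
  B <- settings$bootstrap_reps
  if (is.null(B) || B < 1) stop("bootstrap_reps must be at least 1")
  inf <- attr(curve, "influence")
  if (is.null(inf)) stop("curve carries no influence contributions")
  n <- attr(curve, "n")
  set.seed(settings$seed)
  ## draw the external weights in blocks to keep the B x n matrix small
  block <- max(1L, min(B, ceiling(2e7 / n)))
  R <- matrix(NA_real_, B, ncol(inf))
  done <- 0L
  while (done < B) {
    nb <- min(block, B - done)
    V <- if (settings$bootstrap_weights == "rademacher") {
      matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    } else {
      phi <- (sqrt(5) + 1) / (2 * sqrt(5))
      lo <- -(sqrt(5) - 1) / 2
      hi <- (sqrt(5) + 1) / 2
      matrix(ifelse(stats::runif(nb * n) < phi, lo, hi), nb, n)
    }
    R[done + seq_len(nb), ] <- 100 * (V %*% inf) / n   # percentage points
    done <- done + nb
  }
  qs <- apply(R, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  bse <- (qs[2, ] - qs[1, ]) / (stats::qnorm(0.75) - stats::qnorm(0.25))
  free <- bse > 0                # excludes the k = -1 reference point
  tb <- apply(abs(R[, free, drop = FALSE]) /
                rep(bse[free], each = B), 1, max)
  crit <- stats::quantile(tb, settings$conf_level, names = FALSE)
  z <- stats::qnorm(1 - (1 - settings$conf_level) / 2)
  curve$se <- bse
  curve$ci_lo <- curve$theta - z * bse
  curve$ci_hi <- curve$theta + z * bse
  curve$band_lo <- curve$theta - crit * bse
  curve$band_hi <- curve$theta + crit * bse
  curve$ci_lo[!free] <- curve$ci_hi[!free] <- curve$theta[!free]
  curve$band_lo[!free] <- curve$band_hi[!free] <- curve$theta[!free]
  attr(curve, "crit_val") <- crit
  curve
}

#' @export
print.ltc_event_study <- function(x, digits = 3, ...) {
  lab <- if (any(x$corrected)) "mortality-corrected" else "uncorrected"
  cat(sprintf("<ltc_event_study> %s, %d event times (k = %d..%d)\n",
              lab, nrow(x), min(x$k), max(x$k)))
  print.data.frame(round_df(as.data.frame(x)[, c("k", "theta", "se",
                                                 "ci_lo", "ci_hi")], digits),
                   row.names = FALSE)
  invisible(x)
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], round, digits)
  d
}

#' Plot an event-study curve
#'
#' @param x An `ltc_event_study`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ltc_event_study <- function(x, ...) {
  has_band <- !all(is.na(x$band_lo))
  ylim <- range(c(x$ci_lo, x$ci_hi, x$band_lo, x$band_hi, 0), na.rm = TRUE)
  graphics::plot(x$k, x$theta, type = "n", ylim = ylim,
                 xlab = "months since partner loss",
                 ylab = "effect on entitlement probability (pp)", ...)
  if (has_band) {
    graphics::polygon(c(x$k, rev(x$k)), c(x$band_lo, rev(x$band_hi)),
                      col = "grey90", border = NA)
  }
  graphics::polygon(c(x$k, rev(x$k)), c(x$ci_lo, rev(x$ci_hi)),
                    col = "grey75", border = NA)
  graphics::abline(h = 0, lty = 2)
  graphics::abline(v = -0.5, lty = 3)
  graphics::lines(x$k, x$theta, type = "b", pch = 16)
  invisible(x)
}

#' Run the full pipeline within each stratum
#'
#' Splits the cohort by a baseline stratifier and runs, independently per
#' stratum, panel construction, all group-time effects, event-study
#' aggregation, the multiplier bootstrap and (optionally) the
#' selective-mortality correction.
#'
#' @param cohort An `ltc_cohort`.
#' @param strata Either the name of a built-in stratifier (`"homecare_self"`,
#'   `"homecare_partner"`, `"ses"`, `"age"`, `"sex"`, `"children"`,
#'   `"daughter"`, or `"all"` for no stratification) or a factor/vector of
#'   length `nrow(cohort)` defining the strata.
#' @param settings An [estimator_settings()].
#' @param outcome Outcome type passed to [build_panel()].
#' @param correct Apply the attrition correction within each stratum.
#' @return Named list (one element per stratum) of lists with components
#'   `curve` (corrected if requested), `uncorrected`, `attrition` and
#'   `n`.
#' @export
stratified_run <- function(cohort, strata = "all",
                           settings = estimator_settings(),
                           outcome = "all", correct = TRUE) {
  f <- if (is.character(strata) && length(strata) == 1) {
    builtin_strata(cohort, strata)
  } else if (is.factor(strata)) {
    strata            # keep declared levels: empty strata warn, not vanish
  } else {
    factor(strata)
  }
  stopifnot(length(f) == nrow(cohort))
  out <- list()
  for (lev in levels(f)) {
    sub <- cohort[!is.na(f) & f == lev, , drop = FALSE]
    attr(sub, "config") <- attr(cohort, "config")
    class(sub) <- class(cohort)
    if (nrow(sub) == 0) {
      warning("stratum '", lev, "' is empty; skipped")
      next
    }
    res <- tryCatch(
      event_study_pipeline(sub, outcome = outcome, settings = settings,
                           correct = correct),
      error = function(e) {
        warning("stratum '", lev, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) out[[lev]] <- res
  }
  out
}

## Built-in subgroup definitions used in the stratified analyses.
builtin_strata <- function(cohort, name) {
  switch(name,
    all = factor(rep("all", nrow(cohort))),
    homecare_self = factor(ifelse(cohort$homecare_self, "homecare",
                                  "no_homecare")),
    homecare_partner = factor(ifelse(cohort$homecare_partner,
                                     "partner_homecare",
                                     "partner_no_homecare")),
    ses = factor(ifelse(cohort$ses_category == "missing", NA,
                        ifelse(cohort$ses_category == "<25%", "low_ses",
                               "high_ses"))),
    age = factor(ifelse(cohort$age_band %in% c("75-79", "80-84"),
                        "age_75_84", "age_85_plus")),
    sex = factor(cohort$sex),
    children = factor(ifelse(cohort$n_children_alive == 0, NA,
                             ifelse(cohort$n_children_alive == 1,
                                    "one_child", "more_children"))),
    daughter = factor(ifelse(cohort$has_daughter, "daughter", "no_daughter")),
    stop("unknown stratifier: ", name)
  )
}

#' One-shot pipeline: cohort to (corrected) event-study curve
#'
#' Convenience wrapper running [build_panel()], [att_gt_all()],
#' [aggregate_event_study()], [multiplier_bootstrap()] and, if requested,
#' [estimate_attrition_inputs()] + [correct_curve()].
#'
#' @inheritParams stratified_run
#' @return List with `curve` (final), `uncorrected`, `attrition` (inputs
#'   table or `NULL`), `attset` and `n`.
#' @export
event_study_pipeline <- function(cohort, outcome = "all",
                                 settings = estimator_settings(),
                                 correct = TRUE) {
  panel <- build_panel(cohort, outcome = outcome)
  attset <- att_gt_all(panel, settings)
  curve <- aggregate_event_study(attset)
  curve <- multiplier_bootstrap(curve, settings)
  attr_inputs <- NULL
  final <- curve
  if (correct) {
    attr_inputs <- estimate_attrition_inputs(panel)
    final <- correct_curve(curve, attr_inputs)
  }
  list(curve = final, uncorrected = curve, attrition = attr_inputs,
       attset = attset, n = nrow(cohort))
}
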