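# Shared fixtures: fast configs with fixed (uncalibrated) hazards, a
# hand-built cohort constructor, and an ltc_panel constructor for toy
# panels with prescribed outcome paths.

quick_config <- function(n = 2000, seed = 1, n_months = 24,
                         effect_profile = default_effect_profile(),
                         baseline_rate = 0.00094,
                         calendar_trend = 0.975,
                         death_hazard_not_entitled = 0.0044,
                         death_hazard_entitled = 0.0044 * 25 / 6, ...) {
  generator_config(n_individuals = n, seed = seed, n_months = n_months,
                   effect_profile = effect_profile,
                   baseline_rate = baseline_rate,
                   calendar_trend = calendar_trend,
                   death_hazard_not_entitled = death_hazard_not_entitled,
                   death_hazard_entitled = death_hazard_entitled, ...)
}

null_config <- function(n = 2000, seed = 1, ...) {
  quick_config(n = n, seed = seed, effect_profile = c(0, 0), ...)
}

# cohort from explicit event dates; covariates filled with constants
make_cohort <- function(g, entitlement_month = NA, death_month = NA,
                        entitlement_type = NULL, n_months = 24) {
  n <- length(g)
  ent <- rep_len(as.integer(entitlement_month), n)
  coh <- data.frame(
    id = seq_len(n),
    sex = rep("female", n),
    age_band = rep("80-84", n),
    ses_category = rep("<25%", n),
    n_children_alive = rep(2L, n),
    has_daughter = rep(TRUE, n),
    homecare_self = rep(FALSE, n),
    homecare_partner = rep(TRUE, n),
    g = as.integer(g),
    death_month = rep_len(as.integer(death_month), n),
    entitlement_month = ent,
    entitlement_type = if (is.null(entitlement_type)) {
      ifelse(is.na(ent), "none", "PG")
    } else rep_len(entitlement_type, n),
    stringsAsFactors = FALSE
  )
  class(coh) <- c("ltc_cohort", "data.frame")
  attr(coh, "config") <- list(n_months = n_months)
  coh
}

# toy panel with arbitrary numeric outcome paths: ylist is a named list
# id -> list(g = ..., y = numeric vector over months 1..M (NA = missing))
make_panel <- function(ylist, n_months) {
  rows <- do.call(rbind, lapply(seq_along(ylist), function(i) {
    p <- ylist[[i]]
    s <- which(!is.na(p$y))
    data.frame(id = i, s = s, g = p$g, k = s - p$g, Y = p$y[s],
               death_month = NA_integer_, entitlement_month = NA_integer_,
               sex = "female", stringsAsFactors = FALSE)
  }))
  attr(rows, "n_months") <- n_months
  attr(rows, "outcome") <- "all"
  class(rows) <- c("ltc_panel", "data.frame")
  rows
}

no_cov <- function(...) estimator_settings(covariates = character(0), ...)

# closed-form 2x2 difference-in-differences of available-case means,
# computed directly from a panel, independent of the estimator code path
did_2x2 <- function(panel, g, t) {
  b0 <- g - 1
  yb <- panel$Y[panel$s == b0]
  ids_b <- panel$id[panel$s == b0]
  yt <- panel$Y[panel$s == t]
  ids_t <- panel$id[panel$s == t]
  gi <- panel$g[match(unique(panel$id), panel$id)]
  names(gi) <- unique(panel$id)
  tr_b <- gi[as.character(ids_b)] == g
  tr_t <- gi[as.character(ids_t)] == g
  cp_b <- gi[as.character(ids_b)] > max(t, b0) & gi[as.character(ids_b)] != g
  cp_t <- gi[as.character(ids_t)] > max(t, b0) & gi[as.character(ids_t)] != g
  (mean(yt[tr_t]) - mean(yb[tr_b])) - (mean(yt[cp_t]) - mean(yb[cp_b]))
}
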