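## Person-month estimation panel.
##
## One row per person per observed calendar month. The entitlement indicator
## Y is an absorbing state: 0 before the entitlement month, 1 from it onward,
## and missing (row absent) from the month of death on; the last observed
## month is death_month - 1.

#' Event time relative to partner loss
#'
#' @param s Calendar month.
#' @param g Partner-death month.
#' @return `s - g`: negative values are leads (pre-loss), non-negative lags.
#' @export
#' @examples
#' event_time(5, 3)   # 2
#' event_time(1, 24)  # -23, the maximal lead in a 24-month window
event_time <- function(s, g) {
  stopifnot(all(s >= 1), all(g >= 1))
  s - g
}

#' Build the person-month estimation panel
#'
#' Expands a cohort into monthly observations from month 1 through
#' `min(n_months, death_month - 1)` with the absorbing entitlement indicator
#' `Y`, the partner-death month `g`, the event time `k = s - g`, and all
#' baseline covariates carried through. For the type-specific outcomes only
#' entitlements of that type switch `Y` on.
#'
#' @param cohort An `ltc_cohort` data frame (from [simulate_cohort()] or
#'   [read_cohort_csv()]).
#' @param outcome `"all"`, `"pg"` or `"somatic"`.
#' @param n_months Window length; defaults to the generating config's value
#'   or, failing that, the largest month implied by the data.
#' @return A data.frame of class `ltc_panel` with columns `id`, `s`, `g`,
#'   `k`, `Y`, `death_month`, `entitlement_month` (of the selected outcome
#'   type) and the baseline covariates.
#' @export
build_panel <- function(cohort, outcome = c("all", "pg", "somatic"),
                        n_months = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("id", "g") %in% names(cohort)))
  if (is.null(n_months)) {
    cfg <- attr(cohort, "config")
    n_months <- if (!is.null(cfg)) cfg$n_months else
      max(cohort$g, cohort$entitlement_month, cohort$death_month - 1L,
          na.rm = TRUE)
  }
  M <- as.integer(n_months)

  bad <- cohort$id[!is.na(cohort$death_month) & cohort$death_month < cohort$g]
  if (length(bad)) {
    stop("invalid records: death before partner loss for ids ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- cohort$id[!is.na(cohort$entitlement_month) &
                     !is.na(cohort$death_month) &
                     cohort$entitlement_month >= cohort$death_month]
  if (length(bad)) {
    stop("invalid records: entitlement at or after death for ids ",
         paste(utils::head(bad, 10), collapse = ", "))
  }

  ent <- cohort$entitlement_month
  if (outcome != "all") {
    want <- if (outcome == "pg") "PG" else "somatic"
    ent[is.na(cohort$entitlement_type) | cohort$entitlement_type != want] <-
      NA_integer_
  }

  last_s <- pmin(M, ifelse(is.na(cohort$death_month), M,
                           cohort$death_month - 1L))
  keep <- last_s >= 1L
  idx <- rep(which(keep), last_s[keep])
  s <- sequence(last_s[keep])

  covars <- intersect(c("sex", "age_band", "ses_category", "n_children_alive",
                        "has_daughter", "homecare_self", "homecare_partner"),
                      names(cohort))
  out <- data.frame(
    id = cohort$id[idx],
    s = s,
    g = cohort$g[idx],
    k = s - cohort$g[idx],
    Y = as.integer(!is.na(ent[idx]) & s >= ent[idx]),
    death_month = cohort$death_month[idx],
    entitlement_month = ent[idx],
    cohort[idx, covars, drop = FALSE],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "n_months") <- M
  attr(out, "outcome") <- outcome
  class(out) <- c("ltc_panel", "data.frame")
  out
}

#' Monthly mortality rates by current entitlement status
#'
#' For each calendar month, the fraction of persons at risk (under
#' observation in the previous month) who die that month, stratified by
#' their entitlement status at the start of the month. Mirrors the
#' attrition diagnostic of mortality rates among the entitled versus the
#' not (yet) entitled, the mechanism behind the selective-attrition bias.
#'
#' @param panel An `ltc_panel`.
#' @return A data.frame with columns `s`, `entitled` (status at `s - 1`),
#'   `n_at_risk`, `n_deaths`, `rate`.
#' @export
attrition_summary <- function(panel) {
  stopifnot(inherits(panel, "ltc_panel"))
  M <- attr(panel, "n_months")
  prev <- panel[panel$s < M, c("id", "s", "Y", "death_month")]
  dies <- !is.na(prev$death_month) & prev$death_month == prev$s + 1L
  agg <- stats::aggregate(
    cbind(n_at_risk = rep(1L, nrow(prev)), n_deaths = as.integer(dies)),
    by = list(s = prev$s + 1L, entitled = prev$Y == 1L), FUN = sum)
  agg <- agg[order(agg$s, agg$entitled), , drop = FALSE]
  agg$rate <- agg$n_deaths / agg$n_at_risk
  rownames(agg) <- NULL
  agg
}

#' Read / write a cohort table as CSV
#'
#' The CSV header matches the cohort column list: `id, sex, age_band,
#' ses_category, n_children_alive, has_daughter, homecare_self,
#' homecare_partner, g, death_month, entitlement_month, entitlement_type`.
#' Empty fields are missing values (no own death / never entitled).
#'
#' @param path File path.
#' @return `read_cohort_csv`: an `ltc_cohort` data frame.
#' @export
read_cohort_csv <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "g", "entitlement_month", "death_month")
  miss <- setdiff(need, names(coh))
  if (length(miss)) {
    stop("cohort CSV is missing required columns: ",
         paste(miss, collapse = ", "))
  }
  for (col in c("g", "entitlement_month", "death_month",
                "n_children_alive")) {
    if (col %in% names(coh)) coh[[col]] <- as.integer(coh[[col]])
  }
  for (col in c("has_daughter", "homecare_self", "homecare_partner")) {
    if (col %in% names(coh)) coh[[col]] <- as.logical(coh[[col]])
  }
  if (is.null(coh$entitlement_type)) {
    coh$entitlement_type <- ifelse(is.na(coh$entitlement_month), "none", "PG")
  }
  class(coh) <- c("ltc_cohort", "data.frame")
  coh
}

#' @rdname read_cohort_csv
#' @param cohort An `ltc_cohort` data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
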