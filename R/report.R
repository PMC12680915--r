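## Orchestration: simulate or ingest a cohort, run the estimation pipeline
## per outcome and stratum, and emit all results as tidy CSV files plus a
## machine-readable manifest. Figures are emitted as data (the curve CSVs);
## plot() on a curve renders them when wanted.

#' Baseline sample characteristics table
#'
#' Percent ever entitled to institutional LTC during the window, percent
#' not, and person counts, per level of each baseline stratifier, plus a
#' total row.
#'
#' @param cohort An `ltc_cohort`.
#' @return A data.frame with columns `variable`, `level`, `pct_entitled`,
#'   `pct_not_entitled`, `count`.
#' @export
sample_characteristics <- function(cohort) {
  ever <- !is.na(cohort$entitlement_month)
  vars <- intersect(c("sex", "age_band", "homecare_self",
                      "n_children_alive", "ses_category"), names(cohort))
  one <- function(v) {
    x <- cohort[[v]]
    if (v == "n_children_alive") {
      x <- ifelse(x >= 4, "4+", as.character(x))
    } else if (is.logical(x)) {
      x <- ifelse(x, "yes", "no")
    }
    lev <- unique(x)
    lev <- lev[order(lev)]
    do.call(rbind, lapply(lev, function(l) {
      sel <- x == l
      if (!any(sel)) return(NULL)   # empty stratum: omitted row
      data.frame(variable = v, level = l,
                 pct_entitled = 100 * mean(ever[sel]),
                 pct_not_entitled = 100 * mean(!ever[sel]),
                 count = sum(sel), stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, lapply(vars, one))
  out <- rbind(out, data.frame(variable = "total", level = "total",
                               pct_entitled = 100 * mean(ever),
                               pct_not_entitled = 100 * mean(!ever),
                               count = nrow(cohort)))
  rownames(out) <- NULL
  out
}

#' Excess entitlement-months implied by an event-study curve
#'
#' Back-of-envelope volume effect: the area under the corrected lag curve
#' (probability scale, month-wide steps) times the annual number of newly
#' widowed individuals still living at home.
#'
#' @param curve An `ltc_event_study` (corrected lags recommended).
#' @param annual_widowed Annual count of newly widowed individuals.
#' @param share_at_home Fraction of them still living at home.
#' @return Additional entitlement-months per year (a single number).
#' @export
#' @examples
#' # a flat 1-percentage-point effect over 10 months:
#' cv <- data.frame(k = 0:9, theta = rep(1, 10), corrected = TRUE)
#' class(cv) <- c("ltc_event_study", "data.frame")
#' excess_entitlement_months(cv, 24500, 0.107)   # 262.15
excess_entitlement_months <- function(curve, annual_widowed = 24500,
                                      share_at_home = 0.107) {
  stopifnot(inherits(curve, "ltc_event_study"))
  if (annual_widowed < 0 || share_at_home < 0 || share_at_home > 1) {
    stop("annual_widowed must be non-negative and share_at_home in [0, 1]")
  }
  lag <- curve$k >= 0
  sum(curve$theta[lag] / 100) * annual_widowed * share_at_home
}

#' Run the full analysis
#'
#' Orchestrates the pipeline: simulate a cohort (or read one from CSV),
#' build the person-month panel per outcome, estimate all group-time
#' effects, aggregate, bootstrap, apply the selective-mortality correction,
#' and write per outcome and stratum the uncorrected and corrected
#' event-study curves, the attrition inputs, the monthly mortality summary,
#' the sample-characteristics table, and a manifest of all settings and
#' seeds that fully determines the outputs.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{mode}{`"simulate"` (default) or `"csv"`.}
#'     \item{csv}{Cohort CSV path (mode `"csv"`).}
#'     \item{generator}{List of [generator_config()] arguments (mode
#'       `"simulate"`).}
#'     \item{outcomes}{Subset of `c("all", "pg", "somatic")`.}
#'     \item{strata}{Character vector of stratifier names (see
#'       [stratified_run()]); default `"all"`.}
#'     \item{settings}{List of [estimator_settings()] arguments.}
#'     \item{correction}{Apply the mortality correction (default `TRUE`).}
#'     \item{outdir}{Output directory; `NULL` = write nothing.}
#'   }
#' @return Invisibly, a nested result bundle: per outcome, per stratum, the
#'   pipeline result of [event_study_pipeline()]; plus the cohort and the
#'   manifest.
#' @export
run_analysis <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  mode <- config$mode %||% "simulate"
  outcomes <- config$outcomes %||% "all"
  strata <- config$strata %||% "all"
  correction <- config$correction %||% TRUE
  settings <- do.call(estimator_settings, config$settings %||% list())
  if (!mode %in% c("simulate", "csv")) stop("unknown input mode: ", mode)
  if (!all(outcomes %in% c("all", "pg", "somatic"))) {
    stop("outcomes must be a subset of all/pg/somatic")
  }

  if (mode == "csv") {
    if (is.null(config$csv)) stop("mode 'csv' needs a 'csv' path")
    cohort <- read_cohort_csv(config$csv)
  } else {
    gen <- do.call(generator_config, config$generator %||% list())
    cohort <- simulate_cohort(gen)
  }

  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(outdir)) {
      utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }

  emit(sample_characteristics(cohort), "sample_characteristics")
  results <- list()
  for (oc in outcomes) {
    emit(attrition_summary(build_panel(cohort, outcome = oc)),
         paste0("attrition_summary_", oc))
    res_oc <- list()
    for (sname in strata) {
      res_s <- stratified_run(cohort, strata = sname, settings = settings,
                              outcome = oc, correct = correction)
      if (length(strata) > 1) {
        names(res_s) <- paste0(sname, ".", names(res_s))
      }
      res_oc <- c(res_oc, res_s)
    }
    for (lev in names(res_oc)) {
      stub <- paste0(oc, "_", lev)
      r <- res_oc[[lev]]
      emit(as.data.frame(r$uncorrected), paste0("curve_uncorrected_", stub))
      if (correction) {
        emit(as.data.frame(r$curve), paste0("curve_corrected_", stub))
        emit(as.data.frame(r$attrition), paste0("attrition_inputs_", stub))
      }
      emit(r$attset$atts, paste0("att_gt_", stub))
    }
    results[[oc]] <- res_oc
  }

  manifest <- list(
    package = "widowltc",
    version = as.character(utils::packageVersion("widowltc")),
    mode = mode,
    csv = config$csv,
    generator = if (mode == "simulate") {
      gen[setdiff(names(gen), "covariate_marginals")]
    },
    outcomes = outcomes,
    strata = strata,
    correction = correction,
    settings = unclass(settings)
  )
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(list(cohort = cohort, results = results, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
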