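#' Baseline covariate marginals of the study population
#'
#' Reads the packaged table of baseline sample characteristics of a Dutch
#' registry cohort of community-dwelling adults aged 75-100 who lost their
#' partner during a 24-month observation window: counts and percent
#' ever-entitled to institutional long-term care, by sex, age band, home-care
#' use, number of children alive and neighbourhood socioeconomic status.
#' These marginals are the default calibration input of the synthetic cohort
#' generator.
#'
#' @param path Optional path to a CSV with columns
#'   `variable,level,pct_entitled,count`. Defaults to the packaged table.
#' @return A data.frame with columns `variable`, `level`, `pct_entitled`
#'   (percent ever entitled during the window) and `count`.
#' @export
#' @examples
#' m <- default_marginals()
#' subset(m, variable == "age_band")
default_marginals <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sample_marginals.csv", package = "widowltc")
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "level", "pct_entitled", "count") %in% names(m)))
  m
}

## Named probability vectors per covariate, excluding the total row.
marginal_probs <- function(marginals) {
  m <- marginals[marginals$variable != "total", , drop = FALSE]
  out <- lapply(split(m, m$variable), function(d) {
    p <- d$count / sum(d$count)
    names(p) <- d$level
    p
  })
  out
}
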