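## Selective-mortality attrition correction.
##
## Entitled individuals die faster than non-entitled ones, and in this
## design mortality only occurs after partner loss: the treated survivor
## pool at k months after loss is therefore progressively depleted of the
## entitled, which mechanically drags the estimated lag effects downward.
## The expected estimate equals the true effect plus a closed-form bias
## determined by the observed entitled fraction among survivors and the
## class-specific survivor fractions; subtracting that bias recovers the
## direct effect of partner loss on entitlement.

#' Closed-form selective-mortality bias
#'
#' The bias of the estimated lag effect at a given event time:
#' \deqn{bias = \frac{y (1 - y) (S_L - S_N)}{y S_N + (1 - y) S_L}}
#' where `y` is the observed fraction entitled among the treated survivors,
#' and `S_L`, `S_N` are the survivor fractions among those entitled
#' respectively not entitled one month before partner loss. With equal
#' survival the bias is zero; with excess mortality among the entitled
#' (`S_L < S_N`) it is negative — uncorrected estimates understate the
#' impact of partner loss — and its magnitude accumulates with elapsed time
#' since loss.
#'
#' @param y Observed entitled fraction among survivors, in `[0, 1]`.
#' @param S_L,S_N Survivor fractions of the entitled / not-entitled class,
#'   in `[0, 1]`.
#' @return Signed bias on the probability scale. Vectorised.
#' @export
#' @examples
#' attrition_bias(0.2, 0.8, 0.95)   # about -0.0289
#' attrition_bias(0.2, 0.9, 0.9)    # equal survival: 0
attrition_bias <- function(y, S_L, S_N) {
  stopifnot(all(y >= 0 & y <= 1, na.rm = TRUE),
            all(S_L >= 0 & S_L <= 1, na.rm = TRUE),
            all(S_N >= 0 & S_N <= 1, na.rm = TRUE))
  den <- y * S_N + (1 - y) * S_L
  if (any(!is.na(den) & den <= 0)) {
    stop("degenerate attrition inputs: y * S_N + (1 - y) * S_L must be positive")
  }
  y * (1 - y) * (S_L - S_N) / den
}

#' Estimate the attrition-correction ingredients from a panel
#'
#' Classifies every treated person by entitlement status one month before
#' partner loss (entitled = class L, not entitled = class N) and computes,
#' for each event time k >= 0: the survivor fractions `S_L`, `S_N` of the
#' two classes k months after loss, pooled over all treatment cohorts for
#' which month g+k lies inside the window (count-weighted pooling, so
#' survival is averaged over calendar seasons), and the observed entitled
#' fraction `y` among the survivors at k. By convention `S_0 = 1` for both
#' classes: mortality only occurs after partner loss.
#'
#' @param panel An `ltc_panel` built with death information retained.
#' @return A data.frame of class `ltc_attrition` with columns `k`, `y`,
#'   `S_L`, `S_N`, `bias`, `n_L`, `n_N`. Event times at which a class is
#'   empty carry `NA` and are skipped (with a warning) by
#'   [correct_curve()].
#' @export
estimate_attrition_inputs <- function(panel) {
  stopifnot(inherits(panel, "ltc_panel"),
            "death_month" %in% names(panel))
  M <- attr(panel, "n_months")
  first <- !duplicated(panel$id)
  g <- panel$g[first]
  death <- panel$death_month[first]
  ent <- panel$entitlement_month[first]
  applicant <- !is.na(ent) & ent < g        # entitled at g - 1
  kmax <- M - min(g)
  rows <- lapply(0:kmax, function(k) {
    elig <- g + k <= M
    if (!any(elig)) return(NULL)
    surv <- is.na(death) | death > g + k
    nL <- sum(elig & applicant)
    nN <- sum(elig & !applicant)
    S_L <- if (nL > 0) sum(elig & applicant & surv) / nL else NA_real_
    S_N <- if (nN > 0) sum(elig & !applicant & surv) / nN else NA_real_
    at_k <- elig & surv
    y <- if (any(at_k)) {
      mean(!is.na(ent[at_k]) & ent[at_k] <= g[at_k] + k)
    } else NA_real_
    data.frame(k = k, y = y, S_L = S_L, S_N = S_N,
               n_L = nL, n_N = nN)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$y) & !is.na(out$S_L) & !is.na(out$S_N)
  out$bias <- NA_real_
  out$bias[ok] <- attrition_bias(out$y[ok], out$S_L[ok], out$S_N[ok])
  class(out) <- c("ltc_attrition", "data.frame")
  out
}

#' Correct an event-study curve for selective mortality
#'
#' Subtracts the closed-form attrition bias from the aggregated lag effects
#' (k >= 0); leads are untouched. Uncertainty is carried over unchanged
#' (the bias is treated as known, a plug-in correction). Lags without
#' usable inputs are left uncorrected with a warning.
#'
#' @param curve An uncorrected `ltc_event_study`.
#' @param inputs An `ltc_attrition` table from
#'   [estimate_attrition_inputs()].
#' @return The curve with corrected lag effects and the `corrected` flag
#'   set for every adjusted event time.
#' @export
correct_curve <- function(curve, inputs) {
  stopifnot(inherits(curve, "ltc_event_study"),
            inherits(inputs, "ltc_attrition"))
  if (any(curve$corrected)) stop("curve is already corrected")
  lag <- curve$k >= 0
  m <- match(curve$k[lag], inputs$k)
  bias <- inputs$bias[m]
  if (any(is.na(bias))) {
    warning("no attrition inputs for event time(s) ",
            paste(curve$k[lag][is.na(bias)], collapse = ", "),
            "; left uncorrected")
  }
  adj <- ifelse(is.na(bias), 0, 100 * bias)
  shift <- numeric(nrow(curve))
  shift[lag] <- adj
  curve$theta <- curve$theta - shift
  curve$ci_lo <- curve$ci_lo - shift
  curve$ci_hi <- curve$ci_hi - shift
  curve$band_lo <- curve$band_lo - shift
  curve$band_hi <- curve$band_hi - shift
  curve$corrected[lag] <- !is.na(bias)
  curve
}
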