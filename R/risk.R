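#' Spatial relative risk per area
#'
#' \eqn{\hat\rho_i = \exp(\hat s_i)} where \eqn{\hat s_i} is the posterior
#' mean of the spatially structured effect: the area's multiplicative
#' departure from the overall risk level. Note this is exp of the posterior
#' mean, not the posterior mean of exp — the conventional reporting scale.
#'
#' @param fit an `stmmr` fit or `stmmr_draws`.
#' @return length-N positive vector, named by area.
#' @export
spatial_risk <- function(fit) {
  d <- draws_of_(fit)
  r <- exp(colMeans(d$s))
  names(r) <- area_names_of_(fit)
  r
}

#' Exceedance probability of unit spatial relative risk
#'
#' \eqn{p_i = P(\hat\rho_i > 1 \mid Y)}, estimated as the fraction of
#' retained draws with \eqn{s_i > 0}.
#'
#' @param fit an `stmmr` fit or `stmmr_draws`.
#' @return length-N vector in [0, 1], named by area.
#' @export
exceedance_prob <- function(fit) {
  d <- draws_of_(fit)
  p <- colMeans(d$s > 0)
  names(p) <- area_names_of_(fit)
  p
}

#' Hot-spot / cold-spot classification
#'
#' Areas with exceedance probability strictly above the threshold are
#' classified "hot"; all others (including ties at the threshold) "cold".
#'
#' @param p exceedance probabilities in [0, 1].
#' @param threshold classification threshold in (0, 1); default 0.5.
#' @return character vector of "hot"/"cold" labels.
#' @export
classify_areas <- function(p, threshold = 0.5) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  out <- ifelse(p > threshold, "hot", "cold")
  names(out) <- names(p)
  out
}

#' Summary of area-specific trend deviations
#'
#' Posterior mean and equal-tailed 95% credible interval of each
#' \eqn{\delta_i}, the difference between the area-specific linear trend and
#' the common trend. A positive mean indicates locally rising risk over the
#' study periods ("rising"); zero or negative means are labelled
#' "declining".
#'
#' @param fit an `stmmr` fit or `stmmr_draws`.
#' @return data.frame with columns `area_id`, `delta_mean`, `delta_lo`,
#'   `delta_hi`, `direction`.
#' @export
interaction_trend_summary <- function(fit) {
  d <- draws_of_(fit)
  m <- colMeans(d$delta)
  qs <- apply(d$delta, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(area_id = area_names_of_(fit),
             delta_mean = m, delta_lo = qs[1L, ], delta_hi = qs[2L, ],
             direction = ifelse(m > 0, "rising", "declining"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-area risk report
#'
#' Combines spatial relative risk, exceedance probability, hot/cold label
#' and the trend-deviation summary into one table.
#'
#' @param fit an `stmmr` fit or `stmmr_draws`.
#' @param threshold hot-spot threshold passed to [classify_areas()].
#' @return data.frame of class `stmmr_risk` with columns `area_id`,
#'   `spatial_rr`, `exceed_prob`, `label`, `delta_mean`, `delta_lo`,
#'   `delta_hi`.
#' @export
risk_report <- function(fit, threshold = 0.5) {
  p <- exceedance_prob(fit)
  it <- interaction_trend_summary(fit)
  out <- data.frame(area_id = it$area_id,
                    spatial_rr = unname(spatial_risk(fit)),
                    exceed_prob = unname(p),
                    label = unname(classify_areas(p, threshold)),
                    delta_mean = it$delta_mean,
                    delta_lo = it$delta_lo, delta_hi = it$delta_hi,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("stmmr_risk", "data.frame")
  out
}

draws_of_ <- function(fit) {
  if (inherits(fit, "stmmr")) fit$draws
  else if (inherits(fit, "stmmr_draws")) fit
  else stop("expected an stmmr fit or stmmr_draws object")
}

area_names_of_ <- function(fit) {
  if (inherits(fit, "stmmr")) fit$panel$area_ids
  else paste0("area", seq_len(ncol(fit$s)))
}
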