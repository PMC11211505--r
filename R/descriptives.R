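#' Simple linear trend fit for one area
#'
#' Ordinary least-squares regression of a response series on time, with a
#' 95% confidence interval for the slope based on the t distribution with
#' T - 2 degrees of freedom (appropriate for the very short series typical
#' of MMR panels, where a normal interval would be anti-conservative).
#'
#' @param y numeric response of length T (e.g. one area's MMR series).
#' @param t numeric time scores of the same length, not all equal.
#' @return list with `slope`, `intercept`, `slope_se`, `slope_lo`,
#'   `slope_hi`, `r2`. A zero-variance response is given slope 0 and
#'   `r2 = 0`.
#' @export
fit_area_trend <- function(y, t) {
  if (length(y) != length(t)) stop("y and t must share length")
  T <- length(y)
  if (T < 2L) stop("need at least 2 time points")
  if (stats::var(t) == 0) stop("time scores have zero variance")
  if (stats::var(y) == 0)   # constant response: flat line, define r2 = 0
    return(list(slope = 0, intercept = y[1L], slope_se = 0,
                slope_lo = 0, slope_hi = 0, r2 = 0))
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  sm <- suppressWarnings(summary(fit))   # exact fits trip lm's rank warning
  se <- sm$coefficients[2L, 2L]
  if (!is.finite(se)) se <- 0            # exact fit: zero residual variance
  tcrit <- if (T > 2L) stats::qt(0.975, T - 2L) else Inf
  half <- if (se == 0) 0 else tcrit * se
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0            # constant response: define r2 = 0
  list(slope = slope, intercept = intercept, slope_se = se,
       slope_lo = slope - half, slope_hi = slope + half, r2 = r2)
}

#' Linear trend fits for every area of a panel
#'
#' The per-area regression behind the facet plots: each area's observed
#' count series regressed on time with a 95% confidence band.
#'
#' @param panel an [areal_panel].
#' @param t optional time scores (default `1..T`).
#' @return data.frame of class `stmmr_trends` with one row per area:
#'   `area_id`, `slope`, `intercept`, `slope_se`, `slope_lo`, `slope_hi`,
#'   `r2`.
#' @export
area_trends <- function(panel, t = NULL) {
  stopifnot(inherits(panel, "areal_panel"))
  T <- length(panel$time_ids)
  if (is.null(t)) t <- seq_len(T)
  rows <- lapply(seq_along(panel$area_ids), function(i) {
    f <- fit_area_trend(as.numeric(panel$O[i, ]), t)
    data.frame(area_id = panel$area_ids[i], f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stmmr_trends", "data.frame")
  out
}

#' Standardised matrix for heatmap display
#'
#' Z-scales the panel's count matrix for relative-performance display. With
#' `orientation = "by_column"` each time period is standardised across areas
#' (each column of the area x time matrix gets mean 0, sd 1); with
#' `orientation = "by_row"` the transpose is standardised, i.e. each area is
#' scaled across its own periods.
#'
#' With `include_covariates = TRUE` the matrix instead has one row per area
#' and columns `mmr` (the most recent period's counts) followed by the
#' panel covariates, all column-standardised — the cross-sectional
#' "MMR and associated covariates" display.
#'
#' @param panel an [areal_panel].
#' @param orientation `"by_column"` (default) or `"by_row"`.
#' @param include_covariates join the covariate block (requires covariates).
#' @return list with `matrix` (standardised), `row_labels`, `col_labels`.
#' @export
heatmap_matrix <- function(panel, orientation = c("by_column", "by_row"),
                           include_covariates = FALSE) {
  stopifnot(inherits(panel, "areal_panel"))
  orientation <- match.arg(orientation)
  if (include_covariates) {
    if (is.null(panel$X)) stop("panel has no covariates to include")
    T <- length(panel$time_ids)
    M <- cbind(mmr = as.numeric(panel$O[, T]), panel$X)
    rownames(M) <- panel$area_ids
    sc <- zscale_columns(M)
    return(list(matrix = sc, row_labels = rownames(M), col_labels = colnames(M)))
  }
  M <- panel$O
  storage.mode(M) <- "double"
  if (orientation == "by_row") M <- t(M)
  sc <- zscale_columns(M)
  list(matrix = sc, row_labels = rownames(M), col_labels = colnames(M))
}
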