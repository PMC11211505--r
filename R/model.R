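#' Default covariate sets for the two covariate models
#'
#' Model 2 adjusts for six maternal-health indicators; model 3 for eleven
#' health-system indicators. Model 1 is the purely spatio-temporal baseline.
#' @name covariate_sets
#' @keywords internal
NULL

MATERNAL_COVARIATES <- c("anemia", "low_bmi", "low_birth_interval",
                         "contraception", "c_section", "birth_order_gt3")

SYSTEM_COVARIATES <- c("anc", "pnc", "institutional_delivery", "health_index",
                       "accreditation", "nqas", "ghe", "oope", "jsy",
                       "population", "skilled_attendance")

#' Model specification
#'
#' Describes which of the three model variants to fit: model 1 is the
#' baseline with intercept, spatially structured (ICAR) and unstructured
#' area effects, a common linear time trend and ICAR area-specific trend
#' deviations; models 2 and 3 add the maternal-health and health-system
#' covariate blocks. `model = "custom"` takes any covariate set.
#'
#' @param model 1, 2, 3 or "custom".
#' @param covariate_names covariate columns to include (defaults per model).
#' @param time_coding "centered" (default; the time scores 1..T minus their
#'   mean, decorrelating intercept and trend) or "raw" (1..T).
#' @param standardize_covariates z-scale covariate columns before fitting
#'   (default TRUE; coefficient and relative-risk scales then refer to a
#'   one-standard-deviation change).
#' @param hyper a [hyperparams] object.
#' @param include_spatial,include_iid,include_trend,include_interaction
#'   component switches for the structured effect s, heterogeneity u, common
#'   trend gamma and trend deviations delta; used for reduced/diagnostic fits
#'   such as intercept-only models.
#' @param fixed_tau optional named list fixing any of `tau_s`, `tau_u`,
#'   `tau_delta` instead of sampling them.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = 1, covariate_names = NULL,
                       time_coding = c("centered", "raw"),
                       standardize_covariates = TRUE,
                       hyper = hyperparams(),
                       include_spatial = TRUE, include_iid = TRUE,
                       include_trend = TRUE, include_interaction = TRUE,
                       fixed_tau = NULL) {
  time_coding <- match.arg(time_coding)
  model <- if (identical(model, "custom")) "custom" else as.integer(model)
  if (!identical(model, "custom") && !model %in% 1:3)
    stop("model must be 1, 2, 3 or \"custom\"")
  if (is.null(covariate_names)) {
    covariate_names <- switch(as.character(model),
      "1" = character(0),
      "2" = MATERNAL_COVARIATES,
      "3" = SYSTEM_COVARIATES,
      "custom" = character(0))
  }
  stopifnot(inherits(hyper, "hyperparams"))
  if (!is.null(fixed_tau)) {
    ok <- names(fixed_tau) %in% c("tau_s", "tau_u", "tau_delta")
    if (!all(ok)) stop("fixed_tau names must be tau_s, tau_u, tau_delta")
    if (any(unlist(fixed_tau) <= 0)) stop("fixed_tau values must be positive")
  }
  structure(list(model = model, covariate_names = covariate_names,
                 time_coding = time_coding,
                 standardize_covariates = isTRUE(standardize_covariates),
                 hyper = hyper,
                 include_spatial = isTRUE(include_spatial),
                 include_iid = isTRUE(include_iid),
                 include_trend = isTRUE(include_trend),
                 include_interaction = isTRUE(include_interaction),
                 fixed_tau = fixed_tau),
            class = "model_spec")
}

#' Time scores for the linear trend
#'
#' @param T number of periods.
#' @param coding "centered" (1..T minus mean, summing to zero) or "raw" (1..T).
#' @return numeric vector of length `T`.
#' @examples
#' encode_time(5, "centered")  # -2 -1 0 1 2
#' @export
encode_time <- function(T, coding = c("centered", "raw")) {
  coding <- match.arg(coding)
  if (!is.numeric(T) || T < 1 || T != as.integer(T))
    stop("T must be a positive integer")
  t <- seq_len(T)
  if (coding == "centered") t - mean(t) else as.numeric(t)
}

#' Linear predictor of the spatio-temporal model
#'
#' \deqn{\eta_{it} = \alpha + s_i + u_i + \sum_k \beta_k x_{ik} +
#'   (\gamma + \delta_i)\,\mathrm{time}_t}
#' the log relative risk of area i in period t.
#'
#' @param alpha scalar intercept (overall log risk level).
#' @param s,u,delta length-N area effects (structured, unstructured,
#'   trend deviations).
#' @param beta length-K covariate coefficients (may be length 0).
#' @param X N x K covariate matrix (may have 0 columns).
#' @param gamma scalar common trend per unit of time score.
#' @param time length-T time scores from [encode_time()].
#' @return N x T matrix of log relative risks.
#' @export
linear_predictor <- function(alpha, s, u, beta, X, gamma, delta, time) {
  N <- length(s)
  if (length(u) != N || length(delta) != N)
    stop("s, u, delta must share length N")
  X <- if (is.null(X)) matrix(0, N, 0) else as.matrix(X)
  if (nrow(X) != N) stop("X must have N rows")
  if (ncol(X) != length(beta)) stop("length(beta) must equal ncol(X)")
  if (length(alpha) != 1L || length(gamma) != 1L)
    stop("alpha and gamma must be scalars")
  xb <- if (ncol(X)) as.vector(X %*% beta) else numeric(N)
  level <- alpha + s + u + xb                      # length N
  outer(level, rep(1, length(time))) + outer(gamma + delta, time)
}

#' Poisson log-likelihood of a count panel
#'
#' \deqn{\sum_{it} [O_{it}(\log E_{it} + \eta_{it}) - E_{it} e^{\eta_{it}}
#'   - \log O_{it}!]}
#' The log-factorial term is retained so deviances (and DIC) are absolute.
#' Linear predictors are clipped at +/-700 before exponentiation; the number
#' of clipped cells is attached as attribute `clipped` (with a warning).
#'
#' @param O N x T counts.
#' @param E N x T positive expected counts.
#' @param eta N x T linear predictors.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(O, E, eta) {
  O <- as.matrix(O); E <- as.matrix(E); eta <- as.matrix(eta)
  if (!all(dim(O) == dim(E)) || !all(dim(O) == dim(eta)))
    stop("O, E, eta must share dimensions")
  if (any(E <= 0)) stop("E must be positive")
  clipped <- sum(abs(eta) > 700)
  if (clipped > 0) {
    warning(clipped, " linear predictor cell(s) clipped at +/-700")
    eta <- pmin(pmax(eta, -700), 700)
  }
  ll <- sum(O * (log(E) + eta) - E * exp(eta) - lfactorial(O))
  attr(ll, "clipped") <- clipped
  ll
}

#' Build the covariate design matrix for a model specification
#'
#' Selects the requested covariate columns from the panel in specification
#' order, optionally z-scaling each column.
#'
#' @param panel an [areal_panel].
#' @param spec a [model_spec].
#' @return list with `X` (N x K matrix) and `names`.
#' @export
build_design <- function(panel, spec) {
  stopifnot(inherits(panel, "areal_panel"), inherits(spec, "model_spec"))
  nm <- spec$covariate_names
  if (length(nm) == 0L)
    return(list(X = matrix(0, length(panel$area_ids), 0), names = character(0)))
  have <- colnames(panel$X)
  missing <- setdiff(nm, have)
  if (length(missing))
    stop("covariate(s) not in panel: ", paste(missing, collapse = ", "))
  X <- panel$X[, nm, drop = FALSE]
  storage.mode(X) <- "double"
  if (spec$standardize_covariates) X <- zscale_columns(X)
  list(X = X, names = nm)
}
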