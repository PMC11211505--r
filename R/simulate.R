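#' True parameter set for a simulated panel
#'
#' Either supply the effect vectors directly or give precisions only, in
#' which case `s` and `delta` are drawn from the intrinsic CAR prior on the
#' graph (sum-to-zero per component) and `u` iid Normal(0, 1/tau_u).
#'
#' Defaults target SRS-like MMR magnitudes with unit expected counts:
#' `alpha = log(100)` puts area mean counts around 100 (spread by the area
#' effects into roughly the 20-250 band) and `gamma = -0.121` gives a common
#' declining trend of realistic size.
#'
#' @param graph an [adjacency_graph]; defines N and the spatial structure.
#' @param alpha intercept (overall log risk).
#' @param gamma common linear trend per unit of time score.
#' @param beta optional covariate coefficients.
#' @param tau_s,tau_u,tau_delta positive precisions of s, u, delta.
#' @param s,u,delta optional explicit effect vectors (length N); `s` and
#'   `delta` are centred per component.
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(graph, alpha = log(100), gamma = -0.121, beta = NULL,
                      tau_s = 10, tau_u = 100, tau_delta = 10,
                      s = NULL, u = NULL, delta = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (any(c(tau_s, tau_u, tau_delta) <= 0)) stop("precisions must be positive")
  n <- graph$n
  has_edges <- graph_n_edges(graph) > 0L
  if (is.null(s)) {
    s <- if (has_edges) ricar(graph, tau_s) else numeric(n)
  } else {
    if (length(s) != n) stop("length(s) != graph$n")
    s <- center_by_component_(s, graph)
  }
  if (is.null(u)) u <- stats::rnorm(n, 0, 1 / sqrt(tau_u))
  if (length(u) != n) stop("length(u) != graph$n")
  if (is.null(delta)) {
    delta <- if (has_edges) ricar(graph, tau_delta) else numeric(n)
  } else {
    if (length(delta) != n) stop("length(delta) != graph$n")
    delta <- center_by_component_(delta, graph)
  }
  structure(list(alpha = alpha, gamma = gamma, beta = beta,
                 s = s, u = u, delta = delta,
                 tau_s = tau_s, tau_u = tau_u, tau_delta = tau_delta),
            class = "sim_truth")
}

#' Simulate an areal count panel from the spatio-temporal model
#'
#' Forward simulation of the fitted model: counts are drawn
#' \eqn{O_{it} \sim \mathrm{Poisson}(E_{it}\, e^{\eta_{it}})} with
#' \eqn{\eta_{it} = \alpha + s_i + u_i + \sum_k \beta_k x_{ik} +
#' (\gamma+\delta_i)\,\mathrm{time}_t} and the same time coding as the
#' fitting routine.
#'
#' @param graph an [adjacency_graph].
#' @param truth a [sim_truth], or a named list of arguments forwarded to
#'   [sim_truth()] (e.g. precisions only), or NULL for defaults.
#' @param T number of time periods (default 5).
#' @param expected `"unit"` for E = 1, or an N x T positive matrix.
#' @param covariate_spec optional list describing covariates to generate;
#'   each element is `list(name=, mean=0, sd=1, cor_s=0)` where `cor_s` is
#'   the correlation of the covariate with the spatial effect `s` (giving
#'   covariate models signal to detect).
#' @param seed integer seed; identical seeds give identical panels.
#' @param time_coding passed to [encode_time()] (default "centered").
#' @return list with elements `panel` (an [areal_panel]) and `truth` (the
#'   realised [sim_truth], including any generated `beta`).
#' @export
simulate_panel <- function(graph, truth = NULL, T = 5, expected = "unit",
                           covariate_spec = NULL, seed,
                           time_coding = c("centered", "raw")) {
  stopifnot(inherits(graph, "adjacency_graph"))
  time_coding <- match.arg(time_coding)
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  set.seed(as.integer(seed))
  n <- graph$n
  if (identical(expected, "unit")) {
    E <- matrix(1, n, T)
  } else {
    E <- as.matrix(expected)
    if (!all(dim(E) == c(n, T))) stop("expected matrix must be N x T")
    if (any(!is.finite(E)) || any(E <= 0))
      stop("expected matrix must be positive everywhere")
  }
  if (is.null(truth)) truth <- sim_truth(graph)
  else if (!inherits(truth, "sim_truth")) truth <- do.call(sim_truth, c(list(graph), truth))

  X <- NULL
  beta <- truth$beta
  if (!is.null(covariate_spec)) {
    X <- matrix(0, n, length(covariate_spec))
    nms <- character(length(covariate_spec))
    s_std <- if (stats::sd(truth$s) > 0) as.vector(scale(truth$s)) else stats::rnorm(n)
    for (k in seq_along(covariate_spec)) {
      cs <- covariate_spec[[k]]
      nms[k] <- if (!is.null(cs$name)) cs$name else paste0("x", k)
      m <- if (!is.null(cs$mean)) cs$mean else 0
      sdv <- if (!is.null(cs$sd)) cs$sd else 1
      r <- if (!is.null(cs$cor_s)) cs$cor_s else 0
      z <- r * s_std + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
      X[, k] <- m + sdv * z
    }
    colnames(X) <- nms
    if (is.null(beta)) beta <- rep(0, ncol(X))
    if (length(beta) != ncol(X))
      stop("truth$beta length must match covariate_spec length")
  }
  tvec <- encode_time(T, time_coding)
  eta <- linear_predictor(truth$alpha, truth$s, truth$u,
                          beta %||% numeric(0),
                          if (is.null(X)) NULL else zscale_columns(X),
                          truth$gamma, truth$delta, tvec)
  O <- matrix(stats::rpois(n * T, as.vector(E * exp(eta))), n, T)
  panel <- areal_panel(O, paste0("area", seq_len(n)), seq_len(T), X = X, E = E)
  truth$beta <- beta
  list(panel = panel, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
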