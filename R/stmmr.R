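#' Fit a Bayesian spatio-temporal CAR model to an areal count panel
#'
#' Fits the Poisson areal model
#' \deqn{O_{it} \sim \mathrm{Poisson}(E_{it}\rho_{it}), \quad
#'   \log\rho_{it} = \alpha + s_i + u_i + x_i'\beta +
#'   (\gamma + \delta_i)\,\mathrm{time}_t}
#' where \eqn{s_i} (spatially structured, intrinsic CAR), \eqn{u_i}
#' (unstructured heterogeneity) and \eqn{\delta_i} (area-specific deviations
#' from the common trend \eqn{\gamma}, intrinsic CAR) are random effects.
#' Inference is by MCMC; see [run_mcmc()] for the sampler.
#'
#' @param panel an [areal_panel].
#' @param graph an [adjacency_graph] for the panel's areas.
#' @param model 1 (baseline spatio-temporal), 2 (maternal-health covariates),
#'   3 (health-system covariates), "custom", or a full [model_spec].
#' @param expected `"unit"` (E = 1, for counts that are already standardised
#'   ratios), `"internal"` (per-period internal standardisation from the
#'   panel denominators) or an N x T positive matrix.
#' @param iters,burnin,thin,chains,seed,verbose passed to [run_mcmc()].
#' @param ... further arguments to [model_spec()] when `model` is not already
#'   a `model_spec` (e.g. `covariate_names`, `fixed_tau`, component switches).
#' @return an object of class `stmmr` with elements `call`, `panel`, `graph`,
#'   `spec`, `E`, `time` and `draws` (an `stmmr_draws`).
#' @examples
#' g <- make_lattice_graph(3, 3)
#' sim <- simulate_panel(g, truth = list(alpha = 3), T = 4, seed = 1)
#' fit <- stmmr(sim$panel, g, model = 1, iters = 600, burnin = 300,
#'              thin = 1, chains = 1, seed = 1)
#' coef(fit)
#' @export
stmmr <- function(panel, graph, model = 1, expected = "unit",
                  iters = 20000, burnin = 10000, thin = 5, chains = 4,
                  seed, verbose = FALSE, ...) {
  stopifnot(inherits(panel, "areal_panel"))
  spec <- if (inherits(model, "model_spec")) model else model_spec(model = model, ...)
  E <- if (is.character(expected)) expected_counts(panel, expected) else as.matrix(expected)
  draws <- run_mcmc(panel, graph, spec, iters = iters, burnin = burnin,
                    thin = thin, chains = chains, seed = seed, E = E,
                    verbose = verbose)
  structure(list(call = match.call(), panel = panel, graph = graph,
                 spec = spec, E = E,
                 time = encode_time(length(panel$time_ids), spec$time_coding),
                 draws = draws),
            class = "stmmr")
}

#' @export
print.stmmr <- function(x, ...) {
  cat("Spatio-temporal CAR model (Poisson/ICAR), model",
      as.character(x$spec$model), "\n")
  cat(length(x$panel$area_ids), "areas x", length(x$panel$time_ids),
      "periods;", length(x$draws$alpha), "retained draws from",
      x$draws$meta$chains, "chain(s)\n")
  cm <- coef(x)
  cat("Posterior means: alpha =", format(cm[["alpha"]], digits = 4),
      " gamma =", format(cm[["gamma"]], digits = 4), "\n")
  invisible(x)
}

#' @export
coef.stmmr <- function(object, ...) {
  d <- object$draws
  out <- c(alpha = mean(d$alpha), gamma = mean(d$gamma))
  if (ncol(d$beta) > 0) {
    b <- colMeans(d$beta)
    names(b) <- paste0("beta_", colnames(d$beta))
    out <- c(out, b)
  }
  out
}

#' @export
summary.stmmr <- function(object, ...) {
  s <- summarize_draws(object$draws)
  attr(s, "dic") <- tryCatch(compute_dic(object), error = function(e) NULL)
  attr(s, "model") <- object$spec$model
  s
}

#' @export
print.stmmr_summary <- function(x, n = 12L, ...) {
  cat("Posterior summary (mean, sd, 95% credible interval, rr = exp(mean))\n")
  fixed <- x[grepl("^(alpha|gamma|beta_|tau_)", x$parameter), , drop = FALSE]
  print.data.frame(fixed, digits = 4, row.names = FALSE)
  nlat <- nrow(x) - nrow(fixed)
  if (nlat > 0) cat("... plus", nlat, "latent area effects (s, u, delta)\n")
  d <- attr(x, "dic")
  if (!is.null(d)) cat(sprintf("DIC = %.1f (Dbar = %.1f, pD = %.1f)\n",
                               d$dic, d$dbar, d$p_d))
  invisible(x)
}

# posterior-mean linear predictor
eta_hat_ <- function(object) {
  d <- object$draws
  beta <- if (ncol(d$beta) > 0) colMeans(d$beta) else numeric(0)
  X <- build_design(object$panel, object$spec)$X
  linear_predictor(mean(d$alpha), colMeans(d$s), colMeans(d$u),
                   beta, X, mean(d$gamma), colMeans(d$delta), object$time)
}

#' @export
fitted.stmmr <- function(object, ...) {
  object$E * exp(eta_hat_(object))
}

#' @export
residuals.stmmr <- function(object, type = c("pearson", "deviance", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  O <- object$panel$O
  switch(type,
    response = O - mu,
    pearson = (O - mu) / sqrt(mu),
    deviance = {
      dd <- 2 * (ifelse(O > 0, O * log(O / mu), 0) - (O - mu))
      sign(O - mu) * sqrt(pmax(dd, 0))
    })
}

#' Simulate replicate panels from a fitted model
#'
#' Draws `nsim` replicate count panels, each generated from one retained
#' posterior draw of the full parameter set (posterior predictive
#' replicates).
#'
#' @param object a fitted `stmmr` model.
#' @param nsim number of replicate panels.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of N x T count matrices.
#' @export
simulate.stmmr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$draws
  M <- length(d$alpha)
  X <- build_design(object$panel, object$spec)$X
  idx <- sample.int(M, nsim, replace = nsim > M)
  lapply(idx, function(j) {
    beta <- if (ncol(d$beta) > 0) d$beta[j, ] else numeric(0)
    eta <- linear_predictor(d$alpha[j], d$s[j, ], d$u[j, ], beta, X,
                            d$gamma[j], d$delta[j, ], object$time)
    matrix(stats::rpois(length(eta), as.vector(object$E * exp(eta))),
           nrow(eta), ncol(eta), dimnames = dimnames(object$panel$O))
  })
}

#' @export
plot.stmmr <- function(x, which = c("exceedance", "trend", "trace"), ...) {
  which <- match.arg(which)
  if (which == "exceedance") {
    p <- exceedance_prob(x)
    graphics::barplot(p, names.arg = x$panel$area_ids, las = 2,
                      ylim = c(0, 1), ylab = "P(spatial RR > 1 | data)",
                      main = "Exceedance probability by area", ...)
    graphics::abline(h = 0.5, lty = 2)
  } else if (which == "trend") {
    it <- interaction_trend_summary(x)
    o <- order(it$delta_mean)
    graphics::plot(seq_len(nrow(it)), it$delta_mean[o], pch = 19,
                   ylim = range(c(it$delta_lo, it$delta_hi)),
                   xaxt = "n", xlab = "", ylab = expression(delta[i]),
                   main = "Area-specific trend deviations", ...)
    graphics::segments(seq_len(nrow(it)), it$delta_lo[o],
                       seq_len(nrow(it)), it$delta_hi[o])
    graphics::axis(1, at = seq_len(nrow(it)), labels = it$area_id[o], las = 2)
    graphics::abline(h = 0, lty = 2)
  } else {
    op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$draws$alpha, type = "l", ylab = expression(alpha),
                   main = "Trace: intercept")
    graphics::plot(x$draws$gamma, type = "l", ylab = expression(gamma),
                   main = "Trace: common trend")
  }
  invisible(x)
}

#' Deviance information criterion of a fitted model
#'
#' \eqn{D(\theta) = -2\,\log L(\theta)}; `dbar` is the posterior mean
#' deviance, `d_at_mean` the deviance at the posterior means of all
#' parameters including the latent field (so the effective parameter count
#' `p_d = dbar - d_at_mean` includes the random effects), and
#' `dic = dbar + p_d`. The log-factorial likelihood term is retained, making
#' DIC values absolute and comparable across models on the same data.
#'
#' @param fit a fitted `stmmr` object (or pass `draws`, `panel`, `E`, `spec`
#'   explicitly).
#' @param panel,E,spec optional explicit inputs when `fit` is an
#'   `stmmr_draws` object.
#' @return an object of class `stmmr_dic`: list with `dbar`, `d_at_mean`,
#'   `p_d`, `dic`.
#' @export
compute_dic <- function(fit, panel = NULL, E = NULL, spec = NULL) {
  if (inherits(fit, "stmmr")) {
    draws <- fit$draws; panel <- fit$panel; E <- fit$E; spec <- fit$spec
    tvec <- fit$time
  } else {
    draws <- fit
    stopifnot(inherits(draws, "stmmr_draws"), inherits(panel, "areal_panel"))
    if (is.null(E)) E <- matrix(1, nrow(panel$O), ncol(panel$O))
    if (is.null(spec)) spec <- model_spec(1)
    tvec <- encode_time(ncol(panel$O), spec$time_coding)
  }
  M <- length(draws$alpha)
  if (M < 1) stop("empty draws")
  O <- panel$O
  X <- build_design(panel, spec)$X
  dev <- numeric(M)
  for (j in seq_len(M)) {
    beta <- if (ncol(draws$beta) > 0) draws$beta[j, ] else numeric(0)
    eta <- linear_predictor(draws$alpha[j], draws$s[j, ], draws$u[j, ], beta,
                            X, draws$gamma[j], draws$delta[j, ], tvec)
    dev[j] <- -2 * as.numeric(poisson_loglik(O, E, eta))
  }
  beta_m <- if (ncol(draws$beta) > 0) colMeans(draws$beta) else numeric(0)
  eta_m <- linear_predictor(mean(draws$alpha), colMeans(draws$s),
                            colMeans(draws$u), beta_m, X,
                            mean(draws$gamma), colMeans(draws$delta), tvec)
  d_at_mean <- -2 * as.numeric(poisson_loglik(O, E, eta_m))
  dbar <- mean(dev)
  structure(list(dbar = dbar, d_at_mean = d_at_mean,
                 p_d = dbar - d_at_mean, dic = dbar + (dbar - d_at_mean)),
            class = "stmmr_dic")
}

#' @export
print.stmmr_dic <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (Dbar = %.2f, D(theta_bar) = %.2f, pD = %.2f)\n",
              x$dic, x$dbar, x$d_at_mean, x$p_d))
  invisible(x)
}
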