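#' Posterior sampling for the spatio-temporal CAR model
#'
#' Adaptive Metropolis-within-Gibbs sampler for the Poisson model
#' \eqn{O_{it} \sim \mathrm{Poisson}(E_{it} e^{\eta_{it}})} with
#' \eqn{\eta_{it} = \alpha + s_i + u_i + x_i'\beta + (\gamma+\delta_i)t_t}.
#' Fixed effects get vague Normal(0, 1000^2) priors and adaptive random-walk
#' updates (Robbins-Monro scaling toward 0.44 acceptance, frozen at the end
#' of burn-in). Precisions are updated by their conjugate Gamma full
#' conditionals. The ICAR effects s and delta and the heterogeneity u are
#' updated site-wise, vectorised over graph-colour classes: first an
#' independence proposal from the prior full conditional (whose acceptance
#' ratio is the pure likelihood ratio), then an adaptive random-walk refresh.
#' After every sweep the global means of s and delta are transferred into
#' alpha and gamma respectively (an exact reparameterisation on connected
#' graphs) and per-component sum-to-zero centring is applied.
#'
#' @param panel an [areal_panel].
#' @param graph an [adjacency_graph] with `n` equal to the panel's area count.
#' @param spec a [model_spec].
#' @param iters sweeps per chain (must exceed `burnin`).
#' @param burnin sweeps discarded per chain.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param chains number of independent chains (seeded `seed + 0:(chains-1)`);
#'   retained draws are concatenated.
#' @param seed integer seed; mandatory, drives all randomness.
#' @param E N x T expected-count matrix (default all ones).
#' @param prior_only if TRUE the likelihood is switched off and the sampler
#'   explores the prior (diagnostic use).
#' @param verbose print progress per chain.
#' @return an object of class `stmmr_draws`: vectors/matrices of retained
#'   draws for `alpha`, `gamma`, `beta`, `s`, `u`, `delta`, `tau_s`, `tau_u`,
#'   `tau_delta`, plus `meta` (seed, chains, burn-in, thinning, per-chain
#'   acceptance rates, chain index of every draw, warnings).
#' @export
run_mcmc <- function(panel, graph, spec, iters = 20000, burnin = 10000,
                     thin = 5, chains = 4, seed, E = NULL,
                     prior_only = FALSE, verbose = FALSE) {
  stopifnot(inherits(panel, "areal_panel"), inherits(graph, "adjacency_graph"),
            inherits(spec, "model_spec"))
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  seed <- as.integer(seed)
  N <- length(panel$area_ids); T <- length(panel$time_ids)
  if (graph$n != N) stop("graph has ", graph$n, " areas but panel has ", N)
  if (iters <= burnin) stop("iters must exceed burnin")
  if (thin < 1) stop("thin must be >= 1")
  keep <- floor((iters - burnin) / thin)
  if (keep < 1) stop("no draws would be retained")

  O <- panel$O
  if (is.null(E)) E <- matrix(1, N, T)
  E <- as.matrix(E)
  if (!all(dim(E) == c(N, T)) || any(E <= 0)) stop("E must be a positive N x T matrix")
  des <- build_design(panel, spec)
  X <- des$X; K <- ncol(X)
  tvec <- encode_time(T, spec$time_coding)
  hy <- spec$hyper
  colors <- graph_coloring_(graph)
  colors <- lapply(colors, function(cl) setdiff(cl, graph$islands))
  colors <- colors[lengths(colors) > 0L]
  deg <- lengths(graph$neighbors)
  edges <- edge_list_(graph)
  has_edges <- nrow(edges) > 0L
  non_island <- setdiff(seq_len(N), graph$islands)
  # rank of the ICAR precision: non-island areas minus non-trivial components
  comp_sizes <- tabulate(graph$component)
  icar_rank <- length(non_island) - sum(comp_sizes > 1L)
  connected_clean <- graph$n_components == 1L && length(graph$islands) == 0L

  inc_s <- spec$include_spatial && has_edges
  inc_u <- spec$include_iid
  inc_tr <- spec$include_trend
  inc_int <- spec$include_interaction && has_edges
  ft <- spec$fixed_tau %||% list()

  rowO <- rowSums(O); sumO <- sum(rowO)
  Ot <- as.vector(O %*% tvec)   # per-area count-weighted time scores
  sumOt <- sum(Ot)
  prior_sd <- 1000

  total <- keep * chains
  out <- list(
    alpha = numeric(total), gamma = numeric(total),
    beta = matrix(0, total, K, dimnames = list(NULL, des$names)),
    s = matrix(0, total, N), u = matrix(0, total, N), delta = matrix(0, total, N),
    tau_s = numeric(total), tau_u = numeric(total), tau_delta = numeric(total))
  chain_id <- integer(total)
  acc_meta <- vector("list", chains)
  warnings <- character(0)

  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    # --- state ---
    alpha <- log((sumO + 0.5) / sum(E))
    gamma <- 0
    beta <- rep(0, K)
    s <- numeric(N); u <- numeric(N); delta <- numeric(N)
    tau_s <- ft$tau_s %||% 10
    tau_u <- ft$tau_u %||% 100
    tau_delta <- ft$tau_delta %||% 10
    mu <- E * exp(alpha)
    if (any(!is.finite(mu)) ||
        (!prior_only && !is.finite(poisson_loglik(O, E, matrix(alpha, N, T)))))
      stop("non-finite likelihood at initialisation")

    # adaptive log step sizes
    ls_a <- log(0.1); ls_g <- log(0.05); ls_b <- rep(log(0.1), K)
    ls_s <- rep(log(0.1), N); ls_u <- rep(log(0.1), N); ls_d <- rep(log(0.05), N)
    nacc <- c(alpha = 0, gamma = 0, beta = 0, s = 0, u = 0, delta = 0)
    nprop <- c(alpha = 0, gamma = 0, beta = 0, s = 0, u = 0, delta = 0)

    for (it in seq_len(iters)) {
      adapting <- it <= burnin
      gain <- if (adapting) 2 * (it + 20)^(-0.7) else 0
      post <- it > burnin

      ## alpha
      d <- exp(ls_a) * stats::rnorm(1)
      logr <- (if (prior_only) 0 else sumO * d - sum(mu) * expm1(d)) +
        stats::dnorm(alpha + d, 0, prior_sd, log = TRUE) -
        stats::dnorm(alpha, 0, prior_sd, log = TRUE)
      acc <- is.finite(logr) && log(stats::runif(1)) < logr
      if (acc) { alpha <- alpha + d; if (!prior_only) mu <- mu * exp(d) }
      ls_a <- ls_a + gain * ((if (acc) 1 else 0) - 0.44)
      if (post) { nprop["alpha"] <- nprop["alpha"] + 1; nacc["alpha"] <- nacc["alpha"] + acc }

      ## gamma
      if (inc_tr) {
        d <- exp(ls_g) * stats::rnorm(1)
        fac <- expm1(d * tvec)
        logr <- (if (prior_only) 0 else sumOt * d - sum(colSums(mu) * fac)) +
          stats::dnorm(gamma + d, 0, prior_sd, log = TRUE) -
          stats::dnorm(gamma, 0, prior_sd, log = TRUE)
        acc <- is.finite(logr) && log(stats::runif(1)) < logr
        if (acc) { gamma <- gamma + d; mu <- mu * rep(exp(d * tvec), each = N) }
        ls_g <- ls_g + gain * ((if (acc) 1 else 0) - 0.44)
        if (post) { nprop["gamma"] <- nprop["gamma"] + 1; nacc["gamma"] <- nacc["gamma"] + acc }
      }

      ## beta
      if (K > 0) {
        for (k in seq_len(K)) {
          d <- exp(ls_b[k]) * stats::rnorm(1)
          xk <- X[, k]
          logr <- (if (prior_only) 0 else
                     d * sum(rowO * xk) - sum(rowSums(mu) * expm1(d * xk))) +
            stats::dnorm(beta[k] + d, 0, prior_sd, log = TRUE) -
            stats::dnorm(beta[k], 0, prior_sd, log = TRUE)
          acc <- is.finite(logr) && log(stats::runif(1)) < logr
          if (acc) { beta[k] <- beta[k] + d; mu <- mu * exp(d * xk) }
          ls_b[k] <- ls_b[k] + gain * ((if (acc) 1 else 0) - 0.44)
          if (post) { nprop["beta"] <- nprop["beta"] + 1; nacc["beta"] <- nacc["beta"] + acc }
        }
      }

      ## precisions (conjugate Gamma)
      if (inc_s && is.null(ft$tau_s)) {
        ss <- sum((s[edges[, 1L]] - s[edges[, 2L]])^2)
        tau_s <- stats::rgamma(1, hy$a_s + icar_rank / 2, hy$b_s + ss / 2)
      }
      if (inc_int && is.null(ft$tau_delta)) {
        ss <- sum((delta[edges[, 1L]] - delta[edges[, 2L]])^2)
        tau_delta <- stats::rgamma(1, hy$a_d + icar_rank / 2, hy$b_d + ss / 2)
      }
      if (inc_u && is.null(ft$tau_u)) {
        tau_u <- stats::rgamma(1, hy$a_u + N / 2, hy$b_u + sum(u^2) / 2)
      }

      ## spatial effect s: per colour class
      if (inc_s) {
        for (cl in colors) {
          m <- vapply(graph$neighbors[cl], function(v) sum(s[v]), 0) / deg[cl]
          rs <- rowSums(mu[cl, , drop = FALSE])
          # pass 1: independence proposal from the prior full conditional
          prop <- stats::rnorm(length(cl), m, 1 / sqrt(tau_s * deg[cl]))
          d <- prop - s[cl]
          logr <- if (prior_only) numeric(length(cl)) else rowO[cl] * d - rs * expm1(d)
          acc <- is.finite(logr) & log(stats::runif(length(cl))) < logr
          if (any(acc)) {
            ai <- cl[acc]
            s[ai] <- prop[acc]
            mu[ai, ] <- mu[ai, , drop = FALSE] * exp(d[acc])
            rs[acc] <- rs[acc] * exp(d[acc])
          }
          # pass 2: adaptive random walk
          d <- exp(ls_s[cl]) * stats::rnorm(length(cl))
          prop <- s[cl] + d
          logr <- (if (prior_only) 0 else rowO[cl] * d - rs * expm1(d)) -
            (tau_s * deg[cl] / 2) * ((prop - m)^2 - (s[cl] - m)^2)
          acc <- is.finite(logr) & log(stats::runif(length(cl))) < logr
          if (any(acc)) {
            ai <- cl[acc]
            s[ai] <- prop[acc]
            mu[ai, ] <- mu[ai, , drop = FALSE] * exp(d[acc])
          }
          ls_s[cl] <- ls_s[cl] + gain * (acc - 0.44)
          if (post) { nprop["s"] <- nprop["s"] + length(cl); nacc["s"] <- nacc["s"] + sum(acc) }
        }
      }

      ## heterogeneity u: all sites at once (prior independent)
      if (inc_u) {
        rs <- rowSums(mu)
        prop <- stats::rnorm(N, 0, 1 / sqrt(tau_u))
        d <- prop - u
        logr <- if (prior_only) numeric(N) else rowO * d - rs * expm1(d)
        acc <- is.finite(logr) & log(stats::runif(N)) < logr
        if (any(acc)) {
          u[acc] <- prop[acc]
          mu[acc, ] <- mu[acc, , drop = FALSE] * exp(d[acc])
          rs[acc] <- rs[acc] * exp(d[acc])
        }
        d <- exp(ls_u) * stats::rnorm(N)
        prop <- u + d
        logr <- (if (prior_only) 0 else rowO * d - rs * expm1(d)) -
          (tau_u / 2) * (prop^2 - u^2)
        acc <- is.finite(logr) & log(stats::runif(N)) < logr
        if (any(acc)) {
          u[acc] <- prop[acc]
          mu[acc, ] <- mu[acc, , drop = FALSE] * exp(d[acc])
        }
        ls_u <- ls_u + gain * (acc - 0.44)
        if (post) { nprop["u"] <- nprop["u"] + N; nacc["u"] <- nacc["u"] + sum(acc) }
      }

      ## trend deviations delta: per colour class
      if (inc_int) {
        for (cl in colors) {
          m <- vapply(graph$neighbors[cl], function(v) sum(delta[v]), 0) / deg[cl]
          prop <- stats::rnorm(length(cl), m, 1 / sqrt(tau_delta * deg[cl]))
          d <- prop - delta[cl]
          fac <- exp(outer(d, tvec))           # |cl| x T
          logr <- if (prior_only) numeric(length(cl)) else
            Ot[cl] * d - rowSums(mu[cl, , drop = FALSE] * (fac - 1))
          acc <- is.finite(logr) & log(stats::runif(length(cl))) < logr
          if (any(acc)) {
            ai <- cl[acc]
            delta[ai] <- prop[acc]
            mu[ai, ] <- mu[ai, , drop = FALSE] * fac[acc, , drop = FALSE]
          }
          d <- exp(ls_d[cl]) * stats::rnorm(length(cl))
          prop <- delta[cl] + d
          fac <- exp(outer(d, tvec))
          logr <- (if (prior_only) 0 else
                     Ot[cl] * d - rowSums(mu[cl, , drop = FALSE] * (fac - 1))) -
            (tau_delta * deg[cl] / 2) * ((prop - m)^2 - (delta[cl] - m)^2)
          acc <- is.finite(logr) & log(stats::runif(length(cl))) < logr
          if (any(acc)) {
            ai <- cl[acc]
            delta[ai] <- prop[acc]
            mu[ai, ] <- mu[ai, , drop = FALSE] * fac[acc, , drop = FALSE]
          }
          ls_d[cl] <- ls_d[cl] + gain * (acc - 0.44)
          if (post) { nprop["delta"] <- nprop["delta"] + length(cl); nacc["delta"] <- nacc["delta"] + sum(acc) }
        }
      }

      ## identifiability centring
      if (inc_s) {
        if (connected_clean) {
          mshift <- mean(s)
          alpha <- alpha + mshift
          s <- s - mshift            # eta unchanged; mu untouched
        } else {
          s <- center_by_component_(s, graph)
          s[graph$islands] <- 0
          mu <- E * exp(eta_state_(alpha, s, u, beta, X, gamma, delta, tvec))
        }
      }
      if (inc_int) {
        if (connected_clean && inc_tr) {
          mshift <- mean(delta)
          gamma <- gamma + mshift
          delta <- delta - mshift
        } else {
          delta <- center_by_component_(delta, graph)
          delta[graph$islands] <- 0
          mu <- E * exp(eta_state_(alpha, s, u, beta, X, gamma, delta, tvec))
        }
      }

      ## store
      if (post && (it - burnin) %% thin == 0L) {
        j <- (ch - 1L) * keep + (it - burnin) %/% thin
        if (j <= total) {
          out$alpha[j] <- alpha; out$gamma[j] <- gamma
          if (K > 0) out$beta[j, ] <- beta
          out$s[j, ] <- s; out$u[j, ] <- u; out$delta[j, ] <- delta
          out$tau_s[j] <- tau_s; out$tau_u[j] <- tau_u; out$tau_delta[j] <- tau_delta
          chain_id[j] <- ch
        }
      }
    }
    rates <- ifelse(nprop > 0, nacc / nprop, NA_real_)
    acc_meta[[ch]] <- rates
    bad <- names(rates)[names(rates) %in% c("alpha", "gamma", "beta") &
                          !is.na(rates) & (rates < 0.05 | rates > 0.95)]
    if (length(bad)) {
      msg <- paste0("chain ", ch, ": post-adaptation acceptance rate outside [0.05, 0.95] for ",
                    paste(bad, collapse = ", "))
      warnings <- c(warnings, msg)
      warning(msg)
    }
    if (verbose) message("chain ", ch, " done")
  }

  out$meta <- list(seed = seed, chains = chains, iters = iters, burnin = burnin,
                   thin = thin, chain_id = chain_id,
                   acceptance = acc_meta, warnings = warnings,
                   covariate_names = des$names, time = tvec,
                   prior_only = prior_only)
  class(out) <- "stmmr_draws"
  out
}

# edge list (i < j) as a 2-column integer matrix
edge_list_ <- function(graph) {
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(graph$n)) {
    js <- graph$neighbors[[i]]
    js <- js[js > i]
    ei <- c(ei, rep.int(i, length(js))); ej <- c(ej, js)
  }
  cbind(ei, ej)
}

eta_state_ <- function(alpha, s, u, beta, X, gamma, delta, tvec) {
  linear_predictor(alpha, s, u, beta, X, gamma, delta, tvec)
}

#' @export
print.stmmr_draws <- function(x, ...) {
  cat("stmmr posterior draws:", length(x$alpha), "retained draws,",
      x$meta$chains, "chain(s),", ncol(x$s), "areas\n")
  invisible(x)
}

#' Summarise posterior draws
#'
#' Posterior mean, standard deviation and equal-tailed 95% credible interval
#' for every scalar parameter, plus a relative-risk column `rr = exp(mean)`
#' for the intercept, trend and covariate coefficients (the transformation
#' used to report covariate effects on the risk scale).
#'
#' @param draws an `stmmr_draws` object (or an `stmmr` fit).
#' @return a data.frame of class `stmmr_summary` with columns `parameter`,
#'   `mean`, `sd`, `q2.5`, `q97.5`, `rr`.
#' @export
summarize_draws <- function(draws) {
  if (inherits(draws, "stmmr")) draws <- draws$draws
  stopifnot(inherits(draws, "stmmr_draws"))
  M <- length(draws$alpha)
  if (M < 100) stop("need at least 100 retained draws to summarise (have ", M, ")")
  cols <- list(alpha = draws$alpha, gamma = draws$gamma)
  K <- ncol(draws$beta)
  if (K > 0) {
    bn <- colnames(draws$beta)
    if (is.null(bn)) bn <- paste0("x", seq_len(K))
    for (k in seq_len(K)) cols[[paste0("beta_", bn[k])]] <- draws$beta[, k]
  }
  N <- ncol(draws$s)
  for (i in seq_len(N)) cols[[paste0("s[", i, "]")]] <- draws$s[, i]
  for (i in seq_len(N)) cols[[paste0("u[", i, "]")]] <- draws$u[, i]
  for (i in seq_len(N)) cols[[paste0("delta[", i, "]")]] <- draws$delta[, i]
  cols$tau_s <- draws$tau_s; cols$tau_u <- draws$tau_u; cols$tau_delta <- draws$tau_delta
  nm <- names(cols)
  mean_ <- vapply(cols, mean, 0)
  sd_ <- vapply(cols, stats::sd, 0)
  q <- vapply(cols, function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE), numeric(2))
  rr <- ifelse(grepl("^(alpha|gamma|beta_)", nm), exp(mean_), NA_real_)
  out <- data.frame(parameter = nm, mean = mean_, sd = sd_,
                    q2.5 = q[1L, ], q97.5 = q[2L, ], rr = rr,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("stmmr_summary", "data.frame")
  out
}

#' Relative-risk transform of a log-scale coefficient
#'
#' @param coef finite numeric coefficient(s) on the log relative-risk scale.
#' @return `exp(coef)`.
#' @examples
#' rr_transform(-0.720)   # 0.486752...
#' @export
rr_transform <- function(coef) {
  if (any(!is.finite(coef))) stop("coef must be finite")
  exp(coef)
}
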