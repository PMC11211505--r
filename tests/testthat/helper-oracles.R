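# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own computation paths.

# cell-by-cell Poisson log-pmf sum via dpois
naive_poisson_loglik <- function(O, E, eta) {
  sum(stats::dpois(as.vector(O), as.vector(E * exp(eta)), log = TRUE))
}

# normal-equations OLS with t-based slope CI
naive_ols <- function(y, t) {
  X <- cbind(1, t)
  XtXi <- solve(crossprod(X))
  b <- as.vector(XtXi %*% crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - 2L
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * XtXi[2L, 2L])
  half <- stats::qt(0.975, df) * se
  list(intercept = b[1L], slope = b[2L], se = se,
       lo = b[2L] - half, hi = b[2L] + half)
}

# Brook's-lemma reconstruction of the ICAR kernel log-ratio from the
# full conditionals: log p(x) - log p(x0)
brook_logratio <- function(x, x0, graph, tau) {
  n <- graph$n
  total <- 0
  for (i in seq_len(n)) {
    z <- x0
    if (i > 1L) z[seq_len(i - 1L)] <- x[seq_len(i - 1L)]
    fc <- icar_full_conditional(i, z, graph, tau)
    sdv <- sqrt(fc$variance)
    total <- total +
      stats::dnorm(x[i], fc$mean, sdv, log = TRUE) -
      stats::dnorm(x0[i], fc$mean, sdv, log = TRUE)
  }
  total
}

# all labelled graphs on n nodes with minimum degree >= 1
all_graphs_min_deg1 <- function(n) {
  ed <- t(utils::combn(n, 2L))
  m <- nrow(ed)
  out <- list()
  for (mask in seq_len(2^m - 1L)) {
    sel <- ed[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L, , drop = FALSE]
    deg <- tabulate(c(sel), n)
    if (any(deg == 0L)) next
    nbr <- lapply(seq_len(n), function(i)
      sort(c(sel[sel[, 1L] == i, 2L], sel[sel[, 2L] == i, 1L])))
    out[[length(out) + 1L]] <- adjacency_graph(nbr)
  }
  out
}

# dense grid-integration posterior for the 2-area, 2-time baseline model
# with fixed precisions and no iid term: marginal means of
# (alpha, gamma, s1, delta1) under s = (s1, -s1), delta = (d1, -d1)
grid_posterior_2x2 <- function(O, E, tau_s, tau_d, prior_sd = 1000,
                               npt = 41L, passes = 2L) {
  tvec <- c(-0.5, 0.5)
  logpost <- function(a, g, s1, d1) {
    ll <- 0
    for (i in 1:2) {
      si <- if (i == 1L) s1 else -s1
      di <- if (i == 1L) d1 else -d1
      for (tt in 1:2) {
        eta <- a + si + (g + di) * tvec[tt]
        ll <- ll + O[i, tt] * eta - E[i, tt] * exp(eta)
      }
    }
    ll + stats::dnorm(a, 0, prior_sd, log = TRUE) +
      stats::dnorm(g, 0, prior_sd, log = TRUE) -
      2 * tau_s * s1^2 - 2 * tau_d * d1^2
  }
  a0 <- log(sum(O) / sum(E))
  ctr <- c(a0, 0, 0, 0)
  hw <- c(1.5, 1.5, 1.5, 1.5)
  for (pass in seq_len(passes)) {
    gr <- lapply(1:4, function(k) seq(ctr[k] - hw[k], ctr[k] + hw[k], length.out = npt))
    eg <- expand.grid(a = gr[[1L]], g = gr[[2L]], s1 = gr[[3L]], d1 = gr[[4L]])
    lp <- logpost(eg$a, eg$g, eg$s1, eg$d1)
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    ctr <- c(sum(w * eg$a), sum(w * eg$g), sum(w * eg$s1), sum(w * eg$d1))
    sds <- sqrt(c(sum(w * (eg$a - ctr[1L])^2), sum(w * (eg$g - ctr[2L])^2),
                  sum(w * (eg$s1 - ctr[3L])^2), sum(w * (eg$d1 - ctr[4L])^2)))
    hw <- pmax(7 * sds, 1e-3)
  }
  stats::setNames(ctr, c("alpha", "gamma", "s1", "delta1"))
}

# hand-built draws container for post-inference unit tests
make_draws <- function(s, delta = NULL, alpha = NULL, gamma = NULL) {
  s <- as.matrix(s)
  M <- nrow(s); N <- ncol(s)
  if (is.null(delta)) delta <- matrix(0, M, N)
  if (is.null(alpha)) alpha <- numeric(M)
  if (is.null(gamma)) gamma <- numeric(M)
  structure(list(alpha = alpha, gamma = gamma,
                 beta = matrix(0, M, 0),
                 s = s, u = matrix(0, M, N), delta = as.matrix(delta),
                 tau_s = rep(1, M), tau_u = rep(1, M), tau_delta = rep(1, M),
                 meta = list(chains = 1L)),
            class = "stmmr_draws")
}

# small toy panel used by several io tests
toy_panel <- function() {
  areal_panel(matrix(c(10L, 20L, 12L, 18L), 2, 2),
              c("A", "B"), c(1, 2),
              P = matrix(c(100, 300, 110, 290), 2, 2))
}

# Table of published posterior means and relative risks for the covariate
# models of the state-level MMR analysis (the mutually consistent rows).
published_rr_table <- function() {
  data.frame(
    term = c("birth_order_gt3", "low_birth_interval", "c_section",
             "contraception", "anemia", "low_bmi",
             "population", "pnc", "institutional_delivery", "health_index",
             "accreditation", "nqas", "ghe", "oope", "jsy",
             "skilled_attendance"),
    mean = c(0.4048, 0.4939, -0.125, -0.116, 0.0594, 0.2912,
             0.1655, -0.036, -0.720, -0.486, -0.041, -0.198, -0.083,
             0.2601, 0.3266, -0.968),
    rr = c(1.49900267, 1.638695, 0.8824969, 0.8904752, 1.0612, 1.338032,
           1.179982963, 0.964640293, 0.486752, 0.615082, 0.959829, 0.82037,
           0.920351, 1.29706, 1.386247, 0.379842),
    stringsAsFactors = FALSE)
}
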