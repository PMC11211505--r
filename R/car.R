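#' Gamma hyperprior settings for the random-effect precisions
#'
#' Shape/rate pairs for the Gamma hyperpriors on the three precisions: the
#' spatially structured effect (`tau_s`), the unstructured heterogeneity
#' (`tau_u`) and the area-specific trend deviations (`tau_delta`). The
#' default Gamma(1, 0.0005) is a widespread weakly-informative choice in
#' disease mapping (prior mean 2000, sd 2000 on the precision scale).
#'
#' @param a_s,b_s,a_u,b_u,a_d,b_d positive shape/rate values.
#' @return an object of class `hyperparams`.
#' @export
hyperparams <- function(a_s = 1, b_s = 5e-4, a_u = 1, b_u = 5e-4,
                        a_d = 1, b_d = 5e-4) {
  v <- c(a_s = a_s, b_s = b_s, a_u = a_u, b_u = b_u, a_d = a_d, b_d = b_d)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all hyperparameters must be positive and finite")
  structure(as.list(v), class = "hyperparams")
}

#' Intrinsic CAR log-density (unnormalised)
#'
#' Log kernel of the intrinsic conditionally autoregressive (ICAR) prior with
#' unit adjacency weights:
#' \deqn{((n - c)/2)\log\tau - (\tau/2)\sum_{i \sim j, i<j} (x_i - x_j)^2}
#' where `c` is the number of connected components of the graph (the rank
#' deficiency of the pairwise-difference precision). Additive constants are
#' dropped. The kernel is invariant to adding a constant per component.
#'
#' @param x numeric vector, one value per area.
#' @param graph an [adjacency_graph] with at least one edge.
#' @param tau positive precision.
#' @return scalar log-density (up to a constant).
#' @export
icar_logpdf <- function(x, graph, tau) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(x) != graph$n) stop("length(x) must equal graph$n")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (graph_n_edges(graph) == 0L)
    stop("ICAR prior is undefined on an edgeless graph")
  ss <- 0
  for (i in seq_len(graph$n)) {
    for (j in graph$neighbors[[i]]) {
      if (j > i) ss <- ss + (x[i] - x[j])^2
    }
  }
  ((graph$n - graph$n_components) / 2) * log(tau) - (tau / 2) * ss
}

#' ICAR full-conditional moments at one area
#'
#' Under the intrinsic CAR prior, the conditional distribution of `x[i]` given
#' all other areas is Normal with mean the average of its neighbours' values
#' and variance `1 / (tau * n_i)` where `n_i` is the neighbour count.
#'
#' @param i area index.
#' @param x numeric vector of current values.
#' @param graph an [adjacency_graph].
#' @param tau positive precision.
#' @return list with elements `mean` and `variance`.
#' @export
icar_full_conditional <- function(i, x, graph, tau) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(x) != graph$n) stop("length(x) must equal graph$n")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  nb <- graph$neighbors[[i]]
  if (length(nb) == 0L)
    stop("area ", i, " is an island: its ICAR full conditional is undefined; ",
         "island variation is modelled by the unstructured effect only")
  list(mean = mean(x[nb]), variance = 1 / (tau * length(nb)))
}

#' Centre a vector to sum to zero
#'
#' Subtracts the mean, the sum-to-zero projection used to identify the
#' intrinsic CAR effects against the intercept.
#'
#' @param x numeric vector.
#' @return `x - mean(x)`.
#' @export
center_sum_to_zero <- function(x) {
  if (length(x) < 1L) stop("x must be non-empty")
  x - mean(x)
}

# per-component sum-to-zero projection; islands are left untouched
center_by_component_ <- function(x, graph) {
  for (k in seq_len(graph$n_components)) {
    idx <- which(graph$component == k)
    if (length(idx) > 1L) x[idx] <- x[idx] - mean(x[idx])
  }
  x
}

#' Draw from the intrinsic CAR prior restricted to the sum-to-zero subspace
#'
#' Samples a zero-mean Gaussian whose precision is `tau` times the graph
#' Laplacian, restricted to the span of its positive eigenvalues (the
#' pairwise-difference kernel), then centred per connected component. Island
#' areas receive 0.
#'
#' @param graph an [adjacency_graph].
#' @param tau positive precision.
#' @return numeric vector of length `graph$n` summing to zero per component.
#' @export
ricar <- function(graph, tau) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  n <- graph$n
  deg <- lengths(graph$neighbors)
  Q <- diag(deg, n, n)
  for (i in seq_len(n)) Q[i, graph$neighbors[[i]]] <- -1
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values, 1) * 1e-10
  if (!any(pos)) return(numeric(n))
  z <- stats::rnorm(sum(pos)) / sqrt(tau * e$values[pos])
  x <- as.vector(e$vectors[, pos, drop = FALSE] %*% z)
  x[graph$islands] <- 0
  center_by_component_(x, graph)
}
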