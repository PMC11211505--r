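#' Expected counts for an areal panel
#'
#' `mode = "unit"` returns a matrix of ones: appropriate when the observed
#' quantity is already a ratio standardised to a common denominator (maternal
#' deaths per 100,000 live births), the convention used for the state-level
#' MMR analysis. `mode = "internal"` performs classical internal
#' standardisation within each time period:
#' \deqn{E_{it} = P_{it} \cdot \frac{\sum_i O_{it}}{\sum_i P_{it}}}
#' so that \eqn{\sum_i E_{it} = \sum_i O_{it}} for every period.
#'
#' @param panel an [areal_panel]; `mode = "internal"` requires denominators `P`.
#' @param mode `"unit"` (default) or `"internal"`.
#' @return N x T positive matrix of expected counts.
#' @export
expected_counts <- function(panel, mode = c("unit", "internal")) {
  stopifnot(inherits(panel, "areal_panel"))
  mode <- match.arg(mode)
  O <- panel$O
  if (mode == "unit") {
    E <- matrix(1, nrow(O), ncol(O), dimnames = dimnames(O))
    return(E)
  }
  if (is.null(panel$P))
    stop("internal standardisation requires denominators P in the panel")
  P <- panel$P
  rate <- colSums(O) / colSums(P)      # common rate per period
  E <- sweep(P, 2L, rate, `*`)
  dimnames(E) <- dimnames(O)
  E
}

#' Column-wise z-standardisation
#'
#' Scales each column of a matrix to mean 0 and sample (n-1) standard
#' deviation 1, the transformation behind the relative-performance heatmap.
#' Constant columns map to all zeros.
#'
#' @param M numeric matrix with at least 2 rows.
#' @return matrix of the same shape with standardised columns.
#' @export
zscale_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("z-scaling needs at least 2 rows")
  out <- apply(M, 2L, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) return(rep(0, length(col)))
    (col - mean(col)) / s
  })
  dimnames(out) <- dimnames(M)
  out
}
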