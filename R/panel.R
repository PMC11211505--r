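#' Areal count panel
#'
#' Container for an N-area by T-period panel of observed counts (state-level
#' maternal mortality ratios treated as Poisson counts), optional
#' population/live-birth denominators, optional time-constant area-level
#' covariates, and optional expected counts.
#'
#' @param O N x T matrix of non-negative integer counts.
#' @param area_ids character vector of N unique area labels.
#' @param time_ids vector of T ordered time labels.
#' @param P optional N x T matrix of positive denominators.
#' @param X optional N x K numeric matrix of area-level covariates with
#'   column names.
#' @param E optional N x T matrix of positive expected counts.
#' @return an object of class `areal_panel`.
#' @export
areal_panel <- function(O, area_ids, time_ids, P = NULL, X = NULL, E = NULL) {
  O <- as.matrix(O)
  N <- nrow(O); T <- ncol(O)
  if (N < 2L || T < 1L) stop("panel needs N >= 2 areas and T >= 1 periods")
  if (length(area_ids) != N) stop("length(area_ids) != nrow(O)")
  if (length(time_ids) != T) stop("length(time_ids) != ncol(O)")
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop("area_ids must be unique")
  if (anyNA(O)) stop("counts O contain missing cells")
  if (!is.numeric(O) || any(O < 0)) stop("counts O must be non-negative")
  if (any(O != round(O)))
    stop("counts O must be integers; preprocess real-valued observations explicitly")
  storage.mode(O) <- "integer"
  dimnames(O) <- list(area_ids, as.character(time_ids))
  check_mat <- function(M, nm) {
    if (is.null(M)) return(NULL)
    M <- as.matrix(M)
    if (!all(dim(M) == c(N, T))) stop(nm, " must be ", N, " x ", T)
    if (anyNA(M) || any(M <= 0)) stop(nm, " must be positive everywhere")
    dimnames(M) <- dimnames(O)
    M
  }
  P <- check_mat(P, "P")
  E <- check_mat(E, "E")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != N) stop("X must have one row per area")
    if (is.null(colnames(X)) || any(!nzchar(colnames(X))))
      stop("covariate columns must be named")
    if (anyNA(X) || !is.numeric(X)) stop("covariates must be numeric, no NA")
    rownames(X) <- area_ids
  }
  structure(list(area_ids = area_ids, time_ids = as.character(time_ids),
                 O = O, P = P, X = X, E = E),
            class = "areal_panel")
}

#' @export
print.areal_panel <- function(x, ...) {
  cat("Areal panel:", length(x$area_ids), "areas x", length(x$time_ids),
      "periods; counts", min(x$O), "-", max(x$O), "\n")
  if (!is.null(x$X))
    cat("Covariates:", paste(colnames(x$X), collapse = ", "), "\n")
  if (!is.null(x$P)) cat("Denominators present\n")
  invisible(x)
}

#' Read an areal count panel from CSV
#'
#' The counts file must have columns `area_id,time_id,observed` and optional
#' `population`, one row per (area, time) cell. Areas keep first-appearance
#' order; times are sorted ascending. An optional covariates file keyed by
#' `area_id` supplies time-constant area-level covariates.
#'
#' @param counts_path path to the counts CSV.
#' @param covariates_path optional path to the covariates CSV.
#' @return an [areal_panel].
#' @export
read_panel <- function(counts_path, covariates_path = NULL) {
  d <- utils::read.csv(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("area_id", "time_id", "observed")
  if (!all(need %in% names(d)))
    stop("counts file must have columns area_id, time_id, observed")
  d$area_id <- as.character(d$area_id)
  areas <- unique(d$area_id)
  times <- sort(unique(d$time_id))
  if (!is.numeric(d$observed))
    stop("non-numeric `observed` in ", counts_path)
  bad <- which(is.na(d$observed) | d$observed < 0)
  if (length(bad))
    stop("negative or missing `observed` at row(s) ",
         paste(bad, collapse = ", "), " of ", counts_path)
  key <- paste(d$area_id, d$time_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (area_id, time_id) rows in ", counts_path)
  full <- expand.grid(area_id = areas, time_id = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fkey <- paste(full$area_id, full$time_id, sep = "\r")
  miss <- setdiff(fkey, key)
  if (length(miss))
    stop("missing (area, time) cells: ",
         paste(gsub("\r", " @ ", utils::head(miss, 10L)), collapse = "; "))
  O <- matrix(NA_real_, length(areas), length(times))
  ai <- match(d$area_id, areas); ti <- match(d$time_id, times)
  O[cbind(ai, ti)] <- d$observed
  P <- NULL
  if ("population" %in% names(d)) {
    P <- matrix(NA_real_, length(areas), length(times))
    P[cbind(ai, ti)] <- d$population
  }
  X <- NULL
  if (!is.null(covariates_path)) {
    cv <- utils::read.csv(covariates_path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"area_id" %in% names(cv)) stop("covariates file must have an area_id column")
    cv$area_id <- as.character(cv$area_id)
    unknown <- setdiff(cv$area_id, areas)
    if (length(unknown))
      stop("covariate area_id not in panel: ", paste(unknown, collapse = ", "))
    missing_area <- setdiff(areas, cv$area_id)
    if (length(missing_area))
      stop("covariates missing for area(s): ", paste(missing_area, collapse = ", "))
    cv <- cv[match(areas, cv$area_id), , drop = FALSE]
    X <- as.matrix(cv[, setdiff(names(cv), "area_id"), drop = FALSE])
    rownames(X) <- areas
  }
  areal_panel(O, areas, times, P = P, X = X)
}

#' Write an areal panel to CSV
#'
#' Inverse of [read_panel()]: writes the counts file (and, when covariates are
#' present and `covariates_path` is given, the covariates file).
#'
#' @param panel an [areal_panel].
#' @param counts_path output path for the counts CSV.
#' @param covariates_path optional output path for the covariates CSV.
#' @return `counts_path`, invisibly.
#' @export
write_panel <- function(panel, counts_path, covariates_path = NULL) {
  stopifnot(inherits(panel, "areal_panel"))
  N <- length(panel$area_ids); T <- length(panel$time_ids)
  d <- data.frame(
    area_id = rep(panel$area_ids, times = T),
    time_id = rep(panel$time_ids, each = N),
    observed = as.vector(panel$O),
    stringsAsFactors = FALSE)
  if (!is.null(panel$P)) d$population <- as.vector(panel$P)
  utils::write.csv(d, counts_path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariates_path) && !is.null(panel$X)) {
    cv <- data.frame(area_id = panel$area_ids, panel$X,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(cv, covariates_path, row.names = FALSE, quote = FALSE)
  }
  invisible(counts_path)
}
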