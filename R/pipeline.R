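#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> descriptives -> fit -> risk -> DIC as one
#' reproducible run. The configuration is a named list (or path to a YAML
#' file) with entries:
#' \describe{
#'   \item{outdir}{output directory (created if absent) — required}
#'   \item{seed}{integer seed — required}
#'   \item{counts, covariates, graph}{input file paths (see [read_panel()],
#'     [read_graph()]) — required unless `simulate` is given}
#'   \item{simulate}{optional list: `graph` ("srs" or `c(rows, cols)`), `T`,
#'     `expected` (scalar E), truth parameters (`alpha`, `gamma`, `tau_s`,
#'     `tau_u`, `tau_delta`), `covariates` (covariate spec list); inputs are
#'     generated and written to `outdir`}
#'   \item{model}{1, 2, 3 or "custom" (default 1)}
#'   \item{covariate_names}{for model "custom"}
#'   \item{expected}{"unit" (default) or "internal"}
#'   \item{iters, burnin, thin, chains}{MCMC settings (defaults 2000, 1000,
#'     2, 2)}
#'   \item{threshold}{hot-spot threshold (default 0.5)}
#'   \item{orientation}{heatmap orientation (default "by_column")}
#' }
#' Entries passed through `...` override the config. Every stage writes to a
#' `.partial` file first and renames on success, so a failed run leaves its
#' partial outputs identifiable. The run log records the seed, a hash of the
#' resolved configuration, and the package version.
#'
#' @param config named list or path to a YAML config file.
#' @param ... overrides for individual config entries.
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a named list or a YAML file path")
  dots <- list(...)
  config[names(dots)] <- dots

  ## schema check before any computation
  if (is.null(config$outdir)) stop("config error: `outdir` is required")
  if (is.null(config$seed)) stop("config error: `seed` is required")
  if (is.null(config$simulate)) {
    for (f in c("counts", "graph"))
      if (is.null(config[[f]]))
        stop("config error: `", f, "` path is required when not simulating")
  }
  model <- config$model %||% 1
  if (!identical(model, "custom") && !as.integer(model) %in% 1:3)
    stop("config error: model must be 1, 2, 3 or \"custom\"")
  expected <- config$expected %||% "unit"
  if (!expected %in% c("unit", "internal"))
    stop("config error: expected must be \"unit\" or \"internal\"")
  seed <- as.integer(config$seed)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(name, file, writer) {
    target <- file.path(outdir, file)
    partial <- paste0(target, ".partial")
    writer(partial)
    file.rename(partial, target)
    paths[[name]] <<- target
    target
  }

  ## inputs
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    graph <- if (is.null(sim_cfg$graph) || identical(sim_cfg$graph, "srs")) {
      make_srs_graph()
    } else {
      make_lattice_graph(sim_cfg$graph[[1L]], sim_cfg$graph[[2L]])
    }
    T <- sim_cfg$T %||% 5
    Emat <- if (is.null(sim_cfg$expected)) "unit" else
      matrix(as.numeric(sim_cfg$expected), graph$n, T)
    truth_args <- sim_cfg[intersect(names(sim_cfg),
      c("alpha", "gamma", "beta", "tau_s", "tau_u", "tau_delta"))]
    sim <- simulate_panel(graph, truth = if (length(truth_args)) truth_args else NULL,
                          T = T, expected = Emat,
                          covariate_spec = sim_cfg$covariates, seed = seed)
    panel <- sim$panel
    emit("counts", "counts.csv", function(p) {
      write_panel(panel, p,
                  covariates_path = if (!is.null(panel$X)) file.path(outdir, "covariates.csv"))
    })
    if (!is.null(panel$X)) paths$covariates <- file.path(outdir, "covariates.csv")
    emit("graph", "graph.txt", function(p) write_graph(graph, p))
    emit("truth", "truth.json", function(p) {
      tr <- sim$truth
      jsonlite::write_json(list(alpha = tr$alpha, gamma = tr$gamma,
                                beta = tr$beta, s = tr$s, u = tr$u,
                                delta = tr$delta, tau_s = tr$tau_s,
                                tau_u = tr$tau_u, tau_delta = tr$tau_delta),
                           p, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    })
  } else {
    panel <- read_panel(config$counts, config$covariates)
    graph <- read_graph(config$graph)
  }

  ## descriptive layer
  emit("heatmap", "heatmap_scaled.csv", function(p) {
    hm <- heatmap_matrix(panel, orientation = config$orientation %||% "by_column")
    df <- data.frame(label = hm$row_labels, hm$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_report(df, p, "csv")
  })
  emit("trends", "trends.csv", function(p) write_report(area_trends(panel), p, "csv"))

  ## inference
  fit <- stmmr(panel, graph, model = model,
               covariate_names = config$covariate_names,
               expected = expected,
               iters = config$iters %||% 2000, burnin = config$burnin %||% 1000,
               thin = config$thin %||% 2, chains = config$chains %||% 2,
               seed = seed)
  emit("summary", "posterior_summary.csv",
       function(p) write_report(summarize_draws(fit$draws), p, "csv"))
  emit("risk", "risk_report.csv",
       function(p) write_report(risk_report(fit, config$threshold %||% 0.5), p, "csv"))
  emit("dic", "dic.json", function(p) write_report(compute_dic(fit), p, "json"))

  ## run log
  cfg_no_out <- config; cfg_no_out$outdir <- NULL   # location-independent echo
  cfg_echo <- utils::capture.output(utils::str(cfg_no_out, give.attr = FALSE))
  emit("log", "run.log", function(p) {
    writeLines(c(
      paste0("stmmr pipeline v", as.character(utils::packageVersion("stmmr"))),
      paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      paste0("seed: ", seed),
      paste0("config_hash: ", config_hash_(config)),
      "config:", cfg_echo), p)
  })
  invisible(paths)
}

# 32-bit FNV-1a hash of the deparsed configuration
config_hash_ <- function(config) {
  config$outdir <- NULL   # location-independent
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit multiply without double-precision overflow
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
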