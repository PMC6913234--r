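# End-to-end orchestration of the simulation + mapping pipeline.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' All defaults equal the mapping protocol's printed constants: gate 0.01
#' (fine-fit admission), 0.10 (map display threshold), 0.15 (summary
#' inclusion), 1000 bootstrap resamples at the 95% level.
#'
#' @param design A [bar_design()].
#' @param hrf An [hrf_spec()].
#' @param grid A [grid_spec()].
#' @param thresholds Named list `gate`, `display`, `summary` in `[0, 1]`.
#' @param filter_sd_s Optional Gaussian low-pass SD in seconds (`NULL` =
#'   no filtering).
#' @param bootstrap Named list `n`, `level`.
#' @param simulation Named list passed to the synthetic-data generator:
#'   `n_vertices`, `ecc_range`, `sigma_a`, `sigma_b`, `amplitude`,
#'   `noise_sd`, `n_runs`.
#' @param seed Integer seed for all randomness.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = bar_design(mask_resolution_px = 50),
                            hrf = hrf_spec(),
                            grid = grid_spec(),
                            thresholds = list(gate = 0.01, display = 0.10,
                                              summary = 0.15),
                            filter_sd_s = NULL,
                            bootstrap = list(n = 1000, level = 0.95),
                            simulation = list(n_vertices = 100,
                                              ecc_range = c(0.5, 8),
                                              sigma_a = 0.3, sigma_b = 0.34,
                                              amplitude = 1,
                                              noise_sd = sqrt(14),
                                              n_runs = 6),
                            seed = 1) {
  stopifnot(inherits(design, "bar_design"), inherits(hrf, "hrf_spec"),
            inherits(grid, "grid_spec"))
  th <- unlist(thresholds)
  stopifnot(all(th >= 0 & th <= 1))
  structure(list(design = design, hrf = hrf, grid = grid,
                 thresholds = thresholds, filter_sd_s = filter_sd_s,
                 bootstrap = bootstrap, simulation = simulation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] (`design`, `hrf`, `grid`, `thresholds`,
#' `filter_sd_s`, `bootstrap`, `simulation`, `seed`); omitted keys take
#' the defaults. Requires the yaml package.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("config_from_yaml() requires the yaml package")
  }
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$design)) args$design <- do.call(bar_design, y$design)
  if (!is.null(y$hrf)) args$hrf <- do.call(hrf_spec, y$hrf)
  if (!is.null(y$grid)) {
    g <- y$grid
    g$ecc_range <- unlist(g$ecc_range)
    g$sigma_range <- unlist(g$sigma_range)
    args$grid <- do.call(grid_spec, g)
  }
  for (k in c("thresholds", "filter_sd_s", "bootstrap", "simulation", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(args$simulation$ecc_range)) {
    args$simulation$ecc_range <- unlist(args$simulation$ecc_range)
  }
  do.call(pipeline_config, args)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full simulation + mapping pipeline
#'
#' Executes the stages end to end on synthetic data: aperture generation,
#' ground-truth simulation, preprocessing (per-run detrend/z-score, run
#' averaging), optional temporal low-pass filtering, two-stage pRF
#' fitting, noise-ceiling estimation, and eccentricity-binned summaries of
#' pRF size, goodness-of-fit, ceiling and normalized goodness-of-fit.
#' Every artifact is written to `out_dir` as TSV, plus a JSON run manifest
#' (config, seed, stage file list, package version) from which the run can
#' be regenerated exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param compare_with Optional second [fit_map()] table (e.g. from a
#'   second simulated "site"); when given, a map-comparison stage writes
#'   circular/rank correlation statistics at the display threshold.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory stage results (`movie`,
#'   `truth`, `fits`, `ceiling`, `summaries`, `comparison`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, compare_with = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[prfmap] ", ...)
  artifacts <- character(0)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  movie <- stage("apertures", {
    m <- generate_apertures(config$design, include_dummies = FALSE)
    artifacts <- c(artifacts, write_tsv(m$schedule,
                                         file.path(out_dir, "schedule.tsv")))
    m
  })

  sim <- config$simulation
  truth <- stage("simulate", {
    tr <- make_truth_layout(sim$n_vertices, ecc_range = sim$ecc_range,
                            sigma_a = sim$sigma_a, sigma_b = sim$sigma_b,
                            amplitude = sim$amplitude, seed = config$seed)
    artifacts <- c(artifacts, write_tsv(tr, file.path(out_dir, "truth.tsv")))
    tr
  })
  runs <- stage("simulate-runs", {
    simulate_runs(truth, movie, config$hrf, n_runs = sim$n_runs,
                  noise_sd = sim$noise_sd, seed = config$seed + 1)
  })

  avg <- stage("preprocess", {
    pp <- preprocess_runs(runs)
    average_runs(pp)
  })

  if (!is.null(config$filter_sd_s)) {
    avg <- stage("filter", {
      out <- gaussian_lowpass(avg, config$filter_sd_s, tr_s = runs$tr_s)
      attr(out, "degenerate_vertices") <- attr(avg, "degenerate_vertices")
      out
    })
  }

  fits <- stage("fit", {
    grid <- build_grid(config$grid, movie, config$hrf)
    f <- fit_map(avg, grid, movie, config$hrf,
                 gate = config$thresholds$gate, verbose = verbose)
    artifacts <- c(artifacts, write_tsv(f, file.path(out_dir, "fits.tsv")))
    f
  })

  ceiling_tab <- stage("ceiling", {
    pp <- preprocess_runs(runs)
    nc <- noise_ceiling_map(pp)
    nc$normalized_r2 <- as.vector(normalized_fit(fits$r2, nc$ceiling))
    artifacts <- c(artifacts, write_tsv(nc, file.path(out_dir, "ceiling.tsv")))
    nc
  })

  summaries <- stage("summarize", {
    ecc <- sqrt(fits$x0^2 + fits$y0^2)
    set.seed(config$seed + 2)
    tabs <- list(
      prf_size = bin_summarize(ecc, fits$sigma, stat = "mean",
                               r_squared = fits$r2,
                               r2_threshold = config$thresholds$summary,
                               n_boot = config$bootstrap$n,
                               level = config$bootstrap$level),
      r2 = bin_summarize(ecc, fits$r2, stat = "median",
                         n_boot = config$bootstrap$n,
                         level = config$bootstrap$level),
      ceiling = bin_summarize(ecc, ceiling_tab$ceiling, stat = "median",
                              n_boot = config$bootstrap$n,
                              level = config$bootstrap$level),
      normalized_r2 = bin_summarize(ecc, ceiling_tab$normalized_r2,
                                    stat = "median",
                                    n_boot = config$bootstrap$n,
                                    level = config$bootstrap$level)
    )
    long <- do.call(rbind, Map(function(nm, tb) cbind(statistic = nm, tb),
                               names(tabs), tabs))
    artifacts <- c(artifacts, write_tsv(long,
                                         file.path(out_dir, "summaries.tsv")))
    tabs
  })

  comparison <- NULL
  if (!is.null(compare_with)) {
    comparison <- stage("compare", {
      cmp <- compare_maps(fits, compare_with,
                          r2_threshold = config$thresholds$display)
      artifacts <- c(artifacts,
                      write_tsv(as.data.frame(cmp),
                                file.path(out_dir, "comparison.tsv")))
      cmp
    })
  }

  manifest <- stage("manifest", {
    cfg_json <- file.path(out_dir, "config.json")
    jsonlite::write_json(config, cfg_json, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    man <- list(
      package_version = as.character(utils::packageVersion("prfmap")),
      seed = config$seed,
      config_file = basename(cfg_json),
      config_md5 = unname(tools::md5sum(cfg_json)),
      artifacts = basename(c(artifacts, cfg_json))
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })

  invisible(list(movie = movie, truth = truth, fits = fits,
                 ceiling = ceiling_tab, summaries = summaries,
                 comparison = comparison, manifest = manifest))
}
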