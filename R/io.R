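#' Read / write tidy expression time series
#'
#' The on-disk format is a plain CSV with columns `gene`, `temperature`,
#' `replicate`, `time_h`, `value`. Writing uses full decimal precision so
#' a write-then-read round trip reproduces values exactly.
#'
#' @param path File path.
#' @return `read_timeseries()` returns the data frame;
#'   `write_timeseries()` returns `path` invisibly.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "temperature", "replicate", "time_h", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("temperature", "time_h", "value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("malformed ", col, " at data row ", bad[1])
    df[[col]] <- v
  }
  df
}

#' @param x Data frame as produced by [generate_expression_dataset()].
#' @rdname read_timeseries
#' @export
write_timeseries <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize parameter sets as JSON
#'
#' Format: `{"model": ..., "rates": {...}, "structural": {...}}`. Copies
#' of the printed reference sets ship in `inst/extdata/`.
#'
#' @param params A `param_set`.
#' @param path File path.
#' @return `read_param_set()` returns a `param_set`.
#' @export
write_param_set <- function(params, path) {
  stopifnot(inherits(params, "param_set"))
  jsonlite::write_json(list(model = params$model,
                            rates = as.list(params$rates),
                            structural = as.list(params$structural)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_param_set
#' @export
read_param_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  param_set(x$model, unlist(x$rates), unlist(x$structural))
}

#' Write a trajectory as CSV
#'
#' Columns: `time` plus one column per state variable.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @param thin Keep every `thin`-th sample (default 1: all).
#' @export
write_trajectory <- function(traj, path, thin = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  keep <- seq(1, nrow(traj$states), by = thin)
  df <- data.frame(time = traj$times[keep], traj$states[keep, , drop = FALSE])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write screen records and census
#'
#' @param screen A `screen_result`.
#' @param records_path CSV path for the per-run records.
#' @param census_path Optional JSON path for the counts.
#' @export
write_screen <- function(screen, records_path, census_path = NULL) {
  stopifnot(inherits(screen, "screen_result"))
  write.csv(screen$records, records_path, row.names = FALSE, quote = FALSE)
  if (!is.null(census_path))
    jsonlite::write_json(screen$census, census_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(records_path)
}

#' Read a workflow configuration (JSON or YAML)
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run a configured workflow
#'
#' Ties the analysis stages into reproducible, file-to-file runs. The
#' config is a named list (or a JSON/YAML file path) with a `command`
#' (`"screen"`, `"sweep"`, `"hopf"`, `"fastslow"`, `"synth"` or
#' `"rhythm"`), a `seed` for stochastic commands, and a per-command block.
#' Results, a machine-readable `summary.json`, and an echo of the config
#' are written to `out_dir`; re-running the same config reproduces the same
#' files.
#'
#' @param config Named list or path to a config file.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_workflow <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$command)) stop("config must name a command")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  t0 <- Sys.time()
  summary <- switch(config$command,
    screen = {
      if (is.null(config$seed)) stop("'screen' requires a seed")
      model <- clock_model(config$model %||% "goodwin")
      std <- if (model$name == "goodwin") goodwin_standard_params()
             else twovar_params("high")
      proto <- do.call(screening_protocol,
                       c(config$protocol, list(seed = config$seed,
                                               model = model$name)))
      scr <- run_screen(model, std, proto)
      write_screen(scr, file.path(out_dir, "records.csv"),
                   file.path(out_dir, "census.json"))
      c(scr$census, summarize_screen(scr)[c("n_maintained",
                                            "headline_fraction")])
    },
    sweep = {
      model <- clock_model(config$model %||% "twovar")
      base <- if (model$name == "twovar") twovar_params("low")
              else goodwin_standard_params()
      arr <- if (model$name == "twovar") twovar_arrhenius()
             else goodwin_arrhenius()
      tab <- temperature_sweep(model, base, arr,
                               T_grid = unlist(config$T_grid))
      write.csv(tab, file.path(out_dir, "sweep.csv"), row.names = FALSE)
      list(n_temperatures = nrow(tab), all_sustained = all(tab$sustained))
    },
    hopf = {
      params <- if (!is.null(config$params_file))
        read_param_set(config$params_file) else twovar_params("high")
      hp <- find_hopf(params, bif_param = config$bif_param %||% "v",
                      interval = unlist(config$interval %||% c(0.3, 2.15)))
      out <- list(parameter = hp$parameter,
                  critical_value = hp$critical_value)
      jsonlite::write_json(out, file.path(out_dir, "hopf.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    },
    fastslow = {
      params <- if (!is.null(config$params_file))
        read_param_set(config$params_file) else twovar_params("low")
      fs <- fastslow_period(params, detail = TRUE)
      out <- fs[c("period", "period_singular", "fold_delay")]
      jsonlite::write_json(out, file.path(out_dir, "fastslow.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    },
    synth = {
      if (is.null(config$seed)) stop("'synth' requires a seed")
      des <- do.call(coupling_design,
                     c(config$design, list(seed = config$seed)))
      dat <- generate_expression_dataset(des)
      write_timeseries(dat, file.path(out_dir, "expression.csv"))
      list(n_rows = nrow(dat))
    },
    rhythm = {
      dat <- read_timeseries(config$input)
      fits <- do.call(rbind, lapply(
        split(dat, dat[c("gene", "temperature", "replicate")], drop = TRUE),
        function(d) {
          f <- fit_harmonic(d$time_h, d$value)
          data.frame(gene = d$gene[1], temperature = d$temperature[1],
                     replicate = d$replicate[1], period = f$period,
                     amplitude = f$amplitude, phase = f$phase,
                     mesor = f$mesor, r_squared = f$r_squared)
        }))
      write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
      list(n_fits = nrow(fits))
    },
    stop("unknown command: ", config$command))
  log <- list(command = config$command, seed = config$seed,
              package_version = as.character(utils::packageVersion("tempamp")),
              wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")))
  jsonlite::write_json(c(log, list(summary = summary)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
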