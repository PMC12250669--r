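# Pipeline driver: validated run configuration -> analysis -> results
# bundle written as delimited text plus a machine-parsable run record.

#' Read a run configuration file
#'
#' Flat key/value text with optional `[section]` headers; values under a
#' section are prefixed `section.key`. Lines starting with `#` are
#' comments. Every CLI flag can be given in the config; CLI values win.
#'
#' @param path Config file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) mf_stop(sprintf("config file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  config <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      mf_stop(sprintf("config line is not 'key = value': %s", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    if (identical(val, "true")) val <- TRUE
    if (identical(val, "false")) val <- FALSE
    full <- if (nzchar(section)) paste(section, key, sep = ".") else key
    config[[full]] <- val
  }
  config
}

validate_config <- function(config) {
  if (is.null(config$analysis)) mf_stop("config must name an 'analysis'")
  choices <- c("melt", "gp", "quench", "oxidation", "compare", "simulate")
  if (!config$analysis %in% choices) {
    mf_stop(sprintf("unknown analysis '%s' (one of: %s)", config$analysis,
                    paste(choices, collapse = ", ")))
  }
  needs_input <- !identical(config$analysis, "simulate")
  if (needs_input) {
    if (is.null(config$input)) mf_stop("config must name an 'input' path")
    if (!file.exists(config$input)) {
      mf_stop(sprintf("input path '%s' does not exist", config$input))
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$out <- config$out %||% "."
  config$verbose <- isTRUE(config$verbose)
  config
}

#' Run a configured analysis pipeline
#'
#' Validates the configuration (every referenced path must exist before any
#' computation starts), dispatches to the selected analysis, writes the
#' result tables and a JSON run record into the output directory, and
#' returns the results bundle. Deterministic given config + seed; stage
#' failures propagate as structured errors naming the stage.
#'
#' @param config Named list (see [read_run_config()]); must contain
#'   `analysis` and, for analyses, `input`. Common keys: `seed`, `out`,
#'   `verbose`, plus per-analysis parameters (e.g. `quench.efficiency`,
#'   `oxidation.control_label`, `simulate.what`).
#' @return Results bundle: `list(analysis, results, config, files)`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  files <- character()
  # output location and verbosity do not change what was computed, so they
  # stay out of the config fingerprint
  hash_config <- config[setdiff(names(config), c("out", "verbose"))]
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_result_table(df, p, seed = config$seed, config = hash_config)
    files <<- c(files, p)
    p
  }

  results <- switch(config$analysis,
    melt = {
      log_msg("melting analysis on %s", config$input)
      df <- tryCatch(read_polarized_table(config$input), error = function(e) NULL)
      curve <- if (!is.null(df)) anisotropy_curve_from_readings(df)
               else read_anisotropy_curve(config$input)
      ma <- melting_analysis(curve)
      emit(data.frame(
        parameter = c("t_m_C", "lpw_C", "r_gel", "r_fluid", "t_half_C",
                      "slope_width_C", "sigmoid_residual_rms"),
        value = c(ma$t_m, ma$lpw, ma$boltzmann$r_gel, ma$boltzmann$r_fluid,
                  ma$boltzmann$t_half, ma$boltzmann$slope_width,
                  ma$boltzmann$residual_rms)), "melt_results.csv")
      ma
    },
    gp = {
      spec <- read_spectrum(config$input)
      gp <- generalized_polarization(spec)
      emit(data.frame(parameter = "gp", value = gp), "gp_results.csv")
      list(gp = gp)
    },
    quench = {
      df <- read_delimited(config$input, required = c("f", "f0"),
                           non_negative = c("f", "f0"))
      eff <- config[["quench.efficiency"]] %||% 1
      q <- quench_ratio(df$f, df$f0)
      flo <- raft_fraction(pmin(q, 1), quench_efficiency = eff)
      agg <- aggregate_replicates(flo, warn = FALSE)
      emit(data.frame(replicate = seq_along(q), q = q, raft_fraction = flo),
           "quench_results.csv")
      list(q = q, raft_fraction = flo, summary = agg)
    },
    oxidation = {
      series <- read_oxidation_table(config$input)
      ctrl_label <- config[["oxidation.control_label"]] %||% "control"
      if (!ctrl_label %in% names(series)) {
        mf_stop(sprintf("control series '%s' not found in input", ctrl_label))
      }
      t_end <- config[["oxidation.t_end"]] %||% NULL
      rows <- lapply(names(series), function(lb) {
        s <- series[[lb]]
        ox <- fraction_oxidized(s, t_end)
        dk <- fit_decay(s)
        p <- if (lb == ctrl_label) 1
             else protection_factor(series[[ctrl_label]], s, t_end)
        data.frame(label = lb, fraction_oxidized = ox, k_per_min = dk$k,
                   plateau_fraction = dk$plateau_fraction,
                   protection_factor = p)
      })
      tab <- do.call(rbind, rows)
      emit(tab, "oxidation_results.csv")
      list(table = tab)
    },
    compare = {
      df <- read_group_table(config$input)
      tk <- tukey_hsd(df$value, df$group,
                      alpha = config[["compare.alpha"]] %||% 0.05)
      emit(as.data.frame(tk), "compare_results.csv")
      tk
    },
    simulate = {
      what <- config[["simulate.what"]] %||% "melt"
      sim <- switch(what,
        melt = {
          s <- simulate_polarized_melt(
            r_gel = config[["simulate.r_gel"]] %||% 0.30,
            r_fluid = config[["simulate.r_fluid"]] %||% 0.07,
            t_half = config[["simulate.t_half"]] %||% 39.3,
            slope_width = config[["simulate.slope_width"]] %||% 1.2,
            noise_sd = config[["simulate.noise_sd"]] %||% 0.005,
            n_replicates = config[["simulate.n_replicates"]] %||% 3,
            seed = config$seed)
          emit(s$readings, "simulated_melt.csv")
          s
        },
        spectrum = {
          s <- simulate_laurdan_spectrum(
            gp_target = config[["simulate.gp_target"]] %||% 0.3,
            noise_sd = config[["simulate.noise_sd"]] %||% 0,
            seed = config$seed)
          p <- file.path(out_dir, "simulated_spectrum.csv")
          write_spectrum(s$spectrum, p)
          files <- c(files, p)
          s
        },
        quench = {
          s <- simulate_quenching(
            f_lo = config[["simulate.f_lo"]] %||% 0.35,
            quench_efficiency = config[["simulate.quench_efficiency"]] %||% 0.9,
            noise_sd = config[["simulate.noise_sd"]] %||% 0,
            seed = config$seed)
          emit(s$pairs, "simulated_quench.csv")
          s
        },
        oxidation = {
          s <- simulate_oxidation(
            protection = config[["simulate.protection"]] %||% 2.0,
            noise_sd = config[["simulate.noise_sd"]] %||% 0,
            seed = config$seed)
          long <- rbind(
            data.frame(time_min = s$control$time_min,
                       fluorescence = s$control$fluorescence, label = "control"),
            data.frame(time_min = s$treated$time_min,
                       fluorescence = s$treated$fluorescence, label = "treated"))
          emit(long, "simulated_oxidation.csv")
          s
        },
        mf_stop(sprintf("unknown simulate target '%s'", what)))
      mpath <- file.path(out_dir, sprintf("simulated_%s_manifest.json", what))
      write_manifest(sim$truth, mpath)
      files <- c(files, mpath)
      sim
    })

  record <- list(analysis = config$analysis, seed = config$seed,
                 config = config, files = files,
                 version = as.character(utils::packageVersion("membrafluor")))
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(analysis = config$analysis, results = results,
                 config = config, files = files))
}
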