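#' Read a quantification table from CSV
#'
#' Expects columns `lane`, `f` (mixing series) or `time_h` (time
#' course), and `SC`, `N`, `L`, `EX`; a `BB` column is accepted as an
#' alias for `EX`. Lines starting with `#` (provenance stamps written by
#' [write_quant_table()]) are ignored. Validation — schema, fraction
#' ranges, row sums within 0.02 of 1 — happens before any computation,
#' and offending lanes are named in the error.
#'
#' @param path CSV path.
#' @param series `"mixing"`, `"timecourse"`, or `NULL` to infer from the
#'   columns present.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, series = NULL) {
  df <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  if (is.null(series)) {
    series <- if ("f" %in% names(df)) "mixing"
      else if ("time_h" %in% names(df)) "timecourse"
      else stop("cannot infer series type: need an 'f' or 'time_h' column",
                call. = FALSE)
  }
  quant_table(df, series = series)
}

#' Write a tabular result as stamped CSV
#'
#' Writes the table with leading `#` comment lines recording the package
#' version and, if supplied, a configuration hash, so outputs are
#' traceable without interfering with [read_quant_table()].
#'
#' @param x Data frame (quant table, mix curve, time course, ...).
#' @param path Output path.
#' @param config_hash Optional hash string to stamp.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("marinercleave"))
  writeLines(paste0("# marinercleave ", version), con)
  if (!is.null(config_hash)) {
    writeLines(paste0("# config ", config_hash), con)
  }
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml, got '", ext, "'",
         call. = FALSE)
  }
  # collapse homogeneous scalar lists (YAML sequences) to vectors
  lapply(cfg, function(x) {
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.numeric(e) && length(e) == 1L,
                   logical(1)))) {
      unlist(x)
    } else x
  })
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

.config_get <- function(config, name, default = NULL, required = FALSE) {
  if (!is.null(config[[name]])) return(config[[name]])
  if (required) stop("config is missing required field '", name, "'",
                     call. = FALSE)
  default
}

#' Run a pipeline stage from a configuration
#'
#' Dispatches a validated configuration to one of the package's stages
#' and writes the outputs as stamped CSV (or PDB for geometry exports).
#' All parameters are checked against the owning stage's preconditions
#' before any computation runs; outputs are deterministic given the
#' seeds in the configuration.
#'
#' Supported commands and their fields:
#' * `predict`: `model`, `scenario`, `ordering`, `f_grid`.
#' * `kinetics`: `model`, `subunit_states` (or `scenario` + `f`),
#'   `k5`, `k3`, `leak`, `k_ex_int`, `local_requirement`, `times`.
#' * `fit`: `data` (CSV path), `scenario`, `ordering`,
#'   `rejection_ratio`.
#' * `geometry`: optional helix fields (`twist`, `rise`, `p_radius`,
#'   `p_azimuth_offset`, `p_z_offset`), `n_bp`, and one of `stagger`,
#'   `scan` (length-2 range) or `export` (PDB basename).
#' * `synth`: `kind` (`mixing`/`timecourse`/`exchange`), the matching
#'   truth fields, `sd` and `seed`.
#'
#' @param config Named list, or path to a JSON/YAML file
#'   ([read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Named list with the computed object(s) and the paths written.
#' @export
run_pipeline <- function(config, out_dir = tempdir()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  command <- .config_get(config, "command", required = TRUE)
  if (!command %in% c("predict", "kinetics", "fit", "geometry", "synth")) {
    stop("unknown command '", command, "'", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- .config_hash(config)
  pathof <- function(name) file.path(out_dir, name)

  # validate model names up front so bad configs fail before computing
  if (!is.null(config$model)) cleavage_model(config$model)

  result <- switch(command,
    predict = {
      cv <- mix_curve(
        .config_get(config, "model", required = TRUE),
        .config_get(config, "scenario", "equilibrated"),
        .config_get(config, "ordering", "strict_gate"),
        .config_get(config, "f_grid", seq(0, 1, by = 0.05)))
      out <- cbind(as.data.frame(cv),
                   model = attr(cv, "model"),
                   scenario = attr(cv, "scenario")$mode,
                   ordering = attr(cv, "ordering"))
      p <- pathof("mix_curve.csv")
      write_quant_table(out, p, hash)
      list(curve = cv, files = p)
    },
    kinetics = {
      rates <- kinetic_rates(
        k5 = .config_get(config, "k5", 3),
        k3 = .config_get(config, "k3", 3),
        leak = .config_get(config, "leak", 0.1),
        k_ex_int = .config_get(config, "k_ex_int", 1),
        local_requirement = .config_get(config, "local_requirement", TRUE))
      tc <- simulate_timecourse(
        .config_get(config, "model", required = TRUE),
        subunit_states = config$subunit_states,
        scenario = config$scenario, f = config$f,
        rates = rates,
        times = .config_get(config, "times", seq(0, 4, by = 0.1)))
      p <- pathof("timecourse.csv")
      write_quant_table(tc, p, hash)
      list(timecourse = tc, files = p)
    },
    fit = {
      data <- read_quant_table(.config_get(config, "data", required = TRUE))
      report <- fit_mixing_data(
        data,
        candidate_set(
          scenario = .config_get(config, "scenario", "equilibrated"),
          ordering = .config_get(config, "ordering", "strict_gate")),
        rejection_ratio = .config_get(config, "rejection_ratio", 2))
      p <- pathof("fit_report.csv")
      write_quant_table(report, p, hash)
      list(report = report, files = p)
    },
    geometry = {
      hm <- helix_model(
        twist = .config_get(config, "twist", 36),
        rise = .config_get(config, "rise", 3.38),
        p_radius = .config_get(config, "p_radius", 9.5148),
        p_azimuth_offset = .config_get(config, "p_azimuth_offset", 63.2298),
        p_z_offset = .config_get(config, "p_z_offset", -0.6071))
      tr <- build_duplex(hm, .config_get(config, "n_bp", 30))
      files <- character(0)
      res <- list(trace = tr)
      if (!is.null(config$stagger)) {
        res$distance <- interstrand_p_distance(tr, config$stagger)
      }
      if (!is.null(config$scan)) {
        res$minimum <- min_distance_stagger(
          tr, seq(config$scan[1], config$scan[2]))
      }
      if (!is.null(config$export)) {
        p <- pathof(config$export)
        export_trace(tr, p)
        files <- c(files, p)
      }
      res$files <- files
      res
    },
    synth = {
      kind <- .config_get(config, "kind", required = TRUE)
      sd <- .config_get(config, "sd", 0.05)
      seed <- .config_get(config, "seed", required = TRUE)
      ns <- noise_spec(sd = sd, seed = seed)
      if (kind == "mixing") {
        tab <- gen_mixing_dataset(
          .config_get(config, "model", required = TRUE),
          .config_get(config, "scenario", "equilibrated"),
          .config_get(config, "ordering", "strict_gate"),
          .config_get(config, "f_grid", seq(0, 1, by = 1 / 6)), ns)
        p <- pathof("synth_mixing.csv")
      } else if (kind == "timecourse") {
        tab <- gen_timecourse_dataset(
          .config_get(config, "model", required = TRUE),
          .config_get(config, "subunit_states", c("active", "active")),
          kinetic_rates(
            k5 = .config_get(config, "k5", 3),
            k3 = .config_get(config, "k3", 3),
            leak = .config_get(config, "leak", 0.1)),
          .config_get(config, "times", seq(0, 4, by = 0.5)), ns)
        p <- pathof("synth_timecourse.csv")
      } else if (kind == "exchange") {
        tab <- gen_exchange_dataset(
          .config_get(config, "f", 0.5),
          .config_get(config, "exchange_rate", 0.2),
          .config_get(config, "times", seq(0, 16, by = 1)), ns)
        p <- pathof("synth_exchange.csv")
      } else {
        stop("unknown synth kind '", kind, "'", call. = FALSE)
      }
      write_quant_table(tab, p, hash)
      list(table = tab, files = p)
    })
  result$config_hash <- hash
  invisible(result)
}
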