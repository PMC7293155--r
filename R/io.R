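# Configuration files are flat key-value documents (YAML or JSON) whose keys
# mirror the sim_config() / grid_spec() argument names exactly. Unknown keys
# are rejected before anything runs. Output CSVs are deterministic: UTF-8,
# '.' decimal, no row names, floats at 17 significant digits.

parse_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    # yaml handles both YAML and JSON dialects
    yaml::read_yaml(path)
  }
}

check_keys <- function(lst, allowed, what) {
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown)) {
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  }
  lst
}

#' Read a simulation configuration from a file
#'
#' Reads a flat YAML or JSON document whose keys are the argument names of
#' [sim_config()] (`n_hat`, `lifespan`, `delta`, `mode`, `sigma`, `beta`,
#' `u`, `w`, `cost`, `mu_xi`, `steps`, `burn_in`, `seed`, `init_n_adults`,
#' `init_xi`, `record_age`, `age_bin_max`). Unknown keys are rejected and
#' every value is validated by [sim_config()] before any run starts.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  lst <- parse_config_file(path)
  lst <- check_keys(lst, names(formals(sim_config)), "sim config")
  do.call(sim_config, lst)
}

#' Read a grid specification from a file
#'
#' As [read_sim_config()], for the factorial sweep: keys are the argument
#' names of [grid_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [grid_spec()] object.
#' @export
read_grid_spec <- function(path) {
  lst <- parse_config_file(path)
  lst <- check_keys(lst, names(formals(grid_spec)), "grid spec")
  do.call(grid_spec, lst)
}

#' Serialize a simulation configuration to a list
#'
#' Flat representation that round-trips through [read_sim_config()] via
#' YAML or JSON.
#'
#' @param config A [sim_config()].
#' @return Named list of scalar fields.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$derived
  list(n_hat = d$n_hat, lifespan = d$lifespan, delta = d$delta,
       mode = config$mode, sigma = config$sigma, beta = config$beta,
       u = config$u, w = config$w, cost = config$cost,
       mu_xi = config$mu_xi, steps = config$steps, burn_in = config$burn_in,
       seed = config$seed, init_n_adults = config$init_n_adults,
       init_xi = config$init_xi, record_age = config$record_age,
       age_bin_max = config$age_bin_max)
}

# Internal: format numerics at 17 significant digits (lossless for doubles).
fmt17 <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- "NA"
    trimws(out)
  } else {
    as.character(x)
  }
}

#' Write a data frame as a deterministic CSV
#'
#' UTF-8, header row, no row names, '.' decimal separator, doubles at 17
#' significant digits so re-reading reproduces the values exactly and
#' repeated runs produce byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv17 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt17), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the per-step time series of a run
#'
#' @param run An `sl_run` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  stopifnot(inherits(run, "sl_run"))
  cols <- c("t", "n_census", "n_adults", "n_births", "prop_adapted",
            "mean_xi", "eff_fertility", "eff_survival", "env_epoch",
            "switched")
  write_csv17(run$records[, cols, drop = FALSE], path)
}

#' Write the run summary as JSON
#'
#' Emits the post-burn-in summary together with the full configuration (for
#' audit) as a single JSON object.
#'
#' @param run An `sl_run` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary_json <- function(run, path) {
  stopifnot(inherits(run, "sl_run"))
  s <- run$summary
  obj <- list(summary = unclass(s), extinct = run$extinct,
              steps_completed = nrow(run$records),
              config = config_to_list(run$config),
              derived = list(s = run$config$derived$s,
                             b = run$config$derived$b,
                             delta = run$config$derived$delta,
                             gamma = run$config$derived$gamma,
                             n_hat = run$config$derived$n_hat))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# Internal: cheap deterministic content hash of a config list (hex string).
# Used to make sweeps resumable; not cryptographic.
config_hash <- function(lst) {
  txt <- paste(names(lst), vapply(lst, function(v)
    paste(fmt17(v), collapse = ";"), character(1)),
    sep = "=", collapse = "&")
  h1 <- 0; h2 <- 5381
  for (cc in utf8ToInt(txt)) {
    h1 <- (h1 * 31 + cc) %% 2147483647
    h2 <- (h2 * 33 + cc) %% 1073741789
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}
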