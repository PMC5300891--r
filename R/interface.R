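# Unit handling for config files. Values may be bare numbers (taken as SI:
# M, s, 1/s, 1/(M*s)) or mappings {value: x, unit: "nM"}.
unit_factors <- list(
  "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "nM" = 1e-9, "pM" = 1e-12,
  "s" = 1, "1/s" = 1, "s^-1" = 1,
  "1/(M*s)" = 1, "1/(mM*s)" = 1e3, "1/(uM*s)" = 1e6, "1/(nM*s)" = 1e9,
  "1/(pM*s)" = 1e12
)

convert_to_si <- function(x, field) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (is.list(x) && !is.null(x$value)) {
    unit <- x$unit
    if (is.null(unit)) return(as.numeric(x$value))
    f <- unit_factors[[unit]]
    if (is.null(f)) {
      stop(sprintf("field '%s': unknown unit '%s'", field, unit), call. = FALSE)
    }
    return(as.numeric(x$value) * f)
  }
  stop(sprintf("field '%s': expected a number or {value, unit} mapping", field),
       call. = FALSE)
}

#' Build a scenario configuration
#'
#' A validated bundle of scenario name, kinetic-parameter and concentration
#' overrides (SI units), integrator settings and seed, with defaults taken
#' from [zipcode_defaults()].
#'
#' @param scenario one of `"fig6a"` (base time course), `"fig6b"` (tenfold
#'   reduced closing rates), `"fig6c"` (protein-concentration sweep),
#'   `"no_closing"` (closure disabled at 200 nM protein).
#' @param params a [kinetic_parameters()] object.
#' @param conditions a [mixture_conditions()] object.
#' @param settings an [integrator_settings()] object.
#' @param seed integer seed recorded with the run.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = "fig6a",
                            params = zipcode_defaults()$params,
                            conditions = zipcode_defaults()$conditions,
                            settings = integrator_settings(t_end = 1000),
                            seed = 1L) {
  scenario <- match.arg(scenario, names(scenario_runners))
  structure(list(scenario = scenario,
                 params = as_kinetic_parameters(params),
                 conditions = conditions, settings = settings,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Load a scenario configuration from YAML or JSON
#'
#' Unset fields fall back to the defaults of [zipcode_defaults()]; numeric
#' entries may carry explicit unit tags (e.g. `{value: 0.2, unit: uM}`,
#' `{value: 3.0e4, unit: "1/(M*s)"}`) and are normalised to SI on load.
#' Unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file; an empty file
#'   yields the full default scenario.
#' @return A [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()

  known <- c("scenario", "params", "conditions", "integrator", "seed",
             "out_dir")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }

  def <- zipcode_defaults()
  p <- as.list(unclass(def$params))
  for (f in names(raw$params %||% list())) {
    if (!f %in% names(p)) stop("unknown parameter field: ", f, call. = FALSE)
    p[[f]] <- convert_to_si(raw$params[[f]], f)
  }
  params <- tryCatch(do.call(kinetic_parameters, p), error = function(e) {
    stop("invalid parameters in config: ", conditionMessage(e), call. = FALSE)
  })

  cn <- as.list(unclass(def$conditions))
  for (f in names(raw$conditions %||% list())) {
    if (!f %in% names(cn)) stop("unknown condition field: ", f, call. = FALSE)
    cn[[f]] <- convert_to_si(raw$conditions[[f]], f)
  }
  conditions <- mixture_conditions(cn$P_tot, cn$R_tot)

  it <- list(dt = 0.01, t_end = 1000, equilibrium_tol = 1e-9,
             store_every = 10L)
  for (f in names(raw$integrator %||% list())) {
    if (!f %in% names(it)) stop("unknown integrator field: ", f, call. = FALSE)
    it[[f]] <- convert_to_si(raw$integrator[[f]], f)
  }
  settings <- do.call(integrator_settings, it)

  cfg <- scenario_config(scenario = raw$scenario %||% "fig6a",
                         params = params, conditions = conditions,
                         settings = settings, seed = raw$seed %||% 1L)
  cfg$out_dir <- raw$out_dir
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize kinetic parameters with explicit unit strings
#'
#' Writes the six rate constants as a flat mapping with unit tags, e.g.
#' `"kon3": {"value": 3.0e4, "unit": "1/(M*s)"}`; format chosen from the
#' file extension (`.json` or `.yaml`/`.yml`).
#'
#' @param params a [kinetic_parameters()] object.
#' @param path output path.
#' @export
write_parameters <- function(params, path) {
  params <- as_kinetic_parameters(params)
  units <- c(kon3 = "1/(M*s)", koff3 = "1/s", kon4 = "1/(M*s)",
             koff4 = "1/s", kC3 = "1/s", kC4 = "1/s")
  out <- lapply(names(units), function(f) {
    list(value = params[[f]], unit = unname(units[[f]]))
  })
  names(out) <- names(units)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  fields <- c("kon3", "koff3", "kon4", "koff4", "kC3", "kC4")
  missing <- setdiff(fields, names(raw))
  if (length(missing) > 0) {
    stop("parameter file missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(fields, function(f) convert_to_si(raw[[f]], f))
  names(vals) <- fields
  do.call(kinetic_parameters, vals)
}

summary_as_list <- function(eq, params) {
  st <- as.list(unclass(eq$state))
  names(st) <- paste0(names(st), "_M")
  c(list(fraction_bound = eq$fraction_bound,
         Kd_app_M = eq$Kd_app,
         time_to_equilibrium_s = eq$time_to_equilibrium,
         koff_effective_per_s = effective_dissociation_rate(params)),
    st)
}

scenario_runners <- list(
  fig6a = function(cfg, dir) {
    eq <- run_to_equilibrium(cfg$params, cfg$conditions, cfg$settings)
    write_timecourse(eq$time_course, file.path(dir, "fig6a_timecourse.csv"))
    summary_as_list(eq, cfg$params)
  },
  fig6b = function(cfg, dir) {
    p <- cfg$params
    params <- kinetic_parameters(p[["kon3"]], p[["koff3"]], p[["kon4"]],
                                 p[["koff4"]], kC3 = p[["kC3"]] / 10,
                                 kC4 = p[["kC4"]] / 10)
    eq <- run_to_equilibrium(params, cfg$conditions, cfg$settings)
    write_timecourse(eq$time_course, file.path(dir, "fig6b_timecourse.csv"))
    summary_as_list(eq, params)
  },
  fig6c = function(cfg, dir) {
    pv <- c(5, 20, 50, 200) * 1e-9
    sw <- protein_sweep(cfg$params, pv, cfg$conditions[["R_tot"]])
    write_sweep_table(sw, file.path(dir, "fig6c_protein_sweep.csv"))
    list(P_tot_M = sw$P_tot_M, fraction_bound = sw$fraction_bound,
         Kd_app_M = sw$Kd_app_M)
  },
  no_closing = function(cfg, dir) {
    p <- cfg$params
    params <- kinetic_parameters(p[["kon3"]], p[["koff3"]], p[["kon4"]],
                                 p[["koff4"]], kC3 = 0, kC4 = 0)
    conditions <- mixture_conditions(200e-9, cfg$conditions[["R_tot"]])
    st <- steady_state_solve(params, conditions)
    eq <- equilibrium_summary(st)
    out <- summary_as_list(eq, cfg$params)
    out$koff_effective_per_s <- NULL
    c(out, list(C3_pM = st[["C3"]] * 1e12, C4_pM = st[["C4"]] * 1e12,
                D_pM = st[["D"]] * 1e12))
  }
)

#' Run a named simulation scenario and write its artifacts
#'
#' Scenarios reproduce the model's headline simulations: `"fig6a"` the base
#' time course to equilibrium (apparent Kd ~20.6 nM), `"fig6b"` the same
#' with closing rates reduced tenfold (~150 nM), `"fig6c"` the
#' protein-concentration sweep at 5/20/50/200 nM, and `"no_closing"` the
#' equilibrium with ring closure disabled (38/63/8.2 pM open and 2:1
#' species). Each run writes a CSV of its trajectory or sweep, a JSON
#' summary, and a log of the fully resolved parameter set.
#'
#' @param config a [scenario_config()] (or path handled by
#'   [load_config()]).
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `out_dir` or a temporary directory.
#' @return The summary list, invisibly. Summary and resolved-parameter JSON
#'   files are written under `out_dir`.
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_config("no_closing"), out_dir = tempdir())
#' res$D_pM  # ~8.2
#' }
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "scenario_config"))
  runner <- scenario_runners[[config$scenario]]
  if (is.null(runner)) {
    stop("unknown scenario '", config$scenario, "'; available: ",
         paste(names(scenario_runners), collapse = ", "), call. = FALSE)
  }
  dir <- out_dir %||% config$out_dir %||% tempfile("scenario_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  resolved <- list(scenario = config$scenario,
                   params = as.list(unclass(config$params)),
                   conditions = as.list(unclass(config$conditions)),
                   integrator = unclass(config$settings),
                   seed = config$seed)
  jsonlite::write_json(resolved,
                       file.path(dir, paste0(config$scenario, "_run_log.json")),
                       auto_unbox = TRUE, digits = NA)

  summary <- runner(config, dir)
  jsonlite::write_json(summary,
                       file.path(dir, paste0(config$scenario, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
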