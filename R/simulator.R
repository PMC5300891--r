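#' Integrator settings for the fixed-step RK4 simulator
#'
#' @param dt step size (s); must be positive and below the stability bound
#'   for the fastest rate in the system (checked at integration time).
#' @param t_end maximum simulated time (s); at least one step.
#' @param equilibrium_tol relative-derivative threshold used by
#'   [run_to_equilibrium()]: equilibrium is declared when
#'   `max_i |dC_i/dt| * 1s / max(C_i, 1e-15 M)` drops below this value.
#' @param store_every output thinning: keep every `store_every`-th step.
#' @return An object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 0.01, t_end = 500,
                                equilibrium_tol = 1e-9, store_every = 10L) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.finite(t_end) || t_end < dt) stop("t_end must be >= dt", call. = FALSE)
  if (!is.finite(equilibrium_tol) || equilibrium_tol <= 0) {
    stop("equilibrium_tol must be positive", call. = FALSE)
  }
  store_every <- as.integer(store_every)
  if (is.na(store_every) || store_every < 1L) {
    stop("store_every must be a positive integer", call. = FALSE)
  }
  structure(list(dt = dt, t_end = t_end, equilibrium_tol = equilibrium_tol,
                 store_every = store_every),
            class = "integrator_settings")
}

# Conservative estimate of the largest local loss rate of any species,
# evaluated at the concentration bounds P_tot and R_tot. Used as the RK4
# stability surrogate: classical RK4 on a linear loss term -lambda*x is
# stable for dt*lambda < 2.785; we require dt*lambda_max < 2.5.
max_loss_rate <- function(params, P_max, R_max) {
  p <- params
  max((p[["kon3"]] + p[["kon4"]]) * P_max,                       # R
      (p[["kon3"]] + p[["kon4"]]) * R_max +
        (p[["kon4"]] + p[["kon3"]]) * R_max,                     # P (crude)
      p[["koff3"]] + p[["kC4"]] + p[["kon4"]] * P_max,           # C3
      p[["koff4"]] + p[["kC3"]] + p[["kon3"]] * P_max,           # C4
      p[["koff3"]] + p[["koff4"]])                               # CC, D
}

#' Suggest a stable RK4 step size for a parameter set
#'
#' @param params a [kinetic_parameters()] object.
#' @param conditions a [mixture_conditions()] object.
#' @param safety fraction of the stability bound to use (default 0.1).
#' @return A step size (s), capped at 0.01 s.
#' @export
suggest_dt <- function(params, conditions, safety = 0.1) {
  params <- as_kinetic_parameters(params)
  lam <- max_loss_rate(params, conditions[["P_tot"]], conditions[["R_tot"]])
  if (lam <= 0) return(0.01)
  min(0.01, safety * 2.5 / lam)
}

# Core fixed-step classical RK4 loop over the six-species mass-action
# network (compiled; see src/rk4.cpp). Returns the thinned trajectory
# matrix plus the final state and its derivative. clamp_P = TRUE zeroes
# free protein at every stage evaluation (dissociation-phase protocol:
# released protein is washed away).
rk4_core <- function(params, init, dt, n_steps, store_every,
                     clamp_P = FALSE, stop_tol = NULL, conc_scale = NULL) {
  if (is.null(conc_scale)) conc_scale <- max(init, 1e-15)
  pvec <- as.numeric(params[c("kon3", "koff3", "kon4", "koff4", "kC3", "kC4")])
  res <- .rk4_core_cpp(pvec, as.numeric(init[species_names]), dt,
                       as.integer(n_steps), as.integer(store_every),
                       isTRUE(clamp_P),
                       if (is.null(stop_tol)) -1 else stop_tol,
                       -1e-12 * max(conc_scale, 1e-15))
  names(res$state) <- species_names
  names(res$deriv) <- species_names
  res
}

new_time_course <- function(mat, params, conditions, settings) {
  df <- as.data.frame(mat)
  names(df) <- c("time_s", species_names)
  structure(df, params = params, conditions = conditions,
            settings = settings, class = c("time_course", "data.frame"))
}

#' Integrate the binding network with fixed-step fourth-order Runge-Kutta
#'
#' Propagates the six-species mass-action network from an all-free initial
#' state (or a supplied one) using the classical RK4 scheme with a fixed
#' step. The step size is validated against a stability bound estimated
#' from the largest local loss rate (`dt * lambda_max < 2.5`); trajectories
#' preserve the RNA and protein conservation laws to round-off.
#'
#' @param params a [kinetic_parameters()] object.
#' @param conditions a [mixture_conditions()] object; the default initial
#'   state is `R = R_tot`, `P = P_tot`, all complexes zero.
#' @param settings an [integrator_settings()] object.
#' @param init optional explicit initial [species_state()]; its implied
#'   totals override `conditions`.
#' @return A `time_course` data frame with columns
#'   `time_s, R, P, C3, C4, CC, D` (M) and the inputs attached as
#'   attributes.
#' @examples
#' d <- zipcode_defaults()
#' tc <- simulate_timecourse(d$params, d$conditions,
#'                           integrator_settings(t_end = 50))
#' tail(tc, 1)
#' @export
simulate_timecourse <- function(params, conditions,
                                settings = integrator_settings(),
                                init = NULL) {
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(settings, "integrator_settings"))
  if (is.null(init)) {
    init <- species_state(R = conditions[["R_tot"]], P = conditions[["P_tot"]])
  } else {
    init <- as_species_state(init)
    tot <- conserved_totals(init)
    conditions <- mixture_conditions(tot[["P_tot"]], tot[["R_tot"]])
  }

  lam <- max_loss_rate(params, conditions[["P_tot"]],
                       max(conditions[["R_tot"]], conditions[["P_tot"]]))
  if (settings$dt * lam >= 2.5) {
    stop(sprintf(
      "unstable step size: dt = %.4g s with largest local loss rate %.4g 1/s gives dt*lambda = %.3g >= 2.5; use dt < %.4g s",
      settings$dt, lam, settings$dt * lam, 2.5 / lam), call. = FALSE)
  }

  n_steps <- ceiling(settings$t_end / settings$dt)
  res <- rk4_core(params, unclass(init), settings$dt, n_steps,
                  settings$store_every,
                  conc_scale = max(conditions[["R_tot"]], conditions[["P_tot"]]))
  new_time_course(res$trajectory, params, conditions, settings)
}

#' Final state of a time course
#' @param tc a `time_course`.
#' @return The last stored [species_state()].
#' @export
final_state <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  last <- as.numeric(tc[nrow(tc), species_names])
  names(last) <- species_names
  species_state(last[["R"]], last[["P"]], last[["C3"]], last[["C4"]],
                last[["CC"]], last[["D"]])
}

#' Integrate to equilibrium and summarise
#'
#' Runs [simulate_timecourse()] until the relative derivative of every
#' species, `|dC/dt| * 1s / max(C, 1e-15 M)`, falls below
#' `settings$equilibrium_tol`, then summarises the steady state. The time to
#' equilibrium is reported as the earliest stored time at which the closed
#' complex is within 1% of its final concentration.
#'
#' @inheritParams simulate_timecourse
#' @return An object of class `equilibrium_summary`: a list with `state`
#'   ([species_state()]), `fraction_bound`, `Kd_app` (M, `NA` when nothing
#'   is bound), `time_to_equilibrium` (s) and the full `time_course`.
#' @examples
#' d <- zipcode_defaults()
#' \donttest{
#' eq <- run_to_equilibrium(d$params, d$conditions,
#'                          integrator_settings(t_end = 1000))
#' eq$Kd_app * 1e9  # ~20.6 nM
#' }
#' @export
run_to_equilibrium <- function(params, conditions,
                               settings = integrator_settings()) {
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(settings, "integrator_settings"))
  init <- species_state(R = conditions[["R_tot"]], P = conditions[["P_tot"]])

  lam <- max_loss_rate(params, conditions[["P_tot"]],
                       max(conditions[["R_tot"]], conditions[["P_tot"]]))
  if (settings$dt * lam >= 2.5) {
    stop(sprintf(
      "unstable step size: dt = %.4g s gives dt*lambda = %.3g >= 2.5",
      settings$dt, settings$dt * lam), call. = FALSE)
  }

  n_steps <- ceiling(settings$t_end / settings$dt)
  res <- rk4_core(params, unclass(init), settings$dt, n_steps,
                  settings$store_every, stop_tol = settings$equilibrium_tol,
                  conc_scale = max(conditions[["R_tot"]], conditions[["P_tot"]]))
  if (!res$converged) {
    cond <- structure(
      class = c("zipkinetics_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "equilibrium not reached by t_end = %g s (max relative derivative %.3g > tol %.3g); increase t_end",
        settings$t_end, max(abs(res$deriv) / pmax(res$state, 1e-15)),
        settings$equilibrium_tol),
        call = sys.call(), last_state = res$state))
    stop(cond)
  }

  tc <- new_time_course(res$trajectory, params, conditions, settings)
  st <- final_state(tc)
  cc_final <- st[["CC"]]
  t_eq <- if (cc_final > 0) {
    ok <- abs(tc$CC - cc_final) <= 0.01 * cc_final
    # earliest stored time from which CC stays within 1% of its final value
    idx <- which(rev(cumprod(rev(ok))) == 1)[1L]
    tc$time_s[idx]
  } else 0
  fb <- fraction_bound(st)
  structure(list(
    state = st,
    fraction_bound = fb,
    Kd_app = if (fb > 0) apparent_kd(st) else NA_real_,
    time_to_equilibrium = t_eq,
    time_course = tc
  ), class = "equilibrium_summary")
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  cat("Equilibrium summary\n")
  cat(sprintf("  fraction bound      = %.4f\n", x$fraction_bound))
  if (is.finite(x$Kd_app)) {
    cat(sprintf("  apparent Kd         = %.4g M (%.3g nM)\n",
                x$Kd_app, x$Kd_app * 1e9))
  }
  if (!is.null(x$time_to_equilibrium) && is.finite(x$time_to_equilibrium)) {
    cat(sprintf("  time to equilibrium = %.1f s\n", x$time_to_equilibrium))
  }
  print(x$state)
  invisible(x)
}

#' Simulate a dissociation (wash-out) phase
#'
#' Starting from a supplied state -- typically an equilibrium state -- free
#' protein is clamped to zero at every step: released protein is washed away
#' and cannot re-associate from solution, mirroring the dissociation phase
#' of a BLI experiment. Intramolecular reclosure (kC3, kC4) and all
#' unimolecular dissociations remain active, so the decay of total bound RNA
#' reflects the avidity-limited effective off-rate.
#'
#' @param params a [kinetic_parameters()] object.
#' @param initial the starting [species_state()].
#' @param settings an [integrator_settings()] object.
#' @return A `time_course` of the decay.
#' @seealso [effective_dissociation_rate()] for the analytic companion.
#' @export
dissociation_timecourse <- function(params, initial,
                                    settings = integrator_settings()) {
  params <- as_kinetic_parameters(params)
  initial <- as_species_state(initial)
  stopifnot(inherits(settings, "integrator_settings"))
  tot <- conserved_totals(initial)

  lam <- max_loss_rate(params, 0, tot[["R_tot"]])
  if (settings$dt * lam >= 2.5) {
    stop(sprintf("unstable step size: dt*lambda = %.3g >= 2.5",
                 settings$dt * lam), call. = FALSE)
  }
  n_steps <- ceiling(settings$t_end / settings$dt)
  res <- rk4_core(params, unclass(initial), settings$dt, n_steps,
                  settings$store_every, clamp_P = TRUE,
                  conc_scale = max(tot))
  conditions <- mixture_conditions(0, tot[["R_tot"]])
  new_time_course(res$trajectory, params, conditions, settings)
}

#' Write / read a time course as CSV
#'
#' Plain CSV with header `time_s,R_M,P_M,C3_M,C4_M,CC_M,D_M`; read back
#' losslessly (concentrations serialised at full double precision).
#'
#' @param tc a `time_course`.
#' @param path file path.
#' @return `write_timecourse` returns `path` invisibly; `read_timecourse`
#'   returns a `time_course` (without parameter attributes).
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  out <- as.data.frame(tc)
  names(out) <- c("time_s", paste0(species_names, "_M"))
  utils::write.csv(format(out, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path)
  expected <- c("time_s", paste0(species_names, "_M"))
  if (!identical(names(df), expected)) {
    stop("not a time-course CSV: expected header ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  names(df) <- c("time_s", species_names)
  structure(df, class = c("time_course", "data.frame"))
}
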