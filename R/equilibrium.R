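#' Direct steady-state solution of the binding network
#'
#' At fixed free-protein concentration the balance equations for the four
#' bound species and free RNA are linear; together with RNA conservation
#' they form a 5x5 linear system that is solved directly. Free protein is
#' then updated from protein conservation and the solve repeated to a fixed
#' point. Because RNA is typically in large deficit the fixed point
#' converges in a handful of iterations; protein depletion is nevertheless
#' handled exactly.
#'
#' @param params a [kinetic_parameters()] object.
#' @param conditions a [mixture_conditions()] object.
#' @param tol relative fixed-point tolerance on free protein (default 1e-12).
#' @param max_iter iteration cap (default 1000).
#' @return The steady-state [species_state()].
#' @examples
#' d <- zipcode_defaults()
#' st <- steady_state_solve(d$params, d$conditions)
#' apparent_kd(st) * 1e9  # ~20.6 nM
#' @export
steady_state_solve <- function(params, conditions, tol = 1e-12,
                               max_iter = 1000L) {
  params <- as_kinetic_parameters(params)
  P_tot <- conditions[["P_tot"]]
  R_tot <- conditions[["R_tot"]]
  if (R_tot == 0) {
    return(species_state(P = P_tot))
  }
  if (P_tot == 0) {
    return(species_state(R = R_tot))
  }
  kon3 <- params[["kon3"]]; koff3 <- params[["koff3"]]
  kon4 <- params[["kon4"]]; koff4 <- params[["koff4"]]
  kC3 <- params[["kC3"]]; kC4 <- params[["kC4"]]
  ksum <- koff3 + koff4
  if (ksum <= 0) {
    stop("steady state undefined: koff3 + koff4 must be positive", call. = FALSE)
  }

  P <- P_tot
  b <- c(0, 0, 0, 0, R_tot)
  for (iter in seq_len(max_iter)) {
    # unknowns x = (R, C3, C4, CC, D); rows: dC3=0, dC4=0, dCC=0, dD=0,
    # RNA conservation
    A <- rbind(
      c(kon3 * P, -(koff3 + kC4 + kon4 * P), 0,          koff4, koff4),
      c(kon4 * P, 0, -(koff4 + kC3 + kon3 * P),          koff3, koff3),
      c(0,        kC4,       kC3,                        -ksum, 0),
      c(0,        kon4 * P,  kon3 * P,                   0,     -ksum),
      c(1,        1,         1,                          1,     1))
    x <- tryCatch(solve(A, b), error = function(e) {
      stop("steady-state solve failed: ", conditionMessage(e), call. = FALSE)
    })
    P_new <- P_tot - x[2L] - x[3L] - x[4L] - 2 * x[5L]
    if (P_new < 0) P_new <- 0
    if (abs(P_new - P) <= tol * max(P_tot, 1e-30)) {
      P <- P_new
      return(species_state(R = x[1L], P = P, C3 = x[2L], C4 = x[3L],
                           CC = x[4L], D = x[5L]))
    }
    P <- P_new
  }
  stop("steady-state fixed point did not converge after ", max_iter,
       " iterations", call. = FALSE)
}

#' Closed-form equilibrium state from detailed balance
#'
#' Independent second route to the steady state, valid only when the
#' reaction cycle is thermodynamically consistent
#' ([cycle_consistency_ratio()] = 1 within `tol`). Species follow from the
#' equilibrium constants alone: `C3/R = P/Kd3`, `C4/R = P/Kd4`,
#' `CC/C3 = kC4/koff4`, `D/C3 = P/Kd4`, with free protein obtained from
#' conservation by fixed-point iteration.
#'
#' @inheritParams steady_state_solve
#' @param tol tolerance on the cycle-consistency ratio (default 1e-3).
#' @return The equilibrium [species_state()].
#' @export
detailed_balance_state <- function(params, conditions, tol = 1e-3) {
  params <- as_kinetic_parameters(params)
  if (!is_cycle_consistent(params, tol)) {
    stop(sprintf(
      "detailed-balance closed form requires a consistent cycle; ratio = %.4g",
      cycle_consistency_ratio(params)), call. = FALSE)
  }
  P_tot <- conditions[["P_tot"]]
  R_tot <- conditions[["R_tot"]]
  if (R_tot == 0) return(species_state(P = P_tot))
  if (P_tot == 0) return(species_state(R = R_tot))
  kd <- single_site_kds(params)
  Kd3 <- kd[["Kd3"]]; Kd4 <- kd[["Kd4"]]
  Kc <- params[["kC4"]] / params[["koff4"]]  # CC/C3 closure equilibrium

  P <- P_tot
  for (iter in seq_len(1000L)) {
    a3 <- P / Kd3
    a4 <- P / Kd4
    denom <- 1 + a3 + a4 + a3 * Kc + a3 * a4
    R <- R_tot / denom
    C3 <- a3 * R; C4 <- a4 * R; CC <- a3 * Kc * R; D <- a3 * a4 * R
    P_new <- P_tot - C3 - C4 - CC - 2 * D
    if (P_new < 0) P_new <- 0
    if (abs(P_new - P) <= 1e-12 * max(P_tot, 1e-30)) {
      return(species_state(R = R, P = P_new, C3 = C3, C4 = C4,
                           CC = CC, D = D))
    }
    P <- P_new
  }
  stop("detailed-balance fixed point did not converge", call. = FALSE)
}

#' Summarise an equilibrium state
#'
#' @param state an equilibrium [species_state()].
#' @param params optional [kinetic_parameters()]; when given, the analytic
#'   effective dissociation rate is attached.
#' @return An `equilibrium_summary` (without a time course).
#' @export
equilibrium_summary <- function(state, params = NULL) {
  state <- as_species_state(state)
  fb <- fraction_bound(state)
  structure(list(
    state = state,
    fraction_bound = fb,
    Kd_app = if (fb > 0) apparent_kd(state) else NA_real_,
    time_to_equilibrium = NA_real_,
    koff_effective = if (is.null(params)) NULL else
      effective_dissociation_rate(params)
  ), class = "equilibrium_summary")
}

#' Equilibrium response to protein concentration
#'
#' Solves the steady state at each total protein concentration. Because
#' protein is in large excess over RNA in the cell, the fraction of RNA
#' bound is governed by the protein concentration alone — this sweep is how
#' the model predicts regulation of the Zipcode interaction by ZBP1 levels.
#'
#' @param params a [kinetic_parameters()] object.
#' @param P_values protein concentrations to sweep (M), non-empty and
#'   non-negative.
#' @param R_tot total RNA concentration (M).
#' @return A `sweep_table` data frame with one row per concentration:
#'   `P_tot_M`, `fraction_bound`, `Kd_app_M`, and the six species columns
#'   (M).
#' @examples
#' d <- zipcode_defaults()
#' protein_sweep(d$params, c(5, 50, 200) * 1e-9, 0.4e-9)
#' @export
protein_sweep <- function(params, P_values, R_tot) {
  params <- as_kinetic_parameters(params)
  if (length(P_values) == 0 || any(!is.finite(P_values)) || any(P_values < 0)) {
    stop("P_values must be a non-empty vector of non-negative concentrations",
         call. = FALSE)
  }
  rows <- lapply(P_values, function(P) {
    st <- tryCatch(
      steady_state_solve(params, mixture_conditions(P, R_tot)),
      error = function(e) {
        stop(sprintf("steady-state solve failed at P_tot = %.4g M: %s",
                     P, conditionMessage(e)), call. = FALSE)
      })
    fb <- fraction_bound(st)
    data.frame(P_tot_M = P, fraction_bound = fb,
               Kd_app_M = if (fb > 0) apparent_kd(st) else NA_real_,
               t(unclass(st)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_table", "data.frame"),
            swept = "P_tot_M", params = params)
}

#' Equilibrium response to the ring-closure rate
#'
#' Sweeps kC3 and reports the apparent Kd, fraction of RNA bound and the
#' analytic effective dissociation rate at each value. By default kC4 is
#' co-scaled to preserve the baseline kC4/kC3 ratio, which keeps the
#' thermodynamic cycle consistent (the ratio is pinned to kon4/kon3 by
#' detailed balance); setting `preserve_ratio = FALSE` holds kC4 fixed
#' instead.
#'
#' @param params baseline [kinetic_parameters()].
#' @param kC3_values closing rates to sweep (1/s), strictly positive.
#' @param conditions a [mixture_conditions()] object.
#' @param preserve_ratio co-scale kC4 with kC3 (default `TRUE`).
#' @return A `sweep_table` with columns `kC3_per_s`, `kC4_per_s`,
#'   `fraction_bound`, `Kd_app_M`, `koff_effective_per_s`, and the species
#'   columns.
#' @export
closing_rate_sweep <- function(params, kC3_values, conditions,
                               preserve_ratio = TRUE) {
  params <- as_kinetic_parameters(params)
  if (length(kC3_values) == 0 || any(!is.finite(kC3_values)) ||
      any(kC3_values <= 0)) {
    stop("kC3_values must be strictly positive", call. = FALSE)
  }
  ratio <- params[["kC4"]] / params[["kC3"]]
  rows <- lapply(kC3_values, function(kc3) {
    kc4 <- if (preserve_ratio) kc3 * ratio else params[["kC4"]]
    p <- kinetic_parameters(params[["kon3"]], params[["koff3"]],
                            params[["kon4"]], params[["koff4"]],
                            kC3 = kc3, kC4 = kc4)
    st <- steady_state_solve(p, conditions)
    fb <- fraction_bound(st)
    data.frame(kC3_per_s = kc3, kC4_per_s = kc4, fraction_bound = fb,
               Kd_app_M = if (fb > 0) apparent_kd(st) else NA_real_,
               koff_effective_per_s = effective_dissociation_rate(p),
               t(unclass(st)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_table", "data.frame"),
            swept = "kC3_per_s", params = params)
}

#' Write a sweep table as CSV
#'
#' @param x a `sweep_table`.
#' @param path file path.
#' @export
write_sweep_table <- function(x, path) {
  stopifnot(inherits(x, "sweep_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
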