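#' A biolayer interferometry sensorgram
#'
#' A single BLI trace: response against time for one analyte (protein)
#' concentration, with the boundaries between the association and
#' dissociation phases recorded alongside the data.
#'
#' @param times strictly increasing time vector (s).
#' @param response response vector (response units), same length as `times`.
#' @param analyte_concentration protein concentration of the trace (M).
#' @param phase_bounds named numeric vector
#'   `c(assoc_start, assoc_end, dissoc_end)` (s), ordered and inside the
#'   time range.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(times, response, analyte_concentration, phase_bounds) {
  times <- as.numeric(times)
  response <- as.numeric(response)
  if (length(times) != length(response)) {
    stop("times and response must have the same length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  pb <- phase_bounds
  need <- c("assoc_start", "assoc_end", "dissoc_end")
  if (!all(need %in% names(pb))) {
    stop("phase_bounds must contain assoc_start, assoc_end, dissoc_end",
         call. = FALSE)
  }
  pb <- pb[need]
  if (is.unsorted(pb, strictly = TRUE) ||
      pb[1L] < times[1L] || pb[3L] > times[length(times)]) {
    stop("phase bounds must be strictly ordered and within the time range",
         call. = FALSE)
  }
  structure(list(times = times, response = response,
                 analyte_concentration = analyte_concentration,
                 phase_bounds = pb),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf(
    "Sensorgram: %d points, analyte %.4g M, association %g-%g s, dissociation to %g s\n",
    length(x$times), x$analyte_concentration,
    x$phase_bounds[["assoc_start"]], x$phase_bounds[["assoc_end"]],
    x$phase_bounds[["dissoc_end"]]))
  invisible(x)
}

#' Mono-exponential fit of a signal phase
#'
#' Least-squares fit of `A * (1 - exp(-k t)) + c` (`mode = "rise"`) or
#' `A * exp(-k t) + c` (`mode = "decay"`) by Levenberg-Marquardt. Starting
#' values come from the signal end-points and the half-change time, so the
#' fit is self-starting on clean sensorgram phases.
#'
#' @param times time vector (s), at least 5 points.
#' @param values signal vector.
#' @param mode `"rise"` or `"decay"`.
#' @return A list with `rate` (1/s), `amplitude`, `offset`, `rate_se`
#'   (standard error of the fitted rate) and the `fit` object.
#' @examples
#' t <- 0:600
#' y <- 0.8 * (1 - exp(-0.0097 * t))
#' exponential_fit(t, y, "rise")$rate
#' @export
exponential_fit <- function(times, values, mode = c("rise", "decay")) {
  mode <- match.arg(mode)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 5L || length(values) != length(times)) {
    stop("need at least 5 (time, value) pairs", call. = FALSE)
  }
  t0 <- times - times[1L]
  span <- diff(range(values))
  scale <- max(abs(values), span)
  if (span <= 1e-12 * max(scale, 1e-300) || span == 0) {
    stop("fit error: signal shows no evolution (amplitude ~ 0)", call. = FALSE)
  }

  n <- length(values)
  if (mode == "rise") {
    c0 <- values[1L]
    A0 <- values[n] - values[1L]
    half <- c0 + A0 / 2
    ih <- which(if (A0 >= 0) values >= half else values <= half)[1L]
  } else {
    c0 <- values[n]
    A0 <- values[1L] - values[n]
    half <- c0 + A0 / 2
    ih <- which(if (A0 >= 0) values <= half else values >= half)[1L]
  }
  t_half <- if (!is.na(ih) && t0[ih] > 0) t0[ih] else max(t0) / 4
  k0 <- log(2) / t_half

  model <- if (mode == "rise") {
    function(par) par[[1L]] * (1 - exp(-par[[2L]] * t0)) + par[[3L]]
  } else {
    function(par) par[[1L]] * exp(-par[[2L]] * t0) + par[[3L]]
  }
  # Levenberg-Marquardt on the raw residuals: robust to the zero-residual
  # (noiseless) case, where stats::nls and nlsLM's model construction fail
  fit <- minpack.lm::nls.lm(
    par = c(A = A0, k = k0, c = c0),
    fn = function(par) values - model(par),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4) {
    stop("fit error: exponential fit did not converge (", fit$message, ")",
         call. = FALSE)
  }
  cf <- fit$par
  if (!is.finite(cf[["k"]]) || cf[["k"]] <= 0) {
    stop("fit error: fitted rate is not positive", call. = FALSE)
  }
  se <- tryCatch({
    sigma2 <- fit$deviance / (length(values) - 3L)
    sqrt(diag(sigma2 * solve(fit$hessian)))[["k"]]
  }, error = function(e) NA_real_)
  list(rate = unname(cf[["k"]]), amplitude = unname(cf[["A"]]),
       offset = unname(cf[["c"]]), rate_se = se, fit = fit)
}

#' Association rate constant from the kobs-concentration line
#'
#' For 1:1 Langmuir kinetics the observed association rate is affine in
#' analyte concentration, `kobs = kon * P + koff`; the slope of an ordinary
#' least-squares line through the (concentration, kobs) points is kon and
#' the intercept estimates koff.
#'
#' @param concentrations analyte concentrations (M); at least 3 distinct
#'   values.
#' @param kobs_values observed association rates (1/s).
#' @return A list with `kon` (1/(M*s)), `intercept` (1/s) and the `lm` fit.
#' @export
kon_from_kobs <- function(concentrations, kobs_values) {
  conc <- as.numeric(concentrations)
  kobs <- as.numeric(kobs_values)
  if (length(conc) != length(kobs)) {
    stop("concentrations and kobs_values must match in length", call. = FALSE)
  }
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct concentrations for the kobs line",
         call. = FALSE)
  }
  fit <- stats::lm(kobs ~ conc)
  cf <- stats::coef(fit)
  list(kon = unname(cf[["conc"]]), intercept = unname(cf[["(Intercept)"]]),
       fit = fit)
}

#' Equilibrium dissociation constant from the response titration
#'
#' Fits the 1:1 binding isotherm `Req = Rmax * P / (P + Kd)` to the
#' equilibrium responses measured across the concentration series.
#'
#' @param concentrations analyte concentrations (M); at least 4 values.
#' @param equilibrium_responses plateau responses, one per concentration.
#' @return A list with `Kd` (M), `Rmax`, `saturation_warning` (`TRUE` when
#'   the highest concentration is below `Kd/2`, i.e. saturation was never
#'   approached) and the `fit` object.
#' @export
kd_from_responses <- function(concentrations, equilibrium_responses) {
  conc <- as.numeric(concentrations)
  resp <- as.numeric(equilibrium_responses)
  if (length(conc) != length(resp)) {
    stop("concentrations and responses must match in length", call. = FALSE)
  }
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations for the titration fit",
         call. = FALSE)
  }
  if (all(resp == 0)) {
    stop("fit error: all responses are zero", call. = FALSE)
  }
  rmax0 <- max(resp) * 1.2
  ih <- which(resp >= max(resp) / 2)[1L]
  kd0 <- max(conc[ih], min(conc[conc > 0]))
  fit <- minpack.lm::nls.lm(
    par = c(Rmax = rmax0, Kd = kd0),
    lower = c(0, 0),
    fn = function(par) resp - par[[1L]] * conc / (conc + par[[2L]]),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4) {
    stop("fit error: titration fit did not converge (", fit$message, ")",
         call. = FALSE)
  }
  cf <- fit$par
  if (!is.finite(cf[["Kd"]]) || cf[["Kd"]] <= 0) {
    stop("fit error: fitted Kd is not positive", call. = FALSE)
  }
  list(Kd = unname(cf[["Kd"]]), Rmax = unname(cf[["Rmax"]]),
       saturation_warning = max(conc) < cf[["Kd"]] / 2, fit = fit)
}

segment <- function(sg, from, to) {
  sel <- sg$times >= from & sg$times <= to
  list(t = sg$times[sel], y = sg$response[sel])
}

#' Full BLI kinetic analysis of a concentration series
#'
#' Reproduces the standard BLI workflow for a 1:1 Langmuir analysis of a
#' sensorgram series: a mono-exponential fit of each association phase
#' gives per-trace kobs values; kon is the slope of kobs against
#' concentration; the equilibrium-response titration gives Kd and Rmax;
#' koff is obtained as `Kd * kon` and cross-checked against direct
#' mono-exponential fits of the dissociation phases. The cross-check flag
#' `accuracy_confirmed` is set when the two koff estimates agree within
#' 25%.
#'
#' @param sensorgrams list of [sensorgram()] objects at 3 or more distinct
#'   concentrations sharing the same phase boundaries.
#' @param plateau how the per-trace equilibrium response is estimated:
#'   `"fit"` (default) uses the fitted plateau `A + c` of the association
#'   exponential; `"tail"` uses the mean of the last 10% of the association
#'   phase.
#' @return An object of class `bli_fit_result` with fields
#'   `kobs_per_concentration` (data frame), `kon`, `kobs_intercept`, `Kd`,
#'   `Rmax`, `koff_from_kd_kon`, `koff_direct`, `accuracy_confirmed`,
#'   `saturation_warning`.
#' @examples
#' ds <- generate_bli_dataset("didomain", noise_sd = 0, seed = 1)
#' fit <- analyze_bli_dataset(ds$sensorgrams)
#' fit$Kd * 1e9  # ~20 nM
#' @export
analyze_bli_dataset <- function(sensorgrams, plateau = c("fit", "tail")) {
  plateau <- match.arg(plateau)
  if (length(sensorgrams) < 3L) {
    stop("need at least 3 sensorgrams", call. = FALSE)
  }
  stopifnot(all(vapply(sensorgrams, inherits, logical(1), "sensorgram")))
  conc <- vapply(sensorgrams, function(s) s$analyte_concentration, numeric(1))
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct analyte concentrations", call. = FALSE)
  }
  pb <- vapply(sensorgrams, function(s) s$phase_bounds, numeric(3))
  if (any(apply(pb, 1L, function(r) diff(range(r)) > 0))) {
    stop("sensorgrams must share the same phase boundaries", call. = FALSE)
  }
  b <- sensorgrams[[1L]]$phase_bounds

  assoc_fits <- lapply(sensorgrams, function(sg) {
    seg <- segment(sg, b[["assoc_start"]], b[["assoc_end"]])
    exponential_fit(seg$t, seg$y, "rise")
  })
  kobs <- vapply(assoc_fits, `[[`, numeric(1), "rate")

  req <- if (plateau == "fit") {
    vapply(assoc_fits, function(f) f$amplitude + f$offset, numeric(1))
  } else {
    vapply(sensorgrams, function(sg) {
      seg <- segment(sg, b[["assoc_start"]], b[["assoc_end"]])
      tail_from <- b[["assoc_end"]] - 0.1 * (b[["assoc_end"]] - b[["assoc_start"]])
      mean(seg$y[seg$t >= tail_from])
    }, numeric(1))
  }

  kline <- kon_from_kobs(conc, kobs)
  titr <- kd_from_responses(conc, req)

  koff_direct <- mean(vapply(sensorgrams, function(sg) {
    seg <- segment(sg, b[["assoc_end"]], b[["dissoc_end"]])
    exponential_fit(seg$t, seg$y, "decay")$rate
  }, numeric(1)))

  koff_kdkon <- titr$Kd * kline$kon
  structure(list(
    kobs_per_concentration = data.frame(concentration_M = conc,
                                        kobs_per_s = kobs,
                                        Req = req),
    kon = kline$kon,
    kobs_intercept = kline$intercept,
    Kd = titr$Kd,
    Rmax = titr$Rmax,
    koff_from_kd_kon = koff_kdkon,
    koff_direct = koff_direct,
    accuracy_confirmed =
      abs(koff_direct - koff_kdkon) / koff_direct < 0.25,
    saturation_warning = titr$saturation_warning
  ), class = "bli_fit_result")
}

#' @export
print.bli_fit_result <- function(x, ...) {
  cat("BLI kinetic analysis (1:1 Langmuir)\n")
  cat(sprintf("  kon            = %.4g 1/(M*s)\n", x$kon))
  cat(sprintf("  Kd             = %.4g M (%.3g nM)\n", x$Kd, x$Kd * 1e9))
  cat(sprintf("  koff = Kd*kon  = %.4g 1/s\n", x$koff_from_kd_kon))
  cat(sprintf("  koff (direct)  = %.4g 1/s  [%s]\n", x$koff_direct,
              if (isTRUE(x$accuracy_confirmed)) "accuracy confirmed"
              else "cross-check outside 25%"))
  cat(sprintf("  Rmax           = %.4g RU\n", x$Rmax))
  if (isTRUE(x$saturation_warning)) {
    cat("  warning: saturation not approached (max concentration < Kd/2)\n")
  }
  invisible(x)
}

#' Write / read a sensorgram as CSV with a JSON side-car
#'
#' The trace is a two-column CSV (`time_s,response`); concentration and
#' phase boundaries go to `<path>.json`.
#'
#' @param sg a [sensorgram()].
#' @param path CSV file path.
#' @export
write_sensorgram <- function(sg, path) {
  stopifnot(inherits(sg, "sensorgram"))
  utils::write.csv(data.frame(time_s = sg$times, response = sg$response),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(analyte_concentration_M = sg$analyte_concentration,
         phase_bounds_s = as.list(sg$phase_bounds)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sensorgram(df$time_s, df$response, meta$analyte_concentration_M,
             unlist(meta$phase_bounds_s))
}

#' Serialize a BLI fit result to JSON
#'
#' @param x a `bli_fit_result`.
#' @param path file path.
#' @export
write_bli_fit <- function(x, path) {
  stopifnot(inherits(x, "bli_fit_result"))
  jsonlite::write_json(
    list(kon_per_M_s = x$kon, kobs_intercept_per_s = x$kobs_intercept,
         Kd_M = x$Kd, Rmax = x$Rmax,
         koff_from_kd_kon_per_s = x$koff_from_kd_kon,
         koff_direct_per_s = x$koff_direct,
         accuracy_confirmed = x$accuracy_confirmed,
         saturation_warning = x$saturation_warning,
         kobs_per_concentration = x$kobs_per_concentration),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
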