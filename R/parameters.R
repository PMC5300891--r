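#' Kinetic parameters of the bivalent KH3-KH4 / Zipcode binding scheme
#'
#' Bundles the six rate constants that define the reaction network: the
#' association and dissociation rate constants of the individual KH3 and KH4
#' domains for their cognate sites on the Zipcode RNA, and the two
#' intramolecular ring-closure ("looping") rates. `kC3` applies when KH3 is
#' the second domain to engage (closing from the KH4-bound open complex),
#' `kC4` when KH4 closes onto the KH3-bound open complex.
#'
#' @param kon3,kon4 association rate constants (1/(M*s)); must be positive.
#' @param koff3,koff4 dissociation rate constants (1/s); must be non-negative.
#' @param kC3,kC4 ring-closure rates (1/s); must be non-negative.
#'
#' @return An object of class `kinetic_parameters`: a named numeric vector
#'   with elements `kon3, koff3, kon4, koff4, kC3, kC4` and derived
#'   single-site dissociation constants available via [single_site_kds()].
#' @seealso [zipcode_defaults()] for the measured/derived default set,
#'   [derive_closing_rates()], [cycle_consistency_ratio()].
#' @examples
#' p <- kinetic_parameters(kon3 = 3.0e4, koff3 = 0.046,
#'                         kon4 = 1.4e5, koff4 = 0.13,
#'                         kC3 = 2, kC4 = 9.333)
#' single_site_kds(p)
#' @export
kinetic_parameters <- function(kon3, koff3, kon4, koff4, kC3 = 0, kC4 = 0) {
  p <- c(kon3 = kon3, koff3 = koff3, kon4 = kon4, koff4 = koff4,
         kC3 = kC3, kC4 = kC4)
  if (!all(is.finite(p))) {
    stop("all rate constants must be finite numbers", call. = FALSE)
  }
  if (any(p < 0)) {
    stop("rate constants must be non-negative", call. = FALSE)
  }
  structure(p, class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (bivalent binding scheme)\n")
  cat(sprintf("  kon3  = %.4g 1/(M*s)   koff3 = %.4g 1/s\n", x[["kon3"]], x[["koff3"]]))
  cat(sprintf("  kon4  = %.4g 1/(M*s)   koff4 = %.4g 1/s\n", x[["kon4"]], x[["koff4"]]))
  cat(sprintf("  kC3   = %.4g 1/s       kC4   = %.4g 1/s\n", x[["kC3"]], x[["kC4"]]))
  kd <- tryCatch(single_site_kds(x), error = function(e) NULL)
  if (!is.null(kd)) {
    cat(sprintf("  Kd3   = %.4g M         Kd4   = %.4g M\n",
                kd[["Kd3"]], kd[["Kd4"]]))
  }
  r <- tryCatch(cycle_consistency_ratio(x), error = function(e) NA_real_)
  if (is.finite(r)) {
    cat(sprintf("  cycle consistency ratio = %.6g (%s)\n", r,
                if (abs(r - 1) < 1e-3) "thermodynamically consistent"
                else "inconsistent cycle"))
  }
  invisible(x)
}

#' Single-site dissociation constants
#'
#' @param params a [kinetic_parameters()] object.
#' @return Named numeric vector `c(Kd3, Kd4)` in M, where
#'   `Kd3 = koff3/kon3` and `Kd4 = koff4/kon4`.
#' @export
single_site_kds <- function(params) {
  params <- as_kinetic_parameters(params)
  if (params[["kon3"]] <= 0 || params[["kon4"]] <= 0) {
    stop("single-site Kds require strictly positive kon3 and kon4",
         call. = FALSE)
  }
  c(Kd3 = params[["koff3"]] / params[["kon3"]],
    Kd4 = params[["koff4"]] / params[["kon4"]])
}

as_kinetic_parameters <- function(x) {
  if (inherits(x, "kinetic_parameters")) return(x)
  nm <- c("kon3", "koff3", "kon4", "koff4", "kC3", "kC4")
  if (is.numeric(x) && all(nm %in% names(x))) {
    return(kinetic_parameters(x[["kon3"]], x[["koff3"]], x[["kon4"]],
                              x[["koff4"]], x[["kC3"]], x[["kC4"]]))
  }
  if (is.list(x) && all(nm %in% names(x))) {
    return(kinetic_parameters(x$kon3, x$koff3, x$kon4, x$koff4, x$kC3, x$kC4))
  }
  stop("cannot interpret object as kinetic parameters", call. = FALSE)
}

#' Mixture conditions: total protein and RNA concentrations
#'
#' @param P_tot total protein concentration (M).
#' @param R_tot total RNA concentration (M).
#' @return An object of class `mixture_conditions`.
#' @examples
#' mixture_conditions(P_tot = 2e-7, R_tot = 4e-10)
#' @export
mixture_conditions <- function(P_tot, R_tot) {
  if (!is.finite(P_tot) || !is.finite(R_tot) || P_tot < 0 || R_tot < 0) {
    stop("P_tot and R_tot must be finite and non-negative", call. = FALSE)
  }
  structure(c(P_tot = P_tot, R_tot = R_tot), class = "mixture_conditions")
}

#' @export
print.mixture_conditions <- function(x, ...) {
  cat(sprintf("Mixture: P_tot = %.4g M, R_tot = %.4g M\n",
              x[["P_tot"]], x[["R_tot"]]))
  invisible(x)
}

#' Default parameter set and conditions for the ZBP1 KH3-KH4 / Zipcode system
#'
#' The single-domain rate constants measured by BLI on the 28-nt Zipcode RNA
#' (KH3: kon 3.0e4 1/(M*s), koff 0.046 1/s; KH4: kon 1.4e5 1/(M*s), koff
#' 0.13 1/s), the ring-closure rates derived from those constants and the
#' 20 nM di-domain Kd (kC3 = 2 1/s, kC4 = 9.333 1/s), and the cellular
#' concentration estimates used in the simulations (0.2 uM protein, 0.4 nM
#' RNA).
#'
#' @return A list with elements `params` ([kinetic_parameters()]) and
#'   `conditions` ([mixture_conditions()]).
#' @examples
#' zipcode_defaults()$params
#' @export
zipcode_defaults <- function() {
  list(
    params = kinetic_parameters(kon3 = 3.0e4, koff3 = 0.046,
                                kon4 = 1.4e5, koff4 = 0.13,
                                kC3 = 2, kC4 = 9.333),
    conditions = mixture_conditions(P_tot = 0.2e-6, R_tot = 0.4e-9)
  )
}

#' Derive the ring-closure rates from measured kinetics and the overall Kd
#'
#' The closure rates are not directly measurable; they follow from requiring
#' that the bivalent scheme reproduces the measured overall dissociation
#' constant of the di-domain complex. With `Kd3 = koff3/kon3` and
#' `Kd4 = koff4/kon4`:
#'
#'   kC3 = Kd4 * koff3 / Kd_overall
#'   kC4 = Kd3 * koff4 / Kd_overall
#'
#' The returned pair automatically satisfies the detailed-balance constraint
#' `kC4/kC3 = kon4/kon3`, so the reaction cycle supports a true equilibrium.
#'
#' @param kon3,koff3,kon4,koff4 single-domain rate constants (1/(M*s), 1/s);
#'   all strictly positive.
#' @param Kd_overall measured dissociation constant of the di-domain complex
#'   (M); strictly positive.
#' @return Named numeric vector `c(kC3, kC4)` in 1/s.
#' @examples
#' derive_closing_rates(3.0e4, 0.046, 1.4e5, 0.13, 20e-9)
#' @export
derive_closing_rates <- function(kon3, koff3, kon4, koff4, Kd_overall) {
  vals <- c(kon3, koff3, kon4, koff4, Kd_overall)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all rate constants and Kd_overall must be finite and strictly positive",
         call. = FALSE)
  }
  Kd3 <- koff3 / kon3
  Kd4 <- koff4 / kon4
  c(kC3 = Kd4 * koff3 / Kd_overall,
    kC4 = Kd3 * koff4 / Kd_overall)
}

#' Detailed-balance consistency ratio of the reaction cycle
#'
#' Around the cycle free -> KH3-bound open -> closed -> KH4-bound open ->
#' free, detailed balance requires the product of forward rate constants to
#' equal the product of reverse ones, which reduces to
#' `(kon3 * kC4) / (kon4 * kC3) = 1`. A ratio of 1 means the network admits a
#' true equilibrium with no circulating flux; parameter sets produced by
#' [derive_closing_rates()] satisfy this by construction.
#'
#' @param params a [kinetic_parameters()] object with strictly positive
#'   `kon4` and `kC3`.
#' @return Dimensionless ratio; 1 indicates a consistent cycle.
#' @export
cycle_consistency_ratio <- function(params) {
  params <- as_kinetic_parameters(params)
  if (params[["kon4"]] <= 0 || params[["kC3"]] <= 0) {
    stop("cycle ratio undefined: kon4 and kC3 must be strictly positive",
         call. = FALSE)
  }
  (params[["kon3"]] * params[["kC4"]]) / (params[["kon4"]] * params[["kC3"]])
}

#' Is a parameter set thermodynamically consistent?
#'
#' @param params a [kinetic_parameters()] object.
#' @param tol relative tolerance on the cycle ratio (default 1e-3).
#' @return `TRUE` if [cycle_consistency_ratio()] is within `tol` of 1.
#' @export
is_cycle_consistent <- function(params, tol = 1e-3) {
  abs(cycle_consistency_ratio(params) - 1) <= tol
}

#' Analytic effective dissociation rate of the closed complex
#'
#' Escape-probability approximation for the rate at which the closed (looped)
#' complex fully releases the RNA when rebinding from solution is impossible,
#' as in a wash-out (BLI dissociation) phase. Opening through either domain
#' competes with reclosure:
#'
#'   k_off,eff = koff4 * koff3/(koff3 + kC4) + koff3 * koff4/(koff4 + kC3)
#'
#' Each term is an opening rate times the probability that the transiently
#' open complex releases rather than recloses. The approximation is accurate
#' in the avidity regime kC >> koff.
#'
#' @param params a [kinetic_parameters()] object.
#' @return Effective dissociation rate (1/s).
#' @examples
#' effective_dissociation_rate(zipcode_defaults()$params)  # ~0.0034 1/s
#' @export
effective_dissociation_rate <- function(params) {
  params <- as_kinetic_parameters(params)
  d1 <- params[["koff3"]] + params[["kC4"]]
  d2 <- params[["koff4"]] + params[["kC3"]]
  if (d1 <= 0 || d2 <= 0) {
    stop("degenerate denominators: koff3 + kC4 and koff4 + kC3 must be positive",
         call. = FALSE)
  }
  params[["koff4"]] * params[["koff3"]] / d1 +
    params[["koff3"]] * params[["koff4"]] / d2
}
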