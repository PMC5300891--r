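#' Species state of the six-species binding network
#'
#' Concentrations (M) of the six species in the bivalent binding scheme:
#' free RNA `R`, free protein `P`, the KH3-engaged open 1:1 complex `C3`,
#' the KH4-engaged open 1:1 complex `C4`, the closed (looped) 1:1 complex
#' `CC` with both domains engaged, and the 2:1 protein:RNA complex `D` in
#' which two proteins each engage one site.
#'
#' @param R,P,C3,C4,CC,D species concentrations (M), all non-negative
#'   (values above -1e-15 are clipped to zero to absorb round-off).
#' @return Named numeric vector of class `species_state`.
#' @export
species_state <- function(R = 0, P = 0, C3 = 0, C4 = 0, CC = 0, D = 0) {
  s <- c(R = R, P = P, C3 = C3, C4 = C4, CC = CC, D = D)
  if (!all(is.finite(s))) {
    stop("species concentrations must be finite", call. = FALSE)
  }
  if (any(s < -1e-15)) {
    stop("species concentrations must be non-negative", call. = FALSE)
  }
  s[s < 0] <- 0
  structure(s, class = "species_state")
}

species_names <- c("R", "P", "C3", "C4", "CC", "D")

as_species_state <- function(x) {
  if (inherits(x, "species_state")) return(x)
  if (is.numeric(x) && all(species_names %in% names(x))) {
    return(species_state(x[["R"]], x[["P"]], x[["C3"]], x[["C4"]],
                         x[["CC"]], x[["D"]]))
  }
  stop("cannot interpret object as a species state", call. = FALSE)
}

#' @export
print.species_state <- function(x, ...) {
  cat("Species state (M):\n")
  print(format(unclass(x), digits = 4))
  invisible(x)
}

#' Total RNA and protein implied by a species state
#'
#' Conserved totals: RNA appears once in each RNA-containing species while
#' the 2:1 complex carries two proteins.
#'
#' @param state a [species_state()].
#' @return Named vector `c(R_tot, P_tot)` in M.
#' @export
conserved_totals <- function(state) {
  state <- as_species_state(state)
  c(R_tot = state[["R"]] + state[["C3"]] + state[["C4"]] +
      state[["CC"]] + state[["D"]],
    P_tot = state[["P"]] + state[["C3"]] + state[["C4"]] +
      state[["CC"]] + 2 * state[["D"]])
}

#' Mass-action time derivatives of the six-species network
#'
#' Transcribes the reaction scheme into rate equations. Reactions (with rate
#' constants forward/reverse):
#' \itemize{
#'   \item R + P <-> C3 (kon3 / koff3) and R + P <-> C4 (kon4 / koff4):
#'     either domain binds its cognate site first;
#'   \item C3 <-> CC (kC4 / koff4) and C4 <-> CC (kC3 / koff3): the free
#'     domain of a singly-bound protein captures the remaining site on the
#'     same RNA (ring closure), reopening at that domain's off-rate;
#'   \item C3 + P <-> D (kon4 / koff4) and C4 + P <-> D (kon3 / koff3): a
#'     second protein occupies the free site through its cognate domain.
#' }
#'
#' @param state a [species_state()] with finite, non-negative entries.
#' @param params a [kinetic_parameters()] object.
#' @return Named numeric vector of derivatives (M/s) for
#'   `R, P, C3, C4, CC, D`. The RNA-weighted and protein-weighted sums of the
#'   derivatives are zero by construction.
#' @export
mass_action_rhs <- function(state, params) {
  state <- as_species_state(state)
  params <- as_kinetic_parameters(params)
  mass_action_rhs_raw(unclass(state), params)
}

# Internal hot path: no validation, plain named vector in and out.
mass_action_rhs_raw <- function(s, p) {
  kon3 <- p[["kon3"]]; koff3 <- p[["koff3"]]
  kon4 <- p[["kon4"]]; koff4 <- p[["koff4"]]
  kC3 <- p[["kC3"]]; kC4 <- p[["kC4"]]
  R <- s[["R"]]; P <- s[["P"]]; C3 <- s[["C3"]]
  C4 <- s[["C4"]]; CC <- s[["CC"]]; D <- s[["D"]]

  v_on3  <- kon3 * R * P;  v_off3 <- koff3 * C3   # R+P <-> C3
  v_on4  <- kon4 * R * P;  v_off4 <- koff4 * C4   # R+P <-> C4
  v_c4   <- kC4 * C3;      v_o4   <- koff4 * CC   # C3 <-> CC
  v_c3   <- kC3 * C4;      v_o3   <- koff3 * CC   # C4 <-> CC
  v_d3   <- kon4 * C3 * P; v_dr3  <- koff4 * D    # C3+P <-> D
  v_d4   <- kon3 * C4 * P; v_dr4  <- koff3 * D    # C4+P <-> D

  # pairwise grouping keeps the KH3/KH4 label-swap symmetry bit-exact
  c(R  = (v_off3 - v_on3) + (v_off4 - v_on4),
    P  = ((v_off3 - v_on3) + (v_off4 - v_on4)) +
         ((v_dr3 - v_d3) + (v_dr4 - v_d4)),
    C3 = (v_on3 - v_off3) + (v_o4 - v_c4) + (v_dr3 - v_d3),
    C4 = (v_on4 - v_off4) + (v_o3 - v_c3) + (v_dr4 - v_d4),
    CC = (v_c4 + v_c3) - (v_o4 + v_o3),
    D  = (v_d3 + v_d4) - (v_dr3 + v_dr4))
}

#' Fraction of RNA bound in any protein-containing species
#'
#' @param state a [species_state()].
#' @return `(C3 + C4 + CC + D) / R_tot`, in `[0, 1]`; `0` when no RNA is
#'   present.
#' @export
fraction_bound <- function(state) {
  state <- as_species_state(state)
  bound <- state[["C3"]] + state[["C4"]] + state[["CC"]] + state[["D"]]
  rtot <- bound + state[["R"]]
  if (rtot <= 0) return(0)
  bound / rtot
}

#' Apparent dissociation constant from equilibrium species concentrations
#'
#' The overall affinity the looped bivalent complex presents to the outside
#' world: free protein times free RNA over all protein-bound RNA species,
#'
#'   Kd_app = P_free * R_free / (C3 + C4 + CC + D)
#'
#' For a single 1:1 reaction this reduces to koff/kon exactly.
#'
#' @param state a [species_state()] at equilibrium.
#' @return Apparent Kd (M).
#' @export
apparent_kd <- function(state) {
  state <- as_species_state(state)
  bound <- state[["C3"]] + state[["C4"]] + state[["CC"]] + state[["D"]]
  if (bound <= 0) {
    stop("apparent Kd undefined: no RNA is bound", call. = FALSE)
  }
  state[["P"]] * state[["R"]] / bound
}
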