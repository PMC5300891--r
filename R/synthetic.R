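# Run code under a locally-seeded RNG without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a 1:1 Langmuir BLI sensorgram
#'
#' Generates an idealised sensorgram with a mono-exponential association
#' phase and a mono-exponential dissociation phase:
#' association `R(t) = Req * (1 - exp(-kobs t))` with
#' `kobs = kon * P + koff` and `Req = Rmax * P / (P + koff/kon)`;
#' dissociation `R(t) = R(t_assoc) * exp(-koff (t - t_assoc))`. Optional
#' i.i.d. Gaussian noise is added on the response; a fixed seed makes the
#' trace exactly reproducible.
#'
#' @param kon,koff 1:1 rate constants (1/(M*s), 1/s), positive.
#' @param P analyte (protein) concentration (M), non-negative.
#' @param Rmax maximal response at saturation (response units).
#' @param t_assoc,t_dissoc phase durations (s), positive.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (response units), non-negative.
#' @param seed optional integer seed for the noise.
#' @param dt sampling interval (s).
#' @return A [sensorgram()] with phase bounds
#'   `(0, t_assoc, t_assoc + t_dissoc)`.
#' @examples
#' sg <- simulate_sensorgram(1.6e5, 0.0033, P = 40e-9, Rmax = 1,
#'                           noise_sd = 0)
#' @export
simulate_sensorgram <- function(kon, koff, P, Rmax = 1,
                                t_assoc = 600, t_dissoc = 900,
                                noise_sd = 0, seed = NULL, dt = 1) {
  if (!all(is.finite(c(kon, koff, P, Rmax, t_assoc, t_dissoc, noise_sd, dt)))) {
    stop("all generator arguments must be finite", call. = FALSE)
  }
  if (kon <= 0 || koff <= 0) stop("kon and koff must be positive", call. = FALSE)
  if (P < 0) stop("P must be non-negative", call. = FALSE)
  if (t_assoc <= 0 || t_dissoc <= 0 || dt <= 0) {
    stop("invalid phase durations or sampling interval", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)

  times <- seq(0, t_assoc + t_dissoc, by = dt)
  kobs <- kon * P + koff
  req <- Rmax * P / (P + koff / kon)
  r_end <- req * (1 - exp(-kobs * t_assoc))
  resp <- ifelse(times <= t_assoc,
                 req * (1 - exp(-kobs * times)),
                 r_end * exp(-koff * (times - t_assoc)))
  if (noise_sd > 0) {
    resp <- resp + with_seed(seed, stats::rnorm(length(resp), 0, noise_sd))
  }
  sensorgram(times, resp, P,
             c(assoc_start = 0, assoc_end = t_assoc,
               dissoc_end = t_assoc + t_dissoc))
}

bli_presets <- list(
  didomain = list(kon = 1.6e5, koff = 0.0033,
                  concentrations = c(5, 10, 20, 40, 80, 160) * 1e-9),
  kh3_only = list(kon = 3.0e4, koff = 0.046,
                  concentrations = c(125, 250, 500, 1000, 2000, 4000, 8000) * 1e-9),
  kh4_only = list(kon = 1.4e5, koff = 0.13,
                  concentrations = c(125, 250, 500, 1000, 2000, 4000, 8000) * 1e-9)
)

#' Generate a synthetic BLI concentration series with known ground truth
#'
#' Emulates the BLI acquisitions on the immobilised 28-nt Zipcode RNA: a
#' two-fold protein concentration series of 5-160 nM for the KH3-KH4
#' di-domain and 125-8,000 nM for the single-functional-domain mutants,
#' with the measured rate constants as ground truth (di-domain: kon
#' 1.6e5 1/(M*s), koff 0.0033 1/s; KH3 only: 3.0e4, 0.046; KH4 only:
#' 1.4e5, 0.13).
#'
#' @param protein preset name: `"didomain"`, `"kh3_only"` or `"kh4_only"`.
#' @param noise_sd Gaussian noise standard deviation (response units; the
#'   default `Rmax` is 1, so 0.02 is 2% of `Rmax`).
#' @param seed integer seed; each trace draws its noise from a sub-seed
#'   derived deterministically from it.
#' @param Rmax maximal response.
#' @param t_assoc,t_dissoc phase durations (s).
#' @return A list with `sensorgrams` (list of [sensorgram()]) and
#'   `ground_truth` (list: `kon`, `koff`, `Kd`, `concentrations`, `Rmax`,
#'   `noise_sd`, `seed`).
#' @examples
#' ds <- generate_bli_dataset("kh3_only", noise_sd = 0, seed = 1)
#' ds$ground_truth$Kd * 1e6  # ~1.53 uM
#' @export
generate_bli_dataset <- function(protein = c("didomain", "kh3_only", "kh4_only"),
                                 noise_sd = 0, seed = 1L, Rmax = 1,
                                 t_assoc = 600, t_dissoc = 900) {
  if (!is.character(protein) || !protein[1L] %in% names(bli_presets)) {
    stop("unknown preset '", protein[1L], "'; available: ",
         paste(names(bli_presets), collapse = ", "), call. = FALSE)
  }
  protein <- match.arg(protein)
  preset <- bli_presets[[protein]]
  sgs <- lapply(seq_along(preset$concentrations), function(i) {
    simulate_sensorgram(preset$kon, preset$koff, preset$concentrations[i],
                        Rmax = Rmax, t_assoc = t_assoc, t_dissoc = t_dissoc,
                        noise_sd = noise_sd,
                        seed = if (is.null(seed)) NULL else seed * 1000L + i)
  })
  list(sensorgrams = sgs,
       ground_truth = list(kon = preset$kon, koff = preset$koff,
                           Kd = preset$koff / preset$kon,
                           concentrations = preset$concentrations,
                           Rmax = Rmax, noise_sd = noise_sd, seed = seed))
}

#' Write a synthetic BLI dataset to disk
#'
#' One CSV (plus JSON side-car) per trace and a `manifest.json` holding the
#' ground truth and seed.
#'
#' @param dataset output of [generate_bli_dataset()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bli_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(dataset$sensorgrams), function(i) {
    p <- file.path(dir, sprintf("trace_%02d.csv", i))
    write_sensorgram(dataset$sensorgrams[[i]], p)
    basename(p)
  }, character(1))
  jsonlite::write_json(c(dataset$ground_truth, list(traces = paths)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic BLI dataset written by [write_bli_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return A list with `sensorgrams` and `ground_truth`, as produced by
#'   [generate_bli_dataset()].
#' @export
read_bli_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sgs <- lapply(manifest$traces, function(p) read_sensorgram(file.path(dir, p)))
  manifest$traces <- NULL
  list(sensorgrams = sgs, ground_truth = manifest)
}
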