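# Boltzmann-weighted ensemble composition, hybrid reference/surrogate
# composites, and cost accounting.

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal mol^-1 K^-1

#' Boltzmann weights of a conformer ensemble
#'
#' `w_i = exp(-(E_i - E_min) / (kB * T))`, normalized to sum to 1. Shifting
#' all energies by a constant leaves the weights unchanged.
#'
#' @param energies Relative conformer energies in kcal/mol (finite,
#'   nonempty).
#' @param temperature Temperature in Kelvin (> 0), default 298.15.
#' @return Numeric weight vector summing to 1.
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  stopifnot(is.numeric(energies), length(energies) >= 1,
            all(is.finite(energies)))
  if (temperature <= 0) stop("temperature must be positive")
  w <- exp(-(energies - min(energies)) / (KB_KCAL * temperature))
  w / sum(w)
}

#' Weighted composite of conformer spectra
#'
#' Elementwise weighted sum of spectra sharing one grid; with Boltzmann
#' weights this is the simulated molecular spectrum of the ensemble.
#'
#' @param spectra List of [vcd_spectrum()] objects on identical grids.
#' @param weights Numeric weights, one per spectrum, summing to 1 (tolerance
#'   1e-9).
#' @return The composite [vcd_spectrum()].
#' @export
composite_spectrum <- function(spectra, weights) {
  stopifnot(is.list(spectra), length(spectra) == length(weights),
            length(spectra) >= 1)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", sum(weights), ")")
  grid <- spectra[[1]]$grid
  vals <- numeric(grid$points)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    stopifnot(inherits(s, "vcd_spectrum"))
    if (!grids_identical(s$grid, grid))
      stop("spectrum ", i, " is on a different grid")
    vals <- vals + weights[i] * s$values
  }
  vcd_spectrum(grid, vals)
}

#' Hybrid reference/surrogate Boltzmann composite
#'
#' Composes the molecular spectrum of an ensemble in which only a fraction
#' of the conformer spectra come from reference (quantum-chemistry)
#' calculations while the remainder are predicted by the surrogate:
#' `ceiling(dft_fraction * N)` conformers are selected by the given rule to
#' keep their reference spectra, the rest are predicted from their features,
#' and all N spectra are Boltzmann-combined. When every record carries a
#' reference spectrum, the report also contains the cosine similarity
#' (Theta) between the hybrid composite and the all-reference composite.
#'
#' @param records Conformer records; all must have features and an energy,
#'   and every selected record must have a reference spectrum.
#' @param model A trained `vcd_surrogate`.
#' @param dft_fraction Fraction in `(0, 1]` of conformers taking reference
#'   spectra.
#' @param temperature Kelvin, default 298.15.
#' @param selection `"lowest_energy"` (default: reference spectra are spent
#'   on the highest-Boltzmann-weight conformers) or `"random"`.
#' @param seed Seed for `selection = "random"`.
#' @return List with `spectrum` (the hybrid composite), `report` (data
#'   frame: id, energy, weight, source) and `theta` (similarity to the
#'   all-reference composite, or NA when not all references are available).
#' @export
hybrid_composite <- function(records, model, dft_fraction,
                             temperature = 298.15,
                             selection = c("lowest_energy", "random"),
                             seed = 1) {
  selection <- match.arg(selection)
  records_check(records)
  if (dft_fraction <= 0 || dft_fraction > 1)
    stop("dft_fraction must lie in (0, 1]")
  n <- length(records)
  energies <- vapply(records, function(r) r$energy, numeric(1))
  if (any(!is.finite(energies))) stop("all records need finite energies")
  n_ref <- as.integer(ceiling(dft_fraction * n))
  sel <- switch(selection,
    lowest_energy = order(energies)[seq_len(n_ref)],
    random = with_seed(seed, sample.int(n, n_ref)))
  has_ref <- vapply(records, function(r) inherits(r$spectrum, "vcd_spectrum"),
                    logical(1))
  if (!all(has_ref[sel])) {
    miss <- records[[sel[which(!has_ref[sel])[1]]]]$id
    stop("selected record '", miss, "' has no reference spectrum")
  }
  weights <- boltzmann_weights(energies, temperature)
  source <- rep("predicted", n)
  source[sel] <- "reference"
  spectra <- vector("list", n)
  spectra[sel] <- lapply(records[sel], function(r) r$spectrum)
  pred_idx <- setdiff(seq_len(n), sel)
  if (length(pred_idx))
    spectra[pred_idx] <- predict(model, records[pred_idx])
  hybrid <- composite_spectrum(spectra, weights)
  theta <- NA_real_
  if (all(has_ref)) {
    full <- composite_spectrum(lapply(records, function(r) r$spectrum),
                               weights)
    theta <- cosine_similarity(hybrid, full)
  }
  ids <- vapply(records, function(r) r$id, character(1))
  list(spectrum = hybrid,
       report = data.frame(id = ids, energy = energies, weight = weights,
                           source = source),
       theta = theta, dft_fraction = dft_fraction, selection = selection)
}

#' Cost accounting for the surrogate-aided workflow
#'
#' Pure arithmetic on user-supplied per-spectrum costs (nothing is timed):
#' the classical approach computes all `n_total` conformer spectra at the
#' reference level, the aided approach computes only `n_reference` of them
#' plus a one-off model-building cost.
#'
#' @param n_total Total number of conformers.
#' @param n_reference Number computed at the reference level
#'   (`0 < n_reference <= n_total`).
#' @param per_spectrum_reference_cost Cost of one reference spectrum (e.g.
#'   CPU hours), nonnegative.
#' @param ml_build_cost One-off surrogate training cost, nonnegative.
#' @return List with `classical_cost`, `aided_cost`, `savings` and
#'   `speedup`.
#' @export
cost_report <- function(n_total, n_reference,
                        per_spectrum_reference_cost, ml_build_cost = 0) {
  stopifnot(n_total >= 1, per_spectrum_reference_cost >= 0,
            ml_build_cost >= 0)
  if (n_reference <= 0 || n_reference > n_total)
    stop("n_reference must satisfy 0 < n_reference <= n_total")
  classical <- n_total * per_spectrum_reference_cost
  aided <- n_reference * per_spectrum_reference_cost + ml_build_cost
  list(classical_cost = classical, aided_cost = aided,
       savings = classical - aided, speedup = classical / aided)
}

#' Fraction sweep of hybrid-composite fidelity and speedup
#'
#' Re-runs [hybrid_composite()] over a range of reference fractions,
#' randomizing the selected subset over several seeds, and tabulates the
#' median Theta similarity to the all-reference composite together with the
#' accounting speedup (unit reference cost, free surrogate).
#'
#' @param records Records that all carry reference spectra.
#' @param model A trained `vcd_surrogate`.
#' @param fractions Reference fractions to sweep (default 0.1 to 0.9).
#' @param n_seeds Random selections per fraction (default 5).
#' @param temperature Kelvin.
#' @param seed Master seed.
#' @return Data frame with `fraction`, `theta_median`, `speedup`.
#' @export
benchmark_fractions <- function(records, model,
                                fractions = seq(0.1, 0.9, by = 0.1),
                                n_seeds = 5, temperature = 298.15,
                                seed = 1) {
  records_check(records, need_spectrum = TRUE)
  seeds <- derive_seeds(seed, n_seeds)
  rows <- lapply(fractions, function(f) {
    thetas <- vapply(seeds, function(s)
      hybrid_composite(records, model, f, temperature,
                       selection = "random", seed = s)$theta, numeric(1))
    n <- length(records)
    cr <- cost_report(n, ceiling(f * n), 1, 0)
    data.frame(fraction = f, theta_median = median(thetas),
               speedup = cr$speedup)
  })
  do.call(rbind, rows)
}
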