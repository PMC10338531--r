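# Spectrum containers and operations: line (stick) spectra, wavenumber grids,
# Lorentzian broadening, mirroring and cosine similarity.

#' Evenly spaced wavenumber grid
#'
#' Constructs the wavenumber axis on which broadened VCD spectra are
#' represented. The default grid spans 800 to 1800 cm^-1 with a 10 cm^-1
#' spacing (one step per Lorentzian FWHM), giving a 101-dimensional spectrum
#' vector.
#'
#' @param start,stop Grid limits in cm^-1; `stop` must exceed `start`.
#' @param step Node spacing in cm^-1, positive; `stop - start` must be an
#'   integer multiple of `step` (tolerance 1e-9 relative to `step`).
#' @return A `vcd_grid` object: list with `start`, `stop`, `step`, `points`
#'   and the node vector `wavenumbers` (both endpoints included).
#' @examples
#' vcd_grid()$points            # 101
#' vcd_grid(0, 10, 10)$points   # 2
#' @export
vcd_grid <- function(start = 800, stop = 1800, step = 10) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1,
            is.finite(start), is.finite(stop), is.finite(step))
  if (step <= 0) stop("grid step must be positive, got ", step)
  if (stop <= start) stop("grid stop must exceed start")
  n_intervals <- (stop - start) / step
  if (abs(n_intervals - round(n_intervals)) > 1e-9) {
    stop(sprintf(
      "grid span %g is not divisible by step %g (remainder %g)",
      stop - start, step, (stop - start) %% step))
  }
  n_intervals <- as.integer(round(n_intervals))
  structure(
    list(start = start, stop = stop, step = step,
         points = n_intervals + 1L,
         wavenumbers = start + step * (0:n_intervals)),
    class = "vcd_grid")
}

#' @export
print.vcd_grid <- function(x, ...) {
  cat(sprintf("<vcd_grid> %g..%g cm^-1, step %g (%d points)\n",
              x$start, x$stop, x$step, x$points))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$start, b$start)) &&
    isTRUE(all.equal(a$stop, b$stop)) &&
    isTRUE(all.equal(a$step, b$step))
}

#' VCD line (stick) spectrum
#'
#' A line spectrum is the discrete set of vibrational modes a harmonic
#' frequency calculation emits: one `(wavenumber, signed intensity)` pair per
#' mode, before any band-shape broadening. Intensities are in arbitrary
#' consistent Delta-epsilon-area units; negative values flag modes whose
#' rotatory strength has the opposite sign.
#'
#' @param wavenumber Numeric vector of mode positions in cm^-1, all > 0.
#' @param intensity Numeric vector of signed mode intensities, same length.
#' @return A `vcd_lines` data frame sorted by ascending wavenumber. May hold
#'   zero modes.
#' @export
vcd_lines <- function(wavenumber = numeric(0), intensity = numeric(0)) {
  stopifnot(is.numeric(wavenumber), is.numeric(intensity),
            length(wavenumber) == length(intensity))
  if (length(wavenumber) && (any(!is.finite(wavenumber)) || any(wavenumber <= 0)))
    stop("mode wavenumbers must be finite and strictly positive")
  if (length(intensity) && any(!is.finite(intensity)))
    stop("mode intensities must be finite")
  ord <- order(wavenumber)
  structure(
    data.frame(wavenumber = wavenumber[ord], intensity = intensity[ord]),
    class = c("vcd_lines", "data.frame"))
}

#' Grid spectrum container
#'
#' Holds Delta-epsilon values (`epsilon_L - epsilon_R`) sampled on a
#' [vcd_grid()]. This is the fixed-length vector the surrogate model learns
#' and predicts.
#'
#' @param grid A `vcd_grid`.
#' @param values Numeric vector of length `grid$points`, all finite.
#' @return A `vcd_spectrum` object.
#' @export
vcd_spectrum <- function(grid, values) {
  stopifnot(inherits(grid, "vcd_grid"), is.numeric(values))
  if (length(values) != grid$points)
    stop(sprintf("spectrum has %d values but grid has %d points",
                 length(values), grid$points))
  if (any(!is.finite(values))) stop("spectrum values must all be finite")
  structure(list(grid = grid, values = as.numeric(values)),
            class = "vcd_spectrum")
}

#' @export
print.vcd_spectrum <- function(x, ...) {
  cat(sprintf("<vcd_spectrum> %d points on %g..%g cm^-1; range [%.4g, %.4g]\n",
              x$grid$points, x$grid$start, x$grid$stop,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Lorentzian band broadening of a line spectrum
#'
#' Convolves a stick spectrum with an area-normalized Lorentzian,
#' `L(x) = (1/pi) * gamma / (x^2 + gamma^2)` with `gamma = fwhm / 2`, and
#' samples the result on `grid`:
#' `value(nu) = sum_k intensity_k * L(nu - nu_k)`.
#' The operation is linear in the mode intensities and additive over modes;
#' the integral of each broadened band recovers the mode intensity (up to
#' Lorentzian tail truncation), so intensities carry Delta-epsilon-area units.
#' Modes outside the grid window still contribute through their tails.
#'
#' @param lines A [vcd_lines()] spectrum (may be empty).
#' @param grid A [vcd_grid()].
#' @param fwhm Full width at half maximum of the Lorentzian in cm^-1
#'   (default 10).
#' @return A [vcd_spectrum()] on `grid`; all zeros for an empty line spectrum.
#' @examples
#' g <- vcd_grid()
#' s <- broaden(vcd_lines(1300, 1), g)
#' s$values[g$wavenumbers == 1300]  # 1 / (pi * 5)
#' @export
broaden <- function(lines, grid, fwhm = 10) {
  stopifnot(inherits(lines, "vcd_lines"), inherits(grid, "vcd_grid"),
            is.numeric(fwhm), length(fwhm) == 1, is.finite(fwhm))
  if (fwhm <= 0) stop("fwhm must be positive")
  if (nrow(lines) == 0)
    return(vcd_spectrum(grid, numeric(grid$points)))
  gam <- fwhm / 2
  d <- outer(grid$wavenumbers, lines$wavenumber, "-")
  vals <- as.vector((gam / pi) * ((1 / (d * d + gam * gam)) %*% lines$intensity))
  vcd_spectrum(grid, vals)
}

#' Mirror (enantiomer) spectrum
#'
#' The VCD spectrum of the enantiomer of a molecule is the sign-inverted
#' spectrum: every Delta-epsilon value is negated. Applying the operation
#' twice returns the original spectrum.
#'
#' @param s A [vcd_spectrum()].
#' @return The negated spectrum on the same grid.
#' @export
mirror_spectrum <- function(s) {
  stopifnot(inherits(s, "vcd_spectrum"))
  vcd_spectrum(s$grid, -s$values)
}

spectrum_values <- function(x, arg = "spectrum") {
  if (inherits(x, "vcd_spectrum")) return(x$values)
  if (is.numeric(x)) return(as.numeric(x))
  stop(arg, " must be a vcd_spectrum or a numeric vector")
}

#' Cosine similarity of two spectra
#'
#' The normalized overlap `sum(a*b) / (||a|| * ||b||)`, bounded in
#' `[-1, 1]`. A value of 1 means identical band shapes (up to positive
#' scaling), 0 means orthogonal spectra and -1 means the spectrum of the
#' enantiomer. The same functional is used both for predicted-versus-reference
#' conformer spectra and for hybrid-versus-full Boltzmann composites.
#'
#' @param a,b [vcd_spectrum()] objects on identical grids, or plain numeric
#'   vectors of equal length. Each must have nonzero norm: the similarity of
#'   a zero spectrum is undefined and raises an error rather than being
#'   absorbed as 0 or 1.
#' @return A single number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (inherits(a, "vcd_spectrum") && inherits(b, "vcd_spectrum") &&
      !grids_identical(a$grid, b$grid))
    stop("spectra are on different grids; cosine similarity is undefined")
  va <- spectrum_values(a, "a")
  vb <- spectrum_values(b, "b")
  if (length(va) != length(vb))
    stop("spectra have different lengths (", length(va), " vs ", length(vb), ")")
  na <- sqrt(sum(va * va))
  nb <- sqrt(sum(vb * vb))
  if (na == 0 || nb == 0)
    stop("undefined similarity: zero-norm spectrum")
  max(-1, min(1, sum(va * vb) / (na * nb)))
}
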