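# Synthetic conformer ensembles with a known, chirality-aware
# dihedral -> line-spectrum ground truth. These stand in for the conformer
# generation and quantum-chemistry stages of a real workflow so that the
# featurization, surrogate and ensemble-composition machinery can be
# exercised and validated end to end. They are synthetic by construction and
# make no claim of chemical realism.

#' Configuration of a synthetic dihedral-to-spectrum map
#'
#' The ground-truth map assigns each of `n_modes` vibrational modes a fixed
#' base frequency (drawn uniformly inside `frequency_range`) and an intensity
#' that is an odd trigonometric polynomial of the dihedral angles:
#' sums of `sin(k * theta_i)` terms (k = 1, 2; torsional expansions are
#' dominated by their low harmonics) and, at `coupling_order`
#' 2, pairwise `sin(theta_i) * cos(theta_j)` mode-coupling terms, with
#' map-fixed random coefficients. Oddness under `theta -> -theta` makes the
#' enantiomer mirror property `map(-theta) = -map(theta)` hold exactly, the
#' property the chirality experiments rely on. Mode frequencies carry a
#' bounded, even, dihedral-dependent shift (at most one FWHM) emulating the
#' mild frequency modulation that conformational change induces.
#'
#' @param n_dihedrals Number of torsions describing a conformer (>= 1).
#' @param n_modes Number of vibrational modes in the fingerprint window
#'   (default 40, a typical mid-IR mode density for a medium-sized organic
#'   molecule).
#' @param coupling_order 1 for independent-torsion intensities, 2 to add
#'   pairwise mode-coupling products (default 2).
#' @param frequency_range Numeric length-2, base-frequency window in cm^-1;
#'   default `c(850, 1750)` keeps all modes inside the default analysis grid.
#' @param intensity_scale Overall intensity scale (default 1).
#' @param noise_sd Standard deviation of Gaussian noise added to realized
#'   mode intensities (default 0 = noiseless oracle).
#' @param seed Integer seed; the map coefficients and every ensemble draw are
#'   reproducible from it.
#' @return A `synthetic_map_config` object.
#' @export
synthetic_map_config <- function(n_dihedrals, n_modes = 40,
                                 coupling_order = 2,
                                 frequency_range = c(850, 1750),
                                 intensity_scale = 1, noise_sd = 0,
                                 seed = 1) {
  stopifnot(n_dihedrals >= 1, n_modes >= 1, coupling_order %in% c(1, 2),
            length(frequency_range) == 2, intensity_scale > 0, noise_sd >= 0)
  if (frequency_range[2] <= frequency_range[1])
    stop("empty frequency range")
  structure(list(n_dihedrals = as.integer(n_dihedrals),
                 n_modes = as.integer(n_modes),
                 coupling_order = as.integer(coupling_order),
                 frequency_range = as.numeric(frequency_range),
                 intensity_scale = intensity_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_map_config")
}

# Build the deterministic map object (coefficients + closure). Internal;
# the closure is exposed on the ensemble as the test oracle.
build_synthetic_map <- function(cfg) {
  d <- cfg$n_dihedrals
  m <- cfg$n_modes
  freq <- runif(m, cfg$frequency_range[1], cfg$frequency_range[2])
  shift_coef <- runif(m, -5, 5)          # |shift| <= 5 cm^-1 < one FWHM
  a <- array(rnorm(m * d * 2), dim = c(m, d, 2))
  pairs <- if (cfg$coupling_order == 2 && d >= 2)
    t(utils::combn(d, 2)) else matrix(integer(0), 0, 2)
  b <- matrix(rnorm(m * nrow(pairs)), m, max(1, nrow(pairs)))[, seq_len(nrow(pairs)), drop = FALSE]
  n_terms <- d * 2 + nrow(pairs)
  scale <- cfg$intensity_scale / sqrt(n_terms)
  fun <- function(theta) {
    stopifnot(length(theta) == d)
    rad <- theta * pi / 180
    sin1 <- sin(rad); cos1 <- cos(rad)
    basis <- c(sin1, sin(2 * rad))                      # length 2d, all odd
    intens <- as.vector(matrix(a, m, d * 2) %*% basis)
    if (nrow(pairs) > 0) {
      pb <- sin1[pairs[, 1]] * cos1[pairs[, 2]]          # odd products
      intens <- intens + as.vector(b %*% pb)
    }
    vcd_lines(freq + shift_coef * mean(cos1), scale * intens)
  }
  list(freq = freq, shift_coef = shift_coef, a = a, b = b, pairs = pairs,
       fun = fun)
}

# Default smooth energy landscape: one cosine well term per dihedral with
# random depth, phase and multiplicity. Depths of 0.5-2.5 kcal/mol per
# torsion give room-temperature ensembles in which a minority of conformers
# carries most of the Boltzmann weight, as in real flexible molecules.
default_energy_params <- function(d) {
  list(depth = runif(d, 0.5, 2.5),
       phase = runif(d, -180, 180),
       mult = sample(1:3, d, replace = TRUE))
}

energy_of <- function(theta, p) {
  rad <- (theta - p$phase) * pi / 180
  sum(p$depth * (1 - cos(p$mult * rad)) / 2)
}

#' Generate a synthetic conformer ensemble
#'
#' Draws `n_conformers` dihedral tuples, assigns each an energy from a smooth
#' cosine-well landscape (shifted so the global minimum found in the ensemble
#' is 0 and truncated at 40 kcal/mol, the conformer-search energy cut-off)
#' and a line spectrum from the ground-truth map of `map_cfg`, optionally
#' with Gaussian intensity noise. The noiseless map itself is retained on the
#' returned object as the test oracle.
#'
#' Sampling modes: `"uniform"` draws each dihedral uniformly on
#' `(-180, 180]`; `"wells"` draws each dihedral near a randomly chosen
#' minimum of its energy term (Gaussian spread 20 degrees). Well positions
#' are random and generically chirality-asymmetric, so a wells-sampled
#' ensemble and its enantiomer occupy disjoint regions of torsion space --
#' the situation in which surrogate transfer across enantiomers fails.
#'
#' With `degenerate_pairs = TRUE`, `n_conformers` must be even: half the
#' conformers are internal-symmetry partners of the other half (dihedral
#' order reversed, emulating a C2 swap of equivalent sidechains) that share
#' the partner's identical spectrum and energy; the pairing is returned in
#' `pair_map`.
#'
#' @param n_conformers Number of conformers (>= 3).
#' @param map_cfg A [synthetic_map_config()].
#' @param energy_cfg Optional list with `depth`, `phase`, `mult` vectors (one
#'   entry per dihedral) overriding the randomly drawn landscape.
#' @param degenerate_pairs Logical (default FALSE).
#' @param sampling `"uniform"` (default) or `"wells"`.
#' @return A `synthetic_ensemble`: dihedral matrix (degrees), `energies`
#'   (kcal/mol), `line_spectra` (list of [vcd_lines()]), conformer `ids`,
#'   `map` (the oracle closure), `pair_map` and the configurations used.
#' @export
generate_ensemble <- function(n_conformers, map_cfg, energy_cfg = NULL,
                              degenerate_pairs = FALSE,
                              sampling = c("uniform", "wells")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(map_cfg, "synthetic_map_config"), n_conformers >= 3)
  if (degenerate_pairs && n_conformers %% 2 != 0)
    stop("degenerate_pairs requires an even number of conformers")
  d <- map_cfg$n_dihedrals
  with_seed(map_cfg$seed, {
    map <- build_synthetic_map(map_cfg)
    ep <- if (is.null(energy_cfg)) default_energy_params(d) else energy_cfg
    stopifnot(length(ep$depth) == d, length(ep$phase) == d,
              length(ep$mult) == d)
    n_draw <- if (degenerate_pairs) n_conformers %/% 2L else n_conformers
    theta <- if (sampling == "uniform") {
      matrix(runif(n_draw * d, -180, 180), n_draw, d)
    } else {
      t(vapply(seq_len(n_draw), function(i) {
        centers <- ep$phase + 360 * (sample(max(ep$mult), d, replace = TRUE) - 1) / ep$mult
        wrap_angle(centers + rnorm(d, 0, 20))
      }, numeric(d)))
    }
    theta <- wrap_angle(theta)
    if (degenerate_pairs && d >= 2) {
      # canonicalize base conformers into the theta_1 <= theta_d half-space
      # so that base + reversed-partner records realize one well-defined
      # symmetrized spectrum function (the internal symmetry is a property
      # of the true map, not a labelling accident)
      flip <- theta[, 1] > theta[, d]
      theta[flip, ] <- theta[flip, rev(seq_len(d)), drop = FALSE]
    }
    spectra <- lapply(seq_len(n_draw), function(i) {
      ln <- map$fun(theta[i, ])
      if (map_cfg$noise_sd > 0)
        ln <- vcd_lines(ln$wavenumber,
                        ln$intensity + rnorm(nrow(ln), 0, map_cfg$noise_sd))
      ln
    })
    energies <- apply(theta, 1, energy_of, p = ep)
    ids <- sprintf("conf%04d", seq_len(n_draw))
    pair_map <- NULL
    if (degenerate_pairs) {
      partner_theta <- theta[, rev(seq_len(d)), drop = FALSE]
      theta <- rbind(theta, partner_theta)
      energies <- c(energies, energies)
      spectra <- c(spectra, spectra)
      ids <- c(ids, sprintf("conf%04d_sym", seq_len(n_draw)))
      pair_map <- lapply(seq_len(n_draw), function(i) c(i, n_draw + i))
    }
    energies <- pmin(energies - min(energies), 40)
    rownames(theta) <- ids
    structure(list(dihedrals = theta, energies = energies,
                   line_spectra = spectra, ids = ids, map = map$fun,
                   map_cfg = map_cfg, energy_params = ep,
                   pair_map = pair_map, sampling = sampling),
              class = "synthetic_ensemble")
  })
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf(
    "<synthetic_ensemble> %d conformers, %d dihedrals, %d modes (%s sampling)\n",
    nrow(x$dihedrals), ncol(x$dihedrals), x$map_cfg$n_modes, x$sampling))
  invisible(x)
}

#' Enantiomer of a synthetic ensemble
#'
#' Negates every dihedral (the feature-space image of reflecting the
#' geometry) and every line-spectrum intensity while preserving energies,
#' exactly as the mirror symmetry of VCD demands. Applying the operation
#' twice restores the original ensemble; an equal-weight composite of an
#' ensemble and its enantiomer cancels to zero (a racemate has no VCD).
#'
#' @param e A `synthetic_ensemble`.
#' @return The mirrored `synthetic_ensemble`.
#' @export
make_enantiomer_ensemble <- function(e) {
  stopifnot(inherits(e, "synthetic_ensemble"))
  out <- e
  out$dihedrals <- wrap_angle(-e$dihedrals)
  out$ids <- ifelse(endsWith(e$ids, "_ent"),
                    sub("_ent$", "", e$ids), paste0(e$ids, "_ent"))
  rownames(out$dihedrals) <- out$ids
  out$line_spectra <- lapply(e$line_spectra, function(ln)
    vcd_lines(ln$wavenumber, -ln$intensity))
  out
}

#' Encode a dihedral tuple as a feature vector
#'
#' The synthetic-ensemble counterpart of [encode_conformer()]: maps a vector
#' of dihedral angles (degrees) to the `(sin, cos)` feature layout the
#' surrogate consumes.
#'
#' @param theta Numeric vector of dihedral angles in degrees.
#' @param encoding `"sincos"` (default) or `"raw_degrees"`.
#' @return A `vcd_features` vector.
#' @export
encode_dihedrals <- function(theta, encoding = c("sincos", "raw_degrees")) {
  encoding <- match.arg(encoding)
  labels <- sprintf("theta%d", seq_along(theta))
  enc <- encode_angles(as.numeric(theta), labels, encoding)
  make_feature_vector(enc$values, enc$names, enc$types)
}

#' Conformer records from a synthetic ensemble
#'
#' Broadens every line spectrum onto `grid` and packages each conformer as a
#' record (id, features, energy, reference spectrum) ready for
#' [split_dataset()], [train_fnn()] and [hybrid_composite()].
#'
#' @param e A `synthetic_ensemble`.
#' @param grid A [vcd_grid()] (default the 800-1800 cm^-1, 101-point grid).
#' @param fwhm Lorentzian FWHM in cm^-1 (default 10).
#' @param encoding Angle encoding passed to [encode_dihedrals()].
#' @return A list of conformer records (each a list with `id`, `features`,
#'   `energy`, `spectrum`, `source = "reference"`).
#' @export
ensemble_records <- function(e, grid = vcd_grid(), fwhm = 10,
                             encoding = "sincos") {
  stopifnot(inherits(e, "synthetic_ensemble"))
  lapply(seq_along(e$ids), function(i) {
    list(id = e$ids[i],
         features = encode_dihedrals(e$dihedrals[i, ], encoding),
         energy = e$energies[i],
         spectrum = broaden(e$line_spectra[[i]], grid, fwhm),
         source = "reference")
  })
}

#' Embed a dihedral tuple as a 3D chain geometry
#'
#' Builds a polymer-like carbon chain whose successive backbone torsions
#' realize the given dihedral angles (natural-extension-reference-frame
#' placement with fixed 1.5 Angstrom bonds and tetrahedral angles). This
#' trivial embedding exists so the Cartesian featurization path
#' ([encode_conformer()], XYZ parsing) can be exercised against known
#' torsions; it is not a physical model.
#'
#' @param theta Numeric vector of d dihedral angles in degrees.
#' @param bond_length Bond length in Angstrom (default 1.5).
#' @param bond_angle Bond angle in degrees (default 109.4712).
#' @return A [conformer_geometry()] with `d + 3` atoms.
#' @export
embed_dihedral_chain <- function(theta, bond_length = 1.5,
                                 bond_angle = 109.4712) {
  d <- length(theta)
  stopifnot(d >= 1)
  n <- d + 3
  coords <- matrix(0, n, 3)
  coords[2, ] <- c(bond_length, 0, 0)
  ang <- bond_angle * pi / 180
  coords[3, ] <- coords[2, ] + bond_length * c(-cos(ang), sin(ang), 0)
  for (k in seq_len(d)) {
    A <- coords[k, ]; B <- coords[k + 1, ]; C <- coords[k + 2, ]
    tor <- theta[k] * pi / 180
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    nvec <- cross3(B - A, bc); nvec <- nvec / sqrt(sum(nvec^2))
    mvec <- cross3(nvec, bc)
    local <- bond_length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
    coords[k + 3, ] <- C + local[1] * bc + local[2] * mvec + local[3] * nvec
  }
  conformer_geometry(rep("C", n), coords)
}

#' Dihedral specs for an embedded chain
#'
#' Companion to [embed_dihedral_chain()]: the list of 0-based atom quadruples
#' whose dihedral angles recover the embedded torsions, suitable for
#' [feature_config()].
#'
#' @param d Number of torsions.
#' @return List of d integer 4-vectors.
#' @export
chain_dihedral_specs <- function(d) {
  lapply(seq_len(d), function(k) c(k - 1, k, k + 1, k + 2) - 0L)
}
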