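# Conformer geometries and their dihedral-angle featurization.
#
# Atom indices in all specs are 0-based, matching programmatic indexing in
# configuration files; conversion from 1-based chemistry tools is the
# caller's responsibility.

#' Conformer geometry
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix with one row per atom and columns x, y, z in
#'   Angstrom. At least 4 atoms; all coordinates finite.
#' @return A `conformer_geometry` object.
#' @export
conformer_geometry <- function(elements, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(is.character(elements), ncol(coords) == 3)
  if (length(elements) != nrow(coords))
    stop("elements and coords describe different atom counts")
  if (length(elements) < 4)
    stop("a conformer geometry needs at least 4 atoms")
  if (any(!is.finite(coords)))
    stop("coordinates must all be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(elements = elements, coords = coords),
            class = "conformer_geometry")
}

#' @export
print.conformer_geometry <- function(x, ...) {
  cat(sprintf("<conformer_geometry> %d atoms (%s)\n", length(x$elements),
              paste(utils::head(x$elements, 8), collapse = " ")))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

check_atom_indices <- function(g, idx, what) {
  n <- nrow(g$coords)
  if (any(idx < 0) || any(idx >= n))
    stop(sprintf("%s: atom index out of range [0, %d): %s", what, n,
                 paste(idx[idx < 0 | idx >= n], collapse = ", ")))
}

#' Dihedral angle of four atoms
#'
#' Signed torsion angle about the j-k bond in the IUPAC convention: looking
#' from atom j towards atom k, a clockwise rotation of the far bond (k-l)
#' relative to the near bond (j-i) is positive. The result lies in
#' `(-180, 180]` degrees.
#'
#' @param g A [conformer_geometry()].
#' @param indices Integer vector `(i, j, k, l)` of four distinct 0-based atom
#'   indices.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(g, indices) {
  stopifnot(inherits(g, "conformer_geometry"))
  indices <- as.integer(indices)
  if (length(indices) != 4 || anyDuplicated(indices))
    stop("a dihedral needs four distinct atom indices")
  check_atom_indices(g, indices, "dihedral")
  p <- g$coords[indices + 1L, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  lens <- c(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2)))
  if (any(lens < 1e-10))
    stop(sprintf("degenerate dihedral (%s): coincident atoms in bond %d",
                 paste(indices, collapse = ","), which(lens < 1e-10)[1]))
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 * lens[1] * lens[2])
    stop(sprintf("degenerate dihedral (%s): atoms %d,%d,%d are collinear",
                 paste(indices, collapse = ","),
                 indices[1], indices[2], indices[3]))
  if (sqrt(sum(n2^2)) < 1e-10 * lens[2] * lens[3])
    stop(sprintf("degenerate dihedral (%s): atoms %d,%d,%d are collinear",
                 paste(indices, collapse = ","),
                 indices[2], indices[3], indices[4]))
  b2u <- b2 / lens[2]
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# circular mean of two angles in degrees, result in (-180, 180]
circular_mean2 <- function(a, b) {
  ar <- a * pi / 180
  br <- b * pi / 180
  s <- sin(ar) + sin(br)
  co <- cos(ar) + cos(br)
  if (sqrt(s^2 + co^2) < 1e-8)
    stop(sprintf("bisector undefined: dihedrals %g and %g are antipodal", a, b))
  ang <- atan2(s, co) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bisector angle of a label-symmetric pair of dihedrals
#'
#' For groups like NH2 whose two hydrogens are chemically equivalent, the raw
#' dihedral to either hydrogen depends on which numeric label the hydrogen
#' happens to carry. The bisector encoding removes that dependence: the two
#' dihedrals `(i, j, k, lA)` and `(i, j, k, lB)` sharing the first three atoms
#' are combined by their circular mean (summed unit vectors on the circle),
#' which is invariant under exchange of the two hydrogen labels.
#'
#' @param g A [conformer_geometry()].
#' @param pair A list of two 4-index dihedral specs (0-based) sharing the
#'   first three atoms and differing in the fourth.
#' @return Angle in degrees in `(-180, 180]`; an error if the two dihedrals
#'   are exactly antipodal (undefined bisector).
#' @export
bisector_angle <- function(g, pair) {
  stopifnot(is.list(pair), length(pair) == 2)
  d1 <- as.integer(pair[[1]])
  d2 <- as.integer(pair[[2]])
  if (!identical(d1[1:3], d2[1:3]))
    stop("bisector dihedrals must share their first three atoms")
  if (d1[4] == d2[4])
    stop("bisector dihedrals must differ in their fourth atom")
  circular_mean2(dihedral_angle(g, d1), dihedral_angle(g, d2))
}

#' Hydrogen-bond distance features
#'
#' Euclidean donor-H to acceptor distances for each `(H index, acceptor
#' index)` pair, in Angstrom and in the pair order given. These are the extra
#' geometry parameters used when torsions alone do not encode an
#' intramolecular hydrogen bond.
#'
#' @param g A [conformer_geometry()].
#' @param pairs List of 2-vectors of 0-based atom indices; may be empty.
#' @return Numeric vector of distances (possibly length 0).
#' @export
hbond_features <- function(g, pairs) {
  stopifnot(inherits(g, "conformer_geometry"), is.list(pairs))
  vapply(pairs, function(p) {
    p <- as.integer(p)
    if (length(p) != 2) stop("an hbond pair needs exactly two atom indices")
    check_atom_indices(g, p, "hbond pair")
    sqrt(sum((g$coords[p[1] + 1L, ] - g$coords[p[2] + 1L, ])^2))
  }, numeric(1))
}

#' Feature configuration for a molecule
#'
#' Declares which internal coordinates describe a conformer: a hand-picked
#' list of sidechain dihedrals, optional bisector-encoded label-symmetric
#' pairs, and optional hydrogen-bond distance pairs. Angles are encoded as
#' `(sin, cos)` pairs by default, which removes the +/-180 degree branch cut
#' from the learning problem; `raw_degrees` is retained for fidelity
#' experiments.
#'
#' @param dihedrals List of 4-vectors of 0-based atom indices.
#' @param bisectors List of bisector pairs, each a list of two 4-vectors
#'   sharing their first three indices.
#' @param hbond_pairs List of 2-vectors `(donor-H index, acceptor index)`.
#' @param angle_encoding `"sincos"` (default) or `"raw_degrees"`.
#' @return A `feature_config` object.
#' @export
feature_config <- function(dihedrals = list(), bisectors = list(),
                           hbond_pairs = list(),
                           angle_encoding = c("sincos", "raw_degrees")) {
  angle_encoding <- match.arg(angle_encoding)
  stopifnot(is.list(dihedrals), is.list(bisectors), is.list(hbond_pairs))
  if (length(dihedrals) + length(bisectors) + length(hbond_pairs) == 0)
    stop("feature configuration must declare at least one feature")
  structure(list(dihedrals = dihedrals, bisectors = bisectors,
                 hbond_pairs = hbond_pairs,
                 angle_encoding = angle_encoding),
            class = "feature_config")
}

# Assemble the named feature vector with per-slot types ("sin", "cos",
# "angle", "dist") used by the mirror rule and by training-time scaling.
make_feature_vector <- function(values, names, types) {
  structure(setNames(as.numeric(values), names), slot_type = types,
            class = "vcd_features")
}

encode_angles <- function(angles, labels, encoding) {
  if (encoding == "sincos") {
    rad <- angles * pi / 180
    vals <- as.vector(rbind(sin(rad), cos(rad)))
    nms <- as.vector(rbind(paste0("sin_", labels), paste0("cos_", labels)))
    types <- rep(c("sin", "cos"), times = length(labels))
  } else {
    vals <- angles
    nms <- labels
    types <- rep("angle", length(labels))
  }
  list(values = vals, names = nms, types = types)
}

#' Encode a conformer geometry as a feature vector
#'
#' Computes all configured dihedral, bisector and hydrogen-bond features in a
#' fixed deterministic order (dihedrals, then bisectors, then distances).
#' Under the `sincos` encoding every angle theta contributes the pair
#' `(sin theta, cos theta)`; distances are appended unscaled (min-max scaling
#' with training-split statistics is applied by the surrogate at training
#' time).
#'
#' @param g A [conformer_geometry()].
#' @param cfg A [feature_config()].
#' @return A named numeric `vcd_features` vector carrying a `slot_type`
#'   attribute.
#' @export
encode_conformer <- function(g, cfg) {
  stopifnot(inherits(g, "conformer_geometry"), inherits(cfg, "feature_config"))
  wrap <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature '%s': %s", label, conditionMessage(e)),
           call. = FALSE))
  }
  ang <- numeric(0)
  labels <- character(0)
  for (i in seq_along(cfg$dihedrals)) {
    lab <- sprintf("dih%d", i)
    ang <- c(ang, wrap(lab, dihedral_angle(g, cfg$dihedrals[[i]])))
    labels <- c(labels, lab)
  }
  for (i in seq_along(cfg$bisectors)) {
    lab <- sprintf("bis%d", i)
    ang <- c(ang, wrap(lab, bisector_angle(g, cfg$bisectors[[i]])))
    labels <- c(labels, lab)
  }
  enc <- if (length(ang)) encode_angles(ang, labels, cfg$angle_encoding)
         else list(values = numeric(0), names = character(0), types = character(0))
  dists <- if (length(cfg$hbond_pairs))
    hbond_features(g, cfg$hbond_pairs) else numeric(0)
  make_feature_vector(
    c(enc$values, dists),
    c(enc$names, if (length(dists)) sprintf("hbond%d", seq_along(dists))),
    c(enc$types, rep("dist", length(dists))))
}

#' Mirror-image geometry
#'
#' Reflects all coordinates through the xy plane (`z -> -z`), producing the
#' geometry of the enantiomeric conformer. Every dihedral angle changes sign;
#' distances are preserved; applying the operation twice restores the input
#' exactly.
#'
#' @param g A [conformer_geometry()].
#' @return The reflected `conformer_geometry`.
#' @export
mirror_geometry <- function(g) {
  stopifnot(inherits(g, "conformer_geometry"))
  coords <- g$coords
  coords[, 3] <- -coords[, 3]
  conformer_geometry(g$elements, coords)
}

#' Mirror rule for feature vectors
#'
#' Applies the enantiomer transformation directly in feature space: sine
#' slots are negated (dihedral angles change sign under reflection), cosine
#' and distance slots are unchanged; raw-degree angle slots are negated with
#' -180 mapped back to 180.
#'
#' @param v A `vcd_features` vector (from [encode_conformer()] or
#'   [encode_dihedrals()]).
#' @return The mirrored feature vector with the same layout.
#' @export
mirror_features <- function(v) {
  types <- attr(v, "slot_type")
  if (is.null(types)) stop("feature vector carries no slot_type layout")
  out <- unclass(v)
  out[types == "sin"] <- -out[types == "sin"]
  raw <- which(types == "angle")
  if (length(raw)) {
    a <- -out[raw]
    a[a <= -180] <- a[a <= -180] + 360
    out[raw] <- a
  }
  make_feature_vector(out, names(out), types)
}
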