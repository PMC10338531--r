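# Dihedral, bisector and hydrogen-bond featurization.

test_that("dihedral angle reproduces anti, syn and rotation-built torsions", {
  anti <- conformer_geometry(rep("C", 4),
    rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)))
  expect_equal(dihedral_angle(anti, 0:3), 180)
  syn <- conformer_geometry(rep("C", 4),
    rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(dihedral_angle(syn, 0:3), 0)

  # independent Rodrigues-rotation oracle, including the sign flip on mirror
  for (target in c(60, -60, 135, -170, 12.5)) {
    g <- torsion_geometry(target)
    expect_equal(dihedral_angle(g, 0:3), target, tolerance = 1e-9)
    expect_equal(dihedral_angle(mirror_geometry(g), 0:3), -target,
                 tolerance = 1e-9)
  }
})

test_that("degenerate dihedrals are rejected with the offending triple named", {
  lin <- conformer_geometry(rep("C", 4),
    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(dihedral_angle(lin, 0:3), "collinear")
  dup <- conformer_geometry(rep("C", 4),
    rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_error(dihedral_angle(dup, 0:3), "coincident")
  expect_error(dihedral_angle(lin, c(0, 1, 2, 2)), "distinct")
  expect_error(dihedral_angle(lin, c(0, 1, 2, 9)), "out of range")
})

test_that("dihedral angles are invariant under rigid motion (randomized)", {
  set.seed(7)
  for (i in 1:25) {
    theta <- runif(3, -179, 179)
    g <- embed_dihedral_chain(theta)
    tr <- random_rigid_transform()
    g2 <- apply_rigid(g, tr)
    for (s in chain_dihedral_specs(3))
      expect_equal(dihedral_angle(g2, s), dihedral_angle(g, s),
                   tolerance = 1e-9)
  }
})

test_that("bisector is the circular mean and is label-exchange symmetric", {
  # geometry with two 'hydrogens' on the same three-atom stem
  make_g <- function(a1, a2) {
    g1 <- torsion_geometry(a1)
    g2 <- torsion_geometry(a2)
    conformer_geometry(rep("C", 5), rbind(g1$coords, g2$coords[4, ]))
  }
  g <- make_g(10, 30)
  pair <- list(c(0, 1, 2, 3), c(0, 1, 2, 4))
  expect_equal(bisector_angle(g, pair), 20, tolerance = 1e-9)
  swapped <- list(c(0, 1, 2, 4), c(0, 1, 2, 3))
  expect_equal(bisector_angle(g, swapped), 20, tolerance = 1e-9)

  # circular mean straddling the branch cut (unit-vector oracle)
  g2 <- make_g(170, -170)
  expect_equal(bisector_angle(g2, pair), 180, tolerance = 1e-9)

  g3 <- make_g(90, -90)
  expect_error(bisector_angle(g3, pair), "antipodal")
  expect_error(bisector_angle(g, list(c(0, 1, 2, 3), c(0, 1, 3, 4))),
               "share")
  expect_error(bisector_angle(g, list(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               "differ")
})

test_that("bisector label-exchange symmetry holds for randomized geometries", {
  set.seed(31)
  for (i in 1:25) {
    a <- runif(2, -179, 179)
    if (abs(abs(diff(a)) - 180) < 5) next   # skip near-antipodal draws
    g1 <- torsion_geometry(a[1]); g2 <- torsion_geometry(a[2])
    g <- conformer_geometry(rep("C", 5), rbind(g1$coords, g2$coords[4, ]))
    p1 <- list(c(0, 1, 2, 3), c(0, 1, 2, 4))
    p2 <- list(c(0, 1, 2, 4), c(0, 1, 2, 3))
    expect_equal(bisector_angle(g, p1), bisector_angle(g, p2),
                 tolerance = 1e-9)
  }
})

test_that("hbond features are ordered distances, rigid-motion invariant", {
  g <- conformer_geometry(rep("O", 4),
    rbind(c(0, 0, 0), c(0, 0, 2), c(1, 0, 0), c(0, 3, 0)))
  expect_equal(hbond_features(g, list(c(0, 1), c(0, 3))), c(2, 3))
  expect_equal(hbond_features(g, list()), numeric(0))
  expect_error(hbond_features(g, list(c(0, 9))), "out of range")

  set.seed(13)
  for (i in 1:10) {
    tr <- random_rigid_transform()
    expect_equal(hbond_features(apply_rigid(g, tr), list(c(0, 1), c(2, 3))),
                 hbond_features(g, list(c(0, 1), c(2, 3))),
                 tolerance = 1e-9)
  }
})

test_that("encode_conformer lays out sincos features and mirrors correctly", {
  g <- torsion_geometry(90)
  cfg <- feature_config(dihedrals = list(0:3))
  v <- encode_conformer(g, cfg)
  expect_equal(as.numeric(v), c(1, 0), tolerance = 1e-12)
  expect_equal(names(v), c("sin_dih1", "cos_dih1"))
  expect_equal(attr(v, "slot_type"), c("sin", "cos"))

  # periodicity: theta and theta + 360 encode identically
  expect_equal(as.numeric(encode_dihedrals(47)),
               as.numeric(encode_dihedrals(47 + 360)), tolerance = 1e-12)

  # mirror geometry negates sines, preserves cosines and distances
  g2 <- embed_dihedral_chain(c(25, -140))
  cfg2 <- feature_config(dihedrals = chain_dihedral_specs(2),
                         hbond_pairs = list(c(0, 4)))
  v2 <- encode_conformer(g2, cfg2)
  vm <- encode_conformer(mirror_geometry(g2), cfg2)
  expect_equal(as.numeric(vm), as.numeric(mirror_features(v2)),
               tolerance = 1e-9)
  expect_equal(vm[["hbond1"]], v2[["hbond1"]], tolerance = 1e-9)
  expect_equal(as.numeric(mirror_geometry(mirror_geometry(g2))$coords),
               as.numeric(g2$coords))

  # planar geometry is a fixed point of the reflection
  flat <- conformer_geometry(rep("C", 4),
    rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)))
  expect_identical(mirror_geometry(flat)$coords, flat$coords)

  expect_error(feature_config(), "at least one feature")
  bad <- feature_config(dihedrals = list(c(0, 1, 2, 3), c(0, 1, 2, 9)))
  expect_error(encode_conformer(g2, bad), "feature 'dih2'")
})

test_that("raw-degree encoding round trips and mirrors with the branch cut", {
  v <- encode_dihedrals(c(60, 180), encoding = "raw_degrees")
  expect_equal(as.numeric(v), c(60, 180))
  m <- mirror_features(v)
  expect_equal(as.numeric(m), c(-60, 180))   # -180 wraps back to 180
})

test_that("the chain embedding realizes requested torsions exactly", {
  set.seed(3)
  theta <- runif(5, -179, 179)
  g <- embed_dihedral_chain(theta)
  got <- vapply(chain_dihedral_specs(5), function(s) dihedral_angle(g, s),
                numeric(1))
  expect_equal(got, theta, tolerance = 1e-8)
})
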