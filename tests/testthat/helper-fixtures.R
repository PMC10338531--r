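# Shared fixture builders. Everything is generated in code; no data files.

# Small coarse grid for fast spectrum tests.
small_grid <- function() vcd_grid(800, 1800, 50)

# A 4-atom geometry whose single torsion equals `angle` degrees, built by
# rotating the syn-periplanar arrangement about the central bond with an
# explicit Rodrigues rotation matrix (independent of dihedral_angle()).
torsion_geometry <- function(angle) {
  rodrigues <- function(u, th) {
    u <- u / sqrt(sum(u^2))
    K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
    diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
  }
  p4 <- as.vector(rodrigues(c(1, 0, 0), angle * pi / 180) %*% c(0, 1, 0)) +
    c(1, 0, 0)
  conformer_geometry(c("C", "C", "C", "C"),
                     rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), p4))
}

random_rigid_transform <- function() {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]    # proper rotation only
  list(R = Q, t = rnorm(3, sd = 5))
}

apply_rigid <- function(g, tr) {
  conformer_geometry(g$elements,
                     sweep(g$coords %*% t(tr$R), 2, -tr$t))
}

# Records with spectra that are an exactly linear function of the sin/cos
# features (coupling_order 1 map is a linear map of the sincos encoding).
linear_map_records <- function(n, d = 3, seed = 5, grid = small_grid()) {
  cfg <- synthetic_map_config(d, n_modes = 15, coupling_order = 1,
                              seed = seed)
  ensemble_records(generate_ensemble(n, cfg), grid = grid)
}

# Cheap deterministic objective for search-behaviour tests: no training,
# just a smooth function of the configuration.
cheap_objective <- function(cfg, seed) {
  log10(cfg$learning_rate / 1e-3)^2 + 0.1 * cfg$hidden_layers +
    0.001 * cfg$neurons_per_layer + cfg$dropout_rate
}
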