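## Shared fixtures and independent oracles. Expensive objects (radial bases)
## are built once per run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached_basis <- function(n_max, r_cut) {
  key <- paste0("basis_", n_max, "_", r_cut)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_radial_basis(n_max, r_cut)
  }
  .fixture_env[[key]]
}

## Random isolated cluster with species drawn from `elements`, pairwise
## distances kept above min_dist.
random_cluster <- function(n, elements, spread = 1.4, min_dist = 0.8) {
  repeat {
    pos <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
    if (n == 1L) break
    d <- as.matrix(stats::dist(pos))
    if (min(d[upper.tri(d)]) > min_dist) break
  }
  atomic_configuration(pos, sample(elements, n, replace = TRUE))
}

## Central finite-difference forces from any energy function.
fd_forces <- function(energy_fn, config, h = 1e-5) {
  n <- nrow(config$positions)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (c in 1:3) {
      cp <- config; cp$positions[i, c] <- cp$positions[i, c] + h
      cm <- config; cm$positions[i, c] <- cm$positions[i, c] - h
      out[i, c] <- -(energy_fn(cp) - energy_fn(cm)) / (2 * h)
    }
  }
  out
}

## Dense finite-difference descriptor Jacobian (independent of the analytic
## derivative code paths).
fd_descriptor_jacobian <- function(config, spec, basis, h = 1e-6) {
  n <- nrow(config$positions)
  n_p <- descriptor_dimension(spec)
  J <- matrix(0, n * n_p, n * 3)
  for (k in seq_len(n)) {
    for (c in 1:3) {
      cp <- config; cp$positions[k, c] <- cp$positions[k, c] + h
      cm <- config; cm$positions[k, c] <- cm$positions[k, c] - h
      dp <- (compute_descriptors(cp, spec, basis) -
               compute_descriptors(cm, spec, basis)) / (2 * h)
      J[, (k - 1) * 3 + c] <- as.numeric(t(dp))
    }
  }
  J
}

## Complex spherical harmonics Y_l^m via the associated Legendre recurrence
## (test-only oracle for the projection form of the descriptors).
assoc_legendre <- function(l, m, x) {
  ## P_m^m = (-1)^m (2m-1)!! (1-x^2)^{m/2}; P_{m+1}^m = x (2m+1) P_m^m;
  ## (l-m) P_l^m = x (2l-1) P_{l-1}^m - (l+m-1) P_{l-2}^m
  pmm <- (-1)^m * prod(seq(1, max(1, 2 * m - 1), by = 2)) *
    (1 - x^2)^(m / 2)
  if (l == m) return(pmm)
  pm1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pm1)
  for (ll in (m + 2):l) {
    p <- (x * (2 * ll - 1) * pm1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pm1
    pm1 <- p
  }
  pm1
}

sph_harm_Y <- function(l, m, unit_vec) {
  ct <- unit_vec[3]
  phi <- atan2(unit_vec[2], unit_vec[1])
  ma <- abs(m)
  norm <- sqrt((2 * l + 1) / (4 * pi) *
                 factorial(l - ma) / factorial(l + ma))
  y <- norm * assoc_legendre(l, ma, ct) * exp(1i * ma * phi)
  if (m < 0) y <- (-1)^ma * Conj(y)
  y
}

## A tagged dimer dataset spanning a window of separations: the package's
## 1-D toy problem (one interatomic degree of freedom).
dimer_dataset <- function(separations, pot = default_toy_system()$potential) {
  frames <- lapply(separations, function(d) {
    cfg <- atomic_configuration(rbind(c(0, 0, 0), c(d, 0, 0)), c("Na", "Cl"))
    lab <- toy_energy_forces(cfg, pot)
    list(config = cfg, energy = lab$energy, forces = lab$forces)
  })
  labeled_dataset(frames)
}

expect_rel_equal <- function(actual, expected, rel_tol, info = NULL) {
  scale <- max(abs(expected))
  expect_lt(max(abs(actual - expected)) / max(scale, .Machine$double.eps),
            rel_tol)
}
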