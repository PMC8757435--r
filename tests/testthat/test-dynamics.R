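## A harmonic dimer force field used by several integrator checks.
harmonic_ff <- function(k_spring = 2.0, r0 = 2.0) {
  structure(list(eval = function(config) {
    d <- config$positions[2, ] - config$positions[1, ]
    r <- sqrt(sum(d^2))
    u <- d / r
    f2 <- -k_spring * (r - r0) * u
    list(energy = 0.5 * k_spring * (r - r0)^2,
         forces = rbind(-f2, f2))
  }, label = "harmonic"), class = "force_field")
}

zero_ff <- structure(list(eval = function(config)
  list(energy = 0, forces = matrix(0, nrow(config$positions), 3)),
  label = "free"), class = "force_field")

test_that("free particles move ballistically without a thermostat", {
  cfg <- atomic_configuration(rbind(c(0, 0, 0), c(5, 0, 0)), c("Ar", "Ar"))
  v0 <- rbind(c(0.01, -0.002, 0.003), c(-0.01, 0.002, -0.003))
  traj <- run_nvt(zero_ff, cfg, temperature = 100, dt = 1, n_steps = 50,
                  thermostat = FALSE, velocities = v0)
  expect_equal(traj$positions[[51]], cfg$positions + 50 * v0,
               tolerance = 1e-12)
  expect_equal(traj$velocities[[51]], v0, tolerance = 1e-14)
})

test_that("NVE velocity Verlet conserves the energy of a harmonic dimer", {
  cfg <- atomic_configuration(rbind(c(0, 0, 0), c(2.3, 0, 0)), c("Ar", "Ar"))
  traj <- run_nvt(harmonic_ff(), cfg, temperature = 50, dt = 0.2,
                  n_steps = 10000, thermostat = FALSE, seed = 61,
                  record_every = 20)
  etot <- traj$energy + traj$kinetic
  drift <- abs(etot - etot[1]) / max(abs(etot[1]), max(traj$kinetic))
  expect_lt(max(drift), 1e-5)
})

test_that("NVE energy error scales as dt^2 (symplectic integrator)", {
  cfg <- atomic_configuration(rbind(c(0, 0, 0), c(2.3, 0, 0)), c("Ar", "Ar"))
  err_at <- function(dt) {
    traj <- run_nvt(harmonic_ff(), cfg, temperature = 80, dt = dt,
                    n_steps = round(2000 / dt), thermostat = FALSE,
                    seed = 62, record_every = 10)
    etot <- traj$energy + traj$kinetic
    max(abs(etot - etot[1]))
  }
  errs <- vapply(c(0.25, 0.5, 1), err_at, numeric(1))
  ## quartering the step cuts the fluctuation ~16x; allow generous slack
  expect_lt(errs[1], errs[3] / 8)
  expect_lt(errs[2], errs[3] / 2)
})

test_that("the Nose-Hoover thermostat holds the kinetic temperature", {
  ds <- generate_toy_dataset(1, seed = 63, verify = FALSE)
  ff <- make_toy_force_field(default_toy_system()$potential)
  traj <- run_nvt(ff, ds[[1]]$config, temperature = 300, dt = 1,
                  n_steps = 6000, tau = 100, seed = 63, record_every = 5)
  t_avg <- mean(traj$temperature[-(1:200)])   # discard equilibration
  expect_lt(abs(t_avg - 300) / 300, 0.03)
})

test_that("the VACF matches a brute-force double-loop oracle", {
  set.seed(64)
  nfr <- 40
  vel <- lapply(1:nfr, function(k) matrix(rnorm(9, sd = 0.01), 3, 3))
  traj <- structure(list(dt = 2, velocities = vel,
                         masses = c(1, 2, 3),
                         groups = list(indices = list(1L, 2L, 3L),
                                       type = c("a", "b", "a"))),
                    class = "md_trajectory")
  vac <- compute_vacf(traj, max_lag = 10)
  for (ti in c("a", "b")) {
    gsel <- which(c("a", "b", "a") == ti)
    for (lag in c(0, 3, 10)) {
      acc <- 0; cnt <- 0
      for (t0 in 1:(nfr - lag)) {
        for (g in gsel) {
          acc <- acc + sum(vel[[t0]][g, ] * vel[[t0 + lag]][g, ])
          cnt <- cnt + 1
        }
      }
      expect_equal(unname(vac$Z[lag + 1, ti]), acc / cnt, tolerance = 1e-12)
    }
  }
  ## zero-lag identity and constant-velocity invariance
  expect_equal(unname(vac$Z[1, "b"]), mean(vapply(1:nfr, function(k)
    sum(vel[[k]][2, ]^2), numeric(1))), tolerance = 1e-12)
  const <- structure(list(dt = 1,
                          velocities = rep(list(matrix(1:6 / 10, 2, 3)), 12),
                          masses = c(1, 1),
                          groups = list(indices = list(1L, 2L),
                                        type = c("a", "a"))),
                     class = "md_trajectory")
  vc <- compute_vacf(const, 5)
  expect_equal(max(abs(vc$Z - vc$Z[1, 1])), 0)
})

test_that("VACF uses center-of-mass velocities of ion groups", {
  v1 <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  traj <- structure(list(dt = 1, velocities = list(v1, v1),
                         masses = c(3, 1),
                         groups = list(indices = list(c(1L, 2L)),
                                       type = "mol")),
                    class = "md_trajectory")
  vac <- compute_vacf(traj, 1)
  ## COM velocity = (3*1 + 1*0)/4 = 0.75 in x
  expect_equal(unname(vac$Z[1, 1]), 0.75^2, tolerance = 1e-14)
})

test_that("Green-Kubo integration reproduces closed forms", {
  ## Z identically zero
  expect_equal(green_kubo_D(rep(0, 100), dt = 1)$D, 0)
  ## exponential VACF: D = Z0 tau / 3
  tau <- 50; z0 <- 0.02; dt <- 0.5
  t <- seq(0, 4000, by = dt)
  Z <- z0 * exp(-t / tau)
  gk <- green_kubo_D(Z, dt, si = FALSE)
  expect_equal(gk$D, z0 * tau / 3, tolerance = 1e-4)
  ## trapezoid quadrature error only: compare against exact partial integral
  exact <- z0 * tau * (1 - exp(-4000 / tau)) / 3
  expect_equal(gk$D, exact, tolerance = 1e-5)
  ## the running integral of a settled VACF has small tail spread
  expect_lt(gk$uncertainty, 1e-8)
})

test_that("a Langevin particle recovers the Einstein diffusion coefficient", {
  ## exact OU discretization of the velocity process:
  ## v(t+dt) = v e^{-g dt} + sqrt(kT/m (1 - e^{-2 g dt})) * N(0,1)
  set.seed(66)
  kT <- 0.025; m <- 20; gam <- 0.02; dt <- 1
  n <- 150000
  decay <- exp(-gam * dt)
  sd_eq <- sqrt(kT * besselff:::.acc_unit / m)
  v <- matrix(0, n, 3)
  v[1, ] <- rnorm(3, sd = sd_eq)
  noise <- sd_eq * sqrt(1 - decay^2)
  for (k in 2:n) v[k, ] <- v[k - 1, ] * decay + rnorm(3, sd = noise)
  traj <- structure(list(dt = dt,
                         velocities = lapply(seq_len(n), function(k)
                           matrix(v[k, ], 1, 3)),
                         masses = m,
                         groups = list(indices = list(1L), type = "p")),
                    class = "md_trajectory")
  vac <- compute_vacf(traj, max_lag = 600)
  gk <- green_kubo_D(vac$Z, dt, si = FALSE)
  d_einstein <- kT * besselff:::.acc_unit / (m * gam)
  expect_lt(abs(gk$D - d_einstein) / d_einstein, 0.15)
})

test_that("bond scans project pair forces onto the bond axis", {
  sys <- default_toy_system()
  pot <- sys$potential
  cfg <- atomic_configuration(rbind(c(0, 0, 0), c(2.5, 0, 0)),
                              c("Na", "Cl"))
  ff <- make_toy_force_field(pot)
  sc <- bond_scan(cfg, 1, 2, distances = seq(2.0, 3.2, length.out = 41),
                  models = list(toy = ff))
  ## default grid has 151 points on [1.05, 1.70]
  def <- formals(bond_scan)$distances
  grid <- eval(def)
  expect_length(grid, 151)
  expect_equal(range(grid), c(1.05, 1.70))
  ## analytic oracle: projection equals minus the radial derivative
  d <- sc$distances
  D <- pot$depth[1, 2]; a <- pot$width[1, 2]; r0 <- pot$r0[1, 2]
  e <- exp(-a * (d - r0))
  phi <- D * ((1 - e)^2 - 1)
  dphi <- 2 * D * a * (1 - e) * e
  sw <- besselff:::switch_fn(d, pot$r_on, pot$r_cut)
  expect_equal(sc$projections$toy, -(dphi * sw$s + phi * sw$ds),
               tolerance = 1e-10)
  ## the projection crosses zero at the model's own equilibrium separation
  sign_change <- diff(sign(sc$projections$toy))
  expect_true(any(sign_change != 0))
  i0 <- which(sign_change != 0)[1]
  expect_lt(abs(d[i0] - r0), 0.05)
  expect_error(bond_scan(atomic_configuration(matrix(0, 2, 3), c("N", "N")),
                         1, 2, models = list()), "zero-length")
})

test_that("trajectories round-trip through extended XYZ with velocities", {
  cfg <- atomic_configuration(rbind(c(0, 0, 0), c(2.3, 0, 0)), c("Ar", "Ar"))
  traj <- run_nvt(harmonic_ff(), cfg, temperature = 40, dt = 1, n_steps = 5,
                  thermostat = FALSE, seed = 67)
  path <- tempfile(fileext = ".xyz")
  write_trajectory(traj, path)
  back <- read_extxyz(path)
  expect_length(back, 6)
  expect_equal(back[[3]]$config$positions, traj$positions[[3]],
               tolerance = 1e-12)
  expect_equal(back[[3]]$extra$velocities, traj$velocities[[3]],
               tolerance = 1e-12)
  expect_equal(back[[3]]$energy, traj$energy[3], tolerance = 1e-12)
})

test_that("the VACF is symmetric under time reversal of the trajectory", {
  set.seed(68)
  vel <- lapply(1:25, function(k) matrix(rnorm(6, sd = 0.02), 2, 3))
  mk <- function(v) structure(list(dt = 1, velocities = v,
                                   masses = c(1, 1),
                                   groups = list(indices = list(1L, 2L),
                                                 type = c("a", "a"))),
                              class = "md_trajectory")
  fwd <- compute_vacf(mk(vel), 6)
  ## reversing time also flips velocity signs; the correlation is even
  rev_vel <- lapply(rev(vel), function(m) -m)
  bwd <- compute_vacf(mk(rev_vel), 6)
  expect_equal(bwd$Z, fwd$Z, tolerance = 1e-12)
})

test_that("the diffusion coefficient is stable under frame decimation", {
  tau <- 80; z0 <- 0.01; dt <- 0.5
  t <- seq(0, 4000, by = dt)
  Z <- z0 * exp(-t / tau)
  full <- green_kubo_D(Z, dt, si = FALSE)$D
  half <- green_kubo_D(Z[seq(1, length(Z), by = 2)], 2 * dt, si = FALSE)$D
  expect_equal(half, full, tolerance = 1e-4)
})
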