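## Molecular dynamics and trajectory-derived observables.
##
## Units: positions Angstrom, time fs, energies eV, masses amu, temperature
## K. Accelerations use 1 eV/(Angstrom amu) = 9.648533e-3 Angstrom/fs^2.

#' Force-field wrappers
#'
#' The dynamics layer consumes any object of class `force_field`: a list
#' with an `eval(config)` function returning `energy` and `forces`, plus a
#' `label`. Constructors are provided for the neural-network model, the
#' analytic toy potential, the CENT-augmented model, an ensemble (mean
#' forces), and a static-charge composite (network + point Coulomb).
#'
#' @param spec,basis Descriptor specification and radial basis.
#' @param params Model parameters.
#' @param label Display label.
#' @return A `force_field` object.
#' @export
make_nn_force_field <- function(spec, basis, params, label = "nn") {
  structure(list(eval = function(config)
    energy_and_forces(config, spec, basis, params),
    label = label), class = "force_field")
}

#' @rdname make_nn_force_field
#' @param pot A [toy_potential()].
#' @export
make_toy_force_field <- function(pot, label = "toy") {
  structure(list(eval = function(config) toy_energy_forces(config, pot),
                 label = label), class = "force_field")
}

#' @rdname make_nn_force_field
#' @param short_params,charge_params As in [cent_energy_and_forces()].
#' @export
make_cent_force_field <- function(spec, basis, short_params, charge_params,
                                  label = "cent") {
  structure(list(eval = function(config) {
    ef <- cent_energy_and_forces(config, spec, basis, short_params,
                                 charge_params)
    list(energy = ef$energy, forces = ef$forces)
  }, label = label), class = "force_field")
}

#' @rdname make_nn_force_field
#' @param ens An [train_ensemble()] object (mean forces are used).
#' @export
make_ensemble_force_field <- function(ens, basis, label = "ensemble") {
  structure(list(eval = function(config) {
    pred <- ensemble_predict(ens, config, basis)
    list(energy = pred$energy_mean, forces = pred$forces_mean)
  }, label = label), class = "force_field")
}

#' @rdname make_nn_force_field
#' @param charge_table Named per-element charges (e) added back as a point
#'   Coulomb term on top of the network.
#' @export
make_static_coulomb_force_field <- function(spec, basis, params, charge_table,
                                            label = "nn+coulomb") {
  structure(list(eval = function(config) {
    ef <- energy_and_forces(config, spec, basis, params)
    q <- as.numeric(charge_table[config$species])
    cf <- point_coulomb_energy_forces(config, q)
    list(energy = ef$energy + cf$energy, forces = ef$forces + cf$forces)
  }, label = label), class = "force_field")
}

#' Run thermostatted molecular dynamics
#'
#' Velocity-Verlet integration with a single Nose-Hoover thermostat
#' (Trotterized half-step updates of the friction variable; thermostat mass
#' \eqn{Q = N_f k_B T \tau^2}). With `thermostat = FALSE` the integrator is
#' plain (symplectic) velocity Verlet, i.e. NVE. Initial velocities are
#' Maxwell-Boltzmann at `temperature` with the center-of-mass drift removed;
#' the run is deterministic given `seed`.
#'
#' @param ff A `force_field`.
#' @param config Starting [atomic_configuration()].
#' @param temperature Target temperature (K).
#' @param dt Time step (fs).
#' @param n_steps Number of integration steps.
#' @param tau Thermostat coupling constant (fs; default 100 fs = 0.1 ps).
#' @param thermostat `FALSE` for NVE.
#' @param seed Seed for the initial velocities.
#' @param record_every Store every this-many-th frame (default 1).
#' @param masses Optional per-atom masses (amu); default from the element
#'   table.
#' @param groups Optional ion/molecule grouping: a list with `indices`
#'   (list of integer vectors partitioning the atoms) and `type` (character
#'   vector of group type labels), carried into the trajectory for VACF
#'   analysis. Default: every atom its own group typed by element.
#' @param velocities Optional starting velocities (Angstrom/fs) overriding
#'   the Maxwell-Boltzmann draw.
#' @return An object of class `md_trajectory`: `dt` (fs, between stored
#'   frames), `positions` and `velocities` (lists of matrices), `energy`
#'   (potential, eV), `kinetic` (eV), `temperature` (instantaneous, K),
#'   `masses`, `species`, `groups`, `cell`, `periodic`.
#' @export
run_nvt <- function(ff, config, temperature, dt, n_steps, tau = 100,
                    thermostat = TRUE, seed = 1L, record_every = 1L,
                    masses = NULL, groups = NULL, velocities = NULL) {
  n <- n_atoms(config)
  if (is.null(masses)) masses <- element_property(config$species, "mass")
  if (is.null(groups)) {
    groups <- list(indices = as.list(seq_len(n)), type = config$species)
  }
  kT <- .kB_eV * temperature
  nf <- 3L * n - 3L
  if (is.null(velocities)) {
    v <- with_seed(seed, matrix(stats::rnorm(3L * n), n, 3L)) *
      sqrt(kT * .acc_unit / masses)
    v <- v - matrix(colSums(v * masses) / sum(masses), n, 3L, byrow = TRUE)
  } else {
    v <- as.matrix(velocities)
  }
  pos <- unname(config$positions)
  cfg <- config
  ef <- ff$eval(cfg)
  acc <- unname(as.matrix(ef$forces)) * .acc_unit / masses
  xi <- 0
  Qth <- nf * kT * tau^2
  n_rec <- floor(n_steps / record_every) + 1L
  traj_pos <- vector("list", n_rec)
  traj_vel <- vector("list", n_rec)
  epot <- numeric(n_rec); ekin <- numeric(n_rec); tinst <- numeric(n_rec)
  rec <- 1L
  kin <- function(v) 0.5 * sum(masses * rowSums(v^2)) / .acc_unit
  store <- function(k, e) {
    traj_pos[[k]] <<- pos
    traj_vel[[k]] <<- v
    epot[k] <<- e
    ekin[k] <<- kin(v)
    tinst[k] <<- 2 * ekin[k] / (nf * .kB_eV)
  }
  store(1L, ef$energy)
  for (step in seq_len(n_steps)) {
    if (thermostat) {
      xi <- xi + dt / 2 * (2 * kin(v) - nf * kT) / Qth
      v <- v * exp(-xi * dt / 2)
    }
    v <- v + dt / 2 * acc
    pos <- pos + dt * v
    cfg$positions <- pos
    ef <- ff$eval(cfg)
    if (!all(is.finite(ef$forces)) || !is.finite(ef$energy)) {
      stop("non-finite force/energy at step ", step)
    }
    acc <- unname(as.matrix(ef$forces)) * .acc_unit / masses
    v <- v + dt / 2 * acc
    if (thermostat) {
      v <- v * exp(-xi * dt / 2)
      xi <- xi + dt / 2 * (2 * kin(v) - nf * kT) / Qth
    }
    if (step %% record_every == 0L) {
      rec <- rec + 1L
      store(rec, ef$energy)
    }
  }
  structure(list(dt = dt * record_every, positions = traj_pos,
                 velocities = traj_vel, energy = epot, kinetic = ekin,
                 temperature = tinst, masses = masses,
                 species = config$species, groups = groups,
                 cell = config$cell, periodic = config$periodic),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", length(x$positions), " frames, dt = ", x$dt,
      " fs, <T> = ", round(mean(x$temperature), 1), " K\n", sep = "")
  invisible(x)
}

#' Write a trajectory as multi-frame extended XYZ
#'
#' @param traj An [run_nvt()] trajectory.
#' @param path Output path. Velocities are stored as an extra
#'   `velocities:R:3` column (Angstrom/fs).
#' @export
write_trajectory <- function(traj, path) {
  frames <- lapply(seq_along(traj$positions), function(k) {
    list(config = atomic_configuration(traj$positions[[k]], traj$species,
                                       traj$cell, traj$periodic),
         energy = traj$energy[k],
         extra = list(velocities = traj$velocities[[k]]))
  })
  write_extxyz(labeled_dataset(frames), path)
}

#' Velocity autocorrelation function per ion type
#'
#' \eqn{Z_I(t) = \langle v_I(t_0) \cdot v_I(t_0 + t) \rangle}, with
#' \eqn{v_I} the center-of-mass velocity of each ion/molecule of the type,
#' averaged over time origins (every `origin_stride`-th frame) and over the
#' ions of that type.
#'
#' @param traj An [run_nvt()] trajectory carrying `groups`.
#' @param max_lag Maximum lag in stored frames (must be below the number of
#'   frames).
#' @param origin_stride Use every this-many-th frame as a time origin.
#' @return List with `t` (fs), `Z` (a `(max_lag + 1) x n_types` matrix,
#'   Angstrom^2/fs^2) and `types`.
#' @export
compute_vacf <- function(traj, max_lag, origin_stride = 1L) {
  nfr <- length(traj$velocities)
  if (nfr < 2L) stop("need at least 2 frames")
  if (max_lag >= nfr) stop("lag beyond trajectory length")
  types <- unique(traj$groups$type)
  ng <- length(traj$groups$indices)
  ## center-of-mass velocities: [frame, group, coord]
  vcom <- array(0, c(nfr, ng, 3L))
  for (g in seq_len(ng)) {
    idx <- traj$groups$indices[[g]]
    mg <- traj$masses[idx]
    for (k in seq_len(nfr)) {
      vcom[k, g, ] <- colSums(traj$velocities[[k]][idx, , drop = FALSE] * mg) /
        sum(mg)
    }
  }
  Z <- matrix(0, max_lag + 1L, length(types),
              dimnames = list(NULL, types))
  for (ti in seq_along(types)) {
    gsel <- which(traj$groups$type == types[ti])
    for (lag in 0:max_lag) {
      origins <- seq(1L, nfr - lag, by = origin_stride)
      acc <- 0
      for (c in 1:3) {
        v0 <- vcom[origins, gsel, c, drop = FALSE]
        vl <- vcom[origins + lag, gsel, c, drop = FALSE]
        acc <- acc + sum(v0 * vl)
      }
      Z[lag + 1L, ti] <- acc / (length(origins) * length(gsel))
    }
  }
  list(t = (0:max_lag) * traj$dt, Z = Z, types = types)
}

#' Green-Kubo diffusion coefficient
#'
#' \eqn{D = \frac{1}{3}\int_0^T Z(t)\,dt} by the trapezoidal rule. The
#' uncertainty is half the spread (max - min) of the running integral over
#' the final `tail_window` of the integration interval, where the numerical
#' integral oscillates around its limit.
#'
#' @param Z Numeric vector (one type) or matrix (columns = types) of VACF
#'   values on a uniform grid, in Angstrom^2/fs^2.
#' @param dt Grid spacing (fs).
#' @param tail_window Length (fs) of the final window used for the
#'   uncertainty (default: the last 10% of the interval).
#' @param si Convert to m^2/s (default `TRUE`; 1 Angstrom^2/fs = 1e-5 m^2/s).
#' @return A data frame with one row per type: `D`, `uncertainty`, `cutoff`
#'   (the integration time, fs).
#' @export
green_kubo_D <- function(Z, dt, tail_window = NULL, si = TRUE) {
  Z <- as.matrix(Z)
  if (!nrow(Z)) stop("empty VACF")
  nt <- nrow(Z)
  t_end <- (nt - 1L) * dt
  if (is.null(tail_window)) tail_window <- 0.1 * t_end
  unit <- if (si) .D_unit else 1
  out <- lapply(seq_len(ncol(Z)), function(ci) {
    z <- Z[, ci]
    cum <- c(0, cumsum((z[-1L] + z[-nt]) / 2 * dt))
    runD <- cum / 3 * unit
    tail_idx <- which((seq_len(nt) - 1L) * dt >= t_end - tail_window)
    data.frame(type = colnames(Z)[ci] %||% paste0("type", ci),
               D = runD[nt],
               uncertainty = diff(range(runD[tail_idx])) / 2,
               cutoff = t_end)
  })
  do.call(rbind, out)
}

#' Bond scan: projected force along a bond
#'
#' Displaces `moved_atom` along the axis towards `center_atom` so that the
#' separation takes each requested value (no other atom moves), evaluates
#' each model, and returns the projection of the force on the moved atom
#' onto the bond axis. An `ensemble_model` entry contributes its mean and
#' standard deviation.
#'
#' @param config The base [atomic_configuration()].
#' @param center_atom,moved_atom Atom indices defining the bond.
#' @param distances Separations to sample (Angstrom); default 151 points on
#'   [1.05, 1.70].
#' @param models Named list of `force_field` objects and/or
#'   `ensemble_model`s.
#' @param basis Radial basis (needed for ensemble entries).
#' @return A list with `distances` and `projections` (a data frame with a
#'   column per model, plus `<name>_sd` columns for ensembles), in
#'   eV/Angstrom.
#' @export
bond_scan <- function(config, center_atom, moved_atom,
                      distances = seq(1.05, 1.70, length.out = 151L),
                      models = list(), basis = NULL) {
  axis <- config$positions[moved_atom, ] - config$positions[center_atom, ]
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("zero-length bond axis")
  axis <- axis / nrm
  cols <- list()
  for (nm in names(models)) {
    mdl <- models[[nm]]
    is_ens <- inherits(mdl, "ensemble_model")
    proj <- numeric(length(distances))
    proj_sd <- numeric(length(distances))
    for (di in seq_along(distances)) {
      cfg <- config
      cfg$positions[moved_atom, ] <- cfg$positions[center_atom, ] +
        distances[di] * axis
      if (is_ens) {
        pj <- vapply(mdl$members, function(pp) {
          sum(forces(cfg, mdl$spec, basis, pp)[moved_atom, ] * axis)
        }, numeric(1))
        proj[di] <- mean(pj)
        proj_sd[di] <- stats::sd(pj)
      } else {
        proj[di] <- sum(mdl$eval(cfg)$forces[moved_atom, ] * axis)
      }
    }
    cols[[nm]] <- proj
    if (is_ens) cols[[paste0(nm, "_sd")]] <- proj_sd
  }
  list(distances = distances, projections = as.data.frame(cols))
}
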