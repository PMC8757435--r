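## Long-range electrostatics: a fixed-charge Coulomb baseline and the
## charge-equilibration (CENT) model, where environment-dependent
## electronegativities predicted by a small network drive a constrained
## quadratic minimization for the atomic charges.
##
## Smearing convention: each atom carries a Gaussian charge density of width
## sigma_i, so a pair interacts as k Q_i Q_j erf(r / gamma_ij) / r with
## gamma_ij = sqrt(sigma_i^2 + sigma_j^2), and the on-site self-energy is
## k Q_i^2 / (sqrt(2 pi) sigma_i) (the r -> 0 limit of half the pair term at
## gamma_ii = sqrt(2) sigma_i). Periodic systems use the real-space
## minimum-image sum only, which is adequate for the dense, strongly screened
## regime exercised here; Ewald summation is out of scope.

## Pair geometry helper: unique pairs i < j with minimum-image displacement.
all_pairs <- function(config) {
  n <- n_atoms(config)
  if (n < 2L) {
    return(list(i = integer(0), j = integer(0),
                disp = matrix(0, 0L, 3L), r = numeric(0)))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  disp <- config$positions[j, , drop = FALSE] -
    config$positions[i, , drop = FALSE]
  disp <- minimum_image(disp, config$cell, config$periodic)
  list(i = i, j = j, disp = disp, r = sqrt(rowSums(disp^2)))
}

#' Smeared-Coulomb energy and forces at fixed charges
#'
#' Electrostatic energy of Gaussian-smeared charges:
#' \eqn{E = \sum_{i<j} k Q_i Q_j \mathrm{erf}(r_{ij}/\gamma_{ij})/r_{ij} +
#' \sum_i k Q_i^2 / (\sqrt{2\pi}\sigma_i)}, finite at \eqn{r \to 0}. Forces
#' are the exact derivatives at fixed charges.
#'
#' @param config An [atomic_configuration()].
#' @param charges Numeric vector of atomic charges (e).
#' @param sigmas Numeric vector of positive Gaussian widths (Angstrom).
#' @return List with `energy` (eV) and `forces` (`n_atoms x 3`).
#' @export
smeared_coulomb_energy <- function(config, charges, sigmas) {
  n <- n_atoms(config)
  if (length(charges) != n || length(sigmas) != n) {
    stop("charges/sigmas must have one entry per atom")
  }
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  pr <- all_pairs(config)
  force <- matrix(0, n, 3L)
  self_e <- sum(.coulomb_k * charges^2 / (sqrt(2 * pi) * sigmas))
  if (!length(pr$i)) return(list(energy = self_e, forces = force))
  gam <- sqrt(sigmas[pr$i]^2 + sigmas[pr$j]^2)
  qq <- charges[pr$i] * charges[pr$j]
  x <- pr$r / gam
  epair <- .coulomb_k * qq * erf_(x) / pr$r
  ## d/dr [erf(r/g)/r] = 2 exp(-x^2) / (sqrt(pi) g r) - erf(x) / r^2
  dEdr <- .coulomb_k * qq *
    (2 * exp(-x^2) / (sqrt(pi) * gam * pr$r) - erf_(x) / pr$r^2)
  u <- pr$disp / pr$r
  fj <- -dEdr * u
  for (c in 1:3) {
    acc_j <- rowsum(fj[, c], pr$j)
    force[as.integer(rownames(acc_j)), c] <-
      force[as.integer(rownames(acc_j)), c] + acc_j
    acc_i <- rowsum(fj[, c], pr$i)
    force[as.integer(rownames(acc_i)), c] <-
      force[as.integer(rownames(acc_i)), c] - acc_i
  }
  list(energy = sum(epair) + self_e, forces = force)
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Charge-equilibration model parameters
#'
#' Bundles the per-element atomic hardnesses (learnable), the Gaussian
#' widths (fixed to covalent radii), and the electronegativity network
#' (default widths 16:16:16:1, Swish-1) that maps the same descriptor +
#' embedding input as the short-range model to a per-atom electronegativity.
#'
#' @param spec A [descriptor_spec()].
#' @param hardness Per-element hardness J (eV/e^2); scalar recycled, default 5.
#' @param sigmas Per-element Gaussian widths (Angstrom); defaults to the
#'   tabulated covalent radii of `spec$elements`.
#' @param chi_widths Hidden widths of the electronegativity network.
#' @param seed Seed for the network initialization.
#' @return An object of class `charge_model_params`.
#' @export
init_charge_model <- function(spec, hardness = 5, sigmas = NULL,
                              chi_widths = c(16L, 16L, 16L), seed = 1L) {
  if (is.null(sigmas)) {
    sigmas <- element_property(spec$elements, "covalent_radius")
  }
  if (length(hardness) == 1L) hardness <- rep(hardness, spec$n_el)
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  d_in <- descriptor_dimension(spec) + spec$n_emb
  chi_layers <- with_seed(seed, init_layers(d_in, chi_widths, 1L))
  structure(list(spec = spec, hardness = hardness, sigmas = sigmas,
                 chi_layers = chi_layers, activation = "swish1",
                 layernorm = TRUE, coulomb_k = .coulomb_k),
            class = "charge_model_params")
}

## Build the quadratic form of the equilibration problem.
## A = A_elec + diag(hardness); A_elec holds the smeared pair interactions
## plus twice the self-energy coefficient on the diagonal.
charge_matrix <- function(config, charge_params) {
  s_idx <- match(config$species, charge_params$spec$elements)
  if (anyNA(s_idx)) stop("species outside the charge-model element table")
  sig <- charge_params$sigmas[s_idx]
  n <- n_atoms(config)
  A_elec <- diag(2 * .coulomb_k / (sqrt(2 * pi) * sig), n)
  pr <- all_pairs(config)
  if (length(pr$i)) {
    gam <- sqrt(sig[pr$i]^2 + sig[pr$j]^2)
    val <- .coulomb_k * erf_(pr$r / gam) / pr$r
    A_elec[cbind(pr$i, pr$j)] <- val
    A_elec[cbind(pr$j, pr$i)] <- val
  }
  list(A_elec = A_elec, hardness = charge_params$hardness[s_idx],
       sigmas = sig, pairs = pr, s_idx = s_idx)
}

#' Equilibrate atomic charges
#'
#' Minimizes \eqn{\sum_i (\chi_i Q_i + J_i Q_i^2 / 2) + E_{coul}(Q)} subject
#' to global neutrality \eqn{\sum_i Q_i = 0}, by solving the KKT linear
#' system with a Lagrange multiplier. The solution is unique whenever the
#' quadratic form is positive definite on the neutral subspace.
#'
#' @param config An [atomic_configuration()].
#' @param chis Per-atom electronegativities (eV/e).
#' @param charge_params An [init_charge_model()] object.
#' @return An object of class `charge_solution`: `charges` (e),
#'   `lagrange_multiplier` (eV/e), `objective` (eV), and the KKT `residual`.
#' @export
equilibrate_charges <- function(config, chis, charge_params) {
  n <- n_atoms(config)
  if (length(chis) != n) stop("chis must have one entry per atom")
  cm <- charge_matrix(config, charge_params)
  A <- cm$A_elec + diag(cm$hardness, n)
  K <- rbind(cbind(A, 1), c(rep(1, n), 0))
  rhs <- c(-chis, 0)
  if (rcond(K) < 1e-12) {
    stop("charge-equilibration system is singular or ill-conditioned ",
         "(rcond = ", format(rcond(K), digits = 3), ")")
  }
  sol <- solve(K, rhs)
  Q <- sol[seq_len(n)]
  lambda <- sol[n + 1L]
  obj <- sum(chis * Q) + 0.5 * sum(Q * (A %*% Q))
  structure(list(charges = Q, lagrange_multiplier = lambda,
                 objective = obj,
                 residual = max(abs(K %*% sol - rhs))),
            class = "charge_solution")
}

#' CENT energy and forces
#'
#' Augments the short-range additive model with the smeared-Coulomb energy
#' of globally equilibrated charges: the electronegativity network maps the
#' same descriptors and embedding as the short-range network to per-atom
#' \eqn{\chi_i}, the charges minimize the equilibration objective under
#' neutrality, and the total energy is
#' \eqn{E = E_{short} + E_{elec}(Q^*)}. Forces are exact total derivatives:
#' the charge response to atomic displacements is handled by solving the
#' adjoint of the KKT system (no differentiation through the solve is
#' needed), and the position dependence of \eqn{\chi} flows through the
#' descriptor pullback.
#'
#' @param config An [atomic_configuration()].
#' @param spec,basis Descriptor specification and radial basis.
#' @param short_params Short-range model parameters ([init_params()]).
#' @param charge_params An [init_charge_model()] object.
#' @return List with `energy` (eV), `forces` (`n_atoms x 3`), `charges`,
#'   `chis`, and `energy_short` / `energy_elec` components.
#' @export
cent_energy_and_forces <- function(config, spec, basis, short_params,
                                   charge_params) {
  ws <- descriptor_workspace(config, spec, basis, derivatives = TRUE)
  p <- descriptors_from_workspace(ws)
  X <- model_input(short_params, p, ws$s_idx)
  n <- n_atoms(config)
  n_p <- descriptor_dimension(spec)

  vg <- mlp_value_and_grad(short_params$layers, X,
                           activation = short_params$activation,
                           layernorm = short_params$layernorm)
  e_short <- sum(vg$out) + short_params$offset
  G <- vg$dX[, seq_len(n_p), drop = FALSE]

  chi_fw <- mlp_forward(charge_params$chi_layers, X,
                        activation = charge_params$activation,
                        layernorm = charge_params$layernorm)
  chis <- chi_fw$out
  cm <- charge_matrix(config, charge_params)
  A <- cm$A_elec + diag(cm$hardness, n)
  K <- rbind(cbind(A, 1), c(rep(1, n), 0))
  sol <- solve(K, c(-chis, 0))
  Q <- sol[seq_len(n)]
  e_elec <- 0.5 * sum(Q * (cm$A_elec %*% Q))

  ## adjoint of the KKT system for w = dE_elec/dQ = A_elec Q
  w <- as.numeric(cm$A_elec %*% Q)
  adj <- solve(K, c(w, 0))
  y <- adj[seq_len(n)]

  ## cotangent on chi: dE/dchi = -y (from dQ = -A^{-1}_{kkt} dchi)
  chi_bw <- mlp_backward(charge_params$chi_layers, chi_fw$tape, chi_fw$H_last,
                         -y, charge_params$activation, charge_params$layernorm)
  G_total <- G + chi_bw$dX[, seq_len(n_p), drop = FALSE]
  if (!is.null(short_params$standardize)) {
    G_total <- G_total * rep(1 / short_params$standardize$scale, each = n)
  }
  grad <- pullback_apply(ws, G_total)

  ## explicit position dependence of the pair interactions: effective pair
  ## weight Q_i Q_j (from E_elec at fixed Q) minus y_i Q_j + Q_i y_j (from
  ## the adjoint term through A)
  pr <- cm$pairs
  if (length(pr$i)) {
    gam <- sqrt(cm$sigmas[pr$i]^2 + cm$sigmas[pr$j]^2)
    x <- pr$r / gam
    dfun <- .coulomb_k *
      (2 * exp(-x^2) / (sqrt(pi) * gam * pr$r) - erf_(x) / pr$r^2)
    wpair <- Q[pr$i] * Q[pr$j] - (y[pr$i] * Q[pr$j] + Q[pr$i] * y[pr$j])
    dEdr <- wpair * dfun
    u <- pr$disp / pr$r
    gj <- dEdr * u
    for (c in 1:3) {
      acc_j <- rowsum(gj[, c], pr$j)
      grad[as.integer(rownames(acc_j)), c] <-
        grad[as.integer(rownames(acc_j)), c] + acc_j
      acc_i <- rowsum(gj[, c], pr$i)
      grad[as.integer(rownames(acc_i)), c] <-
        grad[as.integer(rownames(acc_i)), c] - acc_i
    }
  }
  list(energy = e_short + e_elec, forces = -grad, charges = Q, chis = chis,
       energy_short = e_short, energy_elec = e_elec)
}

#' Point-charge Coulomb energy and forces
#'
#' Bare \eqn{k q_i q_j / r_{ij}} interactions of fixed point charges
#' (minimum image when periodic); the baseline long-range term of
#' molecular-mechanics force fields.
#'
#' @param config An [atomic_configuration()].
#' @param charges Per-atom charges (e).
#' @return List with `energy` (eV) and `forces`.
#' @export
point_coulomb_energy_forces <- function(config, charges) {
  n <- n_atoms(config)
  if (length(charges) != n) stop("charges must have one entry per atom")
  pr <- all_pairs(config)
  force <- matrix(0, n, 3L)
  if (!length(pr$i)) return(list(energy = 0, forces = force))
  qq <- .coulomb_k * charges[pr$i] * charges[pr$j]
  epair <- qq / pr$r
  dEdr <- -qq / pr$r^2
  u <- pr$disp / pr$r
  fj <- -dEdr * u
  for (c in 1:3) {
    acc_j <- rowsum(fj[, c], pr$j)
    force[as.integer(rownames(acc_j)), c] <-
      force[as.integer(rownames(acc_j)), c] + acc_j
    acc_i <- rowsum(fj[, c], pr$i)
    force[as.integer(rownames(acc_i)), c] <-
      force[as.integer(rownames(acc_i)), c] - acc_i
  }
  list(energy = sum(epair), forces = force)
}

#' Subtract static Coulomb forces from a dataset
#'
#' Replaces each frame's reference forces by (reference - fixed-charge point
#' Coulomb forces) given a per-element charge table; reference energies are
#' reduced by the Coulomb energy likewise. Training on the result and adding
#' the Coulomb part back at prediction time realizes the fixed-charge
#' baseline variant. Applying the negated table inverts the transform.
#'
#' @param ds A [labeled_dataset()].
#' @param charge_table Named numeric vector: element symbol -> charge (e).
#' @param sign `-1` (default) subtracts the Coulomb contribution; `+1`
#'   ([add_static_coulomb()]) restores it, so subtract-then-add is the
#'   identity.
#' @return The transformed dataset.
#' @export
subtract_static_coulomb <- function(ds, charge_table, sign = -1) {
  frames <- lapply(ds, function(fr) {
    q <- charge_table[fr$config$species]
    if (anyNA(q)) {
      stop("untyped atom species: ",
           paste(setdiff(unique(fr$config$species), names(charge_table)),
                 collapse = ", "))
    }
    ef <- point_coulomb_energy_forces(fr$config, as.numeric(q))
    if (!is.null(fr$forces)) fr$forces <- fr$forces + sign * ef$forces
    if (!is.null(fr$energy)) fr$energy <- fr$energy + sign * ef$energy
    fr
  })
  labeled_dataset(frames)
}

#' @rdname subtract_static_coulomb
#' @export
add_static_coulomb <- function(ds, charge_table) {
  subtract_static_coulomb(ds, charge_table, sign = 1)
}

#' Read a static charge table
#'
#' Simple typed text format: one `element charge` pair per line, `#`
#' comments allowed.
#'
#' @param path File path.
#' @return Named numeric vector of charges (e).
#' @export
read_charge_table <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) stop("malformed charge table at line ", bad[1L])
  stats::setNames(as.numeric(vapply(toks, `[[`, "", 2L)),
                  vapply(toks, `[[`, "", 1L))
}
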