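## Synthetic-data generator: an analytic Morse-type pair potential with a
## smooth cutoff stands in for the electronic-structure ground truth, so that
## training, ensembling and dynamics can be exercised end to end on labeled
## data whose energies and forces are exact by construction.

#' Parameters of the analytic toy pair potential
#'
#' A per-element-pair Morse potential
#' \eqn{\phi(r) = D[(1 - e^{-a(r - r_0)})^2 - 1]} multiplied by a quintic
#' smoothstep switching function that takes the interaction smoothly to zero
#' between `r_on` and `r_cut`. Energies and forces are analytic, so generated
#' labels are exact.
#'
#' @param elements Ordered character vector of element symbols.
#' @param depth Symmetric matrix of well depths D (eV).
#' @param width Symmetric matrix of inverse-range parameters a (1/Angstrom).
#' @param r0 Symmetric matrix of equilibrium distances (Angstrom).
#' @param r_on Switching onset (Angstrom).
#' @param r_cut Interaction cutoff (Angstrom).
#' @param charges Optional named per-element charges (e) for electrostatics
#'   experiments; not part of the potential itself.
#' @return An object of class `toy_potential`.
#' @export
toy_potential <- function(elements, depth, width, r0,
                          r_on = 0.75 * r_cut, r_cut = 3.5, charges = NULL) {
  n <- length(elements)
  chk <- function(m, nm) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(n, n))) stop(nm, " must be n_el x n_el")
    if (max(abs(m - t(m))) > 1e-12) stop(nm, " must be symmetric")
    m
  }
  depth <- chk(depth, "depth"); width <- chk(width, "width")
  r0 <- chk(r0, "r0")
  if (any(width <= 0) || any(r0 <= 0)) stop("length scales must be positive")
  if (!(r_on < r_cut)) stop("r_on must be below r_cut")
  structure(list(elements = elements, depth = depth, width = width, r0 = r0,
                 r_on = r_on, r_cut = r_cut, charges = charges),
            class = "toy_potential")
}

## Quintic smoothstep switch: 1 for r <= r_on, 0 for r >= r_cut, C^2 in
## between. Returns value and derivative.
switch_fn <- function(r, r_on, r_cut) {
  t <- (r - r_on) / (r_cut - r_on)
  t <- pmin(pmax(t, 0), 1)
  s <- 1 - t^3 * (10 - 15 * t + 6 * t^2)
  ds <- -(30 * t^2 - 60 * t^3 + 30 * t^4) / (r_cut - r_on)
  ds[r <= r_on | r >= r_cut] <- 0
  list(s = s, ds = ds)
}

#' Energy and forces of the toy pair potential
#'
#' @param config An [atomic_configuration()].
#' @param pot A [toy_potential()].
#' @return List with `energy` (eV) and `forces` (`n_atoms x 3`, eV/Angstrom).
#' @export
toy_energy_forces <- function(config, pot) {
  s_idx <- match(config$species, pot$elements)
  if (anyNA(s_idx)) stop("species outside the toy potential element table")
  n <- n_atoms(config)
  energy <- 0
  force <- matrix(0, n, 3L)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      disp <- sweep(config$positions[(i + 1L):n, , drop = FALSE], 2L,
                    config$positions[i, ])
      disp <- minimum_image(disp, config$cell, config$periodic)
      r <- sqrt(rowSums(disp^2))
      keep <- which(r < pot$r_cut)
      if (!length(keep)) next
      disp <- disp[keep, , drop = FALSE]
      r <- r[keep]
      j_idx <- ((i + 1L):n)[keep]
      D <- pot$depth[cbind(s_idx[i], s_idx[j_idx])]
      a <- pot$width[cbind(s_idx[i], s_idx[j_idx])]
      re <- pot$r0[cbind(s_idx[i], s_idx[j_idx])]
      e <- exp(-a * (r - re))
      phi <- D * ((1 - e)^2 - 1)
      dphi <- 2 * D * a * (1 - e) * e
      sw <- switch_fn(r, pot$r_on, pot$r_cut)
      energy <- energy + sum(phi * sw$s)
      dEdr <- dphi * sw$s + phi * sw$ds
      u <- disp / r
      fpair <- -dEdr * u              # force on atom j (disp points i -> j)
      force[j_idx, ] <- force[j_idx, ] + fpair
      force[i, ] <- force[i, ] - colSums(fpair)
    }
  }
  list(energy = energy, forces = force)
}

#' Pack molecular templates into a box
#'
#' Places rigid copies of molecular templates at random positions and
#' orientations inside a (periodic) box, rejecting placements whose
#' intermolecular distances fall below `min_dist`. Reproducible given `seed`.
#'
#' @param n_molecules Integer vector: number of copies of each template.
#' @param templates List of templates, each a list with `positions`
#'   (`n x 3`, Angstrom, any origin) and `species`.
#' @param box Box edge length (scalar) or length-3 vector (Angstrom); the
#'   cell is orthorhombic.
#' @param min_dist Minimum allowed intermolecular atom-atom distance
#'   (Angstrom), applied with the minimum-image convention.
#' @param seed Integer seed.
#' @param periodic Whether the box is periodic (default `TRUE`).
#' @param max_attempts Placement attempts per molecule before giving up.
#' @return An [atomic_configuration()].
#' @export
pack_box <- function(n_molecules, templates, box, min_dist = 2.0, seed = 1L,
                     periodic = TRUE, max_attempts = 2000L) {
  if (length(box) == 1L) box <- rep(box, 3L)
  cell <- diag(box)
  if (length(n_molecules) != length(templates)) {
    stop("n_molecules must have one entry per template")
  }
  with_seed(seed, {
    placed_pos <- NULL
    placed_spec <- character(0)
    for (t_idx in seq_along(templates)) {
      tpl <- templates[[t_idx]]
      tp <- as.matrix(tpl$positions)
      tp <- sweep(tp, 2L, colMeans(tp))
      for (copy in seq_len(n_molecules[t_idx])) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          Rm <- random_rotation()
          shift <- stats::runif(3L) * box
          cand <- sweep(tp %*% t(Rm), 2L, -shift)
          if (!is.null(placed_pos)) {
            d2min <- Inf
            for (k in seq_len(nrow(cand))) {
              disp <- sweep(placed_pos, 2L, cand[k, ])
              if (periodic) disp <- minimum_image(disp, cell, rep(TRUE, 3L))
              d2min <- min(d2min, min(rowSums(disp^2)))
            }
            if (d2min < min_dist^2) next
          }
          placed_pos <- rbind(placed_pos, cand)
          placed_spec <- c(placed_spec, tpl$species)
          ok <- TRUE
          break
        }
        if (!ok) {
          stop("packing failed: could not place template ", t_idx,
               " copy ", copy, " after ", max_attempts, " attempts")
        }
      }
    }
    atomic_configuration(placed_pos, placed_spec,
                         cell = if (periodic) cell else NULL,
                         periodic = periodic)
  })
}

#' Default toy system: a reduced-scale molten-salt-like ionic box
#'
#' Four Na and four Cl atoms in a periodic cubic box, bound by a Morse pair
#' potential with attractive unlike pairs and shallow like pairs. This
#' emulates the structure of a thermally sampled multi-species ionic-liquid
#' training database at a size where every label is exact and cheap.
#'
#' @return A list with `templates`, `n_molecules`, `box`, `min_dist` and
#'   `potential` (a [toy_potential()]).
#' @export
default_toy_system <- function() {
  elements <- c("Na", "Cl")
  depth <- matrix(c(0.08, 0.45, 0.45, 0.06), 2, 2)
  width <- matrix(c(1.6, 1.8, 1.8, 1.5), 2, 2)
  r0 <- matrix(c(3.2, 2.5, 2.5, 3.6), 2, 2)
  pot <- toy_potential(elements, depth, width, r0, r_on = 2.6, r_cut = 3.5)
  list(templates = list(list(positions = matrix(0, 1, 3), species = "Na"),
                        list(positions = matrix(0, 1, 3), species = "Cl")),
       n_molecules = c(4L, 4L),
       box = 7.5, min_dist = 2.1, potential = pot)
}

#' Generate a labeled synthetic dataset
#'
#' Draws independent frames by packing the toy system at random and applying
#' Gaussian thermal-like jitter, then labels each frame with the exact
#' analytic energy and forces of the toy potential. All randomness flows from
#' a single dataset seed through per-frame seeds. A finite-difference
#' self-check on up to 10 random frames verifies the labels at generation
#' time.
#'
#' @param n_frames Number of frames.
#' @param system A system description as returned by [default_toy_system()].
#' @param t_spread Standard deviation of the per-coordinate jitter
#'   (Angstrom) emulating thermal disorder (default 0.1).
#' @param seed Integer dataset seed.
#' @param verify Run the finite-difference label self-check (default `TRUE`).
#' @return A [labeled_dataset()].
#' @export
generate_toy_dataset <- function(n_frames, system = default_toy_system(),
                                 t_spread = 0.1, seed = 1L, verify = TRUE) {
  frame_seeds <- with_seed(seed, sample.int(2^31 - 2L, n_frames + 1L))
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    cfg <- pack_box(system$n_molecules, system$templates, system$box,
                    min_dist = system$min_dist, seed = frame_seeds[k])
    jit <- with_seed(frame_seeds[k] + 1L,
                     matrix(stats::rnorm(3L * n_atoms(cfg), sd = t_spread),
                            ncol = 3L))
    cfg$positions <- cfg$positions + jit
    lab <- toy_energy_forces(cfg, system$potential)
    frames[[k]] <- list(config = cfg, energy = lab$energy,
                        forces = lab$forces)
  }
  ds <- labeled_dataset(frames)
  if (verify) {
    check <- with_seed(frame_seeds[n_frames + 1L],
                       sample(n_frames, min(10L, n_frames)))
    h <- 1e-6
    for (k in check) {
      cfg <- ds[[k]]$config
      i <- 1L + (k %% n_atoms(cfg))
      for (c in 1:3) {
        cp <- cfg; cp$positions[i, c] <- cp$positions[i, c] + h
        cm <- cfg; cm$positions[i, c] <- cm$positions[i, c] - h
        fd <- -(toy_energy_forces(cp, system$potential)$energy -
                  toy_energy_forces(cm, system$potential)$energy) / (2 * h)
        if (abs(fd - ds[[k]]$forces[i, c]) > 1e-5) {
          stop("label self-check failed on frame ", k)
        }
      }
    }
  }
  ds
}
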