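#' Create an atomic configuration
#'
#' Bundles one frame of an atomistic system: Cartesian coordinates, chemical
#' species, and (optionally) a periodic simulation cell. This is the common
#' input type of the descriptor, electrostatics and dynamics layers.
#'
#' @param positions Numeric `n_atoms x 3` matrix of Cartesian coordinates in
#'   Angstrom.
#' @param species Character vector of element symbols, one per atom.
#' @param cell Optional `3 x 3` matrix of lattice vectors (rows) in Angstrom.
#' @param periodic Logical scalar or length-3 vector of per-axis periodicity
#'   flags. Defaults to `TRUE` when a cell is given, `FALSE` otherwise.
#' @return An object of class `atomic_configuration` with fields `positions`,
#'   `species`, `cell` (or `NULL`) and `periodic`.
#' @examples
#' dimer <- atomic_configuration(rbind(c(0, 0, 0), c(0, 0, 1.1)), c("N", "N"))
#' @export
atomic_configuration <- function(positions, species, cell = NULL,
                                 periodic = !is.null(cell)) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n_atoms x 3 matrix")
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  species <- as.character(species)
  if (length(species) != nrow(positions)) {
    stop("species length (", length(species), ") does not match atom count (",
         nrow(positions), ")")
  }
  if (length(periodic) == 1L) periodic <- rep(isTRUE(periodic), 3L)
  if (length(periodic) != 3L) stop("periodic must have length 1 or 3")
  if (any(periodic)) {
    if (is.null(cell)) stop("a periodic configuration requires a cell")
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3L, 3L))) stop("cell must be a 3 x 3 matrix")
    storage.mode(cell) <- "double"
    if (abs(det(cell)) < 1e-10) stop("cell is singular")
  } else if (!is.null(cell)) {
    cell <- as.matrix(cell)
    storage.mode(cell) <- "double"
  }
  structure(list(positions = positions, species = species, cell = cell,
                 periodic = periodic),
            class = "atomic_configuration")
}

#' @export
print.atomic_configuration <- function(x, ...) {
  cat("<atomic_configuration> ", nrow(x$positions), " atoms (",
      paste(names(sort(table(x$species), decreasing = TRUE)), collapse = ", "),
      "), ", if (any(x$periodic)) "periodic" else "isolated", "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a configuration
#'
#' @param config An [atomic_configuration()].
#' @return Integer atom count.
#' @export
n_atoms <- function(config) nrow(config$positions)

## Perpendicular heights of the cell (distance between opposite faces).
## The minimum-image convention is valid only for cutoffs below half of the
## smallest of these.
cell_heights <- function(cell) {
  vol <- abs(det(cell))
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  areas <- c(sqrt(sum(cross(cell[2, ], cell[3, ])^2)),
             sqrt(sum(cross(cell[3, ], cell[1, ])^2)),
             sqrt(sum(cross(cell[1, ], cell[2, ])^2)))
  vol / areas
}

## Minimum-image displacement vectors for a matrix of raw displacements.
minimum_image <- function(disp, cell, periodic) {
  if (is.null(cell) || !any(periodic)) return(disp)
  frac <- disp %*% solve(cell)
  frac[, periodic] <- frac[, periodic] - round(frac[, periodic])
  frac %*% cell
}

#' Apply a rigid motion to a configuration
#'
#' Rotates and translates all coordinates (useful for invariance testing and
#' for packing molecular templates). The cell, if any, is rotated as well so
#' that fractional coordinates are preserved.
#'
#' @param config An [atomic_configuration()].
#' @param rotation A `3 x 3` orthogonal matrix.
#' @param translation Length-3 numeric vector in Angstrom.
#' @return The transformed `atomic_configuration`.
#' @export
transform_configuration <- function(config, rotation = diag(3),
                                    translation = c(0, 0, 0)) {
  pos <- config$positions %*% t(rotation)
  pos <- sweep(pos, 2L, -as.numeric(translation))
  cell <- config$cell
  if (!is.null(cell)) cell <- cell %*% t(rotation)
  atomic_configuration(pos, config$species, cell, config$periodic)
}

#' Draw a uniformly random rotation matrix
#'
#' Generates a rotation from the Haar measure on SO(3) via the QR
#' decomposition of a Gaussian matrix; used by the packing generator and by
#' invariance checks.
#'
#' @param rng_normal Optional function `n -> numeric(n)` supplying standard
#'   normal draws (defaults to [stats::rnorm()], so `set.seed()` applies).
#' @return A `3 x 3` rotation matrix with determinant +1.
#' @export
random_rotation <- function(rng_normal = stats::rnorm) {
  m <- matrix(rng_normal(9L), 3L, 3L)
  qr_m <- qr(m)
  q <- qr.Q(qr_m)
  d <- sign(diag(qr.R(qr_m)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
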