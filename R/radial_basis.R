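## Orthonormal radial basis for the spherical Bessel descriptors.
##
## Construction: for each angular momentum l, primitive profiles are built as
## the normalized linear combination of j_l(u_{l,n} r / r_cut) and
## j_l(u_{l,n+1} r / r_cut) whose slope vanishes at r_cut (the value vanishes
## automatically because the u are zeros of j_l); the second derivative then
## vanishes too, by the spherical Bessel differential equation. The primitives
## are orthonormalized per l with the radial measure r^2 dr by a Gram-Schmidt
## procedure, realized through the Cholesky factor of their Gram matrix.

#' Spherical Bessel function of the first kind
#'
#' Evaluates \eqn{j_l(x)} via the half-integer-order Bessel function
#' `besselJ`, with a series fallback near the origin where the
#' \eqn{\sqrt{\pi/2x}} prefactor is indeterminate.
#'
#' @param l Nonnegative integer order.
#' @param x Numeric vector of nonnegative arguments.
#' @return Numeric vector of \eqn{j_l(x)}.
#' @export
spherical_bessel_j <- function(l, x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  small <- x < 1e-4
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  }
  if (any(small)) {
    xs <- x[small]
    ## j_l(x) = x^l / (2l+1)!! * (1 - x^2 / (2(2l+3)) + x^4 / (8(2l+3)(2l+5)))
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- xs^l / dfact *
      (1 - xs^2 / (2 * (2 * l + 3)) +
         xs^4 / (8 * (2 * l + 3) * (2 * l + 5)))
  }
  out
}

## d j_l / dx, from the recurrence j_l' = j_{l-1} - (l+1)/x * j_l.
spherical_bessel_j_prime <- function(l, x) {
  x <- as.numeric(x)
  if (l == 0L) return(-spherical_bessel_j(1L, x))
  out <- numeric(length(x))
  small <- x < 1e-4
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- spherical_bessel_j(l - 1L, xs) -
      (l + 1) / xs * spherical_bessel_j(l, xs)
  }
  if (any(small)) {
    xs <- x[small]
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    ## derivative of the series above
    out[small] <- (l * xs^pmax(l - 1, 0) -
                     (l + 2) * xs^(l + 1) / (2 * (2 * l + 3))) / dfact
  }
  out
}

#' Positive zeros of spherical Bessel functions
#'
#' Computes the first `n_roots` positive zeros \eqn{u_{l,n}} of \eqn{j_l} for
#' every `l` from 0 to `l_max`, by bracketed root finding: the zeros of
#' \eqn{j_0} are exactly \eqn{n\pi}, and the zeros of consecutive orders
#' interlace, providing guaranteed brackets for `uniroot`.
#'
#' @param l_max Maximum order.
#' @param n_roots Number of zeros per order.
#' @return Numeric matrix of dimension `(l_max + 1) x n_roots`; row `l + 1`
#'   holds the zeros of \eqn{j_l} in increasing order.
#' @export
spherical_bessel_zeros <- function(l_max, n_roots) {
  ## interlacing consumes one root per step up in l
  n_need <- n_roots + l_max
  roots <- matrix(NA_real_, l_max + 1L, n_need)
  roots[1L, ] <- pi * seq_len(n_need)
  if (l_max >= 1L) {
    for (l in seq_len(l_max)) {
      f <- function(x) spherical_bessel_j(l, x)
      for (k in seq_len(n_need - l)) {
        lo <- roots[l, k]
        hi <- roots[l, k + 1L]
        flo <- f(lo)
        fhi <- f(hi)
        if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
          stop(sprintf("root bracketing failed for (l = %d, n = %d)", l, k - 1L))
        }
        roots[l + 1L, k] <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
      }
    }
  }
  roots[, seq_len(n_roots), drop = FALSE]
}

## Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem.
gauss_legendre <- function(n, a = -1, b = 1) {
  k <- seq_len(n - 1L)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- beta
  J[cbind(k + 1L, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- rev(2 * e$vectors[1L, ]^2)
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

## Column index of the (n, l) radial function inside the length-n_B block,
## with functions ordered by n, then l (0 <= l <= n <= n_max).
nl_index <- function(n, l) n * (n + 1L) / 2L + l + 1L

#' Build the orthonormal radial basis
#'
#' Constructs the coefficient table expressing every radial function
#' \eqn{g_{nl}} (for \eqn{0 \le l \le n \le n_{max}}) as a linear combination
#' of spherical Bessel profiles \eqn{j_l(u_{l,k} r / r_{cut})}. Each primitive
#' combines two consecutive zeros so that value, slope and curvature vanish at
#' the cutoff; primitives sharing an `l` are then orthonormalized with respect
#' to \eqn{\int_0^{r_{cut}} f g \, r^2 dr}.
#'
#' @param n_max Nonnegative integer; controls the number of radial functions,
#'   \eqn{n_B = (n_{max}+1)(n_{max}+2)/2}.
#' @param r_cut Cutoff radius in Angstrom.
#' @param n_quad Number of Gauss-Legendre nodes used for the Gram matrices.
#' @return An object of class `radial_basis` with fields `n_max`, `r_cut`,
#'   `n_B`, `roots` (the \eqn{u_{l,n}} table) and `coef` (per-`l` coefficient
#'   matrices over the Bessel profiles).
#' @examples
#' basis <- build_radial_basis(2, 3.5)
#' @export
build_radial_basis <- function(n_max, r_cut, n_quad = 200L) {
  if (n_max < 0L) stop("n_max must be >= 0")
  if (r_cut <= 0) stop("r_cut must be positive")
  n_max <- as.integer(n_max)
  roots <- spherical_bessel_zeros(n_max, n_max + 2L)
  quad <- gauss_legendre(n_quad, 0, r_cut)
  coef <- vector("list", n_max + 1L)
  for (l in 0:n_max) {
    ns <- l:n_max                     # radial indices available at this l
    u <- roots[l + 1L, ]
    ## primitive n: a * j_l(u_n r / rc) + b * j_l(u_{n+1} r / rc),
    ## slope at rc proportional to a u_n j_l'(u_n) + b u_{n+1} j_l'(u_{n+1})
    prim <- matrix(0, length(ns), n_max + 2L)
    vals <- matrix(0, length(quad$nodes), length(ns))
    for (i in seq_along(ns)) {
      n <- ns[i]
      u1 <- u[n + 1L]
      u2 <- u[n + 2L]
      s1 <- u1 * spherical_bessel_j_prime(l, u1)
      s2 <- u2 * spherical_bessel_j_prime(l, u2)
      a <- s2
      b <- -s1
      f <- a * spherical_bessel_j(l, u1 * quad$nodes / r_cut) +
        b * spherical_bessel_j(l, u2 * quad$nodes / r_cut)
      nrm <- sqrt(sum(quad$weights * f^2 * quad$nodes^2))
      prim[i, n + 1L] <- a / nrm
      prim[i, n + 2L] <- b / nrm
      vals[, i] <- f / nrm
    }
    gram <- crossprod(vals * sqrt(quad$weights) * quad$nodes)
    ## gram = U' U; the Gram-Schmidt map is L^{-1} with L = U' (lower
    ## triangular, so g_n only mixes primitives up to index n)
    Linv <- backsolve(chol(gram), diag(length(ns)), transpose = TRUE)
    coef[[l + 1L]] <- Linv %*% prim      # row i: g_{ns[i], l} over profiles
  }
  structure(list(version = 1L, n_max = n_max, r_cut = r_cut,
                 n_B = (n_max + 1L) * (n_max + 2L) / 2L,
                 roots = roots, coef = coef),
            class = "radial_basis")
}

#' Evaluate the radial basis functions
#'
#' @param basis A [build_radial_basis()] object.
#' @param r Numeric vector of radii (Angstrom). Values at or beyond the cutoff
#'   evaluate to exactly zero.
#' @param derivative If `TRUE`, also return first derivatives.
#' @return A list with `value`: a `length(r) x n_B` matrix whose columns
#'   follow the canonical (n, l) ordering (n outer, l inner), and, when
#'   requested, `deriv` of the same shape.
#' @export
radial_basis_eval <- function(basis, r, derivative = FALSE) {
  r <- as.numeric(r)
  nr <- length(r)
  n_max <- basis$n_max
  val <- matrix(0, nr, basis$n_B)
  der <- if (derivative) matrix(0, nr, basis$n_B) else NULL
  inside <- which(r < basis$r_cut & r >= 0)
  if (length(inside)) {
    ri <- r[inside]
    for (l in 0:n_max) {
      u <- basis$roots[l + 1L, ]
      x <- outer(ri, u / basis$r_cut)        # |inside| x (n_max + 2)
      jl <- matrix(spherical_bessel_j(l, x), nrow = length(ri))
      C <- basis$coef[[l + 1L]]
      g <- jl %*% t(C)
      ns <- l:n_max
      cols <- nl_index(ns, l)
      val[inside, cols] <- g
      if (derivative) {
        jlp <- matrix(spherical_bessel_j_prime(l, x), nrow = length(ri))
        jlp <- sweep(jlp, 2L, u / basis$r_cut, `*`)
        der[inside, cols] <- jlp %*% t(C)
      }
    }
  }
  if (derivative) list(value = val, deriv = der) else list(value = val)
}

#' Serialize a radial basis to a versioned JSON sidecar
#'
#' The stored coefficient table and root table reproduce the basis exactly,
#' so models referencing it are reproducible without re-running the
#' orthogonalization.
#'
#' @param basis A `radial_basis` object.
#' @param path Output file path.
#' @export
write_radial_basis <- function(basis, path) {
  obj <- list(format = "besselff-radial-basis", version = basis$version,
              n_max = basis$n_max, r_cut = basis$r_cut, n_B = basis$n_B,
              roots = basis$roots, coef = basis$coef)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized radial basis
#'
#' @param path Path written by [write_radial_basis()].
#' @return A `radial_basis` object.
#' @export
read_radial_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "besselff-radial-basis")) {
    stop("not a radial-basis file: ", path)
  }
  structure(list(version = as.integer(obj$version),
                 n_max = as.integer(obj$n_max),
                 r_cut = as.numeric(obj$r_cut),
                 n_B = as.integer(obj$n_B),
                 roots = matrix(as.numeric(obj$roots), nrow = obj$n_max + 1L),
                 coef = lapply(obj$coef, function(m)
                   matrix(as.numeric(m), ncol = obj$n_max + 2L))),
            class = "radial_basis")
}
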