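## Element-pair spherical Bessel descriptors.
##
## For every atom i, the neighbor density of each element J inside the cutoff
## sphere is projected on the radial basis g_nl and on spherical harmonics,
## and rotational invariance is enforced by contracting over the harmonic
## index m. The contraction is evaluated in its purely real Legendre form,
##
##   p_iJJ'nl = sum_{j in J} sum_{j' in J'} g_nl(r_ij) g_nl(r_ij')
##              P_l(cos gamma_ijj'),
##
## where gamma_ijj' is the angle subtended at atom i. Angular normalization
## convention: with complex projections c_iJnlm on basis functions
## g_nl(r) Y_lm(rhat), the addition theorem gives
## p_iJJ'nl = (4 pi / (2l + 1)) sum_m c_iJnlm conj(c_iJ'nlm); the package
## stores the Legendre form, i.e. the sum over m times 4 pi / (2l + 1).
## The central atom is excluded from its own density (j != i).

#' Specify a descriptor set
#'
#' @param r_cut Cutoff radius in Angstrom.
#' @param n_max Maximum radial index (the number of radial functions is
#'   `n_B = (n_max + 1) * (n_max + 2) / 2`).
#' @param elements Ordered character vector of the element symbols covered by
#'   the model; the order fixes the element-pair enumeration and therefore
#'   the descriptor layout.
#' @param n_emb Width of the per-species embedding vector concatenated with
#'   the descriptors at the network input (default 2).
#' @return An object of class `descriptor_spec`.
#' @examples
#' spec <- descriptor_spec(3.5, 4, c("C", "H", "N", "O"))
#' descriptor_dimension(spec)  # 150
#' @export
descriptor_spec <- function(r_cut, n_max, elements, n_emb = 2L) {
  if (r_cut <= 0) stop("r_cut must be positive")
  if (n_max < 0) stop("n_max must be >= 0")
  elements <- as.character(elements)
  if (anyDuplicated(elements)) stop("elements must be distinct")
  if (n_emb < 0) stop("n_emb must be >= 0")
  n_el <- length(elements)
  structure(list(r_cut = r_cut, n_max = as.integer(n_max),
                 elements = elements, n_el = n_el,
                 n_emb = as.integer(n_emb),
                 n_B = (n_max + 1L) * (n_max + 2L) / 2L),
            class = "descriptor_spec")
}

#' Number of descriptors per atom
#'
#' Evaluates \eqn{n_p = n_B \, n_{el}(n_{el}+1)/2} with
#' \eqn{n_B = (n_{max}+1)(n_{max}+2)/2}.
#'
#' @param spec A [descriptor_spec()].
#' @return Integer descriptor count per atom.
#' @export
descriptor_dimension <- function(spec) {
  as.integer(spec$n_B * spec$n_el * (spec$n_el + 1L) / 2L)
}

## Pair enumeration with J <= J' in the order of spec$elements:
## (1,1), (1,2), ..., (1,n), (2,2), ... Returns an n_el x n_el matrix of pair
## indices (symmetric).
pair_index_matrix <- function(n_el) {
  m <- matrix(0L, n_el, n_el)
  q <- 0L
  for (J in seq_len(n_el)) {
    for (Jp in J:n_el) {
      q <- q + 1L
      m[J, Jp] <- q
      m[Jp, J] <- q
    }
  }
  m
}

## Legendre polynomials P_0..P_lmax (and optionally derivatives) of a matrix
## argument, via the Bonnet recurrence.
legendre_values <- function(x, l_max, derivative = FALSE) {
  P <- vector("list", l_max + 1L)
  P[[1L]] <- array(1, dim = dim(x) %||% length(x))
  if (l_max >= 1L) P[[2L]] <- x
  if (l_max >= 2L) {
    for (l in 2:l_max) {
      P[[l + 1L]] <- ((2 * l - 1) * x * P[[l]] - (l - 1) * P[[l - 1L]]) / l
    }
  }
  out <- list(P = P)
  if (derivative) {
    dP <- vector("list", l_max + 1L)
    dP[[1L]] <- array(0, dim = dim(x) %||% length(x))
    if (l_max >= 1L) dP[[2L]] <- array(1, dim = dim(x) %||% length(x))
    if (l_max >= 2L) {
      for (l in 2:l_max) {
        dP[[l + 1L]] <- dP[[l - 1L]] + (2 * l - 1) * P[[l]]
      }
    }
    out$dP <- dP
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Per-atom geometric workspace shared by the descriptor value, pullback and
## Jacobian-vector-product code paths. For each atom: radial function values
## (and derivatives) at the neighbor distances, neighbor unit vectors, the
## cosine matrix and Legendre values.
descriptor_workspace <- function(config, spec, basis, derivatives = FALSE) {
  if (!inherits(spec, "descriptor_spec")) stop("spec must be a descriptor_spec")
  if (basis$n_max != spec$n_max || abs(basis$r_cut - spec$r_cut) > 1e-12) {
    stop("radial basis does not match the descriptor spec")
  }
  s_idx <- match(config$species, spec$elements)
  if (anyNA(s_idx)) {
    stop("species outside the descriptor element table: ",
         paste(unique(config$species[is.na(s_idx)]), collapse = ", "))
  }
  nt <- build_neighbor_table(config, spec$r_cut)
  atoms <- vector("list", n_atoms(config))
  for (i in seq_along(atoms)) {
    nb <- nt[[i]]
    nn <- length(nb$index)
    if (nn == 0L) {
      atoms[[i]] <- list(n = 0L)
      next
    }
    rb <- radial_basis_eval(basis, nb$dist, derivative = derivatives)
    U <- nb$disp / nb$dist
    C <- U %*% t(U)
    C[C > 1] <- 1
    C[C < -1] <- -1
    leg <- legendre_values(C, spec$n_max, derivative = derivatives)
    atoms[[i]] <- list(n = nn, index = nb$index, dist = nb$dist, U = U,
                       C = C, G = rb$value, dG = rb$deriv,
                       P = leg$P, dP = leg$dP,
                       spec_idx = s_idx[nb$index])
  }
  list(atoms = atoms, s_idx = s_idx, spec = spec,
       pair_mat = pair_index_matrix(spec$n_el))
}

## (n, l) pairs in canonical order together with their flattened l index.
nl_table <- function(n_max) {
  n <- rep.int(0:n_max, 0:n_max + 1L)
  l <- unlist(lapply(0:n_max, seq, from = 0L), use.names = FALSE)
  cbind(n = n, l = l)
}

#' Compute element-pair spherical Bessel descriptors
#'
#' Maps a configuration to its `n_atoms x n_p` descriptor array. Columns are
#' ordered by element pair (J <= J' in the order of `spec$elements`), then
#' radial index n, then angular index l; this flattening is part of the model
#' and file contract. Descriptors are invariant under rigid motions and under
#' relabeling of same-species atoms, and an atom without neighbors has an
#' all-zero row.
#'
#' @param config An [atomic_configuration()].
#' @param spec A [descriptor_spec()]; must cover all species present.
#' @param basis The matching [build_radial_basis()] object.
#' @return A numeric matrix of dimension `n_atoms x n_p` with the spec
#'   attached as attribute `spec`.
#' @export
compute_descriptors <- function(config, spec, basis) {
  ws <- descriptor_workspace(config, spec, basis, derivatives = FALSE)
  descriptors_from_workspace(ws)
}

descriptors_from_workspace <- function(ws) {
  spec <- ws$spec
  n_el <- spec$n_el
  n_B <- spec$n_B
  n_p <- descriptor_dimension(spec)
  nl <- nl_table(spec$n_max)
  vals <- matrix(0, length(ws$atoms), n_p)
  upper <- which(upper.tri(matrix(0, n_el, n_el), diag = TRUE))
  pair_cols <- ws$pair_mat[upper]          # pair index of each (J, J'), J <= J'
  for (i in seq_along(ws$atoms)) {
    at <- ws$atoms[[i]]
    if (at$n == 0L) next
    Gs <- matrix(0, at$n, n_el)
    idx <- cbind(seq_len(at$n), at$spec_idx)
    for (k in seq_len(n_B)) {
      Gs[] <- 0
      Gs[idx] <- at$G[, k]
      S <- crossprod(Gs, at$P[[nl[k, "l"] + 1L]] %*% Gs)
      vals[i, (pair_cols - 1L) * n_B + k] <- S[upper]
    }
  }
  attr(vals, "spec") <- spec
  vals
}

## Symmetrized per-(n,l) weight table: the contraction
## sum_alpha w_alpha p_alpha must equal
## sum_{n,l} sum_{j,j'} G_j G_j' What[s_j, s_j'] P_l(C_jj') with off-diagonal
## entries halved, because p_{JJ'} (J != J') already holds the full ordered
## double sum.
cotangent_tables <- function(w_atom, spec) {
  n_el <- spec$n_el
  n_B <- spec$n_B
  n_pairs <- n_el * (n_el + 1L) / 2L
  Wq <- matrix(w_atom, nrow = n_B)         # n_B x n_pairs (pair is the outer index)
  out <- vector("list", n_B)
  upper <- which(upper.tri(matrix(0, n_el, n_el), diag = TRUE))
  pair_of_upper <- pair_index_matrix(n_el)[upper]
  for (k in seq_len(n_B)) {
    M <- matrix(0, n_el, n_el)
    M[upper] <- Wq[k, pair_of_upper]
    M <- (M + t(M)) / 2                    # halves off-diagonal, keeps diagonal
    out[[k]] <- M
  }
  out
}

#' Vector-Jacobian product operator for the descriptors
#'
#' Returns an operator that contracts a cotangent (sensitivities with respect
#' to every descriptor of every atom, e.g. the network gradient
#' \eqn{\partial E / \partial p_\alpha}) with the descriptor Jacobian,
#' yielding one 3-vector per atom, without ever materializing the full
#' Jacobian. This is the backbone of the force evaluation: the forces are
#' minus the returned gradient.
#'
#' @param config,spec,basis As in [compute_descriptors()].
#' @return A function `(cotangent) -> n_atoms x 3 matrix`, where `cotangent`
#'   is an `n_atoms x n_p` matrix (or a vector of that length, atom-major).
#'   The result is \eqn{\sum_\alpha w_\alpha \, \partial p_\alpha /
#'   \partial r_i}.
#' @export
descriptor_pullback <- function(config, spec, basis) {
  ws <- descriptor_workspace(config, spec, basis, derivatives = TRUE)
  function(cotangent) pullback_apply(ws, cotangent)
}

pullback_apply <- function(ws, cotangent) {
  spec <- ws$spec
  n_p <- descriptor_dimension(spec)
  na <- length(ws$atoms)
  if (is.matrix(cotangent)) {
    if (!all(dim(cotangent) == c(na, n_p))) {
      stop("cotangent must be n_atoms x n_p (", na, " x ", n_p, ")")
    }
  } else {
    if (length(cotangent) != na * n_p) stop("cotangent length mismatch")
    cotangent <- matrix(cotangent, na, n_p, byrow = TRUE)
  }
  nl <- nl_table(spec$n_max)
  n_B <- spec$n_B
  grad <- matrix(0, na, 3L)
  for (i in seq_len(na)) {
    at <- ws$atoms[[i]]
    if (at$n == 0L) next
    What <- cotangent_tables(cotangent[i, ], spec)
    sidx <- at$spec_idx
    alpha <- numeric(at$n)                 # radial coefficients
    Etot <- matrix(0, at$n, at$n)          # angular coefficients
    for (k in seq_len(n_B)) {
      A <- What[[k]][sidx, sidx, drop = FALSE]
      if (all(A == 0)) next
      l <- nl[k, "l"]
      gk <- at$G[, k]
      AP <- A * at$P[[l + 1L]]
      alpha <- alpha + 2 * at$dG[, k] * as.numeric(AP %*% gk)
      Etot <- Etot + (A * at$dP[[l + 1L]]) * (gk %o% gk)
    }
    m <- Etot %*% at$U
    q <- rowSums(Etot * at$C)
    g_nbr <- alpha * at$U + (2 / at$dist) * (m - q * at$U)
    ## accumulate on neighbors and (with opposite sign) on the central atom
    for (jj in seq_len(at$n)) {
      grad[at$index[jj], ] <- grad[at$index[jj], ] + g_nbr[jj, ]
    }
    grad[i, ] <- grad[i, ] - colSums(g_nbr)
  }
  grad
}

## Directional derivative of every descriptor along a displacement field
## (the Jacobian-vector product dual to pullback_apply).
descriptor_jvp <- function(ws, displacement) {
  spec <- ws$spec
  n_el <- spec$n_el
  n_B <- spec$n_B
  n_p <- descriptor_dimension(spec)
  nl <- nl_table(spec$n_max)
  na <- length(ws$atoms)
  displacement <- matrix(displacement, na, 3L)
  out <- matrix(0, na, n_p)
  upper <- which(upper.tri(matrix(0, n_el, n_el), diag = TRUE))
  pair_cols <- ws$pair_mat[upper]
  for (i in seq_len(na)) {
    at <- ws$atoms[[i]]
    if (at$n == 0L) next
    V <- displacement[at$index, , drop = FALSE] -
      matrix(displacement[i, ], at$n, 3L, byrow = TRUE)
    a <- rowSums(V * at$U) / at$dist
    B <- (V %*% t(at$U)) / at$dist
    Cdot <- B + t(B) - at$C * outer(a, a, `+`)
    rdot <- rowSums(V * at$U)              # d r_ij / dt along the field
    idx <- cbind(seq_len(at$n), at$spec_idx)
    Gs <- matrix(0, at$n, n_el)
    Gds <- matrix(0, at$n, n_el)
    for (k in seq_len(n_B)) {
      l <- nl[k, "l"]
      Gs[] <- 0; Gds[] <- 0
      Gs[idx] <- at$G[, k]
      Gds[idx] <- at$dG[, k] * rdot
      P <- at$P[[l + 1L]]
      S <- crossprod(Gds, P %*% Gs)
      S <- S + t(S)
      S <- S + crossprod(Gs, (at$dP[[l + 1L]] * Cdot) %*% Gs)
      out[i, (pair_cols - 1L) * n_B + k] <- S[upper]
    }
  }
  out
}

#' Dense descriptor Jacobian (small systems)
#'
#' Materializes \eqn{\partial p_\alpha / \partial r_{kc}} as an
#' `(n_atoms * n_p) x (n_atoms * 3)` matrix, assembled from the per-atom
#' analytic derivative blocks. Intended for few-atom systems and for
#' precomputing fixed per-frame Jacobians during training; use
#' [descriptor_pullback()] for large systems.
#'
#' @param config,spec,basis As in [compute_descriptors()].
#' @return Numeric matrix; rows are atom-major descriptor indices
#'   (`alpha = (i - 1) * n_p + feature`), columns atom-major Cartesian
#'   components.
#' @export
descriptor_jacobian <- function(config, spec, basis) {
  ws <- descriptor_workspace(config, spec, basis, derivatives = TRUE)
  na <- length(ws$atoms)
  n_el <- spec$n_el
  n_B <- spec$n_B
  n_p <- descriptor_dimension(spec)
  nl <- nl_table(spec$n_max)
  J <- matrix(0, na * n_p, na * 3L)
  for (i in seq_len(na)) {
    at <- ws$atoms[[i]]
    if (at$n == 0L) next
    nn <- at$n
    sidx <- at$spec_idx
    idx <- cbind(seq_len(nn), sidx)
    Gs <- matrix(0, nn, n_el)
    ## local derivative blocks: d p_i(feature) / d r_neighbor
    B <- array(0, c(n_p, nn, 3L))
    for (k in seq_len(n_B)) {
      l <- nl[k, "l"]
      Gs[] <- 0
      Gs[idx] <- at$G[, k]
      P <- at$P[[l + 1L]]
      dP <- at$dP[[l + 1L]]
      T_ <- P %*% Gs                       # sum_{j' in J'} G_j' P_l
      M2 <- (dP * at$C) %*% Gs
      M1 <- lapply(1:3, function(c) dP %*% (Gs * at$U[, c]))
      for (Jp in seq_len(n_el)) {
        q <- ws$pair_mat[cbind(sidx, Jp)]  # pair of (species_j, J') per row
        mult <- ifelse(sidx == Jp, 2, 1)
        cols <- (q - 1L) * n_B + k
        for (c in 1:3) {
          val <- mult * (at$dG[, k] * at$U[, c] * T_[, Jp] +
                           at$G[, k] * (M1[[c]][, Jp] -
                                          M2[, Jp] * at$U[, c]) / at$dist)
          B[cbind(cols, seq_len(nn), c)] <-
            B[cbind(cols, seq_len(nn), c)] + val
        }
      }
    }
    rows <- (i - 1L) * n_p + seq_len(n_p)
    for (jj in seq_len(nn)) {
      cols <- (at$index[jj] - 1L) * 3L + 1:3
      J[rows, cols] <- J[rows, cols] + B[, jj, ]
    }
    J[rows, (i - 1L) * 3L + 1:3] <- J[rows, (i - 1L) * 3L + 1:3] -
      apply(B, c(1L, 3L), sum)
  }
  J
}

#' Fixed element-pair weight tables
#'
#' Builds the symmetric weight tables \eqn{\omega_{JJ'}} used by the premixed
#' (weighted-density) descriptor variants: products of Pauling
#' electronegativities or of atomic numbers.
#'
#' @param elements Ordered character vector of element symbols.
#' @param kind `"electronegativity"` (\eqn{\omega = \chi \chi^T}) or
#'   `"atomic_number"` (\eqn{\omega = Z Z^T}).
#' @return Symmetric `n_el x n_el` numeric matrix.
#' @export
element_weight_table <- function(elements,
                                 kind = c("electronegativity",
                                          "atomic_number")) {
  kind <- match.arg(kind)
  w <- switch(kind,
              electronegativity = element_property(elements, "electronegativity"),
              atomic_number = element_property(elements, "number"))
  outer(w, w)
}

#' Premixed (weighted-density) descriptors
#'
#' Contracts the element-pair-resolved descriptors with a symmetric weight
#' table \eqn{\omega_{JJ'}}, producing `n_B` descriptors per atom:
#' \eqn{\tilde p_{inl} = \sum_{J,J'} \omega_{JJ'} \, p_{iJJ'nl}} (double sum
#' over ordered pairs). The weights may depend on the species of the central
#' atom by passing a 3-d array whose slice `[, , k]` is the table used for
#' central element `k`.
#'
#' @param config,spec,basis As in [compute_descriptors()].
#' @param weights Symmetric `n_el x n_el` matrix (e.g. from
#'   [element_weight_table()]) or an `n_el x n_el x n_el` array of per-central
#'   -element symmetric tables.
#' @return An `n_atoms x n_B` matrix.
#' @export
compute_weighted_descriptors <- function(config, spec, basis, weights) {
  p <- compute_descriptors(config, spec, basis)
  weighted_from_descriptors(p, spec, weights,
                            match(config$species, spec$elements))
}

weighted_from_descriptors <- function(p, spec, weights, s_idx) {
  n_el <- spec$n_el
  n_B <- spec$n_B
  per_central <- length(dim(weights)) == 3L
  check_sym <- function(w) {
    if (!all(dim(w) == c(n_el, n_el))) stop("weight table must be n_el x n_el")
    if (max(abs(w - t(w))) > 1e-12) stop("weight table must be symmetric")
    if (!all(is.finite(w))) stop("weight table must be finite")
  }
  pm <- pair_index_matrix(n_el)
  upper <- which(upper.tri(matrix(0, n_el, n_el), diag = TRUE))
  mult <- ifelse(row(pm)[upper] == col(pm)[upper], 1, 2)
  contract <- function(w) {
    cw <- w[upper] * mult                  # ordered-double-sum multiplicity
    out <- matrix(0, nrow(p), n_B)
    for (q in seq_along(cw)) {
      out <- out + cw[q] * p[, (q - 1L) * n_B + seq_len(n_B), drop = FALSE]
    }
    out
  }
  if (!per_central) {
    check_sym(weights)
    contract(weights)
  } else {
    for (k in seq_len(n_el)) check_sym(weights[, , k])
    out <- matrix(0, nrow(p), n_B)
    for (k in seq_len(n_el)) {
      rows <- which(s_idx == k)
      if (length(rows)) out[rows, ] <- contract(weights[, , k])[rows, ]
    }
    out
  }
}
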