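## Additive atomic-energy model: each atom's descriptors, concatenated with a
## learned per-species embedding row, pass through a multilayer perceptron
## (default hidden widths 64:32:16:16:16, Swish-1, per-sample normalization
## between hidden layers, final linear layer); the total potential energy is
## the sum of the atomic outputs plus a constant offset.

#' Initialize model parameters
#'
#' Weights are drawn from a zero-mean Gaussian with standard deviation
#' \eqn{1/\sqrt{fan_{in}}}, biases start at zero, and embedding rows are
#' small random values (sd 0.1). Deterministic given `seed`; the caller's RNG
#' stream is left untouched.
#'
#' @param spec A [descriptor_spec()]; fixes the input width
#'   `n_p + spec$n_emb` and the number of embedding rows.
#' @param widths Hidden-layer widths (default `c(64, 32, 16, 16, 16)`).
#' @param seed Integer seed.
#' @param activation `"swish1"` (default; smooth) or `"selu"` (the
#'   self-normalizing variant, used without per-sample normalization).
#' @param layernorm Whether to normalize between hidden layers; defaults to
#'   `TRUE` for Swish-1 and `FALSE` for SELU.
#' @param premix_weights Optional symmetric weight table (or per-central
#'   -element array, see [compute_weighted_descriptors()]); when set, the
#'   model consumes the premixed `n_B`-wide descriptors instead of the full
#'   element-pair-resolved ones.
#' @return An object of class `model_params`.
#' @export
init_params <- function(spec, widths = c(64L, 32L, 16L, 16L, 16L), seed = 1L,
                        activation = c("swish1", "selu"),
                        layernorm = NULL, premix_weights = NULL) {
  activation <- match.arg(activation)
  if (is.null(layernorm)) layernorm <- activation == "swish1"
  n_feat <- if (is.null(premix_weights)) descriptor_dimension(spec) else spec$n_B
  d_in <- n_feat + spec$n_emb
  with_seed(seed, {
    layers <- init_layers(d_in, widths, 1L)
    embedding <- matrix(stats::rnorm(spec$n_el * spec$n_emb, sd = 0.1),
                        spec$n_el, spec$n_emb)
  })
  structure(list(version = 1L, spec = spec, widths = as.integer(widths),
                 activation = activation, layernorm = layernorm,
                 embedding = embedding, layers = layers, offset = 0,
                 standardize = NULL, premix_weights = premix_weights,
                 n_feat = n_feat),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> input ", x$n_feat, "+", x$spec$n_emb, " -> ",
      paste(x$widths, collapse = ":"), ":1 (", x$activation,
      if (x$layernorm) ", layernorm" else "", "), offset ",
      signif(x$offset, 6), " eV\n", sep = "")
  invisible(x)
}

## Model feature matrix for a set of atoms: standardized descriptors
## concatenated with the embedding rows of their species.
model_input <- function(params, descr, species_idx) {
  feats <- descr
  if (!is.null(params$standardize)) {
    feats <- sweep(feats, 2L, params$standardize$shift)
    feats <- sweep(feats, 2L, params$standardize$scale, `/`)
  }
  if (params$spec$n_emb > 0L) {
    cbind(feats, params$embedding[species_idx, , drop = FALSE])
  } else {
    feats
  }
}

## Descriptor features the model consumes for a workspace (premixed when the
## model carries a weight table).
model_features <- function(params, ws) {
  p <- descriptors_from_workspace(ws)
  if (is.null(params$premix_weights)) return(p)
  weighted_from_descriptors(p, params$spec, params$premix_weights, ws$s_idx)
}

## Expand a cotangent on premixed features back to the full element-pair
## descriptor layout (the premix is linear with fixed weights).
expand_premix_cotangent <- function(G_premix, params, s_idx) {
  spec <- params$spec
  n_el <- spec$n_el
  n_B <- spec$n_B
  pm <- pair_index_matrix(n_el)
  upper <- which(upper.tri(matrix(0, n_el, n_el), diag = TRUE))
  mult <- ifelse(row(pm)[upper] == col(pm)[upper], 1, 2)
  w <- params$premix_weights
  per_central <- length(dim(w)) == 3L
  out <- matrix(0, nrow(G_premix), descriptor_dimension(spec))
  for (q in seq_along(upper)) {
    cols <- (q - 1L) * n_B + seq_len(n_B)
    if (!per_central) {
      out[, cols] <- G_premix * (w[upper[q]] * mult[q])
    } else {
      wq <- w[cbind(rep(row(pm)[upper[q]], length(s_idx)),
                    rep(col(pm)[upper[q]], length(s_idx)), s_idx)]
      out[, cols] <- G_premix * (wq * mult[q])
    }
  }
  out
}

#' Per-atom energies from descriptors
#'
#' Applies the atomic-energy network to each atom's feature vector. Identical
#' inputs give identical outputs; the energies do not include the global
#' offset.
#'
#' @param descr Descriptor matrix (`n_atoms x n_p`, or `n_atoms x n_B` for a
#'   premixed model) as produced by [compute_descriptors()].
#' @param species Atom species: element symbols or indices into
#'   `params$spec$elements`.
#' @param params A [init_params()] object.
#' @return Numeric vector of atomic energies (eV).
#' @export
atomic_energies <- function(descr, species, params) {
  descr <- as.matrix(descr)
  if (ncol(descr) != params$n_feat) {
    stop("descriptor width ", ncol(descr), " does not match the model input (",
         params$n_feat, " features + ", params$spec$n_emb, " embedding)")
  }
  if (is.character(species)) {
    species <- match(species, params$spec$elements)
    if (anyNA(species)) stop("species outside the model element table")
  }
  X <- model_input(params, descr, species)
  mlp_forward(params$layers, X, params$activation, params$layernorm)$out
}

#' Total potential energy of a configuration
#'
#' \eqn{E_{pot} = \sum_i \Omega(p_i, e_i) + E_0}: the sum of the additive
#' atomic contributions plus the constant offset. Invariant under rigid
#' motions and under permutations of same-species atoms.
#'
#' @param config An [atomic_configuration()].
#' @param spec,basis Descriptor specification and matching radial basis.
#' @param params Model parameters.
#' @return Potential energy in eV.
#' @export
total_energy <- function(config, spec, basis, params) {
  ws <- descriptor_workspace(config, spec, basis, derivatives = FALSE)
  feats <- model_features(params, ws)
  sum(atomic_energies(feats, ws$s_idx, params)) + params$offset
}

#' Energy and exact forces
#'
#' Computes the potential energy together with
#' \eqn{F_i = -\partial E_{pot}/\partial r_i}, obtained by contracting the
#' network gradient \eqn{\partial E/\partial p_\alpha} with the descriptor
#' vector-Jacobian product; the dense descriptor Jacobian is never formed, so
#' the cost stays within a small constant factor of one energy evaluation.
#'
#' @inheritParams total_energy
#' @return A list with `energy` (eV) and `forces` (`n_atoms x 3`, eV/Angstrom).
#' @export
energy_and_forces <- function(config, spec, basis, params) {
  ws <- descriptor_workspace(config, spec, basis, derivatives = TRUE)
  feats <- model_features(params, ws)
  X <- model_input(params, feats, ws$s_idx)
  vg <- mlp_value_and_grad(params$layers, X, activation = params$activation,
                           layernorm = params$layernorm)
  G <- vg$dX[, seq_len(params$n_feat), drop = FALSE]
  if (!is.null(params$standardize)) {
    G <- sweep(G, 2L, params$standardize$scale, `/`)
  }
  if (!is.null(params$premix_weights)) {
    G <- expand_premix_cotangent(G, params, ws$s_idx)
  }
  list(energy = sum(vg$out) + params$offset,
       forces = -pullback_apply(ws, G))
}

#' Forces on every atom
#'
#' @inheritParams total_energy
#' @return `n_atoms x 3` matrix of forces in eV/Angstrom.
#' @export
forces <- function(config, spec, basis, params) {
  energy_and_forces(config, spec, basis, params)$forces
}

#' Initialize deep-sets parameters
#'
#' The deep-sets generalization replaces the additive ansatz by
#' \eqn{E = \mu(\sum_i \Omega(p_i, e_i))}: an encoder network maps each
#' atom's features to a 16-wide latent vector, the latent vectors are summed
#' over atoms (which enforces permutation invariance), and a decoder network
#' (widths 32:32:32:1) maps the pooled latent to the total energy.
#'
#' @param spec A [descriptor_spec()].
#' @param encoder_widths Hidden widths of the encoder; its output width (the
#'   latent dimension) is the last entry.
#' @param decoder_widths Hidden widths of the decoder.
#' @param seed Integer seed.
#' @param activation,layernorm As in [init_params()].
#' @param final_linear If `TRUE`, the last encoder layer is a plain linear
#'   map (no normalization or activation); with a width-1 latent and a `NULL`
#'   decoder this reproduces the additive ansatz exactly. The default
#'   (`FALSE`) activates every encoder layer, so the latent is the last
#'   activated hidden layer.
#' @return An object of class `deep_sets_params`.
#' @export
init_deep_sets_params <- function(spec,
                                  encoder_widths = c(64L, 32L, 16L, 16L, 16L),
                                  decoder_widths = c(32L, 32L, 32L),
                                  seed = 1L, activation = "swish1",
                                  layernorm = TRUE, final_linear = FALSE) {
  d_in <- descriptor_dimension(spec) + spec$n_emb
  latent <- encoder_widths[length(encoder_widths)]
  with_seed(seed, {
    ## encoder: hidden stack whose last activation IS the latent output, so
    ## build hidden widths minus the last, with a "final" layer of the latent
    ## width that we activate manually.
    enc <- init_layers(d_in, encoder_widths[-length(encoder_widths)], latent)
    dec <- init_layers(latent, decoder_widths, 1L)
    embedding <- matrix(stats::rnorm(spec$n_el * spec$n_emb, sd = 0.1),
                        spec$n_el, spec$n_emb)
  })
  structure(list(version = 1L, spec = spec, encoder = enc, decoder = dec,
                 latent = latent, embedding = embedding,
                 activation = activation, layernorm = layernorm, offset = 0,
                 standardize = NULL, final_linear = final_linear),
            class = "deep_sets_params")
}

## Encoder forward: every layer normalized + activated, except that the last
## layer stays linear when final_linear is set.
deep_sets_encode <- function(params, X) {
  act <- .activation(params$activation)
  H <- X
  n_layers <- length(params$encoder)
  for (k in seq_len(n_layers)) {
    L <- params$encoder[[k]]
    Z <- H %*% t(L$W)
    Z <- sweep(Z, 2L, L$b, `+`)
    if (k == n_layers && isTRUE(params$final_linear)) {
      H <- Z
    } else {
      if (params$layernorm) Z <- layernorm_rows(Z)$Y
      H <- act$f(Z)
    }
  }
  H
}

#' Deep-sets total energy
#'
#' @param config An [atomic_configuration()].
#' @param spec,basis As in [total_energy()].
#' @param params An [init_deep_sets_params()] object. A `NULL` decoder is
#'   treated as the identity map, which on a width-1 latent reduces the model
#'   to the additive ansatz.
#' @return Potential energy in eV.
#' @export
deep_sets_energy <- function(config, spec, basis, params) {
  ws <- descriptor_workspace(config, spec, basis, derivatives = FALSE)
  p <- descriptors_from_workspace(ws)
  feats <- p
  if (!is.null(params$standardize)) {
    feats <- sweep(feats, 2L, params$standardize$shift)
    feats <- sweep(feats, 2L, params$standardize$scale, `/`)
  }
  if (params$spec$n_emb > 0L) {
    feats <- cbind(feats, params$embedding[ws$s_idx, , drop = FALSE])
  }
  latent <- deep_sets_encode(params, feats)
  pooled <- colSums(latent)
  if (is.null(params$decoder)) {
    sum(pooled) + params$offset
  } else {
    mlp_forward(params$decoder, matrix(pooled, 1L), params$activation,
                params$layernorm)$out + params$offset
  }
}
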