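## Versioned JSON checkpoints bundling everything needed to reproduce
## predictions: the descriptor specification, the radial basis coefficient
## tables, the flattened network parameters, the energy offset and the
## frozen input standardization. Numbers are written at full precision.

params_to_list <- function(params) {
  list(spec = list(r_cut = params$spec$r_cut, n_max = params$spec$n_max,
                   elements = params$spec$elements,
                   n_emb = params$spec$n_emb),
       widths = params$widths, activation = params$activation,
       layernorm = params$layernorm, offset = params$offset,
       embedding = params$embedding,
       layers = lapply(params$layers, function(L) list(W = L$W, b = L$b)),
       standardize = params$standardize,
       premix_weights = params$premix_weights,
       n_feat = params$n_feat)
}

params_from_list <- function(obj) {
  spec <- descriptor_spec(obj$spec$r_cut, obj$spec$n_max,
                          unlist(obj$spec$elements), obj$spec$n_emb)
  layers <- lapply(obj$layers, function(L) {
    W <- as.matrix(L$W)
    list(W = matrix(as.numeric(W), nrow(W)), b = as.numeric(L$b))
  })
  emb <- matrix(as.numeric(as.matrix(obj$embedding)), spec$n_el)
  std <- if (!is.null(obj$standardize)) {
    list(shift = as.numeric(obj$standardize$shift),
         scale = as.numeric(obj$standardize$scale))
  }
  pw <- if (!is.null(obj$premix_weights)) {
    w <- obj$premix_weights
    if (is.list(w)) w <- simplify2array(w)
    w
  }
  structure(list(version = 1L, spec = spec,
                 widths = as.integer(unlist(obj$widths)),
                 activation = obj$activation, layernorm = obj$layernorm,
                 embedding = emb, layers = layers,
                 offset = as.numeric(obj$offset), standardize = std,
                 premix_weights = pw,
                 n_feat = as.integer(obj$n_feat)),
            class = "model_params")
}

#' Write a model checkpoint
#'
#' @param params Model parameters ([init_params()] / [train_model()]).
#' @param basis The matching radial basis.
#' @param path Output path (JSON).
#' @export
write_model_checkpoint <- function(params, basis, path) {
  obj <- list(format = "besselff-model", version = 1L,
              params = params_to_list(params),
              basis = list(n_max = basis$n_max, r_cut = basis$r_cut,
                           n_B = basis$n_B, roots = basis$roots,
                           coef = basis$coef))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path Path written by [write_model_checkpoint()].
#' @return List with `params` and `basis`.
#' @export
read_model_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "besselff-model")) {
    stop("not a model checkpoint: ", path)
  }
  basis <- structure(list(version = 1L, n_max = as.integer(obj$basis$n_max),
                          r_cut = as.numeric(obj$basis$r_cut),
                          n_B = as.integer(obj$basis$n_B),
                          roots = matrix(as.numeric(obj$basis$roots),
                                         nrow = obj$basis$n_max + 1L),
                          coef = lapply(obj$basis$coef, function(m)
                            matrix(as.numeric(m),
                                   ncol = obj$basis$n_max + 2L))),
                     class = "radial_basis")
  list(params = params_from_list(obj$params), basis = basis)
}

#' Write an ensemble checkpoint
#'
#' A single JSON manifest bundling every member checkpoint.
#'
#' @param ens An [train_ensemble()] object.
#' @param basis The shared radial basis.
#' @param path Output path.
#' @export
write_ensemble_checkpoint <- function(ens, basis, path) {
  obj <- list(format = "besselff-ensemble", version = 1L,
              fraction = ens$fraction, member_seeds = ens$member_seeds,
              replace = ens$replace,
              basis = list(n_max = basis$n_max, r_cut = basis$r_cut,
                           n_B = basis$n_B, roots = basis$roots,
                           coef = basis$coef),
              members = lapply(ens$members, params_to_list))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read an ensemble checkpoint
#'
#' @param path Path written by [write_ensemble_checkpoint()].
#' @return List with `ensemble` and `basis`.
#' @export
read_ensemble_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "besselff-ensemble")) {
    stop("not an ensemble checkpoint: ", path)
  }
  n_max <- as.integer(obj$basis$n_max)
  basis <- structure(list(version = 1L, n_max = n_max,
                          r_cut = as.numeric(obj$basis$r_cut),
                          n_B = as.integer(obj$basis$n_B),
                          roots = matrix(unlist(obj$basis$roots),
                                         nrow = n_max + 1L, byrow = TRUE),
                          coef = lapply(obj$basis$coef, function(m)
                            matrix(unlist(m), ncol = n_max + 2L,
                                   byrow = TRUE))),
                     class = "radial_basis")
  members <- lapply(obj$members, function(m) {
    m$layers <- lapply(m$layers, function(L) {
      list(W = matrix(unlist(L$W), length(L$W), byrow = TRUE),
           b = unlist(L$b))
    })
    m$embedding <- matrix(unlist(m$embedding), length(m$embedding),
                          byrow = TRUE)
    if (!is.null(m$standardize)) {
      m$standardize <- list(shift = unlist(m$standardize$shift),
                            scale = unlist(m$standardize$scale))
    }
    params_from_list(m)
  })
  ens <- structure(list(members = members, spec = members[[1L]]$spec,
                        fraction = as.numeric(obj$fraction),
                        member_seeds = unlist(obj$member_seeds),
                        replace = isTRUE(obj$replace)),
                   class = "ensemble_model")
  list(ensemble = ens, basis = basis)
}
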