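## Subsampling-aggregation ensembles: a committee of independently
## initialized networks, each trained on a random subset of the training
## split. The member spread (sample standard deviation) flags extrapolation;
## the member mean is a more outlier-robust predictor.

#' Train an ensemble of models
#'
#' Trains `n_members` networks with [train_model()], each on an independent
#' random subsample (default 50%, drawn without replacement) of the training
#' split, with a distinct initialization seed per member. The validation
#' split is shared and untouched.
#'
#' @param ds A [labeled_dataset()] (tagged or not).
#' @param spec,basis Descriptor specification and radial basis.
#' @param cfg A [training_config()]; `cfg$seed` drives the split and all
#'   member seeds.
#' @param n_members Number of ensemble members (default 18).
#' @param fraction Fraction of the training split seen by each member
#'   (default 0.5).
#' @param replace Subsample with replacement (classical bootstrap) instead of
#'   without (default `FALSE`).
#' @return An object of class `ensemble_model` holding `members` (list of
#'   trained parameter sets), the shared `spec`, and bookkeeping fields.
#' @export
train_ensemble <- function(ds, spec, basis, cfg = training_config(),
                           n_members = 18L, fraction = 0.5,
                           replace = FALSE) {
  if (n_members < 2L) stop("an ensemble needs at least 2 members")
  tags <- vapply(ds, function(fr) fr$split %||% NA_character_, character(1))
  if (anyNA(tags)) {
    ds <- split_dataset(ds, cfg$split_fraction, seed = cfg$seed)
    tags <- vapply(ds, function(fr) fr$split, character(1))
  }
  train_idx <- which(tags == "train")
  n_sub <- max(1L, round(fraction * length(train_idx)))
  member_seeds <- with_seed(cfg$seed, sample.int(2^31 - 2L, n_members))
  members <- vector("list", n_members)
  subsets <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    sub <- with_seed(member_seeds[k],
                     sample(train_idx, n_sub, replace = replace))
    subsets[[k]] <- sort(sub)
    ds_k <- ds[c(sub, which(tags == "validation"))]
    cfg_k <- cfg
    cfg_k$seed <- member_seeds[k]
    members[[k]] <- train_model(ds_k, spec, basis, cfg_k)$params
  }
  structure(list(members = members, spec = spec, fraction = fraction,
                 member_seeds = member_seeds, subsets = subsets,
                 replace = replace),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$members), " members, subsample fraction ",
      x$fraction, "\n", sep = "")
  invisible(x)
}

#' Ensemble prediction with uncertainty
#'
#' Evaluates every member on a configuration and aggregates: the mean and
#' the sample (n - 1 denominator) standard deviation of the forces
#' (per component) and of the total energy. The spread grows where the
#' configuration leaves the region covered by training data, which makes it
#' a practical extrapolation detector.
#'
#' @param ens An [train_ensemble()] object.
#' @param config An [atomic_configuration()].
#' @param basis The radial basis matching `ens$spec`.
#' @return List with `energy_mean`, `energy_sd`, `forces_mean`
#'   (`n_atoms x 3`) and `forces_sd` (`n_atoms x 3`, per component).
#' @export
ensemble_predict <- function(ens, config, basis) {
  k <- length(ens$members)
  e <- numeric(k)
  f <- vector("list", k)
  for (i in seq_len(k)) {
    ef <- energy_and_forces(config, ens$spec, basis, ens$members[[i]])
    e[i] <- ef$energy
    f[[i]] <- ef$forces
  }
  ## aggregate member deviations from the first member: shift-invariant, and
  ## exactly zero spread for bitwise-identical members
  fd <- lapply(f, function(m) m - f[[1L]])
  dm <- Reduce(`+`, fd) / k
  fm <- f[[1L]] + dm
  fsd <- sqrt(Reduce(`+`, lapply(fd, function(m) (m - dm)^2)) / (k - 1))
  ed <- e - e[1L]
  list(energy_mean = e[1L] + mean(ed),
       energy_sd = sqrt(sum((ed - mean(ed))^2) / (k - 1)),
       forces_mean = fm, forces_sd = fsd)
}
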