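## Force-matched training.
##
## The loss is the mean log-cosh of scaled residuals; in force mode the
## residuals are all Cartesian force components in the batch, in energy mode
## the per-atom total energies. Optimization is Adam with a one-cycle
## learning-rate schedule repeated every epoch. Per-frame descriptors and
## dense descriptor Jacobians are precomputed once (the configurations never
## move during training), so each step reduces to matrix algebra: forces are
## F = -J^T (dE/dp), and the parameter gradient of the force loss is obtained
## by propagating the loss sensitivity u back through J (a Jacobian-vector
## product v = J u) and evaluating the parameter gradient of the directional
## derivative v . dE/dp with a complex-step pass through the network.

#' Log-cosh loss
#'
#' Mean over components of \eqn{\log\cosh((pred - ref)/scale)}, evaluated in
#' the overflow-safe form \eqn{|x| + \log(1 + e^{-2|x|}) - \log 2}. Behaves
#' like half the squared error for small residuals and like the absolute
#' error beyond `scale`, which bounds the per-component gradient (built-in
#' clipping).
#'
#' @param pred,ref Numeric arrays of identical shape.
#' @param scale Characteristic residual scale (same units as the inputs;
#'   0.1 eV/Angstrom for forces, 1e-2 eV/atom for energies).
#' @return The scalar loss (dimensionless).
#' @export
logcosh_loss <- function(pred, ref, scale = 0.1) {
  if (length(pred) != length(ref)) stop("shape mismatch in logcosh_loss")
  if (scale <= 0) stop("scale must be positive")
  x <- abs(pred - ref) / scale
  mean(x + log1p(exp(-2 * x)) - log(2))
}

#' One-cycle learning-rate schedule
#'
#' Linear ramp from `lr_base` to `lr_peak` over the first 45% of the steps,
#' linear descent back to `lr_base` over the next 45%, then a constant
#' `lr_floor` for the final 10%. During training the schedule is repeated
#' every epoch (pass `steps_per_epoch` and the within-epoch step).
#'
#' @param step Zero-based step index, `0 <= step < n_steps`.
#' @param n_steps Number of steps in one cycle.
#' @param cfg A list (e.g. [training_config()]) with `lr_base`, `lr_peak`,
#'   `lr_floor`.
#' @return The learning rate.
#' @export
one_cycle_lr <- function(step, n_steps, cfg) {
  if (any(step < 0L) || any(step >= n_steps)) {
    stop("step out of range [0, ", n_steps, ")")
  }
  frac <- step / n_steps
  ifelse(frac < 0.45,
         cfg$lr_base + (cfg$lr_peak - cfg$lr_base) * frac / 0.45,
         ifelse(frac < 0.9,
                cfg$lr_peak - (cfg$lr_peak - cfg$lr_base) * (frac - 0.45) / 0.45,
                cfg$lr_floor))
}

#' Training configuration
#'
#' @param mode `"forces"` (default): fit all Cartesian force components;
#'   `"energies"`: fit per-atom total energies only.
#' @param scale Loss scale; defaults to 0.1 eV/Angstrom in force mode and
#'   1e-2 eV/atom in energy mode.
#' @param batch_size Configurations per batch (default 8).
#' @param epochs Training epochs (default 500).
#' @param lr_base,lr_peak,lr_floor One-cycle endpoints; default
#'   1e-3 / 1e-2 / 1e-5 in force mode, 1e-5 / 1e-4 / 1e-6 in energy mode.
#' @param split_fraction Training fraction for untagged datasets (0.9).
#' @param seed Master seed for initialization, splitting and shuffling.
#' @param widths Hidden-layer widths.
#' @param activation,layernorm Passed to [init_params()].
#' @param standardize Standardize descriptors per feature on the training
#'   split and freeze the affine into the model (default `TRUE`).
#' @param schedule_span `"epoch"` (default): the one-cycle schedule restarts
#'   every epoch; `"run"`: one cycle over the whole run.
#' @return A list of class `training_config`.
#' @export
training_config <- function(mode = c("forces", "energies"), scale = NULL,
                            batch_size = 8L, epochs = 500L,
                            lr_base = NULL, lr_peak = NULL, lr_floor = NULL,
                            split_fraction = 0.9, seed = 1L,
                            widths = c(64L, 32L, 16L, 16L, 16L),
                            activation = "swish1", layernorm = NULL,
                            standardize = TRUE,
                            schedule_span = c("epoch", "run")) {
  mode <- match.arg(mode)
  schedule_span <- match.arg(schedule_span)
  if (is.null(scale) || is.na(scale)) {
    scale <- if (mode == "forces") 0.1 else 1e-2
  }
  if (scale <= 0) stop("scale must be positive")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)")
  }
  if (is.null(lr_base)) lr_base <- if (mode == "forces") 1e-3 else 1e-5
  if (is.null(lr_peak)) lr_peak <- if (mode == "forces") 1e-2 else 1e-4
  if (is.null(lr_floor)) lr_floor <- if (mode == "forces") 1e-5 else 1e-6
  structure(list(mode = mode, scale = scale, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_base = lr_base,
                 lr_peak = lr_peak, lr_floor = lr_floor,
                 split_fraction = split_fraction, seed = as.integer(seed),
                 widths = as.integer(widths), activation = activation,
                 layernorm = layernorm, standardize = standardize,
                 schedule_span = schedule_span),
            class = "training_config")
}

#' Fit the constant energy offset
#'
#' Chooses the offset so that the mean predicted and mean reference energies
#' coincide over the given frames (force-trained models are otherwise unaware
#' of the reference energy origin).
#'
#' @param params Model parameters.
#' @param ds A [labeled_dataset()] with reference energies.
#' @param spec,basis Descriptor specification and radial basis.
#' @return `params` with the updated offset.
#' @export
fit_energy_offset <- function(params, ds, spec, basis) {
  if (!length(ds)) stop("empty dataset in fit_energy_offset")
  diffs <- vapply(ds, function(fr) {
    fr$energy - total_energy(fr$config, spec, basis, params)
  }, numeric(1))
  params$offset <- params$offset + mean(diffs)
  params
}

## ---- parameter-tree utilities (flat-vector view for Adam) ----

theta_pack <- function(params) {
  list(embedding = params$embedding,
       layers = params$layers,
       offset = params$offset)
}

theta_unpack <- function(params, tree) {
  params$embedding <- tree$embedding
  params$layers <- tree$layers
  params$offset <- tree$offset
  params
}

## Precompute everything that is fixed during training for one frame.
prepare_frame <- function(fr, spec, basis) {
  ws <- descriptor_workspace(fr$config, spec, basis, derivatives = TRUE)
  na <- length(ws$atoms)
  p <- descriptors_from_workspace(ws)
  J <- descriptor_jacobian(fr$config, spec, basis)
  ## permute rows to the column-major (atom, feature) layout so that batch
  ## steps can use as.numeric(G) directly, without per-frame transposes
  n_p <- descriptor_dimension(spec)
  perm <- as.vector(outer(seq_len(na), seq_len(n_p),
                          function(i, f) (i - 1L) * n_p + f))
  list(p = p, s_idx = ws$s_idx, J = J[perm, , drop = FALSE], na = na,
       f_ref = if (!is.null(fr$forces)) as.numeric(t(fr$forces)) else NULL,
       e_ref = fr$energy)
}

#' Train the atomic-energy model
#'
#' Fits the network to reference forces (default) or total energies with the
#' log-cosh loss, Adam and the per-epoch one-cycle schedule. Batches are
#' whole configurations; residuals are pooled over all force components in
#' the batch. In force mode the energy offset is fitted afterwards on the
#' training split. Deterministic given `cfg$seed`.
#'
#' @param ds A [labeled_dataset()]; frames may already carry split tags,
#'   otherwise [split_dataset()] is applied with `cfg$split_fraction`.
#' @param spec,basis Descriptor specification and matching radial basis.
#' @param cfg A [training_config()].
#' @param params Optional starting parameters (default: fresh
#'   [init_params()]).
#' @return A list with `params` (trained model), `history` (a data frame
#'   with per-epoch train/validation MAEs of forces and energies, and the
#'   running loss; epoch 0 is the pre-training baseline) and `cfg`.
#' @export
train_model <- function(ds, spec, basis, cfg = training_config(),
                        params = NULL) {
  tags <- vapply(ds, function(fr) fr$split %||% NA_character_, character(1))
  if (anyNA(tags)) {
    ds <- split_dataset(ds, cfg$split_fraction, seed = cfg$seed)
    tags <- vapply(ds, function(fr) fr$split, character(1))
  }
  frames <- lapply(ds, prepare_frame, spec = spec, basis = basis)
  train_idx <- which(tags == "train")
  val_idx <- which(tags == "validation")
  if (is.null(params)) {
    params <- init_params(spec, widths = cfg$widths, seed = cfg$seed,
                          activation = cfg$activation,
                          layernorm = cfg$layernorm %||%
                            (cfg$activation == "swish1"))
  }
  n_p <- descriptor_dimension(spec)
  if (cfg$standardize && is.null(params$standardize)) {
    ptrain <- do.call(rbind, lapply(frames[train_idx], `[[`, "p"))
    shift <- colMeans(ptrain)
    sd_ <- apply(ptrain, 2L, stats::sd)
    params$standardize <- list(shift = shift,
                               scale = ifelse(sd_ < 1e-8, 1, sd_))
  }
  scale_vec <- if (is.null(params$standardize)) rep(1, n_p) else
    params$standardize$scale
  ## stacked standardized descriptor rows for fast batched passes
  Xd <- lapply(frames, function(fr) {
    x <- fr$p
    if (!is.null(params$standardize)) {
      x <- sweep(sweep(x, 2L, params$standardize$shift), 2L,
                 params$standardize$scale, `/`)
    }
    x
  })

  tree <- theta_pack(params)
  skeleton <- tree
  theta <- unlist(tree, use.names = FALSE)
  m_adam <- numeric(length(theta))
  v_adam <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  eps_cs <- 1e-20
  n_emb <- spec$n_emb
  emb_cols <- if (n_emb > 0L) n_p + seq_len(n_emb) else integer(0)

  ## stacked rows over the whole dataset for the per-epoch metric pass
  Xall <- do.call(rbind, Xd)
  sp_all <- unlist(lapply(frames, `[[`, "s_idx"))
  na_all <- vapply(frames, `[[`, numeric(1), "na")
  frame_of_row_all <- rep(seq_along(frames), na_all)
  rows_of_frame <- split(seq_len(nrow(Xall)), frame_of_row_all)

  metrics <- function(prm) {
    X <- if (n_emb > 0L) cbind(Xall, prm$embedding[sp_all, , drop = FALSE])
    else Xall
    vg <- mlp_value_and_grad(prm$layers, X, activation = prm$activation,
                             layernorm = prm$layernorm)
    G <- sweep(vg$dX[, seq_len(n_p), drop = FALSE], 2L, scale_vec, `/`)
    e_pred <- as.numeric(rowsum(vg$out, frame_of_row_all)) + prm$offset
    f_mae <- vapply(seq_along(frames), function(fi) {
      fr <- frames[[fi]]
      if (is.null(fr$f_ref)) return(NA_real_)
      gvec <- as.numeric(G[rows_of_frame[[fi]], , drop = FALSE])
      mean(abs(-as.numeric(crossprod(fr$J, gvec)) - fr$f_ref))
    }, numeric(1))
    e_ref <- vapply(frames, `[[`, numeric(1), "e_ref")
    ## offset for the energy metric: make train means coincide
    off <- mean(e_ref[train_idx] - e_pred[train_idx])
    e_err <- abs(e_pred + off - e_ref) / na_all
    c(train_force_mae = mean(f_mae[train_idx]),
      val_force_mae = mean(f_mae[val_idx]),
      train_energy_mae = mean(e_err[train_idx]),
      val_energy_mae = mean(e_err[val_idx]))
  }

  steps_per_epoch <- max(1L, ceiling(length(train_idx) / cfg$batch_size))
  total_steps <- steps_per_epoch * cfg$epochs
  history <- vector("list", cfg$epochs + 1L)
  history[[1L]] <- c(epoch = 0, loss = NA_real_, metrics(params))
  step_global <- 0L

  run_epochs <- function() {
    prm <- params
    for (epoch in seq_len(cfg$epochs)) {
      order_ <- sample(train_idx)
      epoch_loss <- 0
      for (bstart in seq(1L, length(order_), by = cfg$batch_size)) {
        bframes <- order_[bstart:min(bstart + cfg$batch_size - 1L,
                                     length(order_))]
        lr <- if (cfg$schedule_span == "epoch") {
          one_cycle_lr(step_global %% steps_per_epoch, steps_per_epoch, cfg)
        } else {
          one_cycle_lr(step_global, total_steps, cfg)
        }
        rows_per <- lapply(bframes, function(fi) frames[[fi]]$na)
        Xb <- do.call(rbind, lapply(bframes, function(fi) Xd[[fi]]))
        sp <- unlist(lapply(bframes, function(fi) frames[[fi]]$s_idx))
        if (n_emb > 0L) Xb <- cbind(Xb, prm$embedding[sp, , drop = FALSE])
        vg <- mlp_value_and_grad(prm$layers, Xb,
                                 activation = prm$activation,
                                 layernorm = prm$layernorm)
        if (cfg$mode == "forces") {
          G <- sweep(vg$dX[, seq_len(n_p), drop = FALSE], 2L, scale_vec, `/`)
          row0 <- 0L
          Vb <- matrix(0, nrow(Xb), n_p)
          n_comp <- 3L * sum(unlist(rows_per))
          loss_b <- 0
          for (bi in seq_along(bframes)) {
            fr <- frames[[bframes[bi]]]
            rows <- row0 + seq_len(fr$na)
            gvec <- as.numeric(G[rows, , drop = FALSE])
            f_pred <- -as.numeric(crossprod(fr$J, gvec))
            x <- (f_pred - fr$f_ref) / cfg$scale
            loss_b <- loss_b +
              sum(abs(x) + log1p(exp(-2 * abs(x))) - log(2))
            u <- tanh(x) / (cfg$scale * n_comp)
            v <- matrix(as.numeric(fr$J %*% u), fr$na, n_p)
            Vb[rows, ] <- v * rep(1 / scale_vec, each = fr$na)
            row0 <- row0 + fr$na
          }
          loss_b <- loss_b / n_comp
          Vfull <- matrix(0, nrow(Xb), ncol(Xb))
          Vfull[, seq_len(n_p)] <- Vb
          cg <- mlp_value_and_grad(prm$layers, Xb + 1i * eps_cs * Vfull,
                                   activation = prm$activation,
                                   layernorm = prm$layernorm)
          gW <- lapply(cg$dW, function(m) -Im(m) / eps_cs)
          gb <- lapply(cg$db, function(v2) -Im(v2) / eps_cs)
          g_emb <- if (n_emb > 0L) {
            dE <- -Im(cg$dX[, emb_cols, drop = FALSE]) / eps_cs
            rowsum_species(dE, sp, spec$n_el)
          } else {
            matrix(0, spec$n_el, 0L)
          }
          g_off <- 0
        } else {
          e_ref_b <- vapply(bframes, function(fi) frames[[fi]]$e_ref,
                            numeric(1))
          na_b <- unlist(rows_per)
          frame_of_row <- rep(seq_along(bframes), na_b)
          e_pred <- as.numeric(rowsum(vg$out, frame_of_row)) + prm$offset
          x <- (e_pred - e_ref_b) / na_b / cfg$scale
          loss_b <- mean(abs(x) + log1p(exp(-2 * abs(x))) - log(2))
          dle <- tanh(x) / (cfg$scale * na_b * length(bframes))
          bw <- mlp_value_and_grad(prm$layers, Xb,
                                   d_out = dle[frame_of_row],
                                   activation = prm$activation,
                                   layernorm = prm$layernorm)
          gW <- bw$dW
          gb <- bw$db
          g_emb <- if (n_emb > 0L) {
            rowsum_species(bw$dX[, emb_cols, drop = FALSE], sp, spec$n_el)
          } else matrix(0, spec$n_el, 0L)
          g_off <- sum(dle)
        }
        if (!is.finite(loss_b)) {
          stop("divergent loss at epoch ", epoch, ", step ",
               step_global %% steps_per_epoch)
        }
        epoch_loss <- epoch_loss + loss_b
        grad_tree <- list(embedding = g_emb,
                          layers = lapply(seq_along(gW), function(k)
                            list(W = gW[[k]], b = gb[[k]])),
                          offset = g_off)
        g <- unlist(grad_tree, use.names = FALSE)
        step_global <<- step_global + 1L
        m_adam <<- beta1 * m_adam + (1 - beta1) * g
        v_adam <<- beta2 * v_adam + (1 - beta2) * g^2
        mhat <- m_adam / (1 - beta1^step_global)
        vhat <- v_adam / (1 - beta2^step_global)
        theta <<- theta - lr * mhat / (sqrt(vhat) + eps_adam)
        tree <- utils::relist(theta, skeleton)
        prm <- theta_unpack(prm, tree)
      }
      history[[epoch + 1L]] <<- c(epoch = epoch,
                                  loss = epoch_loss /
                                    ceiling(length(order_) / cfg$batch_size),
                                  metrics(prm))
    }
    prm
  }
  params <- with_seed(cfg$seed + 1L, run_epochs())

  if (cfg$mode == "forces" && cfg$epochs > 0L) {
    params <- fit_energy_offset(params, ds[train_idx], spec, basis)
  }
  hist_df <- as.data.frame(do.call(rbind, history))
  list(params = params, history = hist_df, cfg = cfg)
}

## Accumulate per-row gradients onto the embedding table by species.
rowsum_species <- function(rows, species_idx, n_el) {
  out <- matrix(0, n_el, ncol(rows))
  agg <- rowsum(rows, species_idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}
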