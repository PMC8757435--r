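test_that("log-cosh loss identities hold", {
  x <- rnorm(20)
  expect_equal(logcosh_loss(x, x, 0.1), 0)
  ## quadratic small-residual limit: loss -> (delta/scale)^2 / 2
  d <- 1e-4
  expect_equal(logcosh_loss(d, 0, 1), d^2 / 2, tolerance = 1e-7)
  ## non-negative, monotone in |delta|
  deltas <- seq(0, 5, by = 0.25)
  vals <- vapply(deltas, function(dd) logcosh_loss(dd, 0, 0.1), numeric(1))
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) > 0))
  expect_error(logcosh_loss(1:3, 1:2, 0.1), "shape")
})

test_that("the stable log-cosh form matches a direct oracle up to |x| = 1e4", {
  ## oracle: log1p(2 sinh(x/2)^2) is cancellation-free wherever sinh is
  ## representable; beyond that the asymptote |x| - log 2 is exact to
  ## double precision (the e^{-2|x|} correction underflows)
  oracle <- function(x) {
    ifelse(abs(x) < 700, log1p(2 * sinh(x / 2)^2), abs(x) - log(2))
  }
  xs <- c(10^seq(-3, 4, by = 0.25), -10^seq(-3, 4, by = 0.5))
  got <- vapply(xs, function(x) logcosh_loss(x, 0, 1), numeric(1))
  want <- oracle(xs)
  ## mixed metric: relative above 1, absolute below (the softplus form is
  ## machine-accurate in absolute terms everywhere; below |x| ~ 1 a purely
  ## relative comparison only measures double-precision cancellation)
  expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-12)
  expect_true(all(is.finite(got)))
  expect_lt(max(abs(got[abs(xs) >= 1] - want[abs(xs) >= 1]) /
                  want[abs(xs) >= 1]), 1e-12)
})

test_that("per-component loss gradient magnitude is bounded by 1/scale", {
  scale <- 0.1
  h <- 1e-6
  for (delta in c(-50, -1, -0.01, 0.02, 3, 100)) {
    g <- (logcosh_loss(delta + h, 0, scale) -
            logcosh_loss(delta - h, 0, scale)) / (2 * h)
    expect_lte(abs(g), 1 / scale + 1e-6)
  }
})

test_that("the one-cycle schedule hits its documented way points", {
  cfg <- training_config()
  n <- 200
  expect_equal(one_cycle_lr(0, n, cfg), 1e-3)
  expect_equal(one_cycle_lr(0.45 * n, n, cfg), 1e-2)
  expect_equal(one_cycle_lr(0.95 * n, n, cfg), 1e-5)
  ## piecewise linear: halfway up the ramp
  expect_equal(one_cycle_lr(0.225 * n, n, cfg), (1e-3 + 1e-2) / 2)
  expect_error(one_cycle_lr(n, n, cfg), "range")
  ## energy-mode endpoints
  cfgE <- training_config(mode = "energies")
  expect_equal(one_cycle_lr(0, n, cfgE), 1e-5)
  expect_equal(one_cycle_lr(0.45 * n, n, cfgE), 1e-4)
  expect_equal(one_cycle_lr(n - 1, n, cfgE), 1e-6)
})

test_that("initialization follows the documented distribution and is deterministic", {
  spec <- descriptor_spec(3.5, 3, c("Na", "Cl"))
  p1 <- init_params(spec, seed = 7)
  p2 <- init_params(spec, seed = 7)
  expect_identical(p1, p2)
  for (L in p1$layers) expect_true(all(L$b == 0))
  ## empirical std of the widest layer ~ 1/sqrt(fan_in) within 5%
  fan_in <- ncol(p1$layers[[1]]$W)
  draws <- unlist(lapply(1:6, function(s)
    init_params(spec, seed = s)$layers[[1]]$W))
  expect_gt(length(draws), 1e4)
  expect_equal(sd(draws), 1 / sqrt(fan_in), tolerance = 0.05)
})

test_that("dataset splitting follows the floor convention and is reproducible", {
  frames <- replicate(741, list(config = atomic_configuration(
    matrix(rnorm(3), 1), "N")), simplify = FALSE)
  ds <- labeled_dataset(frames)
  sp <- split_dataset(ds, 0.9, seed = 3)
  tags <- vapply(sp, function(fr) fr$split, character(1))
  expect_equal(sum(tags == "train"), 667L)
  expect_equal(sum(tags == "validation"), 74L)
  sp2 <- split_dataset(ds, 0.9, seed = 3)
  expect_identical(vapply(sp2, function(fr) fr$split, character(1)), tags)
  ## half-half split of two frames
  two <- split_dataset(ds[1:2], 0.5, seed = 1)
  expect_setequal(vapply(two, function(fr) fr$split, character(1)),
                  c("train", "validation"))
})

test_that("the energy offset fit matches the arithmetic oracle", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(8, 4), seed = 8)
  set.seed(8)
  frames <- lapply(1:3, function(k) {
    cfg <- random_cluster(4, c("Na", "Cl"))
    list(config = cfg, energy = rnorm(1))
  })
  ds <- labeled_dataset(frames)
  fitted <- fit_energy_offset(params, ds, spec, basis)
  preds0 <- vapply(ds, function(fr)
    total_energy(fr$config, spec, basis, params), numeric(1))
  refs <- vapply(ds, `[[`, numeric(1), "energy")
  expect_equal(fitted$offset, params$offset + mean(refs - preds0),
               tolerance = 1e-12)
  ## after fitting, the means coincide; refitting changes nothing
  expect_equal(fit_energy_offset(fitted, ds, spec, basis)$offset,
               fitted$offset, tolerance = 1e-10)
  ## shifting all references by +c shifts the offset by +c
  ds_shift <- labeled_dataset(lapply(ds, function(fr) {
    fr$energy <- fr$energy + 4.2
    fr
  }))
  expect_equal(fit_energy_offset(params, ds_shift, spec, basis)$offset,
               fitted$offset + 4.2, tolerance = 1e-10)
})

test_that("a zero-epoch run returns the initial parameters with baseline metrics", {
  ds <- generate_toy_dataset(6, seed = 91, verify = FALSE)
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  cfg <- training_config(epochs = 0, seed = 2)
  fit <- train_model(ds, spec, basis, cfg)
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$history$epoch, 0)
  ref <- init_params(spec, widths = cfg$widths, seed = cfg$seed)
  expect_equal(fit$params$layers, ref$layers, tolerance = 1e-15)
})

test_that("training is reproducible and reduces the force error", {
  ds <- generate_toy_dataset(24, seed = 92, verify = FALSE)
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  cfg <- training_config(epochs = 25, seed = 4, widths = c(24L, 12L))
  fit1 <- train_model(ds, spec, basis, cfg)
  fit2 <- train_model(ds, spec, basis, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$params$layers, fit2$params$layers, tolerance = 1e-15)
  h <- fit1$history
  expect_lt(h$val_force_mae[nrow(h)], h$val_force_mae[1])
  expect_lt(h$train_force_mae[nrow(h)], 0.65 * h$train_force_mae[1])
})

test_that("the training gradient matches finite differences of the batch loss", {
  ## independent oracle for the complex-step force-loss gradient: perturb a
  ## single weight, recompute the pooled log-cosh force loss directly
  ds <- generate_toy_dataset(3, seed = 93, verify = FALSE)
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(8, 4), seed = 5)
  scale <- 0.1
  batch_loss <- function(prm) {
    tot <- 0
    n_comp <- 0
    for (fr in ds) {
      ef <- energy_and_forces(fr$config, spec, basis, prm)
      x <- (ef$forces - fr$forces) / scale
      tot <- tot + sum(log(cosh(x)))
      n_comp <- n_comp + length(x)
    }
    tot / n_comp
  }
  ## assemble the analytic gradient the way the trainer does (backward pass
  ## for dE/dp, Jacobian transport of the loss sensitivity, complex-step
  ## pass for the parameter derivative of the directional derivative)
  n_p <- descriptor_dimension(spec)
  analytic_grad <- function(prm) {
    eps <- 1e-20
    gW <- NULL
    g_emb <- matrix(0, spec$n_el, spec$n_emb)
    n_comp <- sum(vapply(ds, function(fr) length(fr$forces), numeric(1)))
    for (fr in ds) {
      ws <- besselff:::descriptor_workspace(fr$config, spec, basis, TRUE)
      p <- besselff:::descriptors_from_workspace(ws)
      X <- cbind(p, prm$embedding[ws$s_idx, , drop = FALSE])
      vg <- besselff:::mlp_value_and_grad(prm$layers, X)
      G <- vg$dX[, seq_len(n_p), drop = FALSE]
      f_pred <- -besselff:::pullback_apply(ws, G)
      u <- tanh((f_pred - fr$forces) / scale) / (scale * n_comp)
      v <- besselff:::descriptor_jvp(ws, u)
      V <- cbind(v, matrix(0, nrow(v), spec$n_emb))
      cg <- besselff:::mlp_value_and_grad(prm$layers, X + 1i * eps * V)
      gW_f <- lapply(cg$dW, function(m) -Im(m) / eps)
      gW <- if (is.null(gW)) gW_f else mapply(`+`, gW, gW_f, SIMPLIFY = FALSE)
      dE <- -Im(cg$dX[, n_p + seq_len(spec$n_emb), drop = FALSE]) / eps
      g_emb <- g_emb + besselff:::rowsum_species(dE, ws$s_idx, spec$n_el)
    }
    list(gW = gW, g_emb = g_emb)
  }
  ag <- analytic_grad(params)
  h <- 1e-5
  for (probe in list(c(1, 2, 3), c(2, 1, 4), c(3, 1, 2))) {
    k <- probe[1]; i <- probe[2]; j <- probe[3]
    pp <- params; pp$layers[[k]]$W[i, j] <- pp$layers[[k]]$W[i, j] + h
    pm <- params; pm$layers[[k]]$W[i, j] <- pm$layers[[k]]$W[i, j] - h
    slope <- (batch_loss(pp) - batch_loss(pm)) / (2 * h)
    expect_equal(ag$gW[[k]][i, j], slope, tolerance = 1e-5)
  }
  pp <- params; pp$embedding[1, 2] <- pp$embedding[1, 2] + h
  pm <- params; pm$embedding[1, 2] <- pm$embedding[1, 2] - h
  slope <- (batch_loss(pp) - batch_loss(pm)) / (2 * h)
  expect_equal(ag$g_emb[1, 2], slope, tolerance = 1e-5)
  ## and the loss decreases over one epoch of actual training
  cfg <- training_config(epochs = 1, batch_size = 8, seed = 5,
                         widths = c(8L, 4L), standardize = FALSE,
                         split_fraction = 0.7)
  fit <- train_model(ds[1:3], spec, basis, cfg, params = params)
  expect_lt(fit$history$train_force_mae[2], fit$history$train_force_mae[1])
})

test_that("energy-mode training improves energies and is deterministic", {
  ds <- generate_toy_dataset(16, seed = 94, verify = FALSE)
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  cfg <- training_config(mode = "energies", epochs = 40, seed = 6,
                         widths = c(24L, 12L), lr_base = 1e-4,
                         lr_peak = 1e-3, lr_floor = 1e-5)
  fit <- train_model(ds, spec, basis, cfg)
  h <- fit$history
  expect_lt(h$train_energy_mae[nrow(h)], h$train_energy_mae[1])
})
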