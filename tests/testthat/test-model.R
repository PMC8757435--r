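test_that("activation functions match their defining formulas", {
  expect_equal(swish1(0), 0)
  expect_equal(swish1(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(swish1(1), 0.731059, tolerance = 1e-6)
  ## swish1(x) - x -> 0 for large x
  expect_lt(abs(swish1(60) - 60), 1e-12)
  expect_equal(selu(0), 0)
  expect_equal(selu(2), 1.0507 * 2, tolerance = 1e-12)
  ## x -> -Inf limit is -lambda * alpha = -1.758031 (product of the stated
  ## constants, computed directly)
  expect_equal(selu(-50), -1.0507 * 1.6732, tolerance = 1e-12)
  expect_equal(selu(-50), -1.758031, tolerance = 1e-6)
})

test_that("atomic energies are a pure function of the per-atom input", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  params <- init_params(spec, widths = c(8, 4), seed = 31)
  n_p <- descriptor_dimension(spec)
  p <- matrix(rnorm(2 * n_p), 2, n_p, byrow = FALSE)
  p[2, ] <- p[1, ]                       # bitwise-identical inputs
  e <- atomic_energies(p, c("Na", "Na"), params)
  expect_identical(e[1], e[2])
  ## different species differ through the embedding
  e2 <- atomic_energies(p, c("Na", "Cl"), params)
  expect_false(e2[1] == e2[2])
})

test_that("a zero-width embedding drops the concatenation cleanly", {
  spec0 <- descriptor_spec(3.5, 2, c("Na", "Cl"), n_emb = 0L)
  params <- init_params(spec0, widths = c(8, 4), seed = 32)
  expect_equal(ncol(params$embedding), 0L)
  set.seed(32)
  cfg <- random_cluster(4, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  e <- total_energy(cfg, spec0, basis, params)
  expect_true(is.finite(e))
  ## identical to applying the layer stack to bare descriptors
  p <- compute_descriptors(cfg, spec0, basis)
  oracle <- sum(besselff:::mlp_forward(params$layers, p)$out)
  expect_equal(e, oracle + params$offset, tolerance = 1e-12)
})

test_that("the network matches a straight-line layer-by-layer oracle", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  params <- init_params(spec, widths = c(8, 4), seed = 33)
  n_in <- params$n_feat + spec$n_emb
  x <- rnorm(n_in - spec$n_emb)
  xe <- c(x, params$embedding[1, ])
  ## hand-rolled evaluation: dense -> layernorm -> swish per hidden layer,
  ## then the final linear layer
  h <- xe
  for (k in seq_along(params$widths)) {
    z <- as.numeric(params$layers[[k]]$W %*% h) + params$layers[[k]]$b
    zc <- z - mean(z)
    y <- zc / sqrt(mean(zc^2) + 1e-6)
    h <- y / (1 + exp(-y))
  }
  L <- params$layers[[length(params$layers)]]
  oracle <- as.numeric(L$W %*% h) + L$b
  got <- atomic_energies(matrix(x, 1), "Na", params)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("total energy is invariant under rigid motions and permutations", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(16, 8), seed = 34)
  set.seed(34)
  cfg <- random_cluster(6, c("Na", "Cl"))
  e0 <- total_energy(cfg, spec, basis, params)
  moved <- transform_configuration(cfg, random_rotation(), rnorm(3, sd = 4))
  expect_equal(total_energy(moved, spec, basis, params), e0,
               tolerance = 1e-9 * abs(e0))
  perm <- sample(6)
  permuted <- atomic_configuration(cfg$positions[perm, ], cfg$species[perm])
  expect_equal(total_energy(permuted, spec, basis, params), e0,
               tolerance = 1e-12)
})

test_that("energies add over non-interacting fragments", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(16, 8), seed = 35)
  params$offset <- 2.5
  set.seed(35)
  cfg <- random_cluster(4, c("Na", "Cl"))
  far <- atomic_configuration(rbind(cfg$positions,
                                    sweep(cfg$positions, 2, -c(50, 0, 0))),
                              rep(cfg$species, 2))
  e1 <- total_energy(cfg, spec, basis, params)
  e2 <- total_energy(far, spec, basis, params)
  ## duplicating the cluster doubles everything except the single offset
  expect_equal(e2, 2 * (e1 - params$offset) + params$offset,
               tolerance = 1e-10)
})

test_that("forces sum to zero and rotate with the configuration", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, seed = 36)
  set.seed(36)
  cfg <- random_cluster(5, c("Na", "Cl"))
  f <- forces(cfg, spec, basis, params)
  expect_lt(max(abs(colSums(f))), 1e-8)
  R <- random_rotation()
  f_rot <- forces(transform_configuration(cfg, R), spec, basis, params)
  expect_rel_equal(f_rot, f %*% t(R), 1e-8)
})

test_that("model forces match finite differences of the energy", {
  spec <- descriptor_spec(3.5, 3, c("Na", "Cl"))
  basis <- cached_basis(3, 3.5)
  params <- init_params(spec, seed = 37)
  set.seed(37)
  for (rep_i in 1:3) {
    cfg <- random_cluster(sample(3:6, 1), c("Na", "Cl"))
    f <- forces(cfg, spec, basis, params)
    f_fd <- fd_forces(function(c2) total_energy(c2, spec, basis, params),
                      cfg)
    expect_rel_equal(f, f_fd, 1e-6)
  }
})

test_that("forces are conservative: work around a closed path vanishes", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(16, 8), seed = 38)
  set.seed(38)
  cfg <- random_cluster(4, c("Na", "Cl"))
  ## move atom 1 around a small circle; integrate F . dr with fine steps
  theta <- seq(0, 2 * pi, length.out = 201)
  radius <- 0.15
  base <- cfg$positions[1, ]
  pts <- lapply(theta, function(th) base + radius * c(cos(th), sin(th), 0))
  fs <- lapply(pts, function(pt) {
    c2 <- cfg
    c2$positions[1, ] <- pt
    forces(c2, spec, basis, params)[1, ]
  })
  ## trapezoidal line integral of F . dr around the loop
  work <- sum(vapply(seq_len(length(pts) - 1), function(k) {
    sum((fs[[k]] + fs[[k + 1]]) / 2 * (pts[[k + 1]] - pts[[k]]))
  }, numeric(1)))
  expect_lt(abs(work), 1e-6)
})

test_that("Swish-1 energies have finite symmetric second derivatives", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(8, 4), seed = 39)
  set.seed(39)
  cfg <- random_cluster(3, c("Na", "Cl"))
  ## Hessian block by finite differences of analytic forces
  h <- 1e-4
  hess <- matrix(0, 9, 9)
  for (i in 1:3) {
    for (c in 1:3) {
      cp <- cfg; cp$positions[i, c] <- cp$positions[i, c] + h
      cm <- cfg; cm$positions[i, c] <- cm$positions[i, c] - h
      dF <- (forces(cp, spec, basis, params) -
               forces(cm, spec, basis, params)) / (2 * h)
      hess[(i - 1) * 3 + c, ] <- -as.numeric(t(dF))
    }
  }
  expect_true(all(is.finite(hess)))
  expect_lt(max(abs(hess - t(hess))) / max(abs(hess)), 1e-4)
})

test_that("deep-sets energy is permutation invariant and matches its oracle", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  dsp <- init_deep_sets_params(spec, encoder_widths = c(16, 8, 4),
                               decoder_widths = c(8, 8), seed = 40)
  set.seed(40)
  cfg <- random_cluster(5, c("Na", "Cl"))
  e0 <- deep_sets_energy(cfg, spec, basis, dsp)
  perm <- sample(5)
  permuted <- atomic_configuration(cfg$positions[perm, ], cfg$species[perm])
  expect_equal(deep_sets_energy(permuted, spec, basis, dsp), e0,
               tolerance = 1e-12)
  ## straight-line oracle: encode row-by-row, pool, decode
  p <- compute_descriptors(cfg, spec, basis)
  X <- cbind(p, dsp$embedding[match(cfg$species, spec$elements), ])
  enc <- function(x) {
    h <- x
    for (L in dsp$encoder) {
      z <- as.numeric(L$W %*% h) + L$b
      zc <- z - mean(z)
      y <- zc / sqrt(mean(zc^2) + 1e-6)
      h <- y / (1 + exp(-y))
    }
    h
  }
  pooled <- Reduce(`+`, lapply(seq_len(5), function(i) enc(X[i, ])))
  oracle <- besselff:::mlp_forward(dsp$decoder, matrix(pooled, 1))$out
  expect_equal(e0, oracle, tolerance = 1e-10)
})

test_that("deep sets with identity decoder reduces to the additive ansatz", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(16, 8), seed = 41)
  dsp <- init_deep_sets_params(spec, encoder_widths = c(16, 8, 1),
                               seed = 41, final_linear = TRUE)
  dsp$decoder <- NULL
  dsp$encoder <- params$layers
  dsp$embedding <- params$embedding
  dsp$offset <- params$offset
  set.seed(41)
  cfg <- random_cluster(5, c("Na", "Cl"))
  expect_equal(deep_sets_energy(cfg, spec, basis, dsp),
               total_energy(cfg, spec, basis, params), tolerance = 1e-12)
})

test_that("model checkpoints reproduce predictions exactly", {
  spec <- descriptor_spec(3.5, 2, c("Na", "Cl"))
  basis <- cached_basis(2, 3.5)
  params <- init_params(spec, widths = c(8, 4), seed = 42)
  params$standardize <- list(shift = rnorm(params$n_feat),
                             scale = runif(params$n_feat, 0.5, 2))
  params$offset <- -3.21
  path <- tempfile(fileext = ".json")
  write_model_checkpoint(params, basis, path)
  back <- read_model_checkpoint(path)
  set.seed(42)
  cfg <- random_cluster(4, c("Na", "Cl"))
  ef0 <- energy_and_forces(cfg, spec, basis, params)
  ef1 <- energy_and_forces(cfg, back$params$spec, back$basis, back$params)
  expect_equal(ef1$energy, ef0$energy, tolerance = 1e-12)
  expect_equal(ef1$forces, ef0$forces, tolerance = 1e-12)
})
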