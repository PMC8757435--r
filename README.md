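# besselff

Neural-network interatomic potentials built on element-pair spherical
Bessel descriptors, written in R.

Molecular-dynamics studies of dense molecular and ionic liquids need a
potential-energy surface that is both accurate (ab initio-like forces) and
cheap (millions of force evaluations). `besselff` provides the
machine-learned middle ground: a differentiable model

```
E_pot = sum_i Omega(p_i, e_{s_i}) + E_0
```

where each atom contributes an energy predicted by a shared multilayer
perceptron `Omega` from (i) `p_i`, a vector of translation-, rotation- and
permutation-invariant *spherical Bessel descriptors* of its chemical
environment within a cutoff sphere, resolved per pair of chemical elements,

```
p_iJJ'nl = sum_{j in J} sum_{j' in J'} g_nl(r_ij) g_nl(r_ij') P_l(cos gamma_ijj')
```

and (ii) `e_s`, a short learned per-species embedding. The radial functions
`g_nl` derive from spherical Bessel functions, orthonormalized per angular
momentum and vanishing smoothly (value, slope and curvature) at the cutoff.
Forces are exact derivatives, obtained through a hand-written reverse-mode
pass and a matrix-free descriptor vector-Jacobian product, so the model can
be *trained directly on reference forces* — 3N labels per configuration
instead of one — with a log-cosh loss, Adam and a one-cycle learning-rate
schedule. Everything a force-field practitioner needs around the core model
is included:

- subsampling-aggregation **ensembles** (default 18 members on random 50%
  subsamples) whose predictive spread detects extrapolation;
- optional **long-range electrostatics**: a static-charge Coulomb baseline
  and a charge-equilibration model where a second network predicts
  environment-dependent electronegativities and the atomic charges solve a
  neutrality-constrained quadratic program, with exact forces through the
  solve;
- a velocity-Verlet / Nosé–Hoover **molecular-dynamics** engine, velocity
  autocorrelation functions, Green–Kubo diffusion coefficients with a
  tail-oscillation uncertainty, and bond-scan diagnostics;
- **extended-XYZ** input/output, versioned JSON model checkpoints, a
  synthetic-data generator with exact analytic labels, and a command-line
  interface (`inst/cli/besselff`).

## Worked example

Train a force field on synthetic ionic-box data whose energies and forces
are exact labels of an analytic Morse potential, then predict:

```r
library(besselff)

ds    <- generate_toy_dataset(300, seed = 42)          # 8-atom Na/Cl boxes
spec  <- descriptor_spec(r_cut = 3.5, n_max = 3, elements = c("Na", "Cl"))
basis <- build_radial_basis(spec$n_max, spec$r_cut)
fit   <- train_model(ds, spec, basis, training_config(epochs = 500, seed = 1))

tail(fit$history[, c("epoch", "loss", "val_force_mae", "val_energy_mae")], 1)
#>     epoch      loss val_force_mae val_energy_mae
#> 501   500 0.0741331    0.04637804    0.003328599

ef <- energy_and_forces(ds[[1]]$config, spec, basis, fit$params)
cat("predicted energy:", round(ef$energy, 4), " reference:",
    round(ds[[1]]$energy, 4), "\n")
#> predicted energy: -2.5023  reference: -2.4754
round(ef$forces[1:3, ], 3)          # eV / Angstrom
#>        [,1]   [,2]   [,3]
#> [1,] -0.063 -0.044 -0.071
#> [2,]  0.938 -0.905  1.431
#> [3,]  2.082 -0.542 -2.804
round(ds[[1]]$forces[1:3, ], 3)     # exact reference forces
#>        [,1]   [,2]   [,3]
#> [1,] -0.023 -0.073 -0.070
#> [2,]  0.907 -0.887  1.461
#> [3,]  2.047 -0.558 -2.768
```

The final validation force MAE (0.046 eV/Å) is about 4% of the validation
forces' mean absolute deviation (1.24 eV/Å): the network has genuinely
learned the potential, not the mean. Energies come out to a few meV/atom
even though the loss never saw an energy — only the constant offset is
fitted afterwards. From here, `train_ensemble()` adds uncertainty
estimates, `run_nvt()` + `compute_vacf()` + `green_kubo_D()` turn the model
into transport coefficients, and `bond_scan()` inspects single bonds:

```r
ff   <- make_nn_force_field(spec, basis, fit$params)
traj <- run_nvt(ff, ds[[1]]$config, temperature = 300, dt = 1,
                n_steps = 5000, tau = 100, seed = 7)
vacf <- compute_vacf(traj, max_lag = 1000)
green_kubo_D(vacf$Z, vacf$t[2] - vacf$t[1])   # m^2/s per ion type
```

See the vignette (`vignettes/spherical-bessel-force-fields.Rmd`) for the
model, its conventions and numerical choices in detail.

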