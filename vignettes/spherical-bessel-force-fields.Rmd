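---
title: "Neural-network force fields on spherical Bessel descriptors: models, training and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network force fields on spherical Bessel descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(besselff)
```

# The model

`besselff` implements a neural-network interatomic potential of the
additive-atomic-energy family. The potential energy of a configuration with
positions $r_i$ and species $s_i$ is

$$E_\mathrm{pot} = \sum_i \Omega(p_i, e_{s_i}) + E_0,$$

where $p_i$ is a vector of rotation-, translation- and
permutation-invariant descriptors of atom $i$'s chemical environment,
$e_{s}$ is a short learned embedding vector per species, $\Omega$ is a
multilayer perceptron shared by all atoms, and $E_0$ is a constant offset.
Because the energy is a sum of per-atom terms, the model applies to any
number of atoms and is invariant under relabeling identical atoms by
construction.

## Element-pair spherical Bessel descriptors

The environment of atom $i$ is encoded from the density of each chemical
element $J$ inside a cutoff sphere of radius $r_c$ (default 3.5 Å, the
radius at which accuracy/cost trade-offs saturate for dense molecular
liquids). The density is projected on products of radial functions
$g_{nl}(r)$ and spherical harmonics, and the projections are contracted
over the harmonic index $m$ into a generalized power spectrum. In the
purely real form used throughout the package,

$$p_{iJJ'nl} = \sum_{j \in J}\sum_{j' \in J'} g_{nl}(r_{ij})\,
g_{nl}(r_{ij'})\, P_l(\cos\gamma_{ijj'}),$$

with $P_l$ the Legendre polynomial and $\gamma_{ijj'}$ the angle subtended
at atom $i$. No complex arithmetic is needed; the equivalent
complex-projection form (sum over $m$ of $c\,c^*$ times $4\pi/(2l+1)$ —
this normalization constant is fixed so that both forms agree exactly, and
the test suite checks that equality against an explicit spherical-harmonics
oracle) exists only as a test oracle.

The radial basis is built from spherical Bessel functions: for each $l$,
primitive profiles combine $j_l(u_{l,n} r / r_c)$ at two consecutive zeros
$u_{l,n}, u_{l,n+1}$ of $j_l$ so that the value and slope vanish at $r_c$
(the curvature then vanishes too, by the radial differential equation), and
the primitives are orthonormalized per $l$ with measure $r^2\,dr$ through a
Gram–Schmidt step realized with the Cholesky factor of a Gauss–Legendre
Gram matrix. The published construction leaves the coefficient values to
the orthogonalization procedure rather than printing them, so the package
validates the basis by its defining invariants — orthonormality to $10^{-8}$
and smoothness at the cutoff to $10^{-6}$ — rather than against tabulated
numbers. Zeros of $j_l$ are found by bracketed root finding using the
interlacing property, starting from the exact zeros $n\pi$ of $j_0$.

With $0 \le l \le n \le n_{\max}$ there are
$n_B = (n_{\max}+1)(n_{\max}+2)/2$ radial functions and
$n_p = n_B\,n_{el}(n_{el}+1)/2$ descriptors per atom; for
$n_{\max} = 4$ and four elements that is 150 per atom, and 33 750 for a
225-atom configuration. Descriptors are stored flattened by element pair
($J \le J'$ in the order of the spec's element list), then $n$, then $l$;
this ordering is part of the checkpoint contract.

Conventions the package fixes where the construction leaves freedom:

* the central atom is excluded from its own density ($j \ne i$);
* atoms exactly at $r_{ij} = r_c$ contribute zero (open interval) —
  harmless because $g_{nl}(r_c) = 0$;
* for unordered pairs $J \ne J'$ the stored value is the full ordered
  double sum, which makes $p_{iJJ'} = p_{iJ'J}$ an identity.

Premixed (weighted-density) variants contract the pair-resolved descriptors
with a fixed symmetric weight table $\omega_{JJ'}$ — products of Pauling
electronegativities, products of atomic numbers, or a per-central-element
table — reducing the width to $n_B$ at a documented cost in discriminating
power. They exist for ablation studies; the default model keeps the pairs
separate.

## Network architecture

Each atom's input is its descriptor vector (optionally standardized, see
below) concatenated with the embedding row of its species
($n_{emb} = 2$ by default; wider embeddings add no information, only
reparametrization freedom, since the embedding is a function of the species
alone). The default hidden widths are 64:32:16:16:16 followed by a linear
single-output layer. Hidden layers use the Swish-1 activation
$x\,\sigma(x)$, which is smooth — important because forces are first
derivatives and training forces needs second derivatives; a SELU variant
($\alpha = 1.6732$, $\lambda = 1.0507$, no normalization) is provided for
comparison but its derivative discontinuity at the origin can imprint small
jumps on predicted forces, which is the documented reason Swish-1 is the
default. Between hidden layers the package applies per-sample
normalization (centering and scaling each atom's activation vector by its
own mean and variance, $\epsilon = 10^{-6}$); this carries no trainable
state across calls.

The order of operations inside a hidden layer is dense → normalize →
activate. Input standardization (per-feature shift/scale computed on the
training split and frozen into the checkpoint) is on by default: the raw
power-spectrum features span orders of magnitude, and whether the original
recipe standardized inputs is not stated, so it is exposed as a
configuration flag.

## Forces and differentiation

Forces are exact derivatives: $F_i = -\partial E_\mathrm{pot}/\partial r_i$
is evaluated by backpropagating through the network to get
$\partial E/\partial p_\alpha$ and contracting with the descriptor
vector-Jacobian-product operator, which never materializes the full
descriptor Jacobian and costs a small constant factor over one energy
evaluation. The R environment has no automatic-differentiation framework,
so the reverse pass of the MLP is hand-written; it is validated against
finite differences on every code path.

Training on forces needs one more derivative: the gradient with respect to
the parameters of the directional derivative
$\sum_\alpha v_\alpha \partial E/\partial p_\alpha$. The package computes
it by complex-step differentiation through the hand-written backward pass:
every operation in the network (matrix products, Swish-1, the per-sample
normalization written as $\mathrm{mean}((z-\bar z)^2)$ without complex
conjugation) is an analytic function, so evaluating the backward pass at
$X + i\varepsilon V$ and taking $\mathrm{Im}(\cdot)/\varepsilon$ with
$\varepsilon = 10^{-20}$ yields the mixed second derivative with no
subtractive cancellation — exact to machine precision, as the
finite-difference gradient tests confirm.

# Training

The loss is the mean log-cosh of scaled residuals,
$\langle \log\cosh((f_\mathrm{pred} - f_\mathrm{ref})/\sigma_f)\rangle$
over every Cartesian force component in a batch, with
$\sigma_f = 0.1$ eV/Å. It is quadratic for residuals below $\sigma_f$ and
linear above, which bounds each component's gradient by $1/\sigma_f$
(built-in clipping against outliers). Numerically it is evaluated as
$|x| + \log(1 + e^{-2|x|}) - \log 2$, which cannot overflow.

Optimization uses Adam (moment coefficients 0.9/0.999, $\epsilon=10^{-8}$ —
conventional defaults, as only the learning rates are prescribed) with a
batch size of 8 whole configurations and a one-cycle schedule repeated
every epoch: linear $10^{-3} \to 10^{-2}$ over the first 45% of an epoch's
iterations, back down over the next 45%, then $10^{-5}$ for the last 10%.
The text describing the schedule reads per-epoch ("the iterations in one
epoch"), so the sawtooth restarts each epoch; a `schedule_span = "run"`
flag provides the one-cycle-over-the-whole-run alternative. Weights start
from $N(0, 1/\sqrt{fan_{in}})$, biases at zero. Datasets are split 90/10
at random; the validation count is `floor(n/10)` (741 frames give
667/74). Training runs for 500 epochs by default and returns the final
epoch's parameters — no early stopping, matching converged-training
practice — together with a per-epoch history of train/validation force and
energy MAEs. Since the loss never sees the energy origin, a single
constant offset is fitted afterwards so the mean predicted and reference
energies coincide on the training split.

Energy-only training (`mode = "energies"`) is the documented ablation: the
same loss on per-atom energies with scale $10^{-2}$ eV/atom and the
gentler schedule $10^{-5}/10^{-4}/10^{-6}$. On the synthetic dataset it
reproduces the qualitative finding that energy-trained models predict
forces far worse than force-trained ones.

Because configurations never move during training, per-frame descriptors
and dense descriptor Jacobians are computed once up front; each step is
then pure (small) matrix algebra. The dense per-frame Jacobian is an
internal training optimization for few-atom frames — prediction and
dynamics always use the matrix-free pullback operator.

# Ensembles

`train_ensemble()` trains a committee (default 18 members) on independent
random subsamples (default 50%, drawn without replacement — the members see
"half the training data each", which distinguishes this from a classical
bootstrap; a with-replacement flag exists) of the training split, each with
a distinct initialization seed. `ensemble_predict()` returns member means
and sample (n−1 denominator; the convention is documented because either
is defensible) standard deviations for forces and energy. The spread is an
extrapolation detector: on a one-dimensional dimer problem the mean force
spread outside the training interval of separations exceeds the spread
inside it by close to an order of magnitude in the acceptance experiment.
The mean is also a usable, more outlier-robust predictor
(`make_ensemble_force_field()`).

# Long-range electrostatics

Two optional treatments complement the strictly short-ranged network:

* **Static charges**: `subtract_static_coulomb()` removes the point-charge
  Coulomb forces of a fixed per-element charge table from the reference
  forces before training; `make_static_coulomb_force_field()` adds the
  same contribution back at prediction time. (Subtracting with a negated
  table is *not* the inverse — the Coulomb energy is quadratic in the
  charges — hence the explicit `add_static_coulomb()`.)
* **Charge equilibration**: a second network (widths 16:16:16:1, Swish-1,
  sharing the same descriptors and embedding) predicts per-atom
  electronegativities $\chi_i$; the charges minimize
  $\sum_i (\chi_i Q_i + \tfrac12 J_i Q_i^2) + E_\mathrm{coul}(Q)$ under
  global neutrality, solved as a KKT linear system with a Lagrange
  multiplier. The hardnesses $J_i$ are per-element parameters (the
  per-element reading of "element-specific" is adopted); the Gaussian
  widths $\sigma_i$ are fixed to tabulated covalent radii.

The smeared Coulomb energy uses the Gaussian-charge convention
$E = \sum_{i<j} k Q_i Q_j\,\mathrm{erf}(r_{ij}/\gamma_{ij})/r_{ij} +
\sum_i k Q_i^2/(\sqrt{2\pi}\sigma_i)$ with
$\gamma_{ij} = \sqrt{\sigma_i^2 + \sigma_j^2}$ and
$k = 14.399645$ eV Å e⁻². The published expression truncates the on-site
convention, so the self term is fixed here as the $r \to 0$ limit of half
the pair interaction of an atom with its own image, which makes the energy
finite and consistent at coalescence; every internal oracle uses the same
convention. Whether $\sigma$ should also enter the on-site term
differently is an open convention; the limit-consistent choice above is
pinned and flagged in the documentation.

The total CENT energy is $E_\mathrm{short} + E_\mathrm{coul}(Q^*)$ at the
equilibrated charges. Its forces are exact: the charge response enters
through one adjoint solve of the same KKT matrix (so no differentiation
through the solver is required), and the position dependence of $\chi$
flows through the descriptor pullback. A finite-difference test
differentiates straight through the coupled model to confirm this.

Periodic electrostatics use the real-space minimum-image sum only. That is
adequate for the dense, strongly screened regime the package targets;
Ewald/PME reciprocal-space machinery is out of scope and systems with
long Debye lengths or surfaces are outside the validated domain.

# Dynamics and transport

`run_nvt()` integrates velocity Verlet with a single Nosé–Hoover
thermostat (coupling constant $\tau = 0.1$ ps by default, thermostat mass
$Q = N_f k_B T \tau^2$; a single thermostat rather than a chain, since
only the thermostat and $\tau$ are prescribed). The friction variable is
advanced in Trotterized half steps around the Verlet kick-drift-kick, so
switching the thermostat off leaves the exact symplectic NVE integrator:
energy-conservation fluctuations scale as $O(dt^2)$, which the tests check
over $dt \in \{0.25, 0.5, 1\}$ fs. Initial velocities are
Maxwell–Boltzmann with the center-of-mass drift removed, seeded.

`compute_vacf()` averages $Z_I(t) = \langle v_I(t_0)\cdot
v_I(t_0+t)\rangle$ over time origins (configurable stride, default every
frame) and over the ions of each type, using mass-weighted center-of-mass
velocities of the ion groups carried by the trajectory.
`green_kubo_D()` integrates $D = \tfrac13 \int_0^T Z\,dt$ by the
trapezoidal rule (cutoff defaulting to the full VACF length) and reports
as uncertainty half the spread of the running integral over a final
window — by default the last 10% of the interval, mirroring the
last-10-ps convention of production analyses. Unit conversion is
1 Å²/fs = $10^{-5}$ m²/s.

`bond_scan()` displaces one atom along a bond axis (151 points on
[1.05, 1.70] Å by default, matching the published experiment) without
moving any other atom and returns each model's force projection on the
axis; ensembles contribute mean ± standard deviation, which reproduces the
diagnostic used to visualize extrapolation on bond stretches.

# Synthetic data

`generate_toy_dataset()` makes the whole pipeline testable without any
download: independent frames are created by randomly packing ions into a
periodic box and jittering the coordinates, and labeled with the *exact*
energies and forces of an analytic Morse pair potential with a quintic
smooth cutoff. The default system — four Na and four Cl ions in a 7.5-Å
periodic box, unlike-pair well depth 0.45 eV at 2.5 Å, shallow like pairs,
jitter 0.1 Å — emulates, at reduced scale, the structure of a thermally
sampled ionic-liquid training database: multiple species, dense periodic
boxes, force magnitudes of order 1 eV/Å. Each generation runs a
finite-difference self-check of the labels on up to 10 random frames. All
randomness descends from one dataset seed through per-frame seeds.

What it deliberately does not emulate: electronic-structure many-body
effects (the ground truth is a pair potential, which an atom-centered
model can fit comparatively easily), molecular bonded topology, and
long-range electrostatics. Passing the parameter-recovery experiment
therefore demonstrates that the pipeline — descriptors, derivatives, loss,
optimizer — can drive the error to a small fraction of the force scale
when the ground truth is learnable; it does not by itself establish
accuracy on ab initio data.

# Problem sizes and numerical choices

The acceptance experiments run at sizes chosen so the full suite stays
comfortable on a single core: parameter recovery trains on 300 frames of 8
atoms for 500 epochs (force mode and energy mode); the ensemble experiment
trains 18 members of a reduced 16:8 architecture for 80 epochs on 48 dimer
frames — a deliberately small network for a one-dimensional problem. The
descriptor-cardinality check uses a full 225-atom, four-element molecular
box. Further pinned choices: Gauss–Legendre order 200 for the radial Gram
matrices; descriptor standardization floors degenerate feature scales at
1; the KKT solve refuses systems with reciprocal condition below
$10^{-12}$; dataset splits guarantee at least one frame on each side.

# Known limitations

* Real-space minimum-image electrostatics only (above).
* The dense per-frame descriptor Jacobian used by the trainer scales as
  $O(n_\mathrm{atoms}^2 n_p)$ in memory; training is therefore intended
  for few-hundred-atom frames or smaller, matching its use here.
* Reproducing the published ionic-liquid accuracy figures requires the
  original DFT-labeled database and multi-hour trainings; the package
  ships the machinery (extended-XYZ ingestion, the same training
  protocol) but its in-repo experiments are confined to the synthetic
  system.
* `SELUActivation`-style models are supported but exempt from the
  smoothness guarantees; their bond scans can show derivative artifacts,
  which is the expected behavior of that activation.
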