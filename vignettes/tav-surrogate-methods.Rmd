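---
title: "Surrogate modelling of TAV leaflet deformation and stress: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling of TAV leaflet deformation and stress: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the choices made where the design was
genuinely open. It states no empirical numbers beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## 1. The modelling chain

A transcatheter aortic valve (TAV) leaflet design is a triple
$\{a, b, \mathrm{SSL}\}$. The package turns a design into ground-truth-like
nodal fields and trains neural surrogates to shortcut that computation:

1. **2D contour** — attachment edge $y_a(x) = a\,e^{0.1053 x^2}$ (mm,
   $x$ in mm), free edge
   $y_f(x) = h\,(1 - \frac{e^{x^3 - m^3} - 1}{e^{-m^3} - 1})$ with
   $m = 10.9$ mm, and free-edge height
   $h = h_\mathrm{nom} + r\,(\mathrm{SSL} - \mathrm{SSL}_\mathrm{nom})$
   with $h_\mathrm{nom} = 13.3$ mm, $\mathrm{SSL}_\mathrm{nom} = 19.1$ mm,
   $r = 9.6$.
2. **Mesh** — a fixed-topology transfinite triangulation with 1381 nodes.
3. **3D suturing line** — $z(\theta) = p\,e^{b|\theta|}$, $p = 0.20$ mm,
   $\theta \in [-\pi/3, \pi/3]$, on a stent cylinder whose radius is solved
   so the 3D arc length equals SSL.
4. **Pseudo-FEA** — deterministic mounting + pressure-bulge + analytic
   stress synthesis (Section 4).
5. **Surrogates** — the autoencoder-based model-a and the direct model-d
   (Section 5), evaluated by Monte-Carlo cross-validation (Section 6).

## 2. Geometry: resolved ambiguities

**Free-edge curve.** The printed form of the free-edge expression is
typographically ambiguous. We adopt the reading
$y_f = h\,\bigl(1 - \frac{e^{x^3-m^3}-1}{e^{-m^3}-1}\bigr)$, the only parse
with sane boundary behavior: $y_f(0) = 0$ and $y_f(\pm m) = h$ exactly.
It is evaluated with `expm1` so the enormous exponents ($m^3 \approx 1295$)
neither overflow nor destroy the boundary identities, and with $|x|$ since
the leaflet is symmetric while $x^3$ is odd. A consequence worth knowing:
over a realistic solved half-width ($\approx 3.3$ mm $\ll m$) the curve is
numerically zero, so the 2D free edge is effectively the straight chord at
commissure height and $h$ influences the geometry only through its role in
the 3D free-edge sag of the synthetic mounting.

**Half-width.** The design fixes the attachment-edge *length* (= SSL), not
its $x$-extent. `solve_half_width()` finds the unique $x_{max}$ with
$\int_{-x_{max}}^{x_{max}} \sqrt{1 + y_a'(x)^2}\,dx = \mathrm{SSL}$
(arc length is strictly increasing in $x_{max}$), via bracketing and root
refinement on adaptive quadrature; conservation holds to $10^{-6}$
relative and is asserted in the tests.

**Stent radius.** One leaflet spans one third of the circumference
($\theta \in [-\pi/3, \pi/3]$; three identical leaflets). No stent radius
is prescribed, so the radius is the free variable solved so the 3D curve
length equals SSL — the "conserved between 2D and 3D" rule made
operational.

**Mesh.** 1381 is prime, so no tensor-product grid has exactly 1381 nodes.
The region between the two edges is meshed transfinitely with the two
commissure corners (where the edges meet) collapsed to single nodes:
$(n_u - 2)\,n_v + 2$ nodes, and $1381 - 2 = 197 \times 7$ gives a
$199 \times 7$ grid. Node $k$ sits at the same parametric $(u, v)$ in
every design, which is what makes fields comparable as flat 4143-vectors
across designs. Unrealizable node counts raise a configuration error
rather than silently re-meshing.

## 3. Material model

`strain_energy()` evaluates the modified Gasser–Ogden–Holzapfel energy
$$W = C_{10}\{e^{C_{01}(\bar I_1 - 3)} - 1\}
  + \tfrac{k_1}{2k_2}\sum_{i=1}^{2}\{e^{k_2(\bar I_{4i}-1)^2} - 1\}
  + \tfrac{1}{D}(J-1)^2$$
with the porcine-pericardium constants $C_{01} = 13.48$,
$C_{10} = 2.196$, $k_1 = 22.14$, $k_2 = 107.27$, $\kappa = 1.16\times
10^{-7}$, $\theta = 7.81^\circ$. Three open points and how we resolved
them:

* the printed energy does not show where the dispersion $\kappa$ enters;
  the default evaluates the formula exactly as written, and a standard GOH
  dispersion blend $E_i = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_{4i}
  - 1)$ is available behind `dispersion = TRUE`. At $\kappa \sim 10^{-7}$
  the two are numerically identical;
* $D$ (incompressibility penalty) is a numerical device, not a measured
  property; default $10^{-4}$, configurable;
* units of $C_{10}$, $k_1$, hence $W$, are interpreted as kPa, consistent
  with stresses reported in kPa. Documented, not asserted.

This module evaluates energy only; no stress tensors, no FE constitutive
update, no fitting — deliberately out of scope.

## 4. The synthetic pseudo-FEA generator

The original FE result sets are not deposited, so the package generates
stand-in ground truth. The generator is explicitly **not** a mechanics
solver; its contract is structural fidelity:

* attachment nodes sit exactly on the suturing line (arc-length-matched),
  and stay fixed under load (rigid stent);
* the free edge closes toward the valve axis (coaptation) with a sag
  proportional to the free-edge height;
* pressure adds a belly bulge, radially inward and downward, proportional
  to the load (120 mmHg default; 0 mmHg = no deformation) and vanishing
  identically on the suture line;
* stresses are smooth analytic fields in the parametric coordinates:
  S11 peaks near the suture line and the commissures (the load path),
  S22 in the belly, S12 antisymmetric across the midline; magnitude
  coefficients (600, 150, 100) kPa keep dataset-mean $|S_{11}|$ strictly
  dominant, matching the reported component ordering and placing NMeanE
  denominators at the several-hundred-kPa scale of real leaflet fields;
* every output is an infinitely differentiable function of
  $\{a, b, \mathrm{SSL}\}$, the property that puts sub-percent surrogate
  errors within reach — mirroring the regime of noise-free FE training
  data. Multiplicative Gaussian noise is available (`noise_sd`), default 0,
  because simulation-derived training data carries no appreciable noise.

What the generator does **not** emulate: leaflet–leaflet contact and the
0.1 friction coefficient, bending-dominated wrinkling, dynamic loading,
and any force balance. Passing tests on synthetic data therefore
demonstrate that the surrogate *pipeline* works on fields with the right
structure — not that the networks have learned valve mechanics.

**Low-rank oracle mode.** With `low_rank = TRUE` all fields are exact
linear combinations of 8 fixed basis fields with smooth design-dependent
coefficients, the first coefficient held constant. This gives a ground
truth for which an 8-number code is provably sufficient, with rank-8 PCA
as an independent bound; the tests use it to verify the autoencoder
pipeline end to end. The constant leading coefficient matters: the encoder
ends in a per-sample L2 normalization, which discards one degree of
freedom (overall scale), and a fixed-scale structure makes the normalized
code a lossless representation.

## 5. Networks and training

Architectures follow the reference layer widths exactly: mapping net
3 → 16(Softplus) → 16(Softplus) → 8(linear); decoder 8 → 512(Softplus) →
4143(linear); direct net 3 → 32 → 64 → 256 (Softplus) → 4143(linear). The
encoder's hidden width is not part of the reference description; default 512, mirroring the decoder.
The encoder's final "normalization" layer is likewise unspecified; default
is per-sample scaling of the 8-vector to unit Euclidean norm (a
batch-independent, deterministic parse of "normalization").

Training is minibatch Adamax (lr 0.002, $\beta_1$ 0.9, $\beta_2$ 0.999,
$\epsilon$ $10^{-7}$ — the Keras-documented defaults) on MSE, implemented
in RcppArmadillo with a dedicated `std::mt19937` stream per phase, so
every run is bit-reproducible given the seed on a single CPU thread.
Model-a trains in its three phases (autoencoder → mapping →
end-to-end fine-tune); fine-tuning is guaranteed not to end with a higher
training MSE than the assembled composite (the initial composite is kept
if a fixed-epoch schedule happens to end worse).

Inputs are min–max scaled to $[0,1]$ with the design-space bounds; fields
are standardized per feature with training-set statistics stored on the
model — unstated in the source recipe but necessary for stable
optimization at these output dimensions.

**Output-layer refinement (optional).** `train_config(refit_output =
TRUE)` follows the gradient phase with a ridge least-squares solve of the
final linear layer given the learned hidden features — an exact
minimization of the training objective over that layer. It is **off by
default**: with it on, the refitted direct net behaves like a 256-feature
ridge regression and overtakes the autoencoder-based model (whose
512-feature composite refit is under-determined at typical training sizes
of ~450), which changes the relative standing of the two families away
from what plain gradient training produces. The default protocol therefore
uses the plain optimizer schedule for anything that compares families, and
the refinement where a single regression is being pushed to its capacity
limit — notably the low-rank autoencoder recovery check, where the
question is whether the 8-code bottleneck can match the PCA bound, not how
far Adamax gets in a fixed budget.

**Schedules and problem sizes.** Epoch counts are free parameters here. Package
defaults are 2000 epochs per phase at batch 32. The cross-validation
drivers in the tests and the acceptance script use the package's
documented short schedule — autoencoder 45, mapping 800, fine-tune 35,
direct model 60 epochs, batch 32, on a 500-design dataset — chosen as the
point where errors are deep in the sub-percent regime and a full
Monte-Carlo round remains a desk-scale computation. The low-rank check
uses 200 designs and 150 autoencoder epochs with the refinement.

## 6. Evaluation protocol

Monte-Carlo cross-validation: per repeat, a seeded random $\rho\%$ sample
of designs (without replacement) trains the model; the exact complement
tests it; per-test-design metrics are averaged; mean ± sd across repeats
is reported. Per-repeat seeds derive deterministically from the master
seed. Shape errors: MeanE = mean nodal Euclidean distance, MaxE = largest
distance, both normalized by the circumcircle radius $R$ of the valve's
three commissures *on the true deformed shape* (NMeanE, NMaxE, in %).
Stress errors per component: MeanE = mean absolute nodal difference,
NMeanE normalizes by the true field's range, MaxE compares peak absolute
stresses (locations may differ), NMaxE normalizes by the true peak.

Resolved protocol details:

* **Commissures for $R$**: the attachment-edge endpoint of the leaflet,
  rotated by 0°, 120°, 240° about the valve axis (three-fold symmetry);
  taken from the *deformed* truth, matching the "true valve" reading.
* **Constant stress fields** make NMeanE undefined; this raises an error
  rather than silently reporting zero.
* The **mean-predictor baseline** ("always predict the training mean
  field") is run through the identical CV machinery and reported as a
  per-test-design MeanE distribution — the reference that shows the
  fields genuinely vary across the design space.

## 7. Numerical choices

* Arc-length quadrature: adaptive (`integrate`, rel.tol $10^{-12}$);
  root solves: `uniroot` with tolerances $\sim 10^{-10}$ relative.
* Softplus is evaluated overflow-safe ($x + \log(1+e^{-x})$ for large
  $x$); the L2-normalization layer guards against zero norm with an
  additive $10^{-24}$ under the square root.
* Weight init: Glorot-uniform from a seeded `mt19937`; shuffling uses the
  same generator family. No threading, no nondeterministic reductions.
* Field flattening is block order — $(x, y, z)$ or $(S_{11}, S_{22},
  S_{12})$ — documented in `flatten_field()`.
* Degenerate inputs fail loudly: non-finite design parameters, collinear
  commissures, constant stress fields, unrealizable mesh sizes, version
  mismatches on load.

## 8. Known limitations

* The pseudo-FEA fields are smooth functions of three parameters; real FE
  fields carry contact-induced localization and numerical noise that make
  surrogate errors larger and the two families' gap wider than anything
  measured here. Absolute error levels on synthetic data say nothing
  quantitative about FE-trained deployments.
* The 2D free edge is numerically flat under the adopted free-edge
  parse; if the originating CAD intent differs, the 2D contours (not the
  pipeline) would change.
* Single material, static load, circular deployment, no
  fluid–structure interaction — inherited scope limits of the modelled
  workflow.
* Training determinism is per-platform: identical seeds reproduce bitwise
  on the same BLAS/CPU, not necessarily across platforms.
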