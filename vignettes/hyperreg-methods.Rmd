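---
title: "Amortized hyperparameter learning for deformable image registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amortized hyperparameter learning for deformable image registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deformable registration aligns a moving image $m$ to a fixed image $f$ by a
dense spatial map $\phi$. Learning-based methods train a convolutional
network $g_{\theta_g}(m, f) = \phi$ over an image collection, so each new
pair is registered by a single forward pass. Every such method hinges on
loss hyperparameters — above all the regularization weight that trades
image-matching fidelity against deformation smoothness — and the standard
way to choose them is to train one network per candidate value and compare
on validation data. That grid search is slow, coarse, and must be redone
whenever the data, contrast, or task changes.

`hyperreg` implements the amortized alternative: a small fully connected
*hypernetwork* $h_{\theta_h}(\Lambda) = \theta_g$ maps the hyperparameter
values $\Lambda$ themselves to the full weight vector of the registration
network. Training samples $\Lambda$ anew at every optimization step, so one
trained model spans the whole hyperparameter landscape. At test time the
effect of any $\Lambda$ is a forward pass, which makes dense sweeps and
gradient-based hyperparameter optimization against a validation metric
essentially free.

## Model

### Registration function and deformation model

The registration network is a U-Net: four encoder convolutions (16, 32,
32, 32 channels by default) each followed by 2x max pooling, seven decoder
convolutions (32, 32, 32, 32, 32, 16, 16) interleaved with four
nearest-neighbour upsamplings, kernel size 3, LeakyReLU(0.2), and a final
linear convolution emitting one channel per spatial axis. Skip connections
concatenate the encoder outputs at 1/2, 1/4 and 1/8 resolution after the
first three upsamplings; the full-resolution encoder output is *not*
concatenated. This wiring is pinned by the parameter count: the 3D
configuration has exactly 313,507 trainable parameters
(`build_weight_spec(unet_config(3))$total_count`), and any learned
upsampling or an extra full-resolution skip would change it.

The network output is a stationary velocity field $v$ rather than a
displacement. The deformation is its group exponential
$\phi = \exp(v)$, computed by scaling and squaring: $v$ is divided by
$2^K$ and the resulting small displacement is composed with itself $K$
times ($K = 5$ by default). Composition uses linear interpolation of
displacements with edge clamping,
$u'(p) = u(p + u(p)) + u(p)$. This construction keeps $\phi$ invertible in
practice; the test suite checks that integrated smooth fields have strictly
positive Jacobian determinants and that integrating $-v$ undoes the warp.

Conventions, chosen once and used everywhere: 0-based voxel coordinates;
displacements in voxel units with the component axis last; warping is a
pull-back (the output at $p$ samples the input at $\phi(p)$); out-of-grid
samples clamp to the nearest edge, which avoids injecting zeros into
similarity losses. Physical spacing in mm enters only the surface-distance
metric.

### Hyper-loss

For hyperparameters $\Lambda = \{\lambda, \ldots\}$ the unsupervised
training loss is

$$(1 - \lambda)\, \mathcal{L}_{sim}(f, m \circ \phi; \lambda_{sim})
  + \lambda\, \mathcal{L}_{reg}(v),$$

with $\lambda \in [0, 1]$; scaling the similarity term by $(1 - \lambda)$
is what makes a bounded hyperparameter range possible. With label maps
available, a soft-Dice overlap term weighted by $\gamma \in [0, 1]$ is
added and the similarity coefficient becomes $(1 - \lambda)(1 - \gamma)$.
The coefficients deliberately do not sum to one.

The smoothness regularizer is
$\mathcal{L}_{reg} = \tfrac12 \sum_i \lVert \nabla v_i \rVert^2$ with
forward differences, *averaged* over voxels and components rather than
summed, so the balance point of $\lambda$ does not move with grid
resolution. The regularizer acts on the velocity field, matching the
right-hand side of its definition; regularizing the integrated
displacement instead is a different (also defensible) choice that we did
not take.

### Similarity losses

* **MSE**, scaled by $\sigma^{-2}$ where $\sigma$ is an image-noise
  estimate (default 0.05). The scaling changes where $\lambda$'s sweet
  spot sits, which is precisely the kind of sensitivity hyperparameter
  sweeps are for.
* **Local NCC** with window edge $w$: the mean over all fully contained
  $w \times w$ windows of the squared locally normalized correlation, with
  an $\varepsilon = 10^{-5}$ stabilizer in the denominator. Squared (not
  signed) correlation was chosen; with $w$ equal to the extent of a square
  image it reduces exactly to global squared NCC, which the tests exploit
  as an oracle. Windows are restricted to fully contained positions so
  that edge statistics are never computed from truncated neighbourhoods.
* **Mutual information** over `bins` histogram bins for cross-contrast
  registration. Intensities are min-max rescaled to $[0,1]$ and assigned
  to bins with triangular (partition-of-unity) weights, making the joint
  histogram — and hence MI — differentiable. A hard-binned MI is kept as a
  non-differentiable reference.
* **Soft Dice** over one-hot label channels for the semi-supervised term.
  During training, label channels are warped with linear interpolation so
  gradients flow; evaluation always warps label maps with
  nearest-neighbour interpolation.

All training losses carry hand-derived gradients with respect to their
image argument; backpropagation proceeds analytically through the warp
(bilinear-sampling gradients with respect to both intensities and sampling
locations), through every scaling-and-squaring composition, and through
the U-Net into the hypernetwork. Finite-difference checks in the test
suite guard every one of these paths at relative error below $10^{-3}$.

## Hypernetwork

Five fully connected ReLU layers of 32, 64, 64, 128, 128 units take the
normalized hyperparameter vector and a final linear layer emits all
registration weights; with the 3D U-Net this totals about 40.5 million
trainable parameters, essentially all in the final layer. Discrete
hyperparameters (NCC window, MI bins) are drawn from their legal value
list and normalized to $[0,1]$ by position between the extremes; the
hypernetwork interpolates between the discrete values, which is what makes
gradient-based tuning of a nominally discrete quantity meaningful.

**Initialization.** Hidden layers use fan-in-scaled random weights. The
final layer uses small-variance weights (gain $10^{-2}$) — and its *bias*
carries one conventional fan-in-scaled draw of the registration weights.
The emitted $\theta_g$ therefore starts at an ordinary initialization
scale for every input $\Lambda$, with a small input-dependent modulation
on top. We first implemented the final layer with a zero bias; the emitted
weights then start near zero, the U-Net is a dead function, and training
stalls at the identity deformation. Carrying a conventional init in the
bias is the standard variance-preserving remedy for hypernetworks and is
the package's deliberate choice.

## Hyperparameter sampling

During training, $\lambda$ is uniform on $[0, 1]$ except that a fraction
$r$ (default 0.2) of draws is placed exactly on the endpoints
$\{0, 1\}$, split equally. Endpoint over-sampling exists because the
corners correspond to similarity-only and regularization-only losses,
which a purely continuous prior visits with probability zero; raising $r$
improves agreement there at some cost at interior values. $\gamma$ is
sampled uniformly without endpoint mass, and each discrete hyperparameter
is drawn independently and uniformly from its list. A degenerate
`lam_range = c(a, a)` pins $\lambda$, making hypernetwork training
equivalent in expectation to a fixed-hyperparameter baseline — a useful
consistency check.

## Training

One optimization step = one random image pair + one hyperparameter draw
(batch size 1), Adam, initial learning rate $10^{-4}$ at full scale. The
learning rate halves after `plateau_window` steps without a new minimum of
the running-mean (window 100) training loss; the running mean is our
definition of "no improvement", since per-step losses under random
$\lambda$ draws are far too noisy to monitor raw. Baselines train the
registration weights directly with $\Lambda$ fixed and are otherwise
identical.

## Test-time tuning

With a trained model and labelled validation pairs, the hypernetwork
parameters are frozen and the *input* $\Lambda$ becomes the only trainable
quantity: gradient descent (Adam) on
$\mathcal{L}_{val} = 1 - \text{mean Dice}$ through the frozen network.
$\Lambda$ is reparameterized through a sigmoid so it respects $[0, 1]$ by
construction. The validation metric is pluggable; Dice is simply the
default. Dense sweeps (`sweep_hyper()`) tabulate any metric over a grid of
$\Lambda$ values — the batch equivalent of interactive slider exploration —
and a dense-sweep argmin (ties broken toward the smaller $\lambda$, i.e.
stronger regularization) serves as the reference the gradient optimizer is
tested against. For discrete hyperparameters the tuned optimum is mapped
to the nearest legal value. Both dataset-level (summing over pairs) and
per-pair tuning are available; dataset-level is the default.

## Evaluation metrics

Dice overlap in percentage points per label (labels absent from both maps
are reported missing, not zero); symmetric 95th-percentile surface
distance in mm, with boundaries extracted by face adjacency and the
pooled bidirectional nearest-distance set summarized by a
linear-interpolation quantile; and the standard deviation of the Jacobian
determinant, computed by central differences on the grid interior
(boundary voxels replicate the nearest interior value for full-grid output
and are excluded from the SD).

## Synthetic data

The generator stands in for brain-MRI cohorts. Each pair starts from a
base image of smoothed random blobs (argmax of $k$ smooth Gaussian fields
over a threshold) with one intensity per region and a matching label map,
lightly blurred (1 voxel) to mimic partial-volume softness at interfaces.
The fixed image is the base warped by a known smooth ground-truth SVF
(white noise smoothed at an 8-voxel scale, amplitude-scaled to 6 voxels by
default); its labels are warped consistently. The moving image is the
*unwarped* base after an optional contrast remap (monotone gamma, or an
inverted map for cross-contrast MI tests), an optional strictly positive
low-frequency multiplicative bias field (for local-NCC window tests), and
additive Gaussian noise (SD 0.05 by default). Registering $m$ to $f$
should therefore recover the known field.

Defaults were chosen so that the desk-scale study is informative: enough
deformation (6 voxels) that the unregistered Dice leaves headroom, enough
noise that similarity-only registration overfits, and smooth enough fields
that regularization-only registration underfits — giving the
regularization weight an interior optimum worth finding. What the
generator does *not* emulate: anatomy, k-space/tissue physics, partial
label coverage, or 3D volumes at scan resolution. Passing tests show the
machinery is correct and the amortization property holds under these
statistics; they are not evidence about any particular clinical dataset.

## Desk-scale study configuration

The shipped experiments reproduce the study designs at desk scale, as the
package's own choice of problem size: 2D $64^2$ pairs, a half-width U-Net
(encoder 8/16/16/16, decoder 16/16/16/16/16/8/8), the full stated
hypernetwork stack, Adam at $2 \times 10^{-3}$ for these small synthetic
images, and matched per-model budgets of 2,500 steps. Architecture counts,
loss identities and integration oracles are exact and run at the full
stated configuration; only the training studies are scaled down.

The amortization study registers across a mild within-scan contrast
mismatch (a gamma remap with exponent 1.3 on the moving image): with
perfectly corresponding intensities the similarity optimum coincides with
the true warp at every $\lambda$ and the regularization weight has nothing
to trade off, whereas real MRI pairs never match intensities exactly. It
trains five fixed-$\lambda$ baselines on one seed and three hypernetwork
models on separate seeds, and compares the median agreement across the
$\lambda$ grid.

The test-time-tuning and sampling-rate studies run on $48^2$ pairs with a
quarter-width U-Net and a 4-voxel deformation amplitude (deformation scaled
with the grid), within-contrast: there the trained model registers well and
the validation-loss landscape over $\lambda$ is smooth, which is what those
studies measure. Grids of $32^2$ were rejected during design — label
regions become a handful of voxels and Dice loses all resolution.

Two optimization details matter at this scale and were calibrated during
study design. First, the hypernetwork is markedly more sensitive to the
learning rate than the baselines: at $64^2$, $2\times10^{-3}$ trains
stably while modestly larger rates ($\geq 3\times10^{-3}$) collapse it
toward the identity deformation even though the same rates help the
baselines; the small $48^2$ studies use $10^{-3}$ for the amortized runs
for the same reason. Second, the plateau window of the learning-rate
schedule is model-class specific: a fixed-$\lambda$ baseline monitors a
clean loss and benefits from a short window (400 steps) that anneals the
rate late in training, but the amortized model's per-step loss mixes
random $\lambda$ draws, so new running-mean minima are rare events and a
short window starves it of learning rate long before convergence; it keeps
a window longer than the run (no annealing at this budget).

## Numerical choices and degenerate inputs

* Scaling-and-squaring interpolation and boundary policy (linear +
  edge clamping) are our choices; both are flagged for sensitivity, and
  the integration oracle tests bound their effect on a $32^2$ grid.
* Zero-variance NCC windows are handled by the $\varepsilon$ denominator;
  constant images give MI = 0 by convention (zero marginal entropy).
* Soft one-hot warping can leave a voxel with all-zero label mass near
  strong compressions; the Dice denominator carries an $\varepsilon$.
* Labels are non-negative integers; 0 is background everywhere.
* `integrate_svf(v, 0)` returns the displacement $v$ itself (zero
  compositions), which is the correct $K \to 0$ limit of the scheme.

## Known limitations

* Network evaluation and training are 2D; 3D is supported for the weight
  manifest/parameter counts and for all spatial transforms and metrics.
  The full-scale 3D MRI studies are out of scope.
* The conditional alternatives (pre-/post-/full-integrative conditioning)
  are implemented as buildable forward architectures with their wiring
  checks; no training loop is provided for them.
* The interactive slider workflow is realized as precomputed sweep tables,
  not a GUI.
* Training is single-threaded CPU R/Rcpp; it is adequate for the shipped
  desk-scale studies, not for volumetric cohorts.
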