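---
title: "Physics-guided neural-field retrieval of phase and absorbance from shot-noise-limited in-line holograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-guided neural-field retrieval of phase and absorbance from shot-noise-limited in-line holograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In-line X-ray holographic microscopy records a single intensity image --- the
interference of the unscattered reference beam with the wave scattered by the
sample --- at a detector downstream of the object.  The phase shift and
absorbance the sample imprints on the beam must be recovered computationally.
When the photon flux is low (a nanoscale waveguide source delivers on the
order of tens of photons per pixel per second), the hologram is shot-noise
limited: Poisson counting noise dominates, and classical alternating
projection reconstruction degrades badly.

`holofield` implements a physics-guided neural-field approach to this
inverse problem, together with everything needed to evaluate it: the
scalar-wave forward optics, a phantom and shot-noise simulator, the
Gerchberg--Saxton (GS) and residual U-Net baselines, and region-wise metrics.

## Forward model

A complex wavefield $U$ on an $L \times M$ pixel grid propagates between
parallel planes by the angular spectrum method (ASM): multiplication in the
discrete frequency domain by

$$ K(f_x, f_y; d) \;=\; \exp\!\Big[i\,2\pi \frac{n_\mathrm{med}}{\lambda}\, d
\sqrt{\,1 - (\lambda f_x / n_\mathrm{med})^2 - (\lambda f_y / n_\mathrm{med})^2}\Big], $$

with evanescent components (negative radicand) set to zero.  At the
propagation distances used here (tens of micrometres at $\lambda = 0.1327$ nm)
the entire FFT frequency lattice is propagating, so the hard cutoff is
inactive and propagation is exactly unitary --- the package's tests verify
power conservation and the round-trip identity to $10^{-10}$.

The object is a voxel volume of $N$ slices spaced $\Delta z$ apart, centred
on the approximate object depth $z'$ (default $N = 81$, spanning
$z' \pm 40\,\Delta z$).  Each voxel carries two occupancy values in $[0,1]$,
$o_\phi$ and $o_A$; transmission through a slice multiplies the field by
$\exp(i\,\phi\,o_\phi - A\,o_A)$, where $\phi$ (rad, negative --- X-ray
refractive indices are $n = 1 - \delta + i\kappa$ with $\delta > 0$) and
$A \ge 0$ are the per-object phase and absorbance coefficients.  The incident
beam is the unit field (holograms are background-normalized), the multi-slice
recursion runs from $z_N$ down to $z_1$, and one free-space jump over $z_1$
reaches the detector, where the intensity $|U_0|^2$ is recorded.

## Shot-noise model

Given a noise-free hologram $H$ and a mean photon count per pixel $\mu$, the
expected count at pixel $(p,q)$ is $\lambda_{pq} = \mu H_{pq}/\bar H$ with
$\bar H$ the spatial mean; counts are drawn $C_{pq} \sim
\mathrm{Poisson}(\lambda_{pq})$ under a caller-supplied seed and rescaled to
$H'_{pq} = C_{pq}/\mu$.  The draws are made in a fixed (column-major) order,
so a given (hologram, $\mu$, seed) triple is bit-reproducible.  Monte-Carlo
tests check the first two moments against the Poisson law within central
limit bounds.

## The neural field and its training

A small fully connected network maps normalized coordinates
$(\tilde x, \tilde y, \tilde z) \in [0,1]^3$ to the two occupancies.  The
input is lifted by a fixed Gaussian Fourier-feature projection
$[\sin(2\pi B c), \cos(2\pi B c)]$, $B \sim \mathcal N(0, \sigma^2)$
(default width 128, i.e. 64 random frequencies; $\sigma = 15$ for the
synthetic regime, 25 for the experimental geometry), followed by three dense
swish layers (width 128) and a two-channel sigmoid output.  Training is
full batch --- the forward model couples every voxel to every detector pixel
through the FFTs, so mini-batching pixels has no physical meaning --- and all
gradients are computed analytically in the package, including reverse-mode
differentiation through the FFT propagation (the adjoint of propagation by
kernel $K$ is propagation by $\bar K$).  A finite-difference check of the
end-to-end gradient is part of the test suite.

Training has two stages:

1. **Pre-training** (`pretrain_field()`, default 300 epochs at learning rate
   $10^{-3}$): the occupancies are regressed onto a stack of binary object
   mask labels --- the mask segmented from the in-focus hologram (back-
   propagated to $z'$), replicated over the axial window
   $z' \pm w_z \Delta z$ with $w_z \in [5, 10]$, zero elsewhere.  The mask is
   a *candidate region*, not a segmentation: the workflow deliberately uses a
   permissive gradient threshold (a fraction of the Otsu level) plus a small
   dilation, because a too-large candidate region costs little (the data term
   prunes it) whereas object pixels missed by the mask are driven to zero
   occupancy across all slices and are hard to recover later.
2. **Physics-constrained training** (`train_field()`, default 3000 epochs at
   $10^{-4}$): Adam minimizes $L_\mathrm{Data} + L_\mathrm{BC}$, the MSE
   between $|U_0|^2$ and the measured hologram plus the mean squared
   occupancy on the six faces of the volume (boundary values are zero; this
   suppresses the wrap-around fringe artifacts that would otherwise be
   reconstructed at the image borders, since no zero-padding is applied).

Two optimizer details matter and are exposed as parameters:

* **Warmup** (`warmup`, default 100 epochs of linear learning-rate ramp).
  After pre-training the occupancy fills the whole axial window, so the
  initial simulated hologram is far from the measurement.
* **Warm restarts** (`restart_every`, default 100 epochs): the Adam moment
  estimates are periodically re-initialized.  With a global full-batch
  forward model, the accumulated momentum aligns with a collective
  "scale the whole volume down" direction; uninterrupted, it can carry the
  iterate through the physical optimum into the saturated empty-volume state
  (a strong local minimum whose loss is the raw hologram variance).  In our
  experiments runs without restarts collapsed to that state for candidate
  masks covering more than roughly a fifth of the field of view, while
  restarted runs converged reliably.  Restarting touches only the optimizer
  state, never the loss.

**Early stopping** uses a patience criterion (default 200 epochs) on a
10-epoch moving average of $L_\mathrm{Data}$, active after `min_epochs`:
once the data loss reaches the shot-noise floor
($\approx \overline{\lambda}/\mu^2$), further epochs fit noise.  The
stopping point the method was introduced with is a visual criterion ("when
shot-noise patterns appear"); a loss-plateau patience is the closest
automatic analogue.

Phase and absorbance maps are extracted by summing each occupancy over the
label window and multiplying by the coefficients, so a one-slice object
reproduces its coefficient exactly and multi-slice occupancy accumulates.
The axial thickness of the synthetic objects is not resolvable at these
geometries (the depth of focus $\Delta x^2/\lambda$ spans the whole slice
volume), which is why the thin-object total coefficient interpretation is
used throughout: $\phi$ and $A$ are per-voxel-*column* totals.

**Coefficients.**  In synthetic benchmarking the per-object coefficients are
known and fixed (this mirrors the reference evaluation protocol, which fixes
them for comparability across methods); they enter as per-pixel coefficient
maps built from the object regions.  In experimental mode a single scalar
$(\phi, A)$ pair is initialized from literature values of the material and
optimized jointly with the network (`trainable_coeffs = TRUE`), with $A$
projected to remain nonnegative.

## Baselines

* **Gerchberg--Saxton** (`gs_reconstruct()`): detector amplitude constraint
  $\sqrt{H}$, object constraints $|t| \le 1$ and $\arg t \le 0$, run to
  residual convergence (default 500 iterations, early exit at $10^{-8}$).
  The propagation kernels are referenced to the plane-wave carrier (divided
  by their DC term) so the unit background keeps zero phase and the sign
  constraint acts on the transmission relative to the incident beam.  The
  iteration count and constraint set behind the reference comparison are not
  specified; this configuration is the standard in-line variant, and the
  acceptance band for its noisy-case error is correspondingly wide.
* **Residual U-Net** (`resunet_reconstruct()`): a three-stage residual
  encoder--decoder with skip connections (channel widths 32/64/128 by
  default; widths are free parameters of the reference description), swish
  activations, a sigmoid phase head scaled to the known maximum phase
  magnitude and a leaky-ReLU absorbance head, trained self-supervised on the
  single hologram through the same ASM forward code as the neural field.
  Convolutions, pooling, upsampling and their gradients are implemented
  in-package and verified against finite differences; pooling/upsampling
  adjoints are tested exactly.

## Metrics

`region_stats()`, `mae()`, `percentage_error()` /
`average_percentage_error()` (the unweighted mean over the three object
regions of the percentage error of the region-mean value), and `ssim_map()`
(Gaussian-window SSIM, $\sigma = 1.5$, $11 \times 11$ support,
$K_1 = 0.01$, $K_2 = 0.03$, no sample-covariance correction; the mean
excludes the half-window border).  The SSIM implementation is frozen against
an independent reference implementation on fixed pseudo-random images in the
tests.  `data_range` is set from the reference map's span (0.3 rad for
phase, 0.03 for absorbance on the default phantom) so SSIM is comparable
across methods.

## The synthetic phantom and what the desk-scale study shows

The reference phantom is three objects shaped like the letters alpha, beta
and gamma with phase shifts $-0.3, -0.2, -0.1$ rad and absorbances
$0.03, 0.02, 0.01$, on a $128 \times 128$ grid of 10 nm pixels, 100 um from
the detector; shot-noise levels $\mu \in \{1000, 500, 300, 100\}$.  The
glyphs here are rasterized from built-in stroke outlines (circular arcs and
segments with a stroke half-width of 0.06 of the glyph box); exact glyph
geometry is not critical because all quantitative evaluation is region-mean
based.  A parametric disc phantom backs the sharp-geometry oracle tests.

The package's test suite runs a reduced version of the benchmark chosen to
fit a desktop CPU: $64 \times 64$ pixels, object depth 25 um (scaled with
the grid so the first Fresnel-zone radius occupies the same fraction of the
field of view as at reference scale), $N = 13$ slices, $w_z = 5$, a width-40
network with 20 random frequencies, 100 pre-training epochs at
$5 \times 10^{-3}$ and 400 training epochs at $2 \times 10^{-3}$ (with the
warmup and warm-restart schedule above), three noise seeds per
$\mu \in \{1000, 300, 100\}$.  Two caveats of that scale are
worth recording:

* Region-mean statistics carry a shot-noise floor.  Estimating the mean
  absorbance $A_k$ of a region of $n_k$ pixels from a $\mu$-count hologram
  cannot beat $\sigma(\hat A_k)/A_k \approx 1/(2 A_k \sqrt{\mu n_k})$; at
  $64^2$ scale the three-region average of this floor at $\mu = 1000$ is
  about 12--15 %, compared with roughly 7 % at reference scale.  Absorbance
  errors from the desk-scale runs must be read against that floor ---
  agreement with the reference-scale values is not expected for the
  weak channel.  Phase, whose signal is ten times stronger, does not suffer
  a comparable floor at either scale.
* The faint gamma object sits at the detection limit of the mask
  segmentation at $\mu \le 300$; the permissive threshold keeps it inside
  the candidate region at the cost of a larger region, which the data term
  then prunes.

Within those limits the desk-scale benchmark reproduces the reference
behaviour: neural-field phase errors of a few per cent at $\mu = 1000$,
monotone degradation as $\mu$ falls, and a decisive advantage over GS at
every noise level.

## Numerical choices and degenerate inputs

* Frequencies live on the standard unshifted FFT lattice; rectangular pixels
  are supported (`dx`, `dy`), square by default.
* Evanescent zeroing is a hard cutoff (inactive at these geometries, see
  above).
* No zero-padding by default; the boundary-condition losses take the role of
  padding for the neural field, and the GS baseline accepts the wrap-around
  fringes as the reference protocol does.
* The back-propagation seed phase at the detector is zero (the measured
  intensity fixes only the amplitude).
* The dense-layer kernels can run in single precision
  (`field_network(..., precision = "single")`): float32 matrix products
  are about twice as fast here and training outcomes agree with double
  precision to well within seed-to-seed variation (the optimizer state,
  coefficients and all wave optics remain double).  The desk-scale
  training runs in the test suite use it; gradient-vs-finite-difference
  checks use the double path.
* All-constant in-focus images segment to an empty mask (not an error);
  an empty mask is a legal label stack (pre-training then drives both
  channels to zero everywhere).
* NaN/Inf in fields, maps or losses raise immediate errors; training
  divergence reports the epoch at which the loss left the finite range.
* The absorbance coefficient is projected to $A \ge 0$ when trainable.
* Sidecar JSON metadata must carry `scale` and `offset` for TIFF promotion;
  a missing key is reported by name.

## Known limitations

* Plane-wave geometry only: the cone-beam illumination of a real waveguide
  setup is treated through its effective plane-wave equivalent (magnified
  pixel size, effective distance), as configuration input.
* Thin-object coefficient semantics: 3-D morphology along the beam is not
  resolved, matching the depth-of-focus argument above.
* Experimental beamline holograms are not redistributable here;
  the experimental pathway (200 x 200 grid, experimental pixel and slice
  sizes, trainable coefficients) is exercised on a synthetic surrogate
  with known ground truth instead.  The surrogate keeps the synthetic
  encoding scale $\sigma = 15$: at desk-scale network capacity the
  higher experimental scale ($\sigma = 25$) makes the optimization
  unstable, and the surrogate's features are synthetic-regime features.
* Detector effects (read noise, PSF, flat-field error) are out of scope of
  the noise model.

## Reproducing the benchmark numbers

`scripts/acceptance.R` regenerates the headline baseline quantity from
scratch at full reference scale (it is fast because GS needs no training);
`run_benchmark()` drives the full method-by-noise grid and writes a results
table and manifest; the acceptance test file runs the desk-scale neural-field
benchmark described above.
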