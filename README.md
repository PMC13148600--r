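# holofield

Single-shot retrieval of **phase** and **absorbance** maps from
shot-noise-limited in-line X-ray holograms, using a physics-guided neural
field, with classical baselines and a quantitative evaluation harness.

## Who this is for

X-ray holographic microscopy with nanoscale waveguide sources runs at very
low photon flux: holograms arrive with mean counts of order 100–1000 photons
per pixel, and Poisson noise dominates. Classical Gerchberg–Saxton (GS)
iteration reconstructs noise-free holograms essentially perfectly but
degrades badly under shot noise. This package is for imaging scientists who
want a single-shot reconstruction that stays quantitative in that regime —
and the simulation/evaluation machinery to prove it.

## The method

The object is a voxel volume between the source and the detector, two
occupancy channels per voxel, `o_phi` and `o_A` in [0, 1]. A coordinate
neural field predicts the occupancies: normalized coordinates `(x, y, z)`
pass through a fixed Gaussian Fourier-feature encoding
`[sin(2πBc), cos(2πBc)]` (B ~ N(0, σ²)), three swish dense layers, and a
two-channel sigmoid output. A slice with occupancies `o` multiplies the
wavefield by

```
T_i = exp(i φ o_phi − A o_A)
```

(φ < 0 in rad, A ≥ 0), and the field propagates slice to slice by the
angular spectrum method,

```
U_{i−1} = ASM_dz{ U_i · T_i },    H_sim = |ASM_z1{ U_1 · T_1 }|².
```

Training is self-supervised on **one** hologram: after pre-training the
occupancies on a binary object-mask label stack (segmented from the
back-propagated in-focus image, replicated over `z' ± w_z·dz`), Adam
minimizes `MSE(H_sim, H) + L_BC`, where `L_BC` pins the occupancies to zero
on the six faces of the volume. All gradients — through the FFTs, the slice
transmissions and the network — are computed analytically in the package.
Maps are extracted as `φ · Σ_window o_phi` and `A · Σ_window o_A`.

Baselines: `gs_reconstruct()` (alternating projections with `|t| ≤ 1`,
`arg t ≤ 0`) and `resunet_reconstruct()` (a residual U-Net trained through
the same forward model). Evaluation: region means, MAE, Gaussian-window
SSIM, and region-averaged percentage errors.

## Worked example

Simulate the three-letter phantom (α, β, γ: phases −0.3, −0.2, −0.1 rad,
absorbances 0.03, 0.02, 0.01), add shot noise at μ = 1000 photons/pixel,
reconstruct, and score:

```r
library(holofield)

grid  <- wavefield_grid(64, dx = 10e-9, wavelength = xray_wavelength(9.344))
depth <- depth_grid(z_prime = 25e-6, dz = 20e-9, n_slices = 13)
ref   <- render_phantom(default_phantom(64, dx = 10e-9, z_prime = 25e-6))
H0    <- simulate_hologram(ref$phase, ref$absorbance, 25e-6, grid)
snl   <- apply_shot_noise(H0, mu = 1000, seed = 1)

nf <- neural_holo_reconstruct(snl, grid, depth,
        phi = ref$phase, A = ref$absorbance,   # known per-object values
        n_freq = 20, hidden = c(40, 40, 40), net_seed = 500001,
        pretrain_epochs = 150, pretrain_lr = 5e-3,
        epochs = 600, lr = 2e-3, patience = NULL)
gs <- gs_reconstruct(snl, grid, distance = 25e-6)

refs <- c(alpha = -0.3, beta = -0.2, gamma = -0.1)
average_percentage_error(nf$phase, ref$masks, refs)$average
#> [1] 1.5
average_percentage_error(gs$phase, ref$masks, refs)$average
#> [1] 38.0
```

The two numbers are the average (over the three objects) percentage error
of the region-mean reconstructed phase: the neural field recovers the phase
to about 1 % at this noise level while GS is tens of per cent off, its
magnitudes biased towards zero. `run_benchmark()` drives the full
method × noise grid and writes a results table plus a manifest;
`summarize_benchmark()` gives seed medians.

A thin CLI over the same functions is installed at `inst/cli/holofield`
(subcommands `simulate`, `mask`, `gs`, `nf`, `resunet`, `evaluate`,
`benchmark`).

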