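---
title: "Phasor-FLIM and SHG analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-FLIM and SHG analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorFLIM)
```

## The measurement model

A pulsed laser at repetition rate $f$ (MHz) excites the sample every
$T = 1000/f$ ns. Each pixel accumulates a histogram $c_k$ of photon
arrival times over $n$ uniform bins spanning one period. The expected
histogram is modeled as the *periodic* convolution of a Gaussian
instrument response function (IRF, standard deviation $\sigma$, centered
at $t = 0$) with a mixture of exponential decays
$\sum_i a_i \tau_i^{-1} e^{-t/\tau_i}$, where the amplitudes $a_i$ are
intensity fractions and $\tau_i = 0$ denotes an instantaneous, coherent
(SHG-like) component that contributes the wrapped IRF shape itself.
Observed counts are independent Poisson draws around this expectation.

The phasor transform maps each pixel to
$g = \sum_k c_k \cos(\omega t_k) / N$,
$s = \sum_k c_k \sin(\omega t_k) / N$ with $\omega = 2\pi f$ (rad/ns,
harmonic 1) and $N = \sum_k c_k$. Key properties the package's tests
exercise:

* **Semicircle law.** Mono-exponential decays satisfy
  $(g - \tfrac12)^2 + s^2 = \tfrac14$; $\tau = 0$ sits at $(1, 0)$ and
  $\tau \to \infty$ approaches the origin.
* **Linearity.** The phasor of a sum of signals is the intensity-weighted
  mean of their phasors; mixtures lie on the segment joining their
  endmembers, which is what `linear_unmix_two()` inverts.
* **IRF cancellation.** Convolution multiplies every Fourier harmonic by
  the same complex factor. Calibrating against a reference of known
  mono-exponential lifetime (`calibration_from_reference()`) estimates
  that factor as a rotation `delta_phi` and modulation scale
  `mod_factor`, which `apply_calibration()` divides out. Because the
  same factor applies to every pixel acquired under the same response,
  a single reference calibrates all channels at the same $\omega$.

The phase lifetime $\tau_\phi = s/(g\omega)$ is the headline per-region
statistic; the modulation lifetime
$\tau_m = \omega^{-1}\sqrt{1/(g^2+s^2) - 1}$ is provided as the standard
companion (the two agree exactly on the semicircle, and $\tau_m >
\tau_\phi$ for mixtures, a useful heterogeneity check).

## Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `rep_rate` | MHz | 80 | Ti:Sapphire repetition rate of the emulated instrument. |
| `n_bins` | — | 256 | Digital frequency-domain instruments do not expose a bin count; 256 makes the midpoint-rule discretization error of the first harmonic $\lesssim 10^{-4}$, far below photon noise. |
| `irf_sigma` | ns | 0.1 | Instrument response width is never published for the emulated system; 0.1 ns is typical of PMT-based multiphoton FLIM. Calibration removes its effect, so results are insensitive to the exact value — which is the point of the design. |
| `tau_ref` | ns | required | The coumarin-like reference lifetime is deliberately a parameter, never a constant: the emulated study names the fluorophore but not its lifetime. |
| `pixel_size` | µm | 0.195 | A 100 µm lateral field of view at 512 px. Pixel size is *linear* everywhere in this package; source descriptions of "pixel size 0.207 µm²" are ambiguous between linear size and area, so the canonical config field is the linear one. |
| cursor radius | — | 0.05 | Cursor radii are study-unspecified; 0.05 resolves the ~0.55 phasor distance between SHG and 2.2 ns elastin with wide margin. The pipeline uses 0.12–0.15 together with a 3×3 phasor median filter to keep single-pixel Poisson noise (sd ≈ $1/\sqrt{2N}$) inside the cursor. |
| `harmonic` | — | 1 | All reported quantities use the first harmonic; higher harmonics are accepted but experimental. |

## What the synthetic scenes emulate — and what they do not

`make_label_map()` composes spatial patterns in draw order (later
components overwrite earlier ones; last-wins is the simplest reproducible
layering): curved elastin/collagen fibers are dilated correlated random
walks, cellular NAD(P)H regions are smoothed-noise blobs, red blood cells
are discs, background is uniform. Each component targets an area
*coverage* fraction; blobs hit it exactly (quantile threshold), fibers
and discs stop at the first pattern that crosses the target, so realized
coverage overshoots by at most one fiber (≈2 % of the frame at default
sizes).

The default palettes encode the study conditions: healthy scenes balance
elastin (2.23 ns) against collagen (SHG, $\tau = 0$) at 12 %/12 %
coverage; tumor scenes are elastotic (20 % elastin at 2.31 ns, 3 %
collagen, no red blood cells). NAD(P)H uses a 0.4/3.2 ns free/bound
mixture at 70:30, red blood cells 0.2 ns, lipopigments 0.6 ns — the
fiber lifetimes are the reported fingerprints; the cellular values are
field-typical placeholders, all overridable per component. Elastin's
channel weight of 0.3 in the SHG channel reproduces the hallmark
long-lifetime contamination of the 405/10-like filter by elastin
fluorescence.

The generator intentionally omits optical blur (no PSF), emission-spectrum
structure beyond channel weights, detector afterpulsing, mosaic stitching
and multi-FOV correlation. Passing tests therefore demonstrate that the
*analysis* is correct under Poisson statistics and a Gaussian IRF — not
that it is robust to scattering, bleed-through spectra, or segmentation on
genuinely low-contrast clinical tissue.

## Numerical choices

* **Bin centers** define $t_k$ in all sums (midpoint rule, second-order
  accurate for smooth decays).
* The expected histogram is evaluated by 8× oversampled midpoint
  quadrature of the wrapped exponentially-modified-Gaussian density; the
  wrap sums $k = -1, \dots, \lceil 40\tau/T \rceil$ periods, and the
  scaled complementary error function switches to its asymptotic
  expansion where $e^{z^2}$ would overflow. Histograms are renormalized
  to the requested total exactly (photon conservation to 1e−6 relative is
  a tested invariant).
* **Invalid pixels** (zero photons, $g \le 0$ lifetimes, modulus > 1)
  propagate as flags (`NA` + validity mask); no metric ever averages over
  a silent zero.
* **Unmixing** clips fractions to [0, 1] and reports the perpendicular
  residual instead of failing off-segment: noisy mixtures are the normal
  case.
* **Cursor ties** (a pixel exactly equidistant from two cursor centers)
  go to the first-listed cursor; otherwise assignment is nearest-center
  and order-independent.
* The exact signed-rank null distribution is built by dynamic programming
  over doubled midranks (doubling keeps tied half-ranks integral); zero
  differences are dropped before ranking, the classical rule, and the
  two-sided p is $2\min(P(W \le w), P(W \ge w))$ capped at 1. Above
  $n = 25$ a normal approximation with continuity and tie correction
  takes over.

## Design choices where the design was open

* **Collagen area in the pipeline** is the SHG-channel segmentation
  *gated by the SHG cursor* at $(1, 0)$. Thresholding alone would count
  elastin fluorescence leaking through the SHG filter as collagen —
  precisely the confound the combined FLIM+SHG design exists to remove.
  `segment_fibers()` itself stays a pure intensity operation; the gating
  is composed at the pipeline level.
* **Collagen percentage** uses the full field-of-view area as the
  denominator; fiber *balance* questions should use the ECI, which is
  denominator-free. Frames with no segmented fiber area at all have an
  undefined ECI and are excluded from group statistics with a logged
  count.
* **Pairing unit** for the signed-rank test is the frame within a
  sample's region batch; `wilcoxon_signed_rank()` accepts any paired
  vectors, so patient-level aggregation is a one-line alternative and
  neither granularity is claimed as canonical.
* **Centroids** are intensity-weighted by default, matching the
  photon-weighted semantics of the phasor itself; an unweighted mode
  exists for sensitivity checks.
* **Median filtering** of phasor coordinates is off by default at the
  module level (the emulated instruments do not document spatial
  smoothing) but on (3×3) in the pipeline defaults, where per-pixel
  cursor membership at realistic counts needs it.

## Problem sizes

The test suite and acceptance script run on deliberately small instances
chosen as sufficient for their statistical claims: 48–128 px scenes,
1e4–1e6 photons per decay, 50 regions of 2e4 photons for lifetime
recovery (phasor noise of an aggregate with $N$ photons scales as
$1/\sqrt{2N}$, so 2e4 photons give ≈0.03 ns per-region scatter and the
50-region mean resolves 0.005 ns), and 2000 replicates for the null
calibration of the exact test.

## Known limitations

Two-component unmixing only (no blind multi-component separation); no
fitting-based lifetime estimation; circular cursors only; no PSF or
spectral simulation; single-FOV analysis (no stitching); the cellular
lifetime palette is nominal rather than tissue-calibrated. These bounds
follow the method's scope: cursor-based phasor discrimination of fiber
types and their area balance.
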