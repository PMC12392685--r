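# phasorFLIM

Fit-free, phasor-based analysis of time-resolved multiphoton microscopy of
tissue autofluorescence, combined with second harmonic generation (SHG)
imaging of collagen. The package targets the question pathologists ask of
unstained lung-tissue sections: *what is the balance of elastin and collagen
in this field of view, and how does it differ between healthy and tumor
regions?* Tumor stroma frequently shows **elastosis** — excess elastin
deposition — which phasor lifetime analysis can separate from collagen
without staining.

Because raw clinical FLIM stacks are rarely shared, the package includes a
first-class synthetic-scene generator with known ground truth (component
label maps, areas, lifetimes), so the entire pipeline is testable end to
end: simulation → phasor transform → reference calibration → cursor
selection → fiber segmentation → ECI / collagen-percentage metrics → paired
nonparametric statistics.

## The model

Each pixel of a FLIM acquisition is a photon-arrival histogram `c(t)` over
one laser period `T = 1000 / f_rep` ns (80 MHz → 12.5 ns). Its **phasor** at
angular frequency `ω = 2π f_rep` is

    g = Σ c(t) cos(ωt) / Σ c(t),    s = Σ c(t) sin(ωt) / Σ c(t)

A mono-exponential decay with lifetime τ maps to the **universal
semicircle**:

    g = 1 / (1 + (ωτ)²),    s = ωτ / (1 + (ωτ)²),    (g − ½)² + s² = ¼

Mixtures fall inside the semicircle on the segment joining their component
phasors (law of linear combination), with position given by the intensity
fractions. Coherent SHG has zero lifetime and sits at `(g, s) = (1, 0)`.
The instrument response is cancelled by calibrating against a reference of
known mono-exponential lifetime: the rotation and modulation scale that
move the measured reference phasor onto its theoretical point are applied
to every pixel. The **phase lifetime** is `τ_φ = s / (g ω)`.

Fiber balance per field of view is summarized by the Elastin/Collagen
Index over segmented areas,

    ECI = (Elastin Area − Collagen Area) / (Elastin Area + Collagen Area)

which is 0 for a balanced network, +1 for pure elastin (elastosis), −1 for
pure collagen, and by the collagen percentage of the field of view. Paired
healthy-vs-tumor frames are compared with an exact Wilcoxon signed-rank
test (full null enumeration up to n = 25).

## Worked example

```r
library(phasorFLIM)

# calibration, as measured on a 2.5 ns mono-exponential reference
ref <- simulate_reference(2.5, total_counts = 1e7, seed = 42)
cal <- calibration_from_reference(phasor_transform(ref), 2.5)
cal
#> <phasor_calibration> delta_phi = +0.00047 rad, mod_factor = 1.00132 (tau_ref = 2.5 ns)

# a healthy-like scene: balanced elastin / collagen fibers, cells, RBCs
sim <- simulate_scene(healthy_scene_config(seed = 42))
fib <- apply_calibration(phasor_transform(sim$stacks$fiber), cal)
shg <- apply_calibration(phasor_transform(sim$stacks$shg), cal)

region_centroid(fib, sim$ground_truth$component_masks$elastin, "elastin")
#> <fingerprint> 'elastin': (g, s) = (0.4434, 0.4981), tau_phi = 2.235 ns, n = 1539
region_centroid(shg, sim$ground_truth$component_masks$collagen_shg, "collagen (SHG)")
#> <fingerprint> 'collagen (SHG)': (g, s) = (1.0000, 0.0005), tau_phi = 0.001 ns, n = 2097

# fiber areas: elastin from the fiber-fluorescence channel; collagen from
# the SHG channel, gated by a phasor cursor at (1, 0) so that elastin
# fluorescence leaking through the SHG filter is not counted as collagen
e_mask <- segment_fibers(stack_intensity(sim$stacks$fiber))
c_mask <- segment_fibers(stack_intensity(sim$stacks$shg)) &
  cursor_mask(median_filter_phasor(shg, 3), phasor_cursor(c(1, 0), 0.12, "shg"))
frame_metrics(e_mask, c_mask, pixel_size = 0.195, frame_id = "healthy_demo")
#>       frame_id elastin_area_um2 collagen_area_um2 fov_area_um2        eci collagen_pct elastin_pct
#> 1 healthy_demo         58.52048           79.5483     623.0016 -0.1522996     12.76855    9.393311
```

The elastin fingerprint recovers its generating 2.23 ns lifetime on the
semicircle; the SHG population sits at (1, 0); the healthy frame's ECI is
near 0 (balanced fibers). `run_pipeline(default_run_config(seed = 1))`
runs the full paired healthy/tumor batch and writes per-frame metrics,
fingerprints, group statistics, phasor plots and color-coded maps to a
report directory.

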