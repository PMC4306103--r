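# mmreg

Non-rigid registration of ultrasound (US) and magnetic-resonance (MRI)
image pairs acquired with a dual-modality contrast agent (magnetic
microbubbles, MMBs). The agent brightens the US echo inside the region
where it accumulates and darkens the T2\*-weighted MR signal, giving both
modalities a well-delineated common region of interest — which is what
makes intensity-based US–MRI registration tractable.

The package is aimed at researchers in multimodal medical image analysis
who want a fully reproducible, ground-truth-validated implementation of
this registration chain:

1. **Segmentation** — semi-automatic region-based (Chan–Vese) active
   contour on each modality, minimizing

   F(c₁,c₂,C) = μ·Length(C) + ν·Area(inside C)
   + λ₁₁ Σ_inside (I₀−c₁)² + λ₂₂ Σ_outside (I₀−c₂)²

   over a level-set field (defaults μ = 0, λ₁₁ = λ₂₂ = 1; area weight
   ν = 100 without / 2000 with contrast enhancement). Registration
   consumes the masked intensity images.

2. **Robust optical flow** — the displacement field (u, v) between the
   masked MRI (reference) and masked US (floating) minimizes a robust
   data + smoothness objective coupled quadratically (weight λ₂) to an
   auxiliary field (û, v̂) that carries a nonlocal L1 term (weight λ₃);
   the auxiliary update is a closed-form weighted median (the proximal
   median of the neighbor values and a candidate set spaced λ₃/λ₂).
   Optimization is coarse-to-fine over a Gaussian pyramid with three
   warping steps per level and two-stage graduated non-convexity
   (quadratic → generalized Charbonnier). Defaults: λ₁ = 5, λ₂ = 1e2,
   λ₃ = 1.

3. **Evaluation** — RMS, PSNR (= 20·log₁₀(1/RMS) on [0,1] images),
   Pearson correlation, and mutual information from the joint histogram;
   a registration shows the *normal variation* pattern when RMS falls
   while the other three rise.

4. **Synthetic phantom** — a dual-modality rendering of a "U"-shaped
   tube (9 mm outer / 7 mm inner diameter, 4 px/mm) with three 5 mm disc
   targets, tissue-locked speckle, and analytically specified
   ground-truth deformations, so every stage is testable without
   acquisitions. A rigid FFT phase-correlation baseline is included for
   comparison experiments.

See `vignettes/methods.Rmd` for the full model description, parameter
semantics and design rationale.

## Worked example

Simulate an enhanced phantom pair deformed by the standard study
deformation (a 3, −2 px translation plus two smooth local bumps), then
segment, register and evaluate in one call:

```r
library(mmreg)

cfg <- pipeline_config(
  phantom = phantom_spec(enhancement = TRUE, deform = deform_study()),
  seed = 1L)
run <- run_pipeline(cfg)
run
#> <mmreg_run>
#> <comparison_verdict>
#>   before: <metrics_report>  RMS 0.1578 | PSNR 16.0359 dB | COR 0.8465 | MI 0.5262 bits (256 bins, 65536 px)
#>   after:  <metrics_report>  RMS 0.0643 | PSNR 23.8320 dB | COR 0.9712 | MI 0.7948 bits (256 bins, 65536 px)
#>   NORMAL variation (dRMS -0.0935, dPSNR +7.7962, dCOR +0.1246, dMI +0.2686)
```

Registration cuts the intensity RMS between the masked segmentations by
more than half (PSNR +7.8 dB) and raises correlation and mutual
information — the normal-variation verdict. The manifest records every
stage: here the US segmentation overlaps the true ROI with Dice 0.94
(`run$manifest$segmentation$dice_vs_truth$floating`). Re-running the
same deformation *without* the contrast agent (`enhancement = FALSE`,
ν = 100) segments poorly and fails to register — the package reproduces
that with-vs-without-agent contrast across seeds.

Individual stages are exported (`render_phantom()`, `evolve_contour()`,
`estimate_flow()`, `warp_image()`, `compute_metrics()`,
`phase_correlate()`), flow fields are written as Middlebury `.flo`, and
`inst/cli/mmreg.R` provides a command-line wrapper
(`simulate` / `segment` / `register` / `register-baseline` / `evaluate` /
`pipeline`).

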