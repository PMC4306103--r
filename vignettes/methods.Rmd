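---
title: "Methods: dual-modality phantom registration with active contours and robust optical flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality phantom registration with active contours and robust optical flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mmreg)
```

# The problem

Ultrasound (US) and magnetic-resonance (MR) images of the same anatomy are
complementary — US is real-time and cheap, MRI has superior soft-tissue
contrast — but fusing them requires registration, and intensity-based
registration across these two modalities is notoriously fragile: B-mode
images are dominated by speckle, and US and MR intensities are not related
by any simple mapping. Magnetic microbubbles (MMBs), a dual-modality
contrast agent, change the economics of this problem: the gas bubble
strongly brightens the US echo inside the region where the agent
accumulates, while the embedded superparamagnetic iron oxide shortens T2*
and *darkens* the corresponding MR signal. Both modalities therefore
acquire a well-delineated, agent-defined region of interest.

`mmreg` implements the full registration chain built on that idea:

1. **Segmentation.** Both images are segmented semi-automatically with a
   region-based (Chan–Vese) active contour. Registration then operates on
   the *masked intensity images* (intensity inside the contour, zero
   outside), which removes most of the speckle and background and — this
   is the key point — reduces the multimodal problem to aligning two
   bright regions of comparable support.
2. **Registration.** A dense displacement field between the masked MRI
   (reference) and masked US (floating) is estimated with a robust
   optical-flow model whose flow is coupled to a median-filtered auxiliary
   field, minimized coarse-to-fine with graduated non-convexity (GNC).
3. **Evaluation.** Alignment quality is scored with RMS, PSNR, Pearson
   correlation, and mutual information; a result shows the
   *normal variation* pattern when RMS decreases while the other three
   increase after registration.

Because the original phantom acquisitions are not available, the package
ships a synthetic dual-modality phantom generator with known ground truth;
every stage is validated against it.

# Segmentation model

The active contour minimizes

$$F(c_1,c_2,C) = \mu\,\mathrm{Length}(C) + \nu\,\mathrm{Area}(\mathrm{inside}\,C)
 + \lambda_{11}\!\!\int_{\mathrm{inside}(C)}\!\!(I_0-c_1)^2 +
 \lambda_{22}\!\!\int_{\mathrm{outside}(C)}\!\!(I_0-c_2)^2 ,$$

realized on a level-set field $\phi$ (inside: $\phi \ge 0$) with the
smoothed Heaviside $H_\varepsilon(\phi)=\tfrac12(1+\tfrac2\pi
\arctan(\phi/\varepsilon))$, $\varepsilon = 1$ px, and its derivative as
the regularized delta. This is the canonical discretization of this energy
family. Two numerical choices deserve explanation:

* **Region means.** $c_1, c_2$ are the $H_\varepsilon$-weighted averages
  of the image. They are the exact minimizers of the regularized fit
  terms, so the alternation "update $c$, descend in $\phi$" can only lower
  the energy — the package's descent certificate tests rely on this. At
  convergence they coincide with the plain means inside/outside the curve.
* **Update scheme.** The descent step is normalized (the largest $\phi$
  update per iteration equals `step_size`) and applied over the whole
  domain, i.e. all level sets move, which is the standard extension that
  frees the model from its initialization band. The initial $\phi$ (circle
  or rectangle, the "semi-automatic" user input) is clamped to $\pm 5$ px:
  a thin interface lets every pixel change side within a few steps, where
  an unclamped signed distance would need hundreds of iterations to flip
  far-from-contour pixels. Iteration stops at `max_iters`, at a mean
  $|\Delta\phi|$ tolerance, or once the partition has been stable for five
  consecutive iterations (with a normalized step, $|\Delta\phi|$ never
  vanishes on its own); borderline pixels oscillating with period two
  trigger step halving.

**Parameters.** $\mu \ge 0$ weights curve length; the default is 0 (kept
switchable), which avoids merging nearby objects — here the tube and the
disc targets. $\lambda_{11}=\lambda_{22}=1$. The area weight $\nu$ (in
8-bit intensity units, see below) is the operating parameter: 100 for
unenhanced acquisitions and 2000 with the contrast agent
(`select_nu()`), reflecting that the enhanced ROI tolerates — and needs —
a much stronger shrink force against its bright, high-contrast interior.
Positive $\nu$ penalizes inside area; the sign is configurable
(`nu_sign`) since the energy is stated for $\nu \ge 0$ only.

**Intensity scale.** Images are normalized to $[0,1]$ throughout the
package, but the published operating points for $\nu$ (and the flow
weights below) only balance dimensionally against residuals on the
conventional 0–255 gray scale. The fit terms are therefore multiplied by
`intensity_scale`$^2$ (default $255^2$); equivalently, $\nu$ is quoted
per 8-bit-scale pixel. Setting `intensity_scale = 1` recovers the bare
normalized-units energy.

# Robust flow model

With $I_1$ the (masked) reference and $I_2$ the floating image, the
classical discrete objective is

$$E(u,v)=\sum_{i,j}\Big\{\rho_D\big(I_1(i,j)-I_2(i+u_{ij},\,j+v_{ij})\big)
 + \lambda_1\!\!\sum_{\text{fwd pairs}}\!\rho_S(\cdot)\Big\},$$

and the robust model couples $(u,v)$ to an auxiliary field
$(\hat u,\hat v)$:

$$E(u,v,\hat u,\hat v)=E_{\lambda_1}(u,v)
 + \lambda_2\big(\|u-\hat u\|^2+\|v-\hat v\|^2\big)
 + \lambda_3\sum_{i,j}\sum_{(i',j')\in N_{i,j}}
   \big(|\hat u_{ij}-\hat u_{i'j'}|+|\hat v_{ij}-\hat v_{i'j'}|\big).$$

Minimization alternates two subproblems:

* **Flow given auxiliary.** The data term is linearized at the current
  flow (the floating image is warped; derivatives use the 5-point filter
  $[-1, 8, 0, -8, 1]/12$ on the average of $I_1$ and the warped $I_2$) and
  the sparse normal equations are relaxed by Gauss–Seidel sweeps with
  per-pixel $2{\times}2$ solves, iteratively reweighted for the
  non-convex penalty. Samples that fall off the grid are replicated from
  the border and carry zero data weight. The public solver carries a
  descent certificate: if the relaxed solution does not lower the
  subproblem energy, it backtracks toward its initialization and, failing
  that, returns it unchanged.
* **Auxiliary given flow.** The subproblem separates per pixel into
  $\lambda_2(x-u)^2+\lambda_3\sum_k|x-n_k|$, whose closed-form minimizer
  is the median of the $m$ neighbor values unioned with the $m{+}1$ data
  candidates $u + (2k-m)\,\lambda_3/(2\lambda_2)$ — a weighted median that
  acts as a proximally constrained median filter. The field update runs
  Jacobi sweeps of this formula over a $5\times5$ neighborhood, starting
  from $\hat u = u$ (or from the previous auxiliary field when
  alternating), with a safeguard that rolls back any sweep that does not
  lower the field objective. The per-pixel formula is validated against a
  brute-force scan of the scalar objective in the test suite.

**Schedule.** Gaussian pyramids (factor 0.5, $\sigma=1$ anti-aliasing,
down to 16 px) are traversed coarse-to-fine with three warping steps per
level; after each warping step $(u,v)\leftarrow(\hat u,\hat v)$, and the
auxiliary field of the last warp is the final estimate. GNC runs two
stages: quadratic penalties first, then the generalized Charbonnier
$\rho(x)=(x^2+\epsilon^2)^a$ with $a=0.45$, $\epsilon=0.001$. The
non-convex stage refines at the finest level only, initialized from the
full quadratic pass — re-running the whole pyramid under the non-convex
penalty was measurably harmful on ground-truth phantoms (total-variation
staircasing of smooth fields) while finest-level refinement is neutral or
better.

**Coupling continuation.** Within each warping step the two subproblems
alternate `alternations` times (default 4), with the coupling weight
ramped as $\lambda_2^{(a)} = \lambda_2\,
\mathrm{ramp}^{\,a-A}$ up to the configured $\lambda_2$ on the final
alternation (default ramp 100, i.e. $10^{-4}\lambda_2 \to \lambda_2$
across four alternations). The early, weakly-anchored alternations are
Horn–Schunck-like: the smoothness term can propagate flow into flat and
aperture-limited regions (the tube's parallel vertical walls carry no
information about vertical motion), and the wide median candidate range
acts as a strong denoising filter. The final alternation enforces the
published coupling. With a fixed $\lambda_2=10^2$ the auxiliary anchor
confines every update to $\pm12\lambda_3/\lambda_2 \approx 0.12$ px and
the field cannot converge in homogeneous regions at all — the
continuation is what makes the published endpoint usable as a fixed
setting.

**Defaults.** $\lambda_1 = 5$, $\lambda_2 = 10^2$, $\lambda_3 = 1$ (the
selected operating point; `sweep_lambda2()` reproduces the selection
experiment over $\lambda_2 \in \{10^{-4},10^{-2},1,10^2,10^4\}$), with
`intensity_scale = 255` applied to the images inside `estimate_flow()`
for the same dimensional reason as in the segmentation energy.
Solver internals: 12 Gauss–Seidel sweeps per reweighting, 2 reweightings
(1 for the quadratic stage), over-relaxation 1.8, flow clamped to half
the level size. All operations are deterministic — identical inputs give
bit-identical flows.

# Evaluation metrics

For $[0,1]$ images: $\mathrm{RMS}=\sqrt{\mathrm{mean}((I_r-I_x)^2)}$;
$\mathrm{PSNR} = 20\log_{10}(1/\mathrm{RMS})$ dB (peak value 1, $+\infty$
sentinel at RMS 0); COR is the Pearson coefficient over all pixels (0,
flagged, for a constant image); MI comes from the joint histogram with
`mi_bins` equal-width bins per axis on $[0,1]$, base-2 logs, $0\log 0=0$.
Metrics are computed over the full frame, matching the subtraction-image
presentation of registration results; the *normal variation* verdict
requires RMS to fall and PSNR, COR and MI all to rise after registration.

The MI default of 256 bins is conventional, but note that the plug-in
estimator carries an independence bias of roughly
$(B-1)^2/(2N\ln 2)$ bits — about 0.7 bits at $B=256$, $N=256^2$ — so
absolute MI values are convention-dependent; only comparisons at fixed
binning are meaningful, which is how the package (and the verdict) uses
them. The test suite checks the independence limit at 16 bins, where the
bias is negligible.

# The synthetic phantom

`phantom_spec()`/`render_phantom()` emulate the physical phantom: a
"U"-shaped silicone tube (9 mm outer / 7 mm inner diameter) in agar,
holding three ~5 mm fatty disc targets, at 4 px/mm on a $256^2$ grid, so
the tube wall spans 36 px. Both modalities are rendered analytically from
the same geometry (distance functions to the tube centerline and target
centers, logistic edge profiles of width 0.5 px), so a rendering can be
evaluated at arbitrary continuous coordinates:

* **US analogue** — low-intensity background, near-invisible wall and
  anechoic lumen without enhancement; bright lumen and targets
  (`lumen 0.75`, `targets 0.92` vs `background 0.22`) with enhancement.
  Corrupted by correlated multiplicative speckle
  ($I\cdot(1+n)$, $n$ a $\sigma=1$-smoothed Gaussian field scaled to
  `us_speckle_sd` = 0.2).
* **MRI analogue** — smooth, moderate contrast, additive Gaussian noise
  (`mri_noise_sigma` = 0.015); with enhancement the tube signal *drops*
  (lumen 0.80 → 0.62), emulating the T2* effect.

The ground-truth deformation is specified analytically (translation,
affine, sums of Gaussian bumps, or compositions; `deform_study()` is the
standard evaluation instance: a (3, −2) px translation plus two smooth
local bumps, max displacement ≈ 7 px). The floating image is rendered at
the inverse-mapped coordinates (fixed-point inversion of $y = h + t(h)$),
so backward-warping it by the stored flow reproduces the reference
geometry exactly up to interpolation; noise is injected after the
deformation, so the truth flow relates noiseless geometry.

**Speckle moves with the tissue.** The speckle field is generated once in
material coordinates and sampled through the deformation for the floating
rendering. This reflects the physics — speckle is the deterministic
interference pattern of the scatterers and deforms with the medium (the
basis of ultrasound speckle tracking) — and it is what makes sub-pixel
ground-truth recovery well-posed for mono-modality experiments. Sensor
noise (the MRI term) is drawn independently per rendering.

**What the generator does not emulate:** acoustic wave propagation,
attenuation and shadowing, the reported lateral-wall echo drop-out and
bubble flotation (only the upper boundary visible in real B-mode images),
MR Bloch dynamics, bias fields, and any intensity relationship between
modalities beyond the designed contrast pattern. The modality intensity
tables are chosen so that the two *masked segmentations* share intensity
polarity (bright ROI on zero background) — on real data that
comparability is precisely what the contrast agent plus segmentation
must deliver, and where it fails the intensity-based flow would degrade
gracefully toward the unenhanced behavior shown below. Passing phantom
tests therefore demonstrates correctness of the machinery under the
stated imaging model, not clinical performance.

# Experiment shapes and problem sizes

The packaged experiments (test suite and `scripts/acceptance.R`) run at
the study scale of $256^2$ phantoms:

* mono-modality (US/US) pairs for ground-truth recovery: translations up
  to 12 px recovered to well under 0.5 px per component; smooth
  Gaussian-bump fields of max 8 px recovered to ≈ 0.13 px mean endpoint
  error inside the ROI;
* the full multimodal pipeline on ten enhanced and ten matched unenhanced
  seeds: enhanced runs show the normal-variation pattern with ≈ 7–8 dB
  PSNR gain and segmentation Dice ≈ 0.94 against truth; unenhanced runs
  segment poorly (Dice ≈ 0.7) and fail to register — the central
  with-vs-without-agent contrast;
* the rigid FFT phase-correlation baseline, which captures the global
  shift but leaves the non-rigid residual, ordering it below the robust
  flow on matched seeds.

Descent certificates (flow subproblem, auxiliary update, alternation, and
the contour's energy trace) are asserted on small seeded fixtures;
energy formulas are pinned to brute-force double-loop oracles on
$4^2$–$5^2$ fixtures, and the closed-form median update to an exhaustive
scalar scan over 1000 random instances.

# Known limitations

* Tangential motion inside homogeneous regions is unobservable for any
  intensity-based method; with the phantom's parallel walls this puts an
  aperture limit on point-wise flow accuracy that the smoothness and
  median terms fill in by interpolation. The registered *images* can agree
  better than the recovered *flow* agrees with the truth.
* The multimodal pairing relies on the masked segmentations being
  intensity-comparable; grossly different enhancement levels between
  modalities would reintroduce the multimodal gap (a metric-based,
  e.g. MI-driven, data term is out of scope).
* Two-phase segmentation only; no automatic initialization; 2-D only.
* The auxiliary median update uses the printed per-pixel weight
  $\lambda_3$ (not the $2\lambda_3$ of exact coordinate descent on the
  double-counted nonlocal sum); the energy safeguards make the
  alternation monotone regardless.
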