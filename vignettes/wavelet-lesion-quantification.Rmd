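---
title: "Wavelet-based quantification of contrast-enhanced liver lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based quantification of contrast-enhanced liver lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccwave)
```

## The measurement problem

After local therapy (typically transarterial chemoembolization), the
response of a hepatocellular carcinoma is staged by the longest diameter of
its *viable* — arterially enhancing — tissue, not of the whole mass.
Radiologist calipers on arterial-phase CT are subjective, and necrotic
cores make the enhancing rim hard to delineate by eye. `hccwave`
implements a deterministic measurement chain for a single arterial-phase
slice plus a liver ROI mask:

1. **Multiresolution denoising.** The slice is decomposed with a separable
   2-D discrete wavelet transform and reconstructed from the level-2
   approximation coefficients alone. This removes small-scale intensity
   fluctuations (image noise) while preserving structures larger than the
   level-2 band.
2. **Tissue thresholding.** Normal liver parenchyma and enhanced tumor
   tissue are modeled as two Gaussians in HU; the smoothed image is
   binarized at `mu_normal + sd_normal` (65 HU for the reference model,
   normal tissue 55 ± 10 HU, enhanced tissue 90 ± 11 HU).
3. **Morphological cleanup.** A 3×3 opening (erosion then dilation)
   removes residual specks and smooths region boundaries.
4. **Metrology.** 8-connected components inside the ROI are measured:
   pixel area and maximum Feret (caliper) diameter, converted to cm via
   the DICOM pixel pitch.

## The wavelet transform

For a 1-D signal, the multiresolution expansion splits the signal into
detail coefficients $d_j(k)$ (projections on translated wavelets
$\psi_{j,k}$, one band per level $j \le J$) and approximation coefficients
$C_J(k)$ (projections on the scaling functions $\varphi_{J,k}$). In 2-D
the filtering/decimation is applied along the horizontal direction and
then the vertical, giving per level three oriented detail quadrants (0°,
90°, 45°) and one approximation quadrant, which is recursed on.

The mother wavelet is the 10-tap orthogonal Daubechies filter; its
asymmetry is irrelevant here because approximation-only reconstruction
applies the analysis and synthesis filters in adjoint pairs, so the net
smoothing kernel is symmetric and lesions are not displaced. The physical
meaning of a level is given by its center spatial frequency

$$\xi_s(\psi) = \frac{\xi_0(\psi)}{2^s\,p},$$

with $\xi_0 \approx 0.693$ cycles/sample for this wavelet and $p$ the
pixel pitch in mm. At the typical abdominal-CT pitch of 0.80 mm the
level-2 band is centered near $0.22\ \mathrm{mm^{-1}}$ — structures a few
millimeters and larger survive the approximation, while pixel-scale noise
does not:

```{r band}
band_center_frequency(0.693, 2, 0.80)
```

### Numerical choices

* **Boundary handling** is symmetric (half-sample) padding by default;
  boundary coefficients are kept redundantly, which makes reconstruction
  exact (relative error below 1e-8, in practice machine precision) for
  every image size, including odd dimensions. A `"periodic"` mode is
  provided; it is non-redundant and conserves coefficient energy exactly
  (Parseval), at the price of requiring dyadic-divisible dimensions.
* **Level.** `level = 2` is the pipeline default: level 1 removes too
  little noise, while level 3 and above begin to erase sub-centimeter
  enhancing foci. The decomposition refuses images smaller than $2^J$ per
  side and reports the maximum feasible level.
* The stated pseudo-frequency 0.693 is reporting metadata only; filtering
  always uses the named wavelet's filter bank.

## The tissue intensity model

The reference model (`default_model()`) fixes normal tissue at 55 ± 10 HU
and enhanced tissue at 90 ± 11 HU, values estimated from Gaussian fits to
hand-labelled regions of arterial-phase exams. Because hand labels are
rarely available, `fit_two_gaussians()` offers an opt-in two-component EM
fit over an ROI histogram (convergence at a log-likelihood change below
1e-8 or 500 iterations; a component SD collapsing below 0.5 HU aborts
with a degenerate-fit error). The pipeline default deliberately stays
with the fixed model: an EM fit on a slice whose enhancing fraction is
tiny is poorly conditioned, and a fixed threshold keeps the measurement
chain deterministic.

The threshold is exposed as `threshold_sd_multiplier`: the default 1
gives $\mu_{normal} + \sigma_{normal} = 65$ HU; 0 thresholds at the
normal-tissue mean alone, an alternative reading of the published
binarization rule that we do not use by default.

## The virtual phantom and what it does (not) show

`generate_phantom()` builds a 256 × 512 field at 0.80 mm pitch:
background pixels iid $N(55, 10^2)$ HU, circular lesions filled iid
$N(90, 11^2)$ HU with hard membership decided by pixel centers (no
partial-volume blending — the tissue model describes filled circles, not
an edge model). `run_validation_sweep()` measures single centered disks
of 0.5–14.0 cm in 0.5 cm steps, 10 replicates each (280 runs), deriving
each run's seed from one master seed plus the run counter.

The phantom emulates first-order intensity statistics only. It has no
vessels, no anatomical texture, no necrotic cores, no partial-volume
edges and no inter-scanner variation, so the sweep characterizes the
geometric accuracy of the measurement chain under the modeled contrast,
not clinical performance on patient images.

```{r sweep, eval = FALSE}
sweep <- run_validation_sweep(seed = 1)
bland_altman(sweep$true_diameter_cm, sweep$measured_diameter_cm)
```

Agreement is summarized with Bland–Altman statistics
(`bland_altman()`): mean difference, limits of agreement at mean ± 2 SD
(the 2-SD convention; set `loa_multiplier = 1.96` for the conventional
normal-quantile limits), the $R^2$ of the least-squares fit of measured
on true, and a paired t-test. `group_summary()` stratifies pairs at the
staging cuts of 3 cm and 5 cm.

## Known limitations

* **Outward edge bias.** The level-2 approximation blurs a lesion edge
  over roughly eight pixels, and the 65 HU threshold sits at only ~29% of
  the 55→90 HU ramp, so the binary boundary lands about one pixel outside
  the true edge on each side. Together with rasterization and the
  one-pitch Feret end-correction (which gives a single pixel a one-pitch
  diameter), the sweep shows a systematic overestimate of ~0.25–0.30 cm,
  essentially independent of lesion size ($R^2 \approx 1$ against truth).
  Users comparing against caliper measurements should expect this fixed
  offset; it could be removed by calibrating the threshold to the
  mid-ramp value, but that would depart from the published binarization
  rule, so we report it rather than correct it.
* **Near-deterministic sweep geometry.** Disks are placed at the field
  center, so rasterization and wavelet-grid phase are identical across
  replicates and only the Gaussian noise varies; the spread of the sweep
  differences (SD ≈ 0.03 cm) therefore reflects noise alone and is much
  tighter than would be observed with randomly placed lesions.
* Single-slice only: no volume estimation, no automatic liver
  segmentation (the ROI mask is an input), at most two tissue classes,
  and no HU windowing is applied before analysis.

## Problem sizes used in the test suite

Unit tests run the transform on images up to 256², the EM recovery on
20 simulations of n = 10,000, and the acceptance checks run the full
280-phantom sweep (about half a minute) plus a six-disk noiseless
phantom.
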