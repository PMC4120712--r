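# hccwave

Wavelet-based detection and measurement of contrast-enhanced
hepatocellular-carcinoma (HCC) regions in arterial-phase CT slices.

After local therapies such as transarterial chemoembolization, tumor
response is staged by the longest diameter of the *viable* (arterially
enhancing) tissue. `hccwave` measures that diameter non-subjectively from
a single CT slice and a liver ROI mask:

1. separable 2-D discrete wavelet decomposition (10-tap Daubechies
   filters) and reconstruction from the level-2 approximation
   coefficients — removes pixel-scale noise, keeps structures above the
   band centered at ξ₀/(2²·p) ≈ 0.22 mm⁻¹ for a 0.80 mm pitch;
2. binarization of the smoothed image at μ_normal + σ_normal (65 HU for
   the reference tissue model: normal liver 55 ± 10 HU, enhanced tissue
   90 ± 11 HU);
3. 3×3 morphological opening to drop binarization specks;
4. 8-connected component extraction inside the ROI and per-lesion
   maximum Feret (caliper) diameter in cm.

A virtual-phantom generator (Gaussian background, Gaussian-filled disks
of known diameter) and Bland–Altman agreement statistics are included for
validating the measurement chain against ground truth.

## Worked example

Measure a synthetic slice end to end:

```r
library(hccwave)

# a phantom slice: one 4 cm enhancing disk on 55 +/- 10 HU parenchyma
spec <- phantom_spec(
  lesions = data.frame(center_row = 128.5, center_col = 256.5,
                       diameter_cm = 4.0),
  seed = 7)
ph  <- generate_phantom(spec)
roi <- roi_mask(matrix(TRUE, 256, 512))

lesions <- run_pipeline(ph$slice, roi)
lesions[[1]]
#> <lesion 1> 2066 px, area 13.22 cm^2, max diameter 4.27 cm, centroid (128.5, 256.6)

write_measurements(lesions, "measurements.csv", source_id = ph$slice$source_id)
```

The detected disk measures 4.27 cm for a true 4.00 cm diameter: the
pipeline carries a systematic overestimate of roughly +0.25–0.30 cm
(threshold position on the smoothed edge ramp plus the one-pitch Feret
end-correction; see the vignette's limitations section). Real DICOM
slices enter through `read_ct_slice()` (HU rescale and pixel pitch from
the file metadata) with a PNG/TIFF liver mask via `read_roi_mask()`.

Validation sweep and agreement statistics:

```r
sweep <- run_validation_sweep(seed = 1)   # 280 single-disk phantoms
bland_altman(sweep$true_diameter_cm, sweep$measured_diameter_cm)
#> <agreement_stats> n = 280
#>   mean diff -0.300 cm, SD 0.034 cm
#>   LoA (mean +/- 2 SD): [-0.368, -0.232] cm
#>   R^2 = 1.0000 (r = 1.0000), paired t = -148.467, p = 1.57e-267
```

A thin command-line front end lives at `inst/cli/hccwave.R` with
`measure` and `phantom` subcommands.

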