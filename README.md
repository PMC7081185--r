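# vsimri

Dual-contrast vessel size imaging (VSI) of the brain vasculature:
simulation, mapping and morphometry in R.

After injection of a blood-pool iron-oxide contrast agent, vessels perturb
the local magnetic field and the transverse relaxation rates measured with
spin-echo and gradient-echo MRI increase by ΔR₂ and ΔR₂\*. The ratio of the
two encodes microvessel caliber and their combination encodes density:

    VSI (μm)  = 0.424 · (D / (γ·Δχ·B₀))^(1/2) · (ΔR₂*/ΔR₂)^(3/2)
    Q (s⁻¹ᐟ³) = ΔR₂ / (ΔR₂*)^(2/3)
    MVD (mm⁻²) ≈ Q³ / (4.725·D)

This package implements the full computational side of such a study:

* **Monte Carlo finite-perturber simulator** — random-cylinder vascular
  substrates, FFT dipole-kernel field maps, random-walk proton phase
  accrual, spin/gradient echoes, radius × blood-volume sweeps
  (`generate_cylinder_substrate()`, `compute_field_shift()`,
  `simulate_echo()`, `run_sweep()`);
* **voxel-wise relaxometry and VSI/Q/MVD maps** — mono-exponential ADC,
  R₂ and R₂\* fitting, pre/post-contrast ΔR maps with the fitted-train
  calibration factor (`compute_adc_map()`, `compute_delta_map()`,
  `compute_vsi()`, `compute_q()`, `compute_mvd()`);
* **angiographic morphometry** — intensity thresholding and
  maximal-inscribed-sphere local thickness for per-branch vessel
  diameters (`threshold_vasculature()`, `local_thickness()`,
  `summarize_vessel_diameter()`);
* **ischemic-edema lesion statistics** — ADC < 650 μm²/s classification,
  ROI summaries, cutoff proportions (VSI > 10 μm, MVD > 200 mm⁻²) and
  Student's t-tests (`classify_tissue()`, `proportion_above()`,
  `students_t()`);
* **seeded phantoms with exact ground truth** — a two-hemisphere brain
  phantom with a subcortical lesion and multi-contrast series at Rician
  SNR 40, and tubular vascular phantoms of known radius
  (`make_brain_phantom()`, `render_series()`, `make_vascular_tree()`).

The methods, unit conventions and numerical design choices are documented
in `vignettes/dual-contrast-vsi.Rmd`.

## Worked example

Simulate the contrast response of 3 μm microvessels at 2 % blood volume at
7 T (reduced desk scale: 128³ grid at 1 μm, 2×10⁵ walkers, 3 repetitions —
about a minute on one CPU):

```r
library(vsimri)
sw <- run_sweep(radii = 3, bvfs = 0.02, sim = reduced_sim_profile(), seed = 101)
sw$summary[, c("d_r2_mean", "d_r2star_mean", "vsi_um", "q")]
#> # A tibble: 1 × 4
#>   d_r2_mean d_r2star_mean vsi_um     q
#>       <dbl>         <dbl>  <dbl> <dbl>
#> 1      17.7          68.9   3.18  1.05
```

The spin-echo ΔR₂ of ~18 s⁻¹ matches the ~20 s⁻¹ plateau used to judge
the contrast dose; the derived VSI (3.2 μm) recovers the true 3 μm radius
and Q sits in the physiologic ~1 s⁻¹ᐟ³ range.

Run the full mapping pipeline on the brain phantom and test the
lesion-vs-contralateral remodeling directions:

```r
res <- run_pipeline(default_pipeline_config(), out_dir = "results/phantom")
subset(res$roi_stats, roi %in% c("lesion", "contra_subcortex"),
       c(roi, tissue_class, metric, mean_adc, mean))
#>   roi              tissue_class metric mean_adc   mean
#>   lesion           edema        vsi        499.   12.4
#>   lesion           edema        q          499.    0.59
#>   lesion           edema        mvd        499.   57.5
#>   contra_subcortex normal       vsi        749.    4.19
#>   contra_subcortex normal       q          749.    1.04
#>   contra_subcortex normal       mvd        749.  310.
res$proportions
#>   lesion           vsi  10  0.760
#>   lesion           mvd 200  0
#>   contra_subcortex vsi  10  0.0000312
#>   contra_subcortex mvd 200  0.840
```

The lesion (mean ADC 499 μm²/s) is classified as ischemic edema; relative
to the contralateral subcortex it shows larger vessels (VSI 12.4 vs
4.2 μm; proportion above 10 μm 0.76 vs ~0), a lower density index Q
(0.59 vs 1.04) and a lower proportion of high microvessel density
(MVD > 200 mm⁻²: 0 vs 0.84), all with unpaired p < 0.001.

The numbered drivers under `analysis/` run the complete study — the
radius × Bvf simulation sweep, the phantom mapping pipeline and the
vessel-diameter morphometry — and write their tables and figures under
`results/`:

```sh
Rscript analysis/01_simulate_sweep.R
Rscript analysis/02_phantom_pipeline.R
Rscript analysis/03_vessel_morphometry.R
```

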