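# cardiohelix

Dual-modality mapping of left-ventricular cardiomyocyte orientation:
diffusion tensor imaging (DTI) and structure-tensor analysis of
high-resolution optical (light-sheet) volumes, with helix-angle
transmurality quantification, regional/infarct analysis, FACT
tractography, and method-agreement statistics — validated end to end on
synthetic helical left-ventricle phantoms with known ground truth.

## The problem

The left-ventricular wall is built from helically wound cardiomyocytes:
right-handed at the endocardium, smoothly rotating to left-handed at the
epicardium. The **helix angle** HA is the signed angle between a fiber's
projection onto the local circumferential–longitudinal plane and the
circumferential direction (positive = right-handed helix), computed from
the blood-pool-centred frame of each short-axis slice. Plotting HA
against **transmural depth** TD (0% endocardium, 100% epicardium) along
radial projections and fitting a line per projection gives the
**helix-angle transmurality**

HAT = mean over projections of d(HA)/d(TD)  [°/%TD],

whose magnitude summarises how much helical winding the wall retains;
ischemic remodelling lowers it. Two independent measurement routes are
implemented:

* **DTI path** — per-voxel self-diffusion tensor from the log-linear
  least-squares fit of `ln S = ln S0 − b gᵀ D g` over ≥ 6 directions;
  the primary eigenvector e1 is taken parallel to the local
  cardiomyocyte orientation; mean diffusivity MD = (λ1+λ2+λ3)/3 zones
  infarct (> 1.12 µm²/ms), peri-infarct (0.9–1.12) and remote tissue.
* **Optical path** — light-sheet stripe-artifact removal, Sobel
  gradients, windowed 2D/3D structure tensor; the smallest-eigenvalue
  eigenvector points along the imaged fiber texture.

Because no raw images were available, the package ships a first-class
phantom generator: annular LV geometry, a transmurally ramping helical
fiber field with known HAT, an infarct lesion with elevated MD and
flattened HA, Rician-noise DWI synthesis, and fibrous optical texture
rendered by line-integral convolution. Every stage of the pipeline is
validated against this ground truth.

## Worked example

```r
library(cardiohelix)

spec <- phantom_spec(dim = c(64, 64, 8), ha_endo = 60, ha_epi = -60,
                     seed = 1)              # true HAT = -1.2 deg/%TD
fib  <- make_fiber_field(make_lv_geometry(spec))
dwi  <- synthesize_dwi(fib)                 # 12 directions @ b = 1000
dti  <- analyze_dwi_path(dwi)
dti$hat
#> Global HAT: -1.2134 deg/%TD (|HAT| = 1.2134) from 160 profiles
```

The signed slope is negative because HA runs from +60° (right-handed,
endocardium) to −60° across the wall; the recovered magnitude 1.213
deviates from the generative 1.2 only through nearest-voxel sampling of
the 20 radial projections. The optical route on the same phantom
(`synthesize_optical()` on a 3× refined grid, then
`analyze_optical_path()`) recovers the same slope to within a few
hundredths of a °/%TD.

The numbered drivers under `analysis/` run the full study: `01` builds
7 control-like + 8 ischemic-like noisy phantoms and quantifies HAT by
both modalities, `02` compares the groups (Wilcoxon), `03` computes
cross-modality agreement (R², ICC, Bland-Altman), `04` does AHA-16 /
3.6°-radial-segment / infarct-zone analysis on a lesion phantom, and
`05` renders FACT streamlines. Tables are written under `results/`.

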