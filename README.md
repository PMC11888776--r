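# circpol — multiplexed circular polarimetry for label-free tissue pathology

`circpol` is a simulation and analysis toolkit for circular-polarimetry
screening of fibrous tissue, built around the use case of classifying normal
versus ischemic brain hemispheres in rodent stroke models. Ischemia degrades
the ordered, high-index myelinated axons of white matter into swollen,
chaotically oriented fibers and membranous debris; these structural changes
leave a measurable fingerprint on the polarization state of forward-scattered
light. The package lets you simulate that fingerprint from first principles,
model the instrument that measures it, and run the statistical pipeline that
turns it into a diagnosis — all without any animal data.

## What it computes

Light is described by the Stokes vector `S = (S0, S1, S2, S3)`. Two metrics
derived from the input and output states of a tissue section carry the
pathology signal:

- **Depolarization** `dep = 1 − DOP_out / DOP_in`, with
  `DOP = sqrt(S1² + S2² + S3²) / S0`;
- **Retardance** `δ = angle between the Poincaré-sphere vectors
  (S1, S2, S3) of input and output` (radians).

The toolkit has five layers:

1. **Polarized Monte Carlo transport** (`run_forward`,
   `scattering_pattern`): photon packets with full Stokes bookkeeping
   (meridian-plane method) propagate through a slab of infinite-cylinder
   scatterers — the axons — plus spherical organelle/debris scatterers.
   Single-scattering matrices come from the exact Bessel-series amplitudes
   of the obliquely illuminated cylinder (`cylinder_amplitudes`) and Mie
   theory (`mie_amplitudes`). Presets `tissue_preset("normal")` and
   `tissue_preset("ischemic")` encode the tissue models, including the 50:1
   unmyelinated:myelinated count ratio and orientation disorder of ischemia.
   Circular illumination is the method's key trick: its metrics are
   invariant to fiber orientation, unlike linear illumination.
2. **Rotating quarter-wave-plate polarimeter** (`forward_trace`,
   `demodulate`): the intensity trace measured every 15° of retarder
   rotation is Fourier-demodulated back to the Stokes vector.
3. **Metrics** (`depolarization`, `retardance_angle`) as above.
4. **Four-channel moment features** (`channel_moments`,
   `build_feature_vector`, `feature_table`): the probe samples four spots
   125 µm apart; the mean, SD, skewness and kurtosis of each metric across
   channels capture the spatial texture of the core-to-penumbra injury
   gradient, giving 16 features per scan point.
5. **Classification** (`train_linear_svm`, `roc_auc`, `evaluate_pipeline`,
   `mann_whitney_two_sided`): linear SVM scores, ROC/AUC with the operating
   point at max (sensitivity + specificity)/2, and exact Mann–Whitney
   group tests.

A seeded synthetic generator (`generate_scan`) emulates the zig-zag scans of
both hemispheres (48 points/side single-channel, 64 points/side
four-channel) with a spatial injury gradient, so the whole pipeline
(`run_pipeline`) runs end-to-end from nothing but a seed. A thin CLI lives in
`inst/scripts/circpol` (subcommands `generate`, `simulate`, `pattern`,
`demodulate`, `metrics`, `features`, `classify`, `pipeline`).

## Worked example

```r
library(circpol)

m <- tissue_preset("ischemic")
m
#> <tissue_model> slab 20 um, n_medium 1.34, lambda 852 nm, mu_s 906 /mm
#>   myelinated     cylinder r=0.5 um n=1.44 x=4.94 mu_s=40.7 /mm kappa=6.2
#>   unmyelinated   cylinder r=0.5 um n=1.4 x=4.94 mu_s=737 /mm kappa=6.2
#>   debris         sphere r=0.25 um n=1.45 x=2.47 mu_s=128 /mm

run_forward(m, stokes(1, 0, 0, 1), n_photons = 20000, seed = 42)
#> <detector_result> 538 / 20000 detected | dep = 0.3429 (se 0.0167) | delta = 0.2656 (se 0.0352)
```

538 of 20 000 right-circular photons exit the 20 µm section within the 10°
collection cone; their ensemble Stokes vector has lost ~34% of its degree of
polarization and rotated ~0.27 rad on the Poincaré sphere — the ischemic
signature (the normal preset gives dep ≈ 0.14, δ ≈ 0.27).

```r
rec <- generate_scan(seed = 42)          # synthetic 64-point, 4-channel scan
ft  <- feature_table(rec)
evaluate_pipeline(ft, "one_channel")[[1]]
#> <roc_result> AUC = 0.7324 | operating point: sens = 0.578 spec = 0.828 (thr 0.1408)
evaluate_pipeline(ft, "four_channel")[[1]]
#> <roc_result> AUC = 0.8279 | operating point: sens = 0.828 spec = 0.750 (thr -0.4796)

mw <- mann_whitney_two_sided(rec$dep[rec$side == "contra"],
                             rec$dep[rec$side == "ipsi"])
sprintf("Mann-Whitney dep: U = %d, p = %.3g", mw$u, mw$p_value)
#> "Mann-Whitney dep: U = 16519, p = 2.8e-22"
```

Adding the cross-channel moment features lifts the AUC of this synthetic rat
from 0.73 to 0.83; the two hemispheres differ overwhelmingly in raw
depolarization.

## Documentation

The methods vignette (`vignettes/circular-polarimetry-methods.Rmd`) documents
the physical model and its assumptions, every tunable parameter with units
and defaults, the provenance of the tissue presets, the design of the
synthetic generator, and the package's numerical choices and limitations.
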