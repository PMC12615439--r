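# mpmcollagen

Label-free multiphoton microscopy (MPM) analysis of collagen-rich tissue,
built around the imaging workflow used for fibrous meningioma: two-photon
excited fluorescence (TPEF) plus second harmonic generation (SHG) under
810-nm femtosecond excitation. Fibrillar collagen is the only strong SHG
source in this tissue, emitting coherently at exactly half the excitation
wavelength (405 nm), while NADH, FAD, structural proteins, lipopigments and
porphyrins contribute broad TPEF bands — so collagen architecture and
cellular morphology can be imaged and quantified without any stain.

The package is aimed at microscopists and image-analysis researchers working
with spectral (lambda-mode) or two-channel MPM data. It provides:

- **Spectral data model** — 32-channel lambda stacks on the 382–714 nm grid
  (11-nm spacing), two-channel TPEF/SHG images, ROI-mean emission spectra,
  band integration, TIFF + JSON-sidecar I/O, and the standard renders
  (red/green TPEF/SHG overlay, purple/blue combined spectral image).
- **Eight-component spectral decomposition** — bounded Gaussian multi-peak
  least squares fitting of normalized emission spectra into collagen SHG
  (405 nm), protein-bound NADH (425), free NADH (475), structural proteins
  (510), FAD (545), lipopigments (575) and porphyrins I/II (630/690), with
  relative ratios reported as fitted amplitudes:

  I(λ) = Σⱼ Aⱼ exp( −(λ − μⱼ)² / 2σⱼ² ),  Aⱼ ∈ [0, 1.5], μⱼ ∈ μⱼ⁰ ± 5 nm.

- **Collagen content quantification** — the four-stage pipeline: percentile
  contrast enhancement → Otsu thresholding (between-class variance
  maximization, implemented from the histogram) → morphological
  opening/closing → pixel-fraction collagen content, for both SHG images
  and SHG-band integrals of 32-channel stacks, with batch mean ± SD
  reporting.
- **Synthetic tissue phantoms** — seeded generators for fibrous-tissue
  phantoms (curvilinear collagen bundles, cells with fluorescence-dark
  nuclei and NADH/FAD cytoplasm, Poisson + Gaussian detection noise) with
  full ground truth, so every stage is testable without microscope data.

## Worked example

```r
library(mpmcollagen)

# decompose the published fibrous-meningioma component mixture
spectrum <- reference_spectrum(fibrous_meningioma_ratios())
fit <- fit_components(spectrum)
ratio_report(fit)
#> # A tibble: 8 x 2
#>   name               ratio
#>   <chr>              <dbl>
#> 1 collagen_SHG       0.952
#> 2 structural_protein 0.502
#> 3 NADH_free          0.393
#> 4 FAD                0.199
#> 5 lipopigment        0.198
#> 6 NADH_bound         0.105
#> 7 porphyrin_I        0.104
#> 8 porphyrin_II       0.0150

# a 256x256 phantom with 50% target collagen, quantified from its SHG channel
phantom <- render_two_channel(phantom_spec(seed = 11,
                                           target_collagen_fraction = 0.5))
seg <- quantify_shg(phantom$image)
seg
#> <collagen_segmentation> modality shg | threshold 0.2578 | collagen content 0.4911
phantom$truth$true_fraction
#> [1] 0.4891968
```

The ratio table reproduces the relative abundance ordering measured in
fibrous meningioma tissue — collagen dominant, structural proteins second —
and the phantom's estimated collagen content (0.491) recovers the generator's
true mask fraction (0.489) to two decimals.

A thin command-line wrapper is installed at `inst/scripts/mpm-tool`
(`simulate | fit-spectrum | collagen | render`), writing TIFF/PNG/CSV/JSON
artifacts; see `?mpm_cli`.

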