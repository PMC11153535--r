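# ivoctsim — in silico intravascular OCT with saline flushing

Intravascular optical coherence tomography (IVOCT) images artery walls with
near-infrared light from a catheter-mounted lens pulled back along the
vessel. Blood is opaque at 1300 nm, so it must be flushed with normal saline
during acquisition — and clinicians lack a quantitative basis for choosing
*how much* saline is enough. `ivoctsim` simulates the whole procedure so
injection schedules can be designed and compared on a desk:

- **Flushing hemodynamics** — axisymmetric incompressible flow and
  erythrocyte transport in the vessel–catheter geometry (pulsatile blood
  inflow, saline jet from the guiding catheter), solved with a staggered
  finite-volume scheme (semi-Lagrangian momentum advection, implicit
  viscous diffusion, incremental pressure projection, flux-limited species
  advection; optional mixing-length or k–ω turbulence closures).
- **Optical forward model** — Lambert–Beer attenuation and backscatter
  through the blood/saline mixture, the three vessel-wall layers and
  extramural tissue: A-lines `E(r)`, `M(r)`, `I(r)`, grayscale `G(r)`, and
  rendered cross-sectional / longitudinal OCT images.
- **Scan scoring** — per-frame residual irradiance ratio at the vessel wall
  `M_w = E_w/E_0`, clear-image-frame (CIF) flags at threshold 0.75, clear
  imaging length (CIL), and the composite quality
  `gamma = f1 * mean(M_w) + f2 * (1 - var(M_w)/0.25)`, alongside the saline
  dosage `V = ∫ Q dt`.

Everything is tidyverse-native: waveforms, A-lines, frame series and
summaries are tibbles; result objects have `tidy()`/`glance()`/`autoplot()`
methods.

## Worked example

Closed-form physics first — these print, respectively, the erythrocyte
density, whole-blood erythrocyte mass fraction, and diffusivities implied by
the mixture laws:

```r
library(ivoctsim)
mixture_properties(c(0, 0.45))
#> # A tibble: 2 × 5
#>   haematocrit mass_fraction density viscosity diffusivity
#>         <dbl>         <dbl>   <dbl>     <dbl>       <dbl>
#> 1        0            0       1000   0.0009      9.08e-14
#> 2        0.45         0.479   1056   0.00191     4.27e-14

dosage(build_continuous(), horizon = 7.2)   # 14.4  (mL, continuous scheme)
dosage(build_intermittent(), horizon = 7.2) # 8.0   (mL, intermittent scheme)
```

A whole-blood A-line: only ~16% of the emitted irradiance survives the
1.55 mm lumen path, which is why flushing is needed at all:

```r
geo <- geometry_config()
aline <- propagate(medium_profile(geo, haematocrit = 0.45))
attr(aline, "M_w")
#> [1] 0.1575036
```

The full in silico experiment — flushing, automatic pull-back triggering,
scan scoring and dosage for both default schemes (about 2–10 minutes on one
CPU depending on load):

```r
cmp <- run_comparison(ivoct_config())
tidy(cmp)
#>   scheme       mean_mw  sigma  gamma cil_mm dosage_ml n_frames trigger_time
#> 1 continuous     0.802 0.0584  0.791   36.2      14.4      251         1.21
#> 2 intermittent   0.724 0.0716  0.721   33.8       8.0      251         1.34
cmp$dosage_reduction_pct   # 44.4
cmp$quality_reduction_pct  # 8.9
```

Reading: switching from continuous to intermittent injection cuts the
saline dose by 44.4% while the composite image quality drops only ~9% and
the clear imaging length stays well above the 24 mm clinical minimum —
the case for intermittent flushing. `autoplot(cmp)` plots the per-frame
`M_w` traces; `write_comparison(cmp, "out/")` writes JSON/CSV reports and
longitudinal PNG images.

A command-line front end is included (`inst/cli/ivoct`):

```sh
Rscript inst/cli/ivoct run-comparison --fidelity laminar_eddy --out out/
```

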