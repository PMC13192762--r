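# orgscale

Organelle scaling analysis with synthetic 3D fluorescence stacks.

As cells grow, each organelle must be scaled up — but not all organelles
scale alike. In budding yeast-like cells spanning a ~100-fold volume
range (8–800 μm³), the standard readout is the allometric exponent β
from an ordinary least-squares fit

    log10(content) = log10(a) + β · log10(V),

where *content* is the total background-subtracted fluorescence of an
organelle marker summed inside one cell and *V* is the cell volume
measured from a cytosolic marker. β = 1 is isometric scaling (constant
density), β < 1 subscaling, β > 1 superscaling. Published population
slopes for this system are 1 (mitochondria), 0.96 (ER), 1.1 (vacuole
membrane) and 0.75 (peroxisomes), with cell growth itself exponential
at a ~169 min doubling time.

The raw microscopy behind those numbers is not deposited, so orgscale
is built for *parameter recovery*: it provides

* **synthetic data with ground truth** — tabular (volume, content)
  populations under configurable scaling scenarios; rendered
  two-channel 3D stacks (cytosol + organelle, five organelle
  geometries) written as multi-page TIFF with JSON sidecars;
  single-cell growth traces with budding intervals; and an analytic
  spherical-vacuole oracle for the geometric argument that linear
  membrane scaling with a fixed vacuole number forces vacuole-volume
  superscaling with slope 1.5;
* **an image-quantification pipeline** — cell mask from the cytosolic
  channel (Gaussian smoothing, Otsu, 26-connected labeling, hole
  filling), extracellular background subtraction, in-cell organelle
  segmentation, total content and density, vacuole volumetry with the
  460-nm sub-resolution exclusion, and cortical glancing-slice
  densitometry for the ER;
* **scaling statistics** — log-log fits with regression F-tests,
  density-vs-volume trend tests, small (<100 μm³) vs large (>400 μm³)
  contrasts (Student or Welch, plus a variance F-test), and exponential
  growth fits, all with broom-style `tidy()`/`glance()` and ggplot2
  `autoplot()` methods.

## Worked example

```r
library(orgscale)

# 500 cells under the packaged peroxisome scenario (beta = 0.75)
pop <- sample_population("peroxisome", n = 500, seed = 42)
fit <- loglog_fit(pop)
fit
#> <scaling_fit> log-log slope = 0.7464 (SE 0.0114), R^2 = 0.896, F = 4299.97, p = 4.01e-247, n = 500
```

The recovered slope 0.746 ± 0.011 brackets the generative exponent
0.75: peroxisome content subscales, so peroxisome density must fall in
large cells. The group contrast shows exactly that, along with the
smaller variance in large cells:

```r
pop$density_au_per_um3 <- pop$content_au / pop$volume_um3
compare_groups(pop, welch = TRUE)
#> <group_comparison> small (<100 um^3, n=289): 138 +/- 57.4 | large (>400 um^3, n=77): 66.7 +/- 28.4
#>   Welch t = 15.334, p = 5.91e-38; variance F = 4.084, p = 3.5e-11
```

The analytic vacuole oracle reproduces the slope-1.5 geometry argument
to machine precision:

```r
tab <- spherical_vacuole_oracle("fixed_number", n_cells = 20, k = 4, c_area = 0.5)
loglog_fit(tab, cell_volume_um3, total_vacuole_volume_um3)
#> <scaling_fit> log-log slope = 1.5000 (SE 0.0000), R^2 = 1.000, ...
```

And a noisy growth trace returns the planted doubling time:

```r
tr <- generate_growth_trace(td = 169, v0 = 10, duration = 600,
                            noise_cv = 0.05, seed = 1)
fit_exponential_growth(tr)
#> <growth_fit> doubling time 168.2 +/- 1.3 min (R^2 = 0.996, n = 61)
```

Rendered stacks go through the same chain as real images:

```r
st  <- render_cell_stack(pop[3, ], "peroxisome")   # two-channel voxel grid
measure_stack(st)                                  # per-cell tibble
run_end_to_end(run_config(n = 6, seed = 42))       # simulate -> measure -> scale
```

`run_end_to_end()` writes `measurements.csv`, `report.json`, `run.log`
and a manifest; identical configs reproduce the outputs byte for byte.
A thin command-line front end with `simulate` / `measure` / `scale` /
`growth` / `run` subcommands ships in `inst/cli/orgscale.R`.

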