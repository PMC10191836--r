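# fibrilkit

Quantitative ultrastructure analysis of beaded extracellular-matrix
microfibrils, for electron microscopists and image analysts working on
fibrillin and similar ~57-nm-repeat filaments.

Fibrillin microfibrils are "beads on a string": each repeat shows a
bead, arms, an interbead and a shoulder region, carries ~3 MDa of
protein (~1.1 MDa in the bead), and binds regulators such as LTBP-1
(latent TGF-beta binding protein 1) at the bead. fibrilkit implements
the measurements this field runs on such filaments:

* **Periodicity** — trace filaments in micrographs, straighten them
  along their axis, locate bead peaks on the axial mean profile
  (sub-pixel), and compare condition means with pooled one-way ANOVA
  plus two-sided Dunnett many-to-one contrasts (computed in-house from
  the multivariate-t distribution, also directly from printed
  mean ± se summaries).
* **Axial stain-exclusion profiles** — cut repeats bead-to-bead, align
  translationally, average, and detect lost / gained / broadened peaks
  between conditions.
* **STEM mass mapping** — annular dark-field intensity is linear in
  projected mass; an internal tobacco mosaic virus rod
  (MUL = 131.4 kDa/nm) calibrates intensity to mass per unit length,
  which integrates to mass per repeat: `MUL(x) = k * I_net(x)`,
  `M_repeat = ∫ MUL dx` over one bead-to-bead interval.
* **Volume symmetry** — masked, zero-mean normalized cross-correlation
  NCC(θ) of a 3D map against its own rotation about the fiber axis
  (5° steps); the peak count of the curve gives the rotational
  symmetry order, with a pseudo-symmetry flag. Density-threshold mass
  uses 0.813 Da/Å³ (1.35 g/cm³).
* **Subparticle recentering** — shift particle records from the full
  repeat onto the bead or arm: `Δ = P R(rot, tilt, psi) v`, with R the
  ZYZ rotation and P the projection dropping the beam axis.
* **One-site binding** — equilibrium fits of
  `R_eq(C) = Rmax C / (Kd + C)`.
* **Synthetic generator** — ground-truthed filament images, dark-field
  fields, Cn-symmetric volumes and particle tables at the study
  condition presets (periods 57.95 / 57.14 / 55.21 nm; repeat masses
  3,055 and 3,405 kDa; 2 × 151 kDa ligand at the bead), so every
  analysis is validated by parameter recovery.

## Worked example

Simulate control-condition filaments, recover their periodicity, and
compare the three conditions from printed summaries:

```r
library(fibrilkit)

ps <- run_period_recovery("control", n_filaments = 2, n_repeats = 15,
                          seed = 40)
print(ps)
#> Period set 'control': n = 26, mean 57.99 nm, sd 0.53 nm

compare_to_control(
  list(mean = 57.95, pm = 0.22, n = 100),
  list(dh1 = list(mean = 57.14, pm = 0.27, n = 100),
       wms = list(mean = 55.21, pm = 0.26, n = 100)))
#> one-way ANOVA + Dunnett (quadrature)
#> F(2, 297) = 31.468, p = 4.03e-13
#>  condition mean_diff         t p_unadjusted   adjusted_p
#>        dh1     -0.81 -2.282520 2.316544e-02 4.310661e-02
#>        wms     -2.74 -7.721118 1.775119e-13 5.291323e-13
```

The first block rebuilds noisy filament images at the control preset
(57.95-nm period), traces and straightens them, and measures 26
bead-to-bead periods whose mean recovers the preset to well under 1%.
The second block reproduces the reported group comparison: the 0.81-nm
shortening gives an adjusted P of about 0.043 and the 2.74-nm
shortening is significant far below 1e-4.

STEM mass mapping, equally compact:

```r
bare <- run_stem_recovery(seed = 200, n_fibrils = 6, condition = "fibrils")
deco <- run_stem_recovery(ltbp1_decoration(), seed = 300, condition = "+LTBP-1")
decoration_analysis(list(mass_set = bare$mass_set, mul_avg = bare$mul_avg),
                    list(mass_set = deco$mass_set, mul_avg = deco$mul_avg))
#> Decoration gain: 337.6 +/- 59.7 kDa per repeat (p = 3.01e-109)
#>   102% of the added mass lies within +/- 11 nm of the bead
#>   ~2 ligand copies per repeat
```

## Package layout

* `R/specs.R`, `R/axial-profile-gen.R`, `R/render.R`,
  `R/synthetic-volume.R`, `R/synthetic-particles.R` — the generator
* `R/trace.R`, `R/straighten.R` — filament geometry
* `R/periods.R`, `R/group-compare.R` — periodicity statistics
* `R/repeats.R`, `R/profile-compare.R` — axial profile averaging and
  comparison
* `R/stem-mass.R` — MUL calibration and decoration analysis
* `R/volume-symmetry.R` — rotational correlation and map mass
* `R/recenter.R` — subparticle recentering
* `R/binding.R` — one-site equilibrium fits
* `R/io.R` — MRC, 16-bit TIFF, STAR and CSV readers/writers
* `vignettes/fibrilkit-methods.Rmd` — the methods notes: models,
  defaults, numerical choices and limitations
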