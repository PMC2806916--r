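# seepscape

Quantitative analysis chain for habitat transects across hydrocarbon-seep
sediments: porewater reaction-transport modeling, diffusive flux and
depth-integrated rate bookkeeping, stable carbon isotope utilities, OTU
clustering with Chao1 richness estimation, and joint geochemistry/community
activity summaries — plus a seeded synthetic-data generator so the whole
pipeline can be exercised without any field data.

## The problem

Seafloor microbial mats (e.g. *Beggiatoa* spp.) mark patchy hot spots of
sulfate reduction and anaerobic methane oxidation in seep sediments.
Characterising such a habitat transect means reconciling several data
streams from sectioned push-cores: porewater sulfate and methane
concentration profiles, radiotracer rate profiles, methane δ¹³C profiles,
and clone-library or tag censuses of the microbial community. `seepscape`
implements the quantitative steps that tie these together.

At its core is the 1-D steady-state porewater mass balance

```
d/dx( φ·Ds·dC/dx ) − d(φ·ω·C)/dx + φ·α·(C_OW − C) − φ·R = 0
```

whose terms are molecular diffusion, burial (sedimentation and compaction),
bioirrigation exchange with overlying water, and net reaction. Here `x` is
depth below the sediment–water interface (cm, positive down), `φ` porosity,
`Ds = D_O/(1 − ln φ²)` the tortuosity-corrected diffusivity (cm² s⁻¹),
`ω` the sedimentation rate (cm kyr⁻¹), `α` the bioirrigation coefficient
(d⁻¹), `C_OW` the overlying-water concentration (mM), and `R` the
volumetric rate (positive for consumption, nmol cm⁻³ d⁻¹). The model runs
both ways:

* **forward** (`solve_forward()`): concentrations from rates, via a
  second-order finite-difference tridiagonal solve;
* **inverse** (`fit_rates_inverse()`): piecewise-constant layer rates from
  an observed concentration profile, as an exact linear least-squares
  problem (the forward map is affine in the rates).

Around the model sit `diffusive_flux_top()` (Fick's-law flux from the two
shallowest interval midpoints, upward positive, in mmol m⁻² d⁻¹),
`depth_integrated_rate()` (trapezoidal, nmol cm⁻³ d⁻¹ · cm → mmol m⁻² d⁻¹),
`flux_rate_consistency()` (steady-state QC), `penetration_depth()`,
`mrna_persistence_time()`, `flag_saturation()` (methane > 1.2 mM is only a
lower bound at 1 atm), δ¹³C del-notation conversions with an upcore trend
classifier, complete-linkage OTU clustering with the bias-corrected Chao1
estimator `S_chao1 = S_obs + n1(n1−1)/(2(n2+1))`, clone-library size QC,
and the per-core activity summary with an ordinal flux-vs-community
concordance check.

Everything takes and returns tibbles, so calls chain with the pipe;
`tidy()`/`glance()` summarise inverse fits and `plot_profile()`,
`autoplot()`, `plot_activity_summary()` draw the standard figures.

## Worked example

Impose a depth-integrated sulfate reduction rate of 12.3 mmol m⁻² d⁻¹
(a typical under-mat value) as a constant sink over the top 5 cm of a
diffusion-only 30 cm column and ask where sulfate would fall to the 0.7 mM
background:

```r
library(seepscape)

sys <- transport_system(domain_bottom_cm = 30, dx_cm = 0.1, porosity = 0.8,
                        D_O_cm2_s = 5e-6, C_OW_mM = 28)
layer <- tibble::tibble(depth_top_cm = 0, depth_bottom_cm = 5,
                        rate_nmol_cm3_d = 12.3 / (5 * 0.01))  # 246
prof <- solve_forward(sys, layer)
penetration_depth(prof, threshold_mM = 0.7)
#> # A tibble: 1 × 3
#>   depth_cm beyond_domain domain_bottom_cm
#>      <dbl> <lgl>                    <dbl>
#> 1       30 TRUE                        30
```

Sulfate never reaches background anywhere in the 30 cm column (it levels
off near 17.5 mM below the reactive layer): measured rates of this size
cannot explain a sulfate profile that is depleted by ~5 cm, which is the
argument for an additional transport process such as upward fluid
advection.

The inverse model fits layer rates to a profile; with three equal 10 cm
layers over the profile above:

```r
fit <- fit_rates_inverse(sys, prof$conc_mM, n_layers = 3)
tidy(fit)
#> # A tibble: 3 × 5
#>   depth_top_cm depth_bottom_cm rate_nmol_cm3_d thickness_cm integrated_mmol_m2_d
#> 1            0              10           95.0            10                9.50
#> 2           10              20          -16.4            10               -1.64
#> 3           20              30            3.83           10                0.383
```

(the true sink is confined to 0–5 cm, so the misspecified equal layering
smears it — `glance(fit)$rmse` of 0.8 mM flags the imperfect fit; matching
`breaks = c(0, 5, 30)` recovers the imposed rate to machine precision).

Other one-liners, with their printed values:

```r
mrna_persistence_time(5, 31)$years_floor   # 161 years buried below the horizon
chao1(c(1, 1, 1, 1, 2, 2, 3, 4, 5, 6))$s_chao1   # 12 (S_obs 10, n1 4, n2 2)
```

A full synthetic transect (three cores × two depth layers, seeded) runs the
entire pipeline; in `simulate_transect(seed = 1)$concordance` the surface
layer shows a concordant-pair fraction of 1 between |sulfate flux| and the
sulfate-reducer clone percentage, and between methane flux and the ANME
clone percentage — the designed coupling of geochemistry and community.

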