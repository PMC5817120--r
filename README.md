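# psfland

Community-level plant–soil feedback (PSF) analysis and landscape
projection, for ecologists asking whether soil legacies are strong enough
to set the rank-order dominance of native and non-native plant
communities across a landscape.

In the shrub-steppe study system this package models, never-tilled fields
are dominated by three native bunchgrasses (PSSP = *Pseudoroegneria
spicata*, FEID = *Festuca idahoensis*, KOCR = *Koeleria cristata*) and
abandoned agricultural fields by three short-lived non-natives (BRTE =
*Bromus tectorum*, CEDI = *Centaurea diffusa*, SILO = *Sisymbrium
loeselii*). A two-phase common-garden experiment measures how each
three-species community grows on soils cultivated by single species, and
a community growth model asks whether those soil effects alone reproduce
the dominance switch observed across historical tillage boundaries.

## The model

Each species *i* has a per-step multiplicative growth rate on each
cultivated soil type *s*, derived from its final cover in the experiment:

    r_is = (F_is / I)^(1/55),    I = 0.004 (seed cover),  55 steps/season

The community state is a cover vector *x* and a soil-proportion vector
*w*. Per time step:

1. grow: `x_i <- x_i * sum_s w_s * r_is` (feedback on), or
   `x_i <- x_i * r_i(self)` (null model, feedback off);
2. cap: carrying capacities (pooled mean + 2 SD of community cover,
   ~0.42 native / ~0.41 non-native) bind on a shared-ground ceiling with
   group caps on top (`capacity_mode = "pot"`; `"group"` and `"damped"`
   variants available);
3. cultivate: soil proportions reset to the relative abundance of the
   plants cultivating each soil — between 55-step growing seasons by
   default (`soil_update = "season"`).

Landscape scenarios start every species from equal propagules on soil
mixtures matching native plant abundance at −50, −5, +5 and +50 m from a
tillage boundary (25/36/86/94% native soil), run 165 steps (three
seasons), and are compared with survey observations by rank order.

## Worked example

```r
library(psfland)

plots  <- generate_experiment(seed = 1)   # 250 plots: 2 communities x 5 soils x 25
survey <- generate_survey(seed = 2)       # 25 sites x 4 distances x 7 years

glance(soil_treatment_anova(plots, "native"))
#>   community f_statistic df_num df_den  p_value
#> 1 native           90.6      4    120 2.60e-35

tidy(soil_treatment_anova(plots, "native"))
#>   community soil_type mean_cover mean_transformed se_transformed     n letters
#> 1 native    PSSP            30.6            0.586        0.00958    25 a
#> 2 native    SILO            30.5            0.586        0.00958    25 a
#> 3 native    Mixed           30.3            0.583        0.00958    25 a
#> 4 native    BRTE            30.0            0.580        0.00958    25 a
#> 5 native    CEDI            13.8            0.380        0.00958    25 b
```

The native community differs among soil treatments (F(4, 120) = 90.6):
cover is halved on the soil cultivated by the dominant non-native
(CEDI, 13.8% vs ~30%), which alone carries the distinct letter "b".
The mirrored analysis of the non-native community shows the same
suppression on PSSP-cultivated soil.

```r
rates <- derive_rate_table(plots)    # (F/I)^(1/55) per species x soil
caps  <- derive_capacities(plots)
#> Carrying capacities (sample SD): native 0.4276, non-native 0.4043

comparison <- run_comparison(build_scenarios(), rates, caps, survey)
comparison
#>   distance_m observed_native observed_nonnative psf_native psf_nonnative
#> 1        -50            10.2              29.0        14.8          26.4
#> 2         -5            14.3              24.8        17.2          24.2
#> 3          5            37.6               6.81       28.3          13.7
#> 4         50            41.3               3.53       29.8          12.3
#>   null_native null_nonnative psf_agrees null_agrees
#> 1        13.8           27.4 TRUE       TRUE
#> 2        13.8           27.4 TRUE       TRUE
#> 3        13.8           27.4 TRUE       FALSE
#> 4        13.8           27.4 TRUE       FALSE

autoplot(comparison)   # grouped bars: observed / PSF model / null model
```

With feedback on, the model predicts the observed dominance switch at the
tillage boundary in all four distance classes (native plants dominate
never-tilled soils, non-natives dominate abandoned-agricultural soils).
With feedback removed, the null model predicts non-native dominance
everywhere — right only on the abandoned-agricultural side. The size of
that disagreement is the evidence that the soil feedback, not growth
rates alone, sets the landscape pattern.

See `vignette("plant-soil-feedback-model")` for the model's assumptions,
the generator calibration, and every numerical choice.

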