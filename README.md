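# qlcis

Analysis of time-lapse fluorescence immunospot assays on nanoliter-well
arrays — quantitative live-cell imaging of secretion (qLCI-S).

In this assay single cells sit in an array of nanoliter wells (996 cubic
80 µm wells per chamber, 115 µm pitch) whose glass floor carries capture
antibody; secreted cytokine is captured, stained by a fluorescent detection
antibody and imaged by TIRF microscopy every frame for days. The well-floor
fluorescence is a *cumulative* secretion signal (CSS): every release event
keeps contributing through the binding/bleaching kinetics of the
immunoassay. `qlcis` turns those traces into per-interval release
estimates, secretory phenotypes and secretion-site localizations, for
anyone analyzing single-cell cytokine secretion dynamics (e.g. IL-5/IL-13
release by innate lymphoid cells).

## The model

A unit instantaneous release produces the staining-kinetics response

    A(t) = [ Σ_j w_j exp(−t/τ_d,j) ] · [ Σ_k v_k (1 − exp(−t/τ_a,k)) ]

(1–2 exponential association terms × 1–2 exponential decay terms,
weights summing to 1, `A(0) = 0`). On a binned time grid the observed CSS
is the causal convolution `CSS_k = Σ_{i≤k} DSS_i · A_{k−i+1}` of the
per-bin release train (DSS), which the package inverts recursively:

    DSS_k = ( CSS_k − Σ_{i<k} DSS_i · A_{k−i+1} ) / A_1 ,

clamping negative intermediates to zero (secretion cannot be negative) and
propagating the clamped value. The IL-13 channel is first corrected for
cross-reaction of its detection antibody with captured IL-5 immunocomplexes
via the kernel `χ(Δt) = β e^(−Δt/τ4) {α(1−e^(−Δt/τ5)) + (1−α)(1−e^(−Δt/τ6))}`
driven by the deconvolved IL-5 train. Four microinjection-derived
calibrations (mouse IL-5, human IL-5, human IL-13, IL-13→IL-5 cross-talk)
ship with the package.

Downstream, wells are called positive when their CSS exceeds 3σ̂ for ≥ 2
consecutive frames (σ̂ = 1.4826 × MAD of empty-well intensities; dips ≤ 3
frames tolerated inside an episode) and classified silent / slightly
active / hyperactive with a 50σ̂ hyperactive limit. Secretion sites are
localized by 2D Gaussian fits to deconvolved signal images and compared
with tracked cell centroids. A synthetic experiment generator
forward-models the whole measurement (layout, phenotype mixture, kinetics,
drift, noise) so every stage is testable without microscope data.

## Worked example

```r
library(qlcis)
library(dplyr)

layout <- make_dish_layout(chambers = 2, wells_per_chamber = 200)
spec   <- population_spec(seed = 2024)          # fixes all randomness
truth  <- simulate_population(layout, spec)
obs    <- render_observations(truth, layout,
                              list(IL5 = builtin_calibrations("human-IL-5")),
                              spec)

cfg    <- qlcis_config(kinetics = c(IL5 = "human-IL-5"), seed = 2024)
bundle <- run_qlcis_pipeline(obs, cfg)
bundle$class_counts
#> # A tibble: 3 × 2
#>   class           n_wells
#>   <chr>             <int>
#> 1 hyperactive          52
#> 2 silent              217
#> 3 slightly_active     131
```

400 wells are partitioned into the three phenotypes; the 217 silent wells
include the ~100 empty wells the generator left without a cell. The
thresholds behind the calls come from the empty wells of this very dish:

```r
th <- bundle$thresholds$IL5
sprintf("sigma_hat = %.3f, detect = %.3f, hyper = %.2f",
        th$sigma, th$detect, th$hyper)
#> "sigma_hat = 1.402, detect = 4.206, hyper = 70.10"
```

(the generator's per-frame noise SD is 1; baseline subtraction differences
two frames, so σ̂ ≈ √2 as expected). Activation over time, with censoring
bookkeeping ready for log-rank comparisons:

```r
activation_curve(bundle$calls, horizon = 72) |> head(4)
#> # A tibble: 4 × 4
#>    time n_risk n_event fraction_active
#>   <dbl>  <dbl>   <dbl>           <dbl>
#> 1     1    400       6          0.0150
#> 2     2    394      17          0.0575
#> 3     3    377      46          0.172
#> 4     4    331      39          0.27
```

i.e. 27% of wells have started secreting by 4 h, consistent with the
generator's 1–12 h log-normal onset distribution. Dish optics validation:

```r
check_optics()
#> # A tibble: 3 × 3
#>   quantity                     angle_deg ok
#>   <chr>                            <dbl> <lgl>
#> 1 critical_angle_well_material      61.8 TRUE
#> 2 critical_angle_sample             61   TRUE
#> 3 aperture_limit                    78.6 TRUE
```

The fluoropolymer/glass critical angle (61.8°) sits below the objective's
aperture limit (78.6°), so a usable total-internal-reflection illumination
window exists.

A thin command-line wrapper over the same functions lives at
`inst/cli/qlcis.R` (`simulate | preprocess | deconvolve | call | localize |
stats | check-optics`), composing stages through CSV files.

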