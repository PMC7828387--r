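# vesicleflow

Whole-cell analysis of intracellular vesicle transport direction from
single-channel fluorescence time-lapse microscopy.

Quantum-dot-labeled vesicles are carried along microtubules by motor
proteins: dynein toward the microtubule-organizing center near the
geometric cell center (the direction of endocytosis), kinesin outward.
Instead of tracking individual particles, `vesicleflow` estimates a dense
optical-flow field for every adjacent frame pair and classifies each
pixel's motion as inward or outward relative to the cell center.

The method, per frame pair:

1. **Dense Lucas–Kanade optical flow.** At every pixel, the
   brightness-constancy constraint `Ix·Vx + Iy·Vy + It = 0` is solved in
   the weighted least-squares sense over a Gaussian-weighted window:

   ```
   [Vx]   [ ΣW²Ix²  ΣW²IxIy ]⁻¹ [ −ΣW²IxIt ]
   [Vy] = [ ΣW²IxIy ΣW²Iy²  ]   [ −ΣW²IyIt ]
   ```

   Pixels whose structure tensor has a small eigenvalue below threshold
   (the aperture problem) are flagged invalid.

2. **Cell-center estimation.** The per-pixel temporal standard deviation
   σᵢⱼ of the stack is low where vesicle traffic is quiet — near the
   center during early endocytosis. Pixels with σᵢⱼ < σ̄ − σₛ (σ̄, σₛ:
   mean and SD of the σ distribution) form a quiet mask whose centroid
   (C_x, C_y) is the center. By default the rule is restricted to the
   cell region (Otsu threshold on the temporal mean, holes filled).

3. **Direction classification.** With α the angle of the pixel-to-center
   vector and β the flow angle, the wrapped difference |α−β| ∈ [0, π]
   gives: Inward if |α−β| ≤ π/2, Outward otherwise.

4. **Summaries, polar view, rendering.** Per-frame counts, magnitudes
   and inward/outward proportions; resampling onto an (R, θ) grid about
   the center; and a diverging red–white–blue rendering of |α−β|
   (red = inward, blue = outward) alongside the conventional HSV flow
   encoding.

A seeded synthetic vesicle-movie generator with per-frame ground truth
(`simulate_vesicle_movie()`) makes every stage testable without
microscope data. See the vignette
(`vignettes/vesicle-transport-direction.Rmd`) for the model details,
parameter defaults, and design rationale.

## Worked example

```r
library(vesicleflow)

sim <- simulate_vesicle_movie(scene_config(seed = 1))   # 50 vesicles, half inward
fit <- vesicleflow(sim$stack, center = sim$truth$cell_center)
fit
#> <vesicleflow> 11 frame pair(s), 128 x 128 px
#>   cell center (row, col): (64.50, 64.50) [supplied]
#>   overall inward proportion: 0.491 (155359 vectors)

head(fit$summaries[, c("frame", "n_vectors", "prop_inward", "prop_outward")], 3)
#>   frame n_vectors prop_inward prop_outward
#> 1     1     15313    0.499902     0.500098
#> 2     2     15226    0.474583     0.525417
#> 3     3     15333    0.479293     0.520707
```

About 15 000 flow vectors pass the magnitude threshold per frame pair,
and with half the vesicles moving inward and half outward the proportions
sit near parity — an all-inward scene shifts `prop_inward` above 0.5 in
every frame. Estimating the center instead of supplying it
(`fit <- vesicleflow(sim$stack)`) uses the STD-map rule; on densely
labeled scenes (`scene_config_peripheral()`) it lands within ~1–3 px of
the truth. The sensitivity of the labels to center error:

```r
center_error_sensitivity(fit$flows, sim$truth$cell_center)$by_offset
#>   offset flip_percent mean_delta_error n_pixels
#> 1      1    0.4438912       0.01812802  1242872
#> 2      2    0.8780470       0.03561501  1242872
#> 3      5    2.1977323       0.08550647  1242872
#> 4     10    4.4544410       0.16312319  1242872
```

A 1 px center error flips 0.4% of labels; 10 px flips 4.5%.

`run_pipeline()` chains everything from a YAML/JSON config and writes the
full output bundle (flow CSV, center JSON, summaries CSV, polar TIFF,
PNG renderings, effective config); a thin CLI wrapper with subcommands
(`simulate`, `flow`, `center`, `classify`, `polar`, `render`,
`sensitivity`, `all`) is installed at `cli/vesicleflow.R` under the
package directory.

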