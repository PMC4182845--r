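# mulchres

Estimates the deterioration of agricultural mulch films — black
polyethylene (PE), biodegradable plastic (BD), and paper (PP) — from
color photographs of mulched plots. A film's deterioration is measured
as the percentage of bare soil showing through it.

Black films and moist soil are nearly indistinguishable in grayscale or
in the individual RGB planes, but the **saturation plane** of the HSV
representation separates them: intact black film is almost achromatic
while exposed soil keeps earthy chroma, so the saturation histogram of a
deteriorating plot is bimodal. The pipeline is

1. decode 8-bit sRGB, convert to HSV, take `S(x, y) ∈ [0, 1]`;
2. build the 256-bin histogram of `S`;
3. pick a threshold `t` by one of four methods:
   - **OT** — Otsu: maximize the between-class variance
     `σ_b²(t) = ω₀ω₁(m₁ − m₂)²` over all 256 splits,
   - **RC** — Ridler-Calvard isodata: iterate `t ← (m₁(t) + m₂(t))/2`
     to its fixed point,
   - **LE** — local entropy: maximize the summed Shannon entropy of the
     soil-soil and mulch-mulch quadrants of the gray-level
     co-occurrence matrix,
   - **MT** — a manual, user-supplied threshold;
4. binarize (`soil ⇔ S > t`), delete 8-connected components smaller
   than `m·n/100` pixels in the mask *and* its complement;
5. report `A = 100 · #soil pixels / (m·n)`.

The package also ships the statistical layer used to vet the methods —
paired t / Wilcoxon signed-rank tests with a Shapiro-Wilk normality
gate, and one-way ANOVA with Duncan's multiple range test — plus a
packaged 24-image field dataset (4 mulches × 6 blocks, with
expert-traced reference areas `A_R`) and a synthetic scene generator
with known ground truth.

## Worked example

```r
library(mulchres)

# a synthetic plot whose true bare-soil fraction is 35%
sc  <- make_scene(soil_fraction = 0.35, seed = 42)
rec <- process_image(sc$image, method = "otsu")
rec
#>   image_id mulch block method         t area_pct_precleanup area_pct
#> 1       NA    NA    NA     OT 0.3019608                  35 32.71875
```

The Otsu threshold 0.302 lands between the mulch (S ≈ 0.1) and soil
(S ≈ 0.5) modes; binarizing there recovers the true 35.0% exactly
(`area_pct_precleanup`). The cleanup pass then deletes soil patches
smaller than 1% of the frame — at this fraction the truth mask contains
a few such patches, so the final `area_pct` of 32.7% is slightly
conservative, the same bias the area rule imposes on real photographs.

On the packaged field data, the paired comparison of each method
against the expert reference reproduces the published analysis:

```r
reproduce_table3(load_table1())[, c("g2", "mean_diff", "sd_diff",
                                    "statistic", "p_value", "test_used")]
#>     g2 mean_diff sd_diff statistic p_value test_used
#> 1 A_OT     -1.73    7.42     -1.15  0.2637         t
#> 2 A_RC     -1.17    7.61     -0.75  0.4611         t
#> 3 A_MT     -3.22    6.53     -2.42  0.0241         t
#> 4 A_LE     -5.05   19.23     97.00  0.1355  wilcoxon
```

Only the manual threshold differs significantly from the reference
(p = 0.024); the normality gate routes only the heavy-tailed LE column
to the Wilcoxon test. `reproduce_table4()` runs the per-mulch
ANOVA/Duncan comparison, which puts polyethylene (mulch 3, < 20% bare
soil after 100 days) in its own Duncan group under every reliable
method, against ≈ 50% for the biodegradable films.

A thin command-line front end wraps these functions:

```sh
Rscript inst/cli/mulchres.R process --input photos/ --method otsu --out results.csv
Rscript inst/cli/mulchres.R reproduce-tables
Rscript inst/cli/mulchres.R simulate --out scenes/ --seed 1
Rscript inst/cli/mulchres.R fixtures table1 --out table1.csv
```

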