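# granulekit

Quantification of membraneless cytoplasmic protein granules formed by
RTK fusion oncoproteins (EML4-ALK, CCDC6-RET and kin) in live-cell
fluorescence microscopy — plus the FRAP and western-blot densitometry
analyses that accompany such studies, and a synthetic-data module that
makes every stage verifiable against planted ground truth.

**Who it is for.** Cell biologists and image analysts quantifying
punctate condensates in two-channel fluorescence images: how many
granules per cell, which signaling proteins colocalize with them and
how strongly they are enriched, how mobile the granule component is
(FRAP), and how the biochemical fractionation and signaling ratios
behave — with the statistics (t tests, one-way ANOVA + Tukey HSD, SEM)
used to compare conditions.

## What it computes

| Stage | Model / statistic |
|---|---|
| Correction | `I_corr = max(I / L − b, 0)`, `L` a robust order-2 log-polynomial illumination fit (mean 1), `b` autofluorescence |
| Detection | Otsu threshold over within-cell pixels; 8-connected components; equivalent-diameter gate `d = 2√(A/π)·px` in [0.4, 2] µm |
| Colocalization | object-based: greedy one-to-one matching of centroid pairs with distance ≤ cutoff (default 0.5 µm); % = 100·matched/reference |
| Enrichment | fold = mean signal over granule pixels ÷ mean over the whole cell area (fold 1 = no enrichment) |
| Phenotype | % cells with ≥ 6 granules (replicate-wise, ± SEM); treatment persistence = counts after/before; size/count distributions |
| FRAP | `F_norm = (F − F_b)/(F_pre − F_b)`; mobile fraction = % recovery at 1 min; optional fit of `M(1 − e^(−kt))` |
| Densitometry | fraction in pellet = pellet/(pellet+sup); double normalization `((sig/load)/(sig_c/load_c))/(expr/expr_c)` |
| Statistics | pooled/paired t, one-way ANOVA, Tukey–Kramer HSD via the studentized-range distribution, SEM |

The synthetic generators (`synth_field_image()`, `synth_frap_trace()`,
`synth_densitometry()`) plant cells, Gaussian granules with a chosen
fold enrichment, illumination, autofluorescence, Poisson + Gaussian
noise, two-state FRAP traces, and lognormal band noise — returning the
exact ground truth alongside.

## Worked example

```r
library(granulekit)

# a synthetic field: 5 cells, ~50 granules, SNR ~ 10, fold-3 recruitment
sf  <- synth_field_image(diameter_range = c(0.6, 1.6), seed = 1)
fi  <- correct_image(sf$image, autofluorescence = 20)
gsA <- segment_granules(fi, "A")          # granule channel
gsB <- segment_granules(fi, "B")          # signaling-protein channel
nrow(sf$truth$granules); nrow(gsA); nrow(gsB)
#> 50 planted; 48 and 47 detected

cr <- match_granules(gsA, gsB, cutoff = 0.5)
colocalization_fraction(cr, reference = "A")$pooled
#> 95.8      (percent of granules with a matched signaling feature)

fe <- fold_enrichment(gsA, fi$channels$B, fi$cell_mask)
fe$summary$mean
#> 2.58      (segmentation-based fold; planted 3.0 on half-max disks --
#>            Otsu pixel sets are slightly larger, see the vignette)

tr <- synth_frap_trace(M = 0.40, k = 0.05, dt = 3, noise_sd = 0.02, seed = 7)
mobile_fraction(normalize_trace(tr))
#> 36.5      (% recovery at 1 min; closed-form expectation 38.0)

g <- list(v1 = c(62, 71, 66), v3 = c(34, 30, 38), v5 = c(60, 64, 58))
r <- anova_tukey(g)            # e.g. % granule-positive cells per variant
r$F; r$p_overall
#> 58.8; 0.00011
r$pairwise[, c("group_i", "group_j", "p_adj")]
#>   group_i group_j    p_adj      (v1-v3 ***, v1-v5 n.s., v3-v5 ***)
```

Interpretation: detection recovered 48 of 50 planted granules; 95.8% of
them carry a signaling-channel feature within 0.5 µm (the scene plants
~90–100% recruitment); the mean enrichment reads 2.6 on Otsu pixel sets
for a planted half-max fold of 3; the simulated granule recovered 36.5%
of its bleached intensity in one minute (mobile fraction), near the
planted expectation of 38%; and the three-group comparison finds the
middle group significantly lower by Tukey HSD.

## Command line

```sh
granulekit config --out config.yaml                    # default config
granulekit run --synth --config config.yaml --seed 1 --out results/
granulekit synth frap --seed 3 --out traces/
granulekit frap --in traces/frap_trace.csv --fit
granulekit stats anova --in tidy.csv --alpha 0.05
```

(`granulekit` is `exec/granulekit`, an Rscript wrapper around
`granulekit_main()`; exit codes: 0 ok, 1 user error, 2 internal.)

The methods vignette
(`vignettes/granule-quantification.Rmd`) documents the models, the
tunable parameters with units and defaults, the synthetic world and its
deliberate simplifications, numerical choices, and known limitations.
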