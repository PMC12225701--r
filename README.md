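# sedacomp

Side-by-side analysis of the two sequencing strategies used on sedimentary
ancient DNA (sedaDNA) records — metabarcoding and shotgun metagenomics —
with a damage-based authentication model and a taphonomic simulator that
makes the whole pipeline testable without external data.

## The science

A sediment core is a biodiversity time series, but DNA degrades in it:
fragments shorten (geometric lengths with mean
`lambda(age) = lambda0 * exp(-lambda_decay * age)`) and cytosine
deamination accumulates, read as C-to-T substitutions concentrated at 5'
fragment ends. The two analysis arms respond very differently:

- **Metabarcoding** needs an intact fragment spanning the whole amplicon
  (90–130 bp here). The amplifiable fraction is the geometric tail
  `P(L >= len)`, so per-PCR-replicate detection
  `p = 1 - exp(-gamma * abundance * P(L >= len))` collapses with age.
- **Metagenomics** maps reads down to ~30 bp and keeps detecting, but an
  extraction chain optimised for short ancient fragments under-recovers the
  long fragments that dominate young samples.

With constant true richness, these two filters alone produce opposing
apparent richness trends — a methodological artifact that would read as
ecological change. The package implements:

- the metabarcoding filter cascade: orientation merging, singleton
  removal, a per-ASV negative-control floor (max count across all pooled
  negatives; strictly lower experimental cells zeroed), an inclusive
  75–150 bp length window, rarefaction to 20,000 reads, cumulative sum
  scaling, LCA assignment of ASVs, positive-replicate counting;
- the metagenomic chain: inclusive 0.95–1.00 identity band, per-read LCA,
  genus roll-up with a 100-read observation floor, positional damage
  counting (`k_x`, `n_x` for x = 1..15);
- the age–damage model: binomial MLE of
  `k_x ~ Bin(n_x, A (1-q)^(x-1) + c)` with Wald `z = A/se(A)`; an
  age–damage envelope calibrated on terrestrial plants (≥ 500 reads,
  z ≥ 2, eelgrass excluded) as the running minimum amplitude over
  calibration ages; authentication of each (genus, sample) observation as
  `ancient`, `not_damaged` or `unassessable`;
- diversity statistics: richness OLS comparison, Bray-Curtis/Jaccard on
  relative frequencies, NMDS/PCoA, procrustes (protest) and Mantel
  permutation tests with add-one p-values;
- a seeded simulator of complete records (11 samples, 0–8300 cal BP,
  8 PCR replicates, negative controls, ~64 genera with a realistic rare
  tail) with known ground truth.

## Worked example

```r
library(sedacomp)

report <- run_pipeline(sim_config(seed = 1))
report
#> <sedacomp_report>
#>   samples: 11  ASVs retained: 61  genera profiled: 31
#>   authenticated observations: 225
#>   full-community Mantel (Bray): r = 0.589, p = 9.999e-05

report$richness$age_trends
#> # A tibble: 2 × 3
#>   arm           slope_per_kyr      r
#> 1 metabarcoding        -4.28  -0.947
#> 2 metagenomics          0.558  0.726

report$richness$comparison
#> # A tibble: 1 × 4
#>    slope intercept      r p_value
#> 1 -0.104      26.5 -0.611  0.0460
```

True richness is constant in the simulation, yet metabarcoding richness
falls steeply with age (r = −0.95) while metagenomic genus richness rises
(r = +0.73), and the two series relate negatively (slope −0.10, p < 0.05):
the purely methodological artifact the package exists to expose. Beta
diversity tells the opposite story — the full-community Mantel between the
arms is strongly positive (r = 0.59), because both arms see the same
underlying turnover gradient.

Damage authentication for one abundant genus in the oldest sample:

```r
dc  <- report$mg$damage_counts
one <- dc[dc$genus_taxid == 100 & dc$sample_id == "s11", ]
fit <- fit_damage(one$k, one$n)
fit
#> <damage_fit> A = 0.2976 (se 0.0228, z = 13.07), q = 0.385, c = 0.0145, n = 311
tidy(fit)      # broom-style parameter table
plot_damage_profile(one, fit)
```

An amplitude of ~0.30 at position 1 with z = 13 is an unambiguous ancient
signature; the same genus in the youngest sample fits to a flat profile and
is left unauthenticated. `plot_richness(report)`,
`plot_detections(report$detections, tree)` and
`autoplot(report$beta$full$ord_mb, ages = report$record$samples)` draw the
standard comparison figures.

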