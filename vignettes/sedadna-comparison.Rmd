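---
title: "Comparing metabarcoding and metagenomics of sedimentary ancient DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metabarcoding and metagenomics of sedimentary ancient DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedacomp)
```

## The problem

Sedimentary ancient DNA (sedaDNA) records are analysed with two very
different sequencing strategies. Metabarcoding amplifies a homologous
taxonomically informative fragment (here an 18S V9-style marker of 90--130 bp)
across many independent PCR replicates per sediment sample; shotgun
metagenomics sequences the total DNA pool and classifies reads against
reference databases. Both arms look at the same extract, but each sees it
through its own taphonomic filter. DNA buried in sediment fragments and
deaminates progressively: the mean surviving fragment length declines with
age, and cytosine deamination accumulates as C-to-T substitutions
concentrated at fragment ends. Amplification needs an intact fragment
spanning the whole amplicon, so metabarcoding detectability collapses with
age even while the taxon's shorter fragments are still abundant; read
mapping works down to ~30 bp, so metagenomics keeps detecting. The package
implements both analysis chains, a damage-based authentication model, the
diversity statistics used to compare the two arms, and a simulator that
generates complete records with known ground truth so every stage is
testable without any external data.

`sedacomp` is tidyverse-native: every user-facing function takes a data
frame (or `dist`) first and returns a tibble or a small S3 object with
tibble fields, so chains compose with the pipe; fitted damage models have
`tidy()`/`glance()` methods and result types have plot builders.

## The simulator: what it emulates

`sim_config()` + `simulate_record()` draw the ground truth;
`emit_metabarcoding()` and `emit_metagenomics()` turn it into the raw
observables each arm would produce. Everything is a deterministic function
of the seed.

**Record design.** Eleven samples spanning 50--8300 calibrated years BP,
five younger than 2000 BP and six between 4200 and 8300 BP — the archived
marine-core design the package targets. Each sample carries a true
community over ~64 genera: a few abundant marine taxa (herring, cod, a
larvacean, diatoms, eelgrass), five moderately abundant metazoans, four
terrestrial plant genera (the damage-calibration material), fifteen rarer
genera whose expected metagenomic read counts straddle the 100-read genus
reporting threshold, a 30-genus rare phytoplankton tail far below that
threshold but amplifiable (most amplicon diversity in real records is
exactly this), and three modern contaminants. True richness is constant
across the record by construction: every detectability trend in the output
is methodological, not ecological.

**Turnover.** Log-abundances drift linearly with scaled age
(per-taxon slope ~ N(0, `gradient_sd`), cell noise ~ N(0, `noise_sd`)), so
community composition turns over smoothly through time — the "continuous
separation through time" that ordinations of real records show. Both arms
share this truth unless `decouple_metazoa = TRUE` (below).

**Fragmentation.** Fragment lengths are geometric with age-dependent mean
`lambda(age) = lambda0 * exp(-lambda_decay * age/1000)` (defaults 130 bp and
0.18/kyr, giving ~30 bp at 8 kyr). The geometric law is the standard
single-parameter fragmentation model for ancient DNA. The amplifiable
fraction of a taxon whose amplicon is `L` bp is the geometric tail
`P(len >= L) = (1 - 1/lambda)^(L-1)`; the metagenomic arm instead keeps
fragments inside a capture window (30--70 bp by default: the mapper floor
below, the short-fragment-optimised extraction above). The window's upper
edge is what makes metagenomic genus richness *rise* with age while
metabarcoding richness falls — young samples are rich in long fragments the
ancient-DNA-optimised chain recovers poorly.

**Detection.** A PCR replicate detects a taxon with occupancy probability
`1 - exp(-gamma * abundance * amplifiable_fraction)` rather than via an
explicit PCR-cycle simulation; replicate-level stochastic dropout (the
"number of positive reps") is the quantity analysed downstream, and the
occupancy form reproduces it with one interpretable efficiency parameter
(`gamma_amp = 80`). Sequencing depth per replicate is log-normal and shared
multinomially among detected ASVs plus a small off-target floor; spurious
singletons are injected at 2%; some taxa are emitted in both read
orientations; negative controls receive sparse Poisson contaminant counts.

**Damage.** True amplitude follows a saturating exponential
`A(age) = a_max (1 - exp(-k_age * age/1000))` (defaults 0.30 and 0.35/kyr)
for in-situ and plant material, and 0 for modern contaminants. The source
literature gives no quantitative accumulation law (its own age-damage
profile is not smooth); the saturating form is a stand-in chosen for
monotonicity and boundedness, and the package makes no inference that
depends on its exact shape — only on damage increasing with age. Per read,
C-to-T mismatches are drawn independently at 5' positions `x` with
probability `A (1-q)^(x-1) + c` (`q = 0.35`, background `c = 0.01`); 3'
G-to-A offsets are generated symmetrically and recorded but not modelled.

**What the simulator does not emulate.** No real sequences (ASVs are random
strings; only length and orientation matter downstream), no chimeras, no
sequencer error beyond the identity band, no reference-database
incompleteness, and damage offsets are counted against reads rather than
reference cytosine positions (the estimator uses the same convention, so
estimator and generator are consistent — a documented divergence from
reference-conditioned damage tools). Passing tests therefore demonstrate
internal correctness of the pipeline and the qualitative taphonomic
mechanisms, not performance on real sequence data.

## The metabarcoding filter cascade

The cascade follows a fixed order; each stage is idempotent and
non-increasing in total counts:

1. `merge_orientations()` — reverse-complement one orientation, sum ASVs
   with identical sequence per replicate.
2. `remove_singletons()` — any observation of exactly one read becomes zero.
3. `negative_floor_filter()` — for each ASV, the maximum count across all
   negative controls (extraction, PCR and library negatives pooled) is a
   conservative false-positive floor; experimental cells strictly below it
   are zeroed, cells at the floor are kept. The floor is per-ASV, not
   global; comparison is strict, reading "lower than the maximum"
   literally. A `exclude_replicates` argument lets a known catastrophic
   control replicate be excluded from floor computation (off by default).
4. `length_filter()` — inclusive 75--150 bp window (140 for a vertebrate
   12S-style marker).
5. Two normalisation branches: `rarefy()` (20,000 reads per replicate,
   multivariate hypergeometric, replicates below depth dropped) and
   `css_normalize()` (cumulative sum scaling re-implemented from its
   published description: per-replicate scaling factor = sum of counts up
   to a quantile of the positive counts, rescaled by the median factor;
   the adaptive mode scans quantiles and takes the first unstable one,
   falling back to the fixed median).

Whether the floor pools all three control types, and whether it precedes
the length filter, are genuinely open in the source protocol; pooling and
the narrative order are adopted here and tested as such.

`assign_asvs()` mirrors LCA parsing of reference hits: hits within 1% of
the best identity enter the LCA (a configurable top-percent band, the
common practice where the original parsing script leaves the band
unstated), and ASVs whose best hit fails the >99% identity / >95% coverage
screen are flagged low-quality. `positive_replicates()` collapses the
filtered table to the per-sample occupancy counts used as the
metabarcoding abundance proxy.

## The metagenomic chain and the age-damage model

`filter_hits()` keeps hits with identity in the inclusive 0.95--1.00 band;
`classify_reads()` assigns each read the LCA of its surviving hits;
`genus_table()` rolls genus-or-finer assignments up to genus and drops
(genus, sample) observations under 100 reads (reads assigned above genus
are discarded and audited). The 100-read threshold is applied per
(genus, sample) observation, consistent with how post-filter observation
counts are reported in this literature. `damage_counts()` tallies, per
group and 5' position `x = 1..15`, the mismatch count `k_x` and the
opportunity proxy `n_x` (reads at least `x` bp long); beyond ~15 positions
the signal is indistinguishable from background and fits destabilise.

`fit_damage()` maximises the binomial likelihood of
`k_x ~ Bin(n_x, A(1-q)^(x-1) + c)` under box constraints
(`A, c` in [0,1], `q` in [0, 0.99]) with L-BFGS-B, starting from
moment-style values (background from the profile tail, amplitude from the
position-1 excess). The standard error of `A` comes from the observed
information; if the full Hessian is singular the curvature of the profile
in `A` alone is used, and a flat profile degrades gracefully to `A ~ 0`
with small `z`. The significance statistic is the Wald ratio `z = A/se(A)`
— the simplest defensible reading of a "significance z value". Parameter
recovery and the false-significance rate (under 10% at `A = 0`,
`n_x = 5000`) are checked by simulation in the test suite.

`build_envelope()` calibrates authentication on terrestrial plants
(Viridiplantae excluding the marine eelgrass genus): plant material must
have been transported into marine sediment, so its damage is a conservative
minimum for any in-situ detection of the same age. Calibration points are
plant fits with at least 500 reads and `z >= 2`; the envelope at age `a` is
the running minimum amplitude over calibration points no older than `a`,
linearly interpolated and held constant beyond the oldest point. Because
damage increases with age, the running minimum is typically flat at the
youngest qualifying amplitude — the envelope is a deliberately low bar, and
authentication in practice hinges on the `z >= 2` screen; this matches the
"conservative minimum damage" reading of the source method. Whether
"minimum values" meant raw minima or a fitted lower bound is unstated
there, so a per-age-bin variant (`method = "binned"`) is provided.
`classify_ancient()` marks an observation `ancient` when `z >= 2` and its
amplitude reaches the envelope at its age (both inclusive, so boundary
observations are not silently discarded), `not_damaged` when assessable but
failing either condition, and `unassessable` at ages younger than the first
calibration point — on the default record the youngest sample is always
unassessable, mirroring how young detections cannot be damage-authenticated.

## Diversity comparisons

Richness is positive-feature counts per sample; the two arms' series are
compared by ordinary least squares (`compare_richness()`). Community tables
are standardised to relative frequencies before Bray-Curtis and Jaccard
dissimilarities; metabarcoding abundance is positive-replicate counts,
metagenomics read counts. NMDS uses 20 seeded random restarts (stress type
1); PCoA is classical `cmdscale`. `procrustes_test()` and `mantel_test()`
wrap the standard permutation tests (999 and 10,000 permutations by
default) with add-one p-value estimators, so p is never exactly zero; the
Mantel statistic is the Pearson correlation over off-diagonal upper
triangles. NMDS dimensionality (k = 2) and the restart policy are
documented assumptions; nothing downstream depends on them beyond the
reported stress.

## Orchestration and determinism

`run_pipeline()` chains simulate → emit → filter → profile → damage →
diversity and returns a single report object with a per-stage audit trail
(rows and reads in and out of every filter — the filter accounting that
deserves to be a first-class output). `write_report()` emits the whole
bundle as TSV/JSON plus a manifest. Every random step (simulation,
rarefaction, NMDS restarts, permutation tests) is seeded from the
configuration seed, so an identical configuration reproduces the report
byte for byte. The spec'd command-line surface is served by these exported
functions and by `scripts/acceptance.R`; an R-native package is the
interface its users would actually script against.

## Design notes on the validation experiments

The packaged checks run at deliberately modest problem sizes chosen to make
the statistical properties sharp but cheap: damage recovery uses 50
replicate fits per condition at `n_x = 5000`; permutation-test calibration
uses 500 null datasets of 12 samples × 20 features at 99 permutations
(where the add-one estimator makes the nominal 5% level exact); end-to-end
checks run the default 11-sample record at 40,000 metagenomic reads per
sample. One check deserves a note: with a truly decoupled metazoan block
the cross-arm Mantel p is uniform by construction, so any single-record
assertion "p > 0.05" would fail for one record in twenty no matter how
correct the code. The packaged check therefore asserts the *median* p over
five independently decoupled records exceeds 0.05 — the same scientific
property, with a failure probability near 1e-5 under the null instead
of 5%.

## Known limitations

- The damage opportunity proxy counts reads, not reference cytosines; the
  absolute amplitude is therefore not comparable with reference-conditioned
  tools, though its age trend and significance behave the same way.
- The age-damage accumulation law is a stand-in; only monotonicity is
  relied on.
- The metazoan-subset beta-diversity comparison is intrinsically unstable
  at realistic subset sizes (a handful of genera); the package reports it
  but the validation suite does not assert its significance in the coupled
  case, matching how inconsistently such subsets behave in real records.
- `lca()` treats all retained hits equally; there is no bit-score
  weighting or tie-breaking beyond the identity band, and no name-based
  synonym resolution.
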