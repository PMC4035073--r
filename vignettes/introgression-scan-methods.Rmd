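---
title: "Methods: detecting indica–japonica introgression in admixed rice cultivars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting indica-japonica introgression in admixed rice cultivars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

Japanese high-yielding (HY) rice cultivars descend from crosses between
domestic *japonica* parents (PD) and overseas *indica* parents (PO-indica),
followed by generations of selection. Their genomes are mosaics of the two
subspecies, and regions where one parental genome type dominates across many
cultivars are candidates for loci under selection for yield-related traits.
`introscan` implements the full chain of analyses for this setting:

1. **Panel design** — choose an informative SNP panel whose density is
   matched to the linkage disequilibrium (LD) of the material;
2. **Diversity statistics** — MAF, expected heterozygosity (gene diversity)
   and polymorphism information content (PIC) per population, with a
   resampling adjustment for unequal sample sizes;
3. **Ancestry scan** — a parental-frequency-adjusted indica-allele frequency
   statistic in the HY pool, summarised in five-SNP windows, with skewed
   regions called against a genome-wide quantile band;
4. **Association** — a mixed-linear-model (MLM) genome scan with family-wise
   permutation P-values, intersected with the skewed regions and annotated
   with candidate genes/QTLs from a user-supplied feature catalog;
5. **Simulation** — a breeding-population generator producing genotypes,
   phenotypes and ground truth for parameter-recovery testing.

## Statistical model and procedures

### Informative-marker filters

Two filters mirror the two screening stages of a typical panel design. The
*core screen* (a small set of, say, 14 screening cultivars) keeps markers
with **no missing call** and whose **minor allele is carried by at least 3
cultivars**. The *panel screen*, over all accessions, drops markers that
(1) lack a map position, (2) are heterozygous or missing in more than 5% of
accessions, or (3) have MAF ≤ 2% (inclusive: exactly 2% is dropped — the
rule is a genotyping-error guard, so the boundary errs toward exclusion).

### Adjacent-pair LD and the subset-size curve

For essentially inbred lines, haplotypes are read directly from homozygous
genotypes; heterozygous or missing calls are dropped **pairwise** because
phase is unknown there. For two markers, with `p_A`, `p_B` the allele
frequencies and `p_AB` the two-locus frequency over the shared homozygous
cultivars,

\[
\Delta^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A(1-p_A)\,p_B(1-p_B)},
\]

the squared correlation of 0/1 allele indicators. A marker monomorphic in
the usable subset makes the statistic undefined (`NA`), never zero.

The subset-size simulation draws random panels of increasing size, forms
**within-chromosome adjacent pairs** (chromosome boundaries never pair), and
averages the "complete LD" pairs, those with `0 < Δ² < 1`. The open
interval deliberately excludes pairs in linkage equilibrium (0) and in
perfect LD (1); `mean_mode = "all"` computes the unrestricted mean for
comparison. The curve rises with panel size and plateaus once the mean
inter-marker spacing falls well below the LD decay length; the plateau is
where extra markers stop adding information, and the package reports the
curve (mean ± SE over 10 replicates per size) and leaves the choice of
working size to the user.

### Diversity statistics

Frequencies count gene copies: a homozygote contributes two copies, a
heterozygote one of each, missing calls leave the denominator. For allele
frequencies `p_i`,

- `He = 1 − Σ p_i²`,
- `PIC = 1 − Σ p_i² − Σ_{i<j} 2 p_i² p_j²`,
- `MAF = min(p_i)`.

Per-population means include markers monomorphic within the population
(contributing 0); markers with no call in a population are dropped from its
mean. Because these means depend on sample size, the *adjusted* variants
recompute each mean as the average over 10 subsets of 14 cultivars drawn
**without replacement** (both counts configurable); `seed` fixes the draw.

### The adjusted-HY ancestry statistic

A marker is **discriminating** when the frequency of a fixed allele differs
by strictly more than 0.7 between PD and PO-indica. (Thresholding one
allele's frequency difference is equivalent to the major-allele-frequency
difference for such markers and avoids picking a reference pool.) The
tracked **indica allele** is the PO-indica major allele; exact 0.5 ties are
broken alphabetically with a warning.

With `HY`, `PD`, `PO` the indica-allele frequencies in the three pools,

\[
\text{adjusted HY} = HY - PD - (1 - PO),
\]

unclamped (range −2 to 1). The subtraction corrects for residual indica
alleles in the japonica parents and incomplete fixation in the indica
parents: near 1 means indica introgression, near or below 0 a japonica
background. Note the statistic is *not* antisymmetric between the two
orientations: with fully fixed parents the indica- and japonica-oriented
values are complements (they sum to 1), which is what the package's
property tests assert.

Values are summarised in **non-overlapping windows of 5 consecutive
discriminating SNPs** per chromosome (median and 25th/75th percentiles,
linear-interpolation quantiles). Tiling, rather than sliding, keeps window
values independent; `sliding = TRUE` is available. A terminal remainder
window is summarised and flagged `partial`. The genome-wide band is the
25th–75th percentile range of the **window medians** (default; `band_on =
"snps"` uses all per-SNP values instead — both are defensible readings and
the choice is recorded in the result). A window strictly above the band is
`INDICA_SKEWED`, strictly below `JAPONICA_SKEWED`; adjacent same-class
windows merge into intervals bounded by their first and last member SNPs.
By construction roughly half of all windows lie outside a quartile band, so
isolated one-window calls are expected background; the biologically
interesting signals are the *long merged runs*, and downstream analysis
additionally requires trait association.

Genome types classify each cultivar by its fraction of indica alleles at
discriminating SNPs (heterozygotes count ½): `JA` at ≤ 0.3, `IN` at ≥ 0.7,
`MX` between. The thresholds are reporting conventions — the source
material classifies by visual inspection — chosen to separate
clearly dominant backgrounds from mixtures; they are echoed in the output
and freely adjustable.

### Mixed-model association and permutation calibration

The scan fits `y = μ + xβ + u + e` with `u ~ (0, σ²_g K)` and
`e ~ (0, σ²_e I)`, where `K` is the VanRaden kinship (centered-dosage
cross-product scaled by `Σ 2p(1−p)`, missing dosages mean-imputed for this
computation only). Following the P3D/EMMAX strategy, the variance ratio
`λ = σ²_g/σ²_e` is estimated **once** on the null model by REML — a
bracketed scalar search over `log λ ∈ [−10, 10]` (tolerance 1e-6) on the
eigendecomposition of `K` — and every marker is then tested by a
generalised-least-squares F-test at that ratio. With `K = I` the model
collapses exactly to ordinary least squares, which the tests exploit as an
oracle. The default marker set keeps markers with MAF ≥ 0.05 and call rate
≥ 95% among the phenotyped lines; both filters are exposed, and the chosen
count is reported.

Permutation P-values are **family-wise**: the phenotype vector is permuted
across cultivars, λ is re-estimated per permutation (the null fit is cheap
on the cached eigendecomposition), and the genome-wide maximum F is
recorded; a marker's empirical P is `(1 + #{max F ≥ observed F})/(n_perm +
1)`. The add-one estimator bounds P below by `1/(n_perm+1)` and makes the
test exact under exchangeability. The per-marker and family-wise readings
of "permutation P" differ; the family-wise reading is adopted because it is
the standard error control for a genome scan, with a resolution of about
0.001 at 1000 permutations.

Markers with permutation P **strictly below** 0.01 that fall in a
non-neutral window are intersected into the candidate list; each is then
annotated with features from a user-supplied catalog inside a **closed 4-Mb
window centered on the SNP** (clipped at the chromosome start): `GENE`
features in the matching trait category first, `QTL` features only when no
gene overlaps. The same category filter is applied to both kinds for
consistency, since no separate rule is specified for QTL queries. Allele
effects are reported as mean ± sample SD of the trait per homozygote class
(hets excluded; SD undefined below 2 cultivars).

## The synthetic-data generator

`sim_config()` defaults describe the study system: 12 chromosomes × 30 Mb
scored at 1200 SNPs; 14 PO-indica and 20 PD homozygous parents with 70% of
markers at a fixed frequency difference and 30% partially diverged
(difference ~ Beta(2,2)); 60 HY progeny whose parental-origin tracks form a
Markov mosaic with exponential block lengths (mean 5 Mb) and stationary
indica fraction 0.3, the chain state carried across chromosome boundaries so
the long-block limit yields single-origin genomes; three selection-skewed
regions driven to indica frequency 0.9 by redrawing block origins inside
them (the analysis consumes only the resulting frequency skew, so explicit
truncation selection over named generations is not modelled); heterozygous
and missing calls sprinkled at 1% each, matching material that passes the
5% het+missing filter.

Phenotypes are `Σ effect·dosage(QTL) + polygenic + noise`. QTL effects act
on **standardized** dosages, so each QTL's variance share is set by its
effect size rather than by the realised allele frequency — without this, a
region whose frequency drifts toward fixation would silently abolish its
QTL's variance and with it the premise of any recovery experiment. The
polygenic term is drawn from the progeny kinship and scaled so the QTLs
carry `qtl_frac` of the genetic variance; the noise is scaled so the
realised narrow-sense heritability equals `h2` exactly in the simulated
sample. The default trait architecture is major-gene: two traits, each with
one QTL inside a skew region, `h2 = 0.85` and `qtl_frac = 0.9` (~77% of
trait variance per QTL) — the regime of cloned large-effect rice loci such
as heading-date and blast-resistance genes, which is the kind of signal
this scan is designed to recover. `h2 = 0` produces pure-noise traits for
calibration studies. A variance share near the detection boundary (~25% at
n = 60 against ~1200 markers under family-wise permutation control) sits at
roughly 50% per-replicate power; users studying that regime should expect
partial recovery.

What the generator does *not* emulate: genotyping-error structure beyond
uniform het/missing noise, LD within the parental pools, pedigree-specific
relatedness among HY lines (all lines are exchangeable draws), multi-allelic
markers, and trait architectures with many small QTLs. Passing
recovery tests therefore demonstrates the pipeline's logic on data matching
its assumptions, not performance on any particular real breeding panel.

## Numerical choices and degenerate inputs

- Quantiles are linear-interpolation (R type 7) everywhere.
- "Outside the band" is strict inequality; a degenerate (zero-width) band
  makes every window `NEUTRAL`.
- Undefined quantities are `NA` and excluded with a message — never coerced
  to zero: all-missing allele frequencies, Δ² at monomorphic markers, LD
  replicates with no pair inside (0, 1).
- REML eigenvalues are clipped at zero; a phenotype fully explained by the
  null model returns zero F and P = 1 rather than 0/0.
- Markers monomorphic among phenotyped lines are reported with `NA`
  statistics and logged, keeping the output aligned with the input marker
  list.
- Seeds: every stochastic entry point takes `seed`; internal sub-seeds are
  derived additively and kept below 2^31.

## Problem sizes used by the test-suite experiments

Unit tests run on toy matrices and a 4-chromosome, 240-marker population.
The statistical acceptance experiments use the default study conditions:
permutation calibration uses 200 null traits × 500 permutations on 150
markers × 60 lines; end-to-end recovery uses 20 replicates of the default
1200-marker, 60-line population with 300 permutations per trait; the LD
plateau check uses panel sizes 100–1193 × 10 replicates. These sizes give
each check enough resolution (e.g. a binomial 95% band of [0.02, 0.09]
around the nominal 0.05 family-wise rate) while keeping the suite quick on
a laptop.

## Worked example

```{r example, eval = FALSE}
library(introscan)
library(dplyr)

sim <- simulate_population(sim_config(), seed = 11)

# ancestry scan: discriminating SNPs, windows, skewed intervals
prof <- ancestry_profile(sim$geno, sim$panel)
prof$intervals |> filter(skew == "INDICA_SKEWED", n_windows >= 3)
plot_ancestry_profile(prof)

# association with family-wise permutation P, intersected with skew
scan <- mlm_scan(sim$pheno, sim$geno, trait = "heading_date") |>
  permutation_p(n_perm = 500, seed = 42)
hits <- intersect_with_skew(scan, prof, alpha = 0.01)
candidate_lookup(hits, sim$features, trait_category = "heading_date")
plot_manhattan(scan)
```

## Known limitations

- The ancestry scan is frequency-threshold based, as designed; it does not
  model local-ancestry uncertainty (no HMM) and inherits the band's
  built-in ~50% outside rate for isolated windows.
- The MLM uses a single global λ (P3D); strong QTLs inflate λ slightly and
  cost some power relative to per-marker exact mixed models.
- Kinship includes the tested markers (no leave-one-chromosome-out), the
  standard but slightly conservative choice.
- The permutation test assumes exchangeable phenotypes; structured
  non-genetic covariates should be supplied as fixed covariates.
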