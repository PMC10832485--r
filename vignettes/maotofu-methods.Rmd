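---
title: "Methods: amino-acid scoring, volatile quantification, 16S profiling and correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maotofu)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the methodology left room.

## 1. Amino-acid nutritional scoring

### Model

Seventeen amino acids are measurable after HCl hydrolysis (tryptophan is
destroyed), stored as g per 100 g sample together with the sample's crude
protein percentage. Scoring against a reference pattern first converts to
mg per g protein (`content * 1000 / protein_pct`), because reference
patterns are expressed on a protein basis.

For each essential amino acid (EAA) entry $k$ of the pattern:

$$\mathrm{RAA}_k = \frac{u_k}{\alpha_k},\qquad
  \mathrm{RC}_k = \frac{\mathrm{RAA}_k}{\overline{\mathrm{RAA}}},\qquad
  \mathrm{SRC} = 100 - 100\,\mathrm{CV},\ \ \mathrm{CV}=\frac{\mathrm{sd(RC)}}{\mathrm{mean(RC)}}$$

`mean(RC) = 1` is an algebraic identity (asserted to 1e-9 in the tests);
the EAA with minimal RC is the first limiting amino acid. The fuzzy
closeness to a model protein (whole egg) over the seven combined EAA terms
is

$$\mu(\alpha, u) = 1 - c \sum_{k=1}^{7} \frac{|\alpha_k - u_k|}{\alpha_k + u_k},
  \qquad c = 0.09,$$

which maps into $[1-7c, 1] = [0.37, 1]$: the lower bound is attained by an
all-zero profile, and $\mu = 1$ only for a term-by-term match.

### Reference data and their provenance

Neither the WHO/FAO requirement pattern nor the egg pattern is something a
scoring run should hard-code invisibly, so both ship as editable TSV files
(`extdata/`): the classical WHO/FAO (1973) pattern (Ile 40, Leu 70, Lys 55,
Met+Cys 35, Phe+Tyr 60, Thr 40, Val 50 mg/g protein) and the whole-egg
pattern (54/86/70/57/93/47/66). Trp is excluded by default because the
hydrolysate cannot contain it. The taste-threshold table is likewise a
bundled, editable TSV compiled from the free amino-acid taste literature;
the Tyr and Cys rows are weak/"tasteless" placeholders since no established
thresholds exist for them.

### Numerical decisions

* **CV uses the population (n divisor) standard deviation**, so SRC is
  exactly 100 at uniform RC for any number of entries; the sample-sd
  variant is available via `sd_type = "sample"`.
* **Limiting-amino-acid ties** break alphabetically by code, keeping
  reports deterministic.
* **TAV direction.** Taste activity is computed as content/threshold — the
  only direction under which "TAV > 1 implies a taste contribution" is
  coherent; the inverted ratio found in parts of the literature is
  available via `invert = TRUE`. The contribution test is strictly
  `tav > 1`: a compound exactly at its threshold does not contribute.
* **EAA/NEAA with zero NEAA mass** is reported as `NA` with a
  `neaa_undefined` flag rather than an error, so boundary compositions
  still yield the defined EAA/TAA part.

### A known interpretive limitation

The closeness $\mu$ penalizes deviation from the egg pattern in *either*
direction. Fermented samples with a large EAA excess therefore score lower
than a milder profile, even though an excess is nutritionally benign. Claims
that the most EAA-enriched sample is also the "closest to egg" cannot, in
general, be reproduced by this index and the package does not assert them.

## 2. Volatile semi-quantification

Quantification against a 2-octanol internal standard of known in-matrix
concentration $C_{is}$ (µg/g):

$$C = \frac{A_c}{A_{is}} \cdot C_{is}$$

per sample; the IS row is consumed and excluded from outputs. Relative
percentages are computed over analyte concentrations within each sample and
sum to 100 before filtering. The ">1 %" report uses a strict inequality
(a row at exactly 1 % is dropped). Compound identity across samples is an
exact name match after case-folding and whitespace normalization — no
spectral matching.

The default $C_{is} = 0.0275$ µg/g corresponds to a 0.14 µg spike into
roughly 5.1 mL of extract. The true spike level depends on the extraction
protocol and should always be supplied explicitly when known; the default
is a documented assumption, not a measurement.

## 3. Community profiling

The stage mirrors a full-length 16S CCS workflow at desk scale:

1. **Demultiplexing** is an exact match of the read's first 16 bases
   against the barcode table (the tag is also stripped from the 3′ end when
   it terminates the read, as barcodes are ligated to both ends).
   Exactness — no mismatch tolerance — keeps the stage deterministic.
2. **QC** keeps reads with length in the inclusive interval
   [1400, 1800] bp and predicted accuracy ≥ 0.90. Both boundaries are
   inclusive; the stats count each failure reason independently.
3. **Dereplication** groups exact strings; representatives are first-seen;
   output is sorted by decreasing size with lexicographic tie-break —
   exactly the order the greedy clustering consumes.
4. **OTU clustering** is an abundance-sorted greedy centroid scheme
   (UCLUST-like), re-implemented from first principles: each query joins
   the first centroid whose global-alignment identity reaches the
   threshold (default 0.97), else founds a new centroid. Identity is
   defined as matches / alignment columns under Needleman–Wunsch with
   match +1, mismatch −1, gap −2 and penalized terminal gaps — stated
   explicitly because "97 % similarity" admits several definitions. The
   test suite pins this implementation to an independent exhaustive greedy
   oracle on dozens of random instances.
5. **Chimera removal is a no-op hook** (`remove_chimeras()`): detection
   belongs to specialized tools and is outside scope, but the stage stays
   visible in pipelines.
6. **Diversity**: Shannon $H = -\sum p_i \ln p_i$ (natural log; checked
   against vegan), and rarefaction by seeded subsampling without
   replacement, whose means are verified against the multivariate
   hypergeometric closed form for the expected number of distinct OTUs.

Taxonomy assignment against external databases (RDP/Greengenes/Silva) is
deliberately out of scope: simulated reads carry truth labels, and OTUs are
annotated by the majority label of their member reads.

## 4. Correlation and networks

Taxa are first filtered at a strict >0.1 % mean relative abundance. The
association measure is **Spearman's rho** — standard for rank-based
microbiome–metabolite panels and invariant under monotone transforms —
with Pearson available by flag. Two-sided p-values use the exact
permutation null for n ≤ 8 untied samples and the t approximation
otherwise; the exact branch is pinned to a full 120-permutation enumeration
in the tests. Stars follow P < 0.05 / 0.01 / 0.001. Benjamini–Hochberg
adjustment is computed on request but off by default, matching the common
practice of starring heatmaps on raw p.

Co-occurrence networks connect taxa pairs with $|\rho| \ge 0.6$ and
$p < 0.05$. Both thresholds are conventional defaults, not estimates, and
are configurable. Degree tables sort by descending degree with alphabetical
tie-break.

**Compositionality caveat.** Relative abundances are compositional; closure
can induce spurious negative correlation. No CLR transform is applied by
default (the raw-abundance matrices from the generator avoid the issue in
testing); analyses of real relative-abundance tables should consider it.

## 5. What the synthetic generator emulates — and what it does not

One seeded `synth_config()` drives four generators; identical configurations
give identical outputs (each generator seeds its own RNG stream derived
from the config seed and restores the caller's RNG state).

* **Amino-acid profiles**: log-normal noise (positivity by construction)
  around per-class means with a configurable CV (default 0.05, a typical
  analyzer repeatability). The default class means are the study
  conditions: they are anchored to the published marker contents (Lys
  3.26 and Pro 2.37 g/100 g in the unfermented control, Pro 5.29 in the
  natural fermentation, Lys 7.35 in the inoculated one) and constructed so
  the class totals, EAA fractions, top pattern ratios (Val 7.69-fold, Thr
  6.03-fold) and the Phe+Tyr limiting entry reproduce the published
  class-level composition at the published protein levels.
* **Volatile peak tables**: true concentrations are log-normal per
  compound with a class-level multiplier; areas are built as the exact
  inverse of the quantification formula, so recovery is exact by
  construction — that is the point of the round-trip test.
* **Amplicon reads**: one random template per taxon with length drawn from
  the configured range (independent random templates are pairwise far
  below any OTU threshold), 16-base barcodes on both ends, per-base
  substitution noise (default 0.5 %), truncated-normal predicted accuracy,
  and an optional decoy fraction engineered to fail QC on alternating
  grounds (length, accuracy). No chimeras, no per-base quality
  realism, no indel error model — passing tests show the pipeline's logic
  is right, not that it is robust to PacBio error profiles.
* **Taxa–metabolite matrices**: a latent Gaussian copula; a planted link
  of strength $s$ and sign $\pm$ gives latent Pearson correlation
  $\pm s$, and the exponential transform preserves ranks, so Spearman's
  rho increases with $s$ and equals $\pm 1$ exactly at $s = 1$. Unlinked
  pairs are independent, which is what makes the type-I-error check of the
  edge test meaningful.

## 6. Problem sizes and tolerances

The shipped tests and the acceptance script run at deliberately small
scale, chosen as the smallest sizes at which each property is
discriminating: 40-compound volatile tables; 25–150 reads per sample with
3–6 taxa for community profiling; 60 bp sequences for the
clustering-vs-oracle comparisons (identity thresholds 0.90–0.97); n = 30
samples, strength 0.9 and 20 replicate seeds for planted-link recovery,
with the null-pair star rate required to sit inside the 99.9 % binomial
band around α = 0.05; 1000 replicates for the zero-strength mean-rho and
rarefaction-vs-closed-form checks (tolerances ±0.05 and ±0.1 respectively);
exact identities asserted at 1e-9 to 1e-12.

## 7. Known limitations

* No taxonomy assignment, no phylogenetic diversity, no ordination.
* The greedy clustering is quadratic in centroids per query and meant for
  desk-scale data, not million-read runs.
* Real free-amino-acid taste scoring should use measured free contents;
  driver scripts that scale hydrolysate contents by a nominal free
  fraction are illustrative.
* The internal-standard default concentration is an assumption (see §2).
* Correlation on compositional data without CLR is subject to closure
  effects (see §4).
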