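---
title: "Methods: cross-species methylation arrays and 5-hmC quantification"
author: "crossmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species methylation arrays and 5-hmC quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmeth)
```

# The problem

Human Infinium-style methylation BeadChips interrogate hundreds of thousands
of CpG dinucleotides with 50-nucleotide probes designed against the human
genome. Two questions motivate this package:

1. **Cross-species reuse.** Which of those probes can be trusted when the
   hybridized DNA comes from another mammal? A probe is *species-competent*
   when its 50-mer matches the target genome either exactly (the *exact*
   set) or with at most four substitutions (the *mismatch* set), still
   carries its interrogated CpG at the matched locus, and maps to a single
   locus.
2. **Separating 5-mC from 5-hmC.** Standard bisulfite (BS) conversion
   cannot distinguish 5-methylcytosine from 5-hydroxymethylcytosine. When
   the same DNA is split into a BS-only aliquot and a Tet-assisted
   bisulfite (TAB) aliquot — glucosylation protects 5-hmC while Tet
   oxidation erases the 5-mC signal — the BS aliquot reports *total*
   modification and the TAB aliquot reports *5-hmC only*. Pairing the two
   per sample yields per-CpG 5-hmC levels and, by clamped subtraction,
   5-mC-only levels.

Everything downstream of the raw two-channel intensities is implemented
here: probe discovery by genome scanning, signal processing and QC,
aliquot pairing, per-CpG differential methylation with a BeadChip random
effect, and genomic-context enrichment. A first-class synthetic-data
module generates toy genomes, diverged "species" genomes, manifests and
dual-aliquot intensities with known ground truth, so every stage is
testable end to end without downloads.

# Models and procedures

## Probe scanning (`scan_probe`, `build_competent_sets`)

Each probe is compared against every 50-base window of the target genome
on both strands (reverse-strand hits compare the window against the
probe's reverse complement), counting substitutions only — no indels, no
gapped alignment. Matching runs in raw nucleotide space, not
bisulfite-converted space (a config switch away, off by default): the
biological claim is about genomic sequence identity.

A hit is *acceptable* if its Hamming distance is within the bound **and**
the target carries `CG` at the interrogated position (probe offsets
25–26, which map to window offsets 24–25 on either strand because CG is
its own reverse complement). A methylation probe without its CpG measures
nothing; the check is toggleable for sensitivity analysis. Probes whose
*best* acceptable locus is not unique are excluded and counted
("unique-best" policy) — a probe reporting two loci is uninterpretable.
Under this policy the exact set is provably a subset of the mismatch set.

Under independent per-base divergence at rate $r$, the expected
mismatch-set retention has the closed form
$(1-r)^2 \cdot P\{\mathrm{Bin}(48, r) \le 4\}$
(`expected_retention()`), which the test suite compares against simulated
divergence. The scan itself is validated against an exhaustive,
independently written Hamming oracle.

## Signal processing (`compute_beta`, `detection_pvalues`, `quantile_normalize`, `qc_filter`)

The methylation fraction is $\beta = M/(M+U+100)$; the offset keeps
$\beta < 1$ and regularizes low-intensity probes. Intensities are
quantile-normalized **before** $\beta$ is computed (that is the processing
order the assay's analysis pipeline uses), with M and U normalized
separately within each aliquot by default; joint normalization is a
switch, since nothing in the assay's description fixes the choice.

Detection p-values are rank-based against a negative-control background:
$p = (r+1)/(n+1)$ with $r$ the number of background totals at or above
the observed $M+U$. The vendor's computation is proprietary; this
empirical stand-in is documented as such and is calibrated (approximately
uniform when totals are drawn from the background itself, up to the
sampling error of the shared background sample).

QC applies sample rules first, then probe rules:

| rule | default | comparison |
|---|---|---|
| sample mean intensity | 2000 | `mean(M+U) < 2000` removed |
| sample detection rate | 0.99 | `< 99%` of loci at detection p ≤ 0.01 removed |
| dissimilarity outlier | 3 × IQR | median 1−Pearson above cohort median + 3 IQR |
| probe undetected share | 0.20 | `> 20%` of surviving samples (strict) removed |

Filtering samples before probes is a documented, configurable choice.
The outlier rule is our concrete formulation of "outliers identified by
hierarchical clustering and/or dissimilarity matrices"; no published rule
exists, so it is relative (median + multiple of IQR) with a manual
override list.

## 5-hmC pairing (`pair_aliquots`, `classify_by_cutoff`, `species_overlap`, `density_summary`)

TAB β is taken directly as the 5-hmC level (no subtraction): the TAB
protocol is constructed so that only glucosylated 5-hmC survives as
"methylated" signal. Subtraction only defines the derived 5-mC-only level,
`mc_only = max(0, total − hmc)`; noise can invert the order, so negative
values are clamped at zero and the clamp count is reported. The per-probe
level is the **median** over samples of detected entries; entries
undetected in either aliquot are masked in both (our convention — the
protocol description is silent). Abundance classes use strict
thresholds (`median > cutoff`) at the conventional 20/40/60% cutoffs, and
cross-species overlaps on a shared probe panel get hypergeometric
enrichment p-values.

## Differential methylation (`fit_locus`, `run_dml`, `permute_dml`, `subset_dml`)

Per CpG, a REML linear mixed model on the β scale:

$$\beta_{i} = \alpha + \gamma\,\mathrm{group}_i
  \,(+\,\delta\,\mathrm{intensity}_i) + b_{\mathrm{chip}(i)} + \varepsilon_i,
  \qquad b_c \sim N(0, \sigma^2_c)$$

with the p-value from the conditional t-test on $\gamma$. β (not
logit/M-values) is modeled because that is the scale the downstream
summaries use; the intensity covariate is the per-sample mean total
intensity and is off by default. When the chip effect is unidentifiable
(single chip, one sample per chip) or the conditional test has no
denominator degrees of freedom (group aliased with chip — label
permutations can produce this), the model falls back to ordinary least
squares and the locus is flagged `fixed-fallback`; fewer than 3 residual
df flags `failed`.

Benjamini–Hochberg and Bonferroni adjustments are computed over exactly
the tested loci; significance is declared by Bonferroni < 0.05 — the
conservative family-wise rule appropriate when asymptotics are doubtful
at n of a few samples per group. Label permutations (default 100) refit
the identical model with group labels permuted unconstrained by chip;
the permutation p is the raw count fraction $k/n_{\mathrm{perm}}$ (zero
allowed, matching the printed rule), with an add-one-corrected column for
users who need positive p-values. The −log10 Pearson correlation between
asymptotic and add-one permutation p-values summarizes how well the
asymptotic reference holds.

Gene-restricted analyses (`subset_dml`) re-run the multiple-testing
adjustment over the restricted family only, which is the correct
procedure for an a-priori targeted panel.

## Genomic-context enrichment (`assign_categories`, `fisher_category`, `permute_enrichment`, `split_islands_by_tss`)

Island relation is assigned from the distance between the interrogated
CpG and the nearest island: `Island` inside; shores within (0, 2000]
bases; shelves within (2000, 4000]; `OpenSea` beyond. `N_` flanks lie 5'
of the island, `S_` flanks 3', and a probe equidistant between two
islands takes the 5' one; the far-side-inclusive boundaries are our
documented convention for "0–2 or 2–4 kilobases flanking". Gene-structure
categories (TSS200 = within 200 b upstream of a TSS, TSS1500 = 200–1500 b,
5'UTR, 1st exon, body, 3'UTR) are strand-aware and allow multiple
membership across genes; each category is tested independently.

Enrichment of a hit set (e.g. probes with median 5-hmC > 20%) is tested
two ways, and the tests are required to agree in rank ordering on null
data: Fisher's exact test on the 2×2 (hit × in-category) table, and a
locus-permutation test that draws $|$hits$|$ probes uniformly without
replacement from the panel (default 10,000 draws). The permuted
proportion is the share of the drawn set in the category; over/under
p-values count permutations at least as extreme. For the chromosome-level
analysis a family-wide correction compares each chromosome's *enrichment
ratio* (observed/expected proportion — raw proportions are not comparable
across chromosomes of different sizes) against the most extreme permuted
ratio of *any* chromosome per permutation; the corrected p-value is
never smaller than the uncorrected one. The ratio-based max formulation
is one concrete reading of the published correction sentence and is
recorded here as such.

TSS-associated islands (a TSS within 1500 b of the island interval) are
compared against other islands by a label-permutation test on the
difference of median 5-hmC (one-sided for "TSS lower"); the underlying
published test is unstated, so this stand-in is ours.

## Clustering and reporting (`dissimilarity_matrix`, `hierarchical_cluster`, `assemble_report`)

Sample dissimilarity is 1 − Pearson correlation over commonly detected
probes (Euclidean available); clustering is agglomerative with average
linkage by default (complete available). The distance/linkage choices are
not fixed by any published description, so they are configurable and
recorded in every report; tests assert topology-level properties only.
Reports serialize every tabular output to JSON; reruns with the same seed
are byte-identical.

# The synthetic-data generator

The generator is the package's study-conditions module, not a test
convenience, and its defaults were fixed once:

* **Genomes**: i.i.d. A/C/G/T background; CpG islands as 500 b intervals
  placed one per equal-width block (non-overlapping by construction,
  density accurate to ±2%), filled from a CpG-enriched token process
  (~1 CpG per 7 bases vs ~1/16 background). Genes are 3 kb models
  (5'UTR 100 b, first exon 200 b, body 2.5 kb, 3'UTR 200 b) with random
  strand, non-overlapping.
* **Divergence**: independent per-base substitution at a stated rate,
  no indels — coordinates are preserved so retention has a closed form.
* **Signals**: a single abstract intensity channel per probe. The
  generator inverts the β formula exactly — $M = \beta(T+100)$,
  $U = T − M$ with target total $T = 5000$ — so the noise-free round trip
  through `compute_beta` reproduces the truth table to machine precision
  and the truth table is an exact oracle. Chip batch effects are additive
  on the logit of β before inversion (sd 0.05 in the batched studies);
  measurement noise is additive Gaussian on M and U, truncated at zero
  (sd 60 in the noisy studies); failed probes draw their intensities from
  the background distribution used for detection p-values. Truth
  fractions above the ceiling $T/(T+100)$ cannot be encoded and are
  clamped with a warning.
* **Study designs**: two-group comparisons at n = 5 vs 5 dealt
  round-robin across 3 chips (so chips carry mixed groups, as arrays are
  run); three-replicate single-group designs for reproducibility checks;
  three pseudo-species with planted above-20% 5-hmC fractions
  0.53/0.42/0.17 for the abundance-hierarchy analysis.

The generator emulates: dual-aliquot coupling with 5-hmC ≤ total
everywhere, per-chip batch structure, planted differential loci with
known Δβ, and annotation tracks with known coordinates. It deliberately
does **not** emulate: Infinium I/II two-color chemistry and dye bias,
realistic genome composition (repeats, isochores), correlated
neighboring-CpG methylation, or Tet/β-GT enzyme efficiencies. Passing
tests therefore demonstrate the *statistical machinery* is correct and
calibrated under known conditions — not that any particular biological
dataset would yield particular numbers.

# Numerical choices

A note on normalization at toy scale: quantile normalization equalizes
every sample's marginal intensity distribution. When a non-trivial share
of a *small* panel carries a large group effect (e.g. 5% of 200 probes at
Δβ = 0.25), equalizing the marginals transfers a sliver of that group
difference onto null probes — small (|effect| of a few hundredths) but
precise enough to reach Bonferroni significance. On full-size arrays the
leakage is negligible. The synthetic generator emits intensities that are
scale-matched across samples by construction, so simulation-based
recovery metrics (bias, coverage, false-discovery proportion) are
computed on unnormalized betas; normalization remains the default for
data with real between-sample technical variation.

* Detection p ties count into the upper tail: $r$ = #background ≥
  observed.
* Quantile normalization averages ties (every sample's sorted vector maps
  to the cross-sample mean of order statistics).
* The mixed model suppresses optimizer convergence chatter and accepts
  the returned REML object; degenerate fits are caught by the df and
  fallback rules rather than by optimizer status.
* Permutation p-values live on the $k/n_{\mathrm{perm}}$ grid; tests that
  assert uniformity add the grid granularity to continuous critical
  values.
* Odds ratios add 0.5 to every cell only when a cell is zero, and the
  result is flagged; a category equal to the whole panel yields an
  undefined (NA) odds ratio.
* Hierarchical clustering ties are resolved by `stats::hclust`'s
  deterministic ordering; dendrogram tests compare cophenetic distances,
  which are invariant to leaf order.

# Problem sizes

The shipped tests and the acceptance script run, by design, at desk
scale: genomes of 8–35 kb across 1–2 chromosomes, manifests of 200–500
probes, 100–2,000 loci per statistical calibration (2,000 null loci as
four independent 500-locus cohorts, since loci within one cohort share
realized chip offsets), 100 label permutations, 10,000 locus
permutations for enrichment, and 50–100 seeded repetitions for
recovery-rate properties. These sizes make every stage's behavior
measurable while each property remains independent of scale.

# Known limitations

* Matching uses raw genomic sequence; bisulfite-converted-space matching
  exists only as an off-by-default switch and is untested against data.
* The detection p-value is an empirical stand-in for a proprietary
  computation; absolute detection rates on real exports will differ.
* Two-group designs only; multi-group contrasts must be collapsed first.
* The dissimilarity-outlier QC rule is heuristic and, unlike the
  threshold rules, not guaranteed idempotent.
* No region-level (DMR) calling, no cell-composition or surrogate-variable
  adjustment, no ontology enrichment.
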