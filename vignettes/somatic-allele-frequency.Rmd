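---
title: "Methods: somatic allele frequency in matched tumor/normal DNA and RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic allele frequency in matched tumor/normal DNA and RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical model, the
tunable parameters and their defaults, the design of the synthetic-cohort
generator, and the numerical choices made where the design was genuinely
open.

## The quantities

For a somatic SNV covered by `n_ref` reference and `n_var` variant reads,
the variant allele fraction is `VAF = n_var / (n_ref + n_var)`, computed
separately for tumor DNA (`VAF_tDNA`, from the tumor exome) and tumor RNA
(`VAF_tRNA`, from the tumor transcriptome). The central statistic is the
ratio

$$V_{R:D} = \frac{VAF_{tRNA}}{VAF_{tDNA}}$$

interpreted against 1 (transcriptome mirrors DNA). The ratio is left
**uncapped** above — values well beyond 2 are informative and are used by
the extreme-subset analysis — and is reported as missing whenever
`VAF_tDNA` is 0 (the ratio is undefined there; such variants are excluded
from V_R:D analyses rather than imputed). VAFs are computed on
quality-filtered counts with no pseudocounts: the formula is exact, and
smoothing would bias the extreme statuses this pipeline exists to detect.

Purity weighting multiplies V_R:D by the tumor-cell proportion estimated
by each of five methods (ABSOLUTE, IHC, ESTIMATE, LUMP, CPE), giving
`aV_R:D` through `cV_R:D`. The weighting is a direct multiplication with
no renormalization, and a missing purity method yields a missing weighted
value. DNA and RNA purity are treated as equal, an assumption the
weighting inherits from its definition; it is listed under limitations.

## Expression-status calls (SOM / SOM-E / SOM-L)

The two extreme statuses are defined against an explicit noise-only
model. Let `p_err` be the probability that a sequenced read shows the
minority base at a position by error alone (default **0.05**, a
deliberately generous allowance covering sequencing error plus alignment
artifacts), and `alpha` the significance level (default **0.05**). With
`n` tumor-RNA reads of which `k` carry the variant:

* **SOM-L** (variant allele lost from the transcriptome): the noise-only
  model `X ~ Binomial(n, p_err)` is *not* rejected against the observed
  variant reads, i.e. `P(X >= k) >= alpha`.
* **SOM-E** (variant allele over-expressed): the mirrored condition holds
  for the *reference* reads.
* **SOM** otherwise.

Both extremes additionally require a bi-allelic DNA signal
(`0 < VAF_tDNA < 1`), operationalized as both tumor-DNA alleles carrying
at least `min_dna_minor_reads` reads (default **2**; a single stray read
should not certify bi-allelism). Both tumor DNA and RNA must reach
`min_depth` (default **10**) reads.

One-sided tails on each extreme were chosen over a two-sided
goodness-of-fit because the two named extremes are directional classes;
the p-values for both tails are always emitted so users can audit calls.
A degenerate corner exists at depths of 1–2 where *both* one-sided
conditions can hold simultaneously (e.g. `n = 1`: `P(X >= 0) = 1` and
`P(X >= 1) = p_err >= alpha`); the call falls back to SOM there, keeping
SOM-E and SOM-L mutually exclusive at every depth. The corner is
unreachable at the default `min_depth`.

Calibration: on null cohorts with `VAF_tRNA = VAF_tDNA = 0.5` at depth
50, the SOM-E + SOM-L miscall rate is far below 1% (the acceptance suite
verifies this on 10,000 simulated variants).

## The filter cascade

Samples are dropped when fewer than three of the five purity estimates
are available, when their mutation count exceeds Q3 + 1.5 IQR
(quartiles by linear interpolation between order statistics — the
`quantile` type-7 default, the most common convention), or when their
cancer-type group retains fewer than 10 samples (a group of exactly 10 is
kept). Variants are excluded, in fixed order with each exclusion
attributed to the *first* failing rule: missing counts, tumor DNA or RNA
depth below 10, X-chromosome position (applied unconditionally to all
samples — sex-specific handling would require metadata the pipeline does
not demand), overlap with a known imprinted region, germline evidence
(variant reads above `max_normal_var_reads = 1` in either normal
dataset), splice-annotated consequence (exon-proximal splice variants
alter transcripts in only a fraction of molecules, so their RNA/DNA
comparison is not interpretable here), and non-exonic consequence. The
retained set is order-independent; only the reason attribution depends on
the order. Conservation (`retained + excluded = input`) is asserted on
every run.

## NMD classification of PTVs

A PTV escapes NMD if **any** of six rules fires:

1. the PTC lies in the last exon or within **50 nt** upstream of the last
   exon-exon junction;
2. the PTC lies within the first **200 coding nucleotides** and an
   alternative in-frame AUG exists downstream in the CDS;
3. the PTC lies in a long exon (> **400 nt**) fewer than **250 nt** from
   the closest exon boundary;
4. the transcript half-life is below **1 h**;
5. the transcript is single-exon;
6. the gene is NMD-insensitive.

All distances are measured in spliced mRNA coordinates, strand-aware.
Three rules needed decisions the rule list itself does not fix:

* **Rule-1 polarity.** The canonical boundary rule of the NMD literature
  holds that PTCs *near* (<= 50 nt upstream of) the final junction, or
  downstream of it, escape degradation. The package implements that
  direction by default and exposes `nmd_rules(rule1 = "literal")` for the
  inverted reading ("more than 50 bp upstream" as the escape side), so
  either convention can be reproduced explicitly rather than silently.
* **Rule-2 window.** "First 200 nucleotides" is counted in *coding*
  nucleotides from the start codon, and the alternative AUG is sought
  in-frame, downstream of the PTC, within the annotated CDS. The rule
  requires a coding sequence; if none is supplied the flag is left
  unset with a logged assumption (the same contract as a missing
  half-life for rule 4).
* **Long-exon threshold.** "Long" is parameterized at 400 nt
  (configurable); exons beyond ~400 nt are in the upper tail of human
  internal-exon lengths.

When a variant's annotated transcript is absent from the gene models, the
gene's coding transcript with the longest CDS is used as fallback.
Half-lives and NMD-insensitive gene lists are consumed as input tables,
not bundled.

The rule engine is verified on an exhaustive fixture grid: of the 64
flag combinations, 48 are geometrically realizable (a single-exon
transcript forces rule 1, since its PTC is always in the last exon), and
each is constructed on both strands and checked to give verdict =
OR(flags).

## TFBS gain/loss

Motifs are accepted in JASPAR text format (count matrices normalized to
probabilities). A window centered on the variant is scanned with each
PWM on both strands; the score is the log2-odds against a uniform
background, and a hit requires relative score
`(score - min) / (max - min) >= 0.85` (configurable). A motif is
*gained* when it hits the variant-overlapping region in the alternate
window but not the reference window, *lost* in the converse; a variant
gaining one motif and losing another is reported as `both` and counts in
both categories for two-way comparisons, since no precedence between the
two events is defensible. Note a property of uniformly sharp columns:
a word with *k* mismatches to the consensus of a width-*w* sharp motif
has relative score `(w - k)/w`, so at the 0.85 default a width-6 sharp
motif admits only its exact consensus — the synthetic motif set uses
width 6 for exactly this reason.

## Association analyses

Expression change is `log2[T/N] = log2((T + f)/(N + f))` with floor
`f = 0.01` FPKM-like units (missing when both values are zero) — the
floor only matters for genes detected in one tissue, where it bounds
rather than fabricates the fold change. Correlations are Spearman
(average ranks, two-sided p), group comparisons Kruskal-Wallis
(tie-corrected; the all-tied degenerate case is defined as H = 0, p = 1),
enrichment a 2x2 chi-square without continuity correction (configurable).
No multiple-testing correction is applied — raw p-values are always
emitted so users may correct downstream — and p < 0.05 is the reporting
threshold. Extreme subsets are `V_R:D > 2` with `log2[T/N] >= 1` (up) or
`<= -1` (down); the two sets are disjoint by construction. Gene ranking
averages V_R:D over variants with a defined ratio, requires at least 3
(configurable to 5) mutations, and breaks ties alphabetically for
determinism. SOM-E/SOM-L variants enter correlation analyses with their
computed V_R:D values, not imputed 0/1 surrogates. Copy-number context
joins each variant to the overlapping segment of the same sample and
compares |segment mean| distributions between groups.

## The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes,
with all truths recorded:

* **DNA.** Clonal heterozygous variants in a diploid tumor admixed with
  diploid normal tissue: tumor-cell variant fraction `f_D = 0.5`, sample
  purity `pi ~ Beta(6.5, 3.5)` (mean 0.65, a typical resected-tumor
  range), so the expected `VAF_tDNA = f_D * pi = pi/2`.
* **RNA.** Allelic selection `s` acts as an odds multiplier:
  `E[VAF_tRNA] = s v / (s v + 1 - v)` at `v = E[VAF_tDNA]` — simple,
  invertible, and giving `V_R:D ~ s` near `v = 0.5`. For NMD-elicit PTVs
  the variant transcripts are further scaled by `(1 - d)` and
  renormalized (`d = 0.8` by default; NMD is efficient but rarely
  complete). `log s ~ N(0, 0.5^2)` with a mild negative shift for PTVs
  (meanlog `log 0.8`), plus a 5% admixture of strong positive skew
  (meanlog `log 50`) emulating allelic amplification/LOH so that SOM-E
  calls occur at realistic rates.
* **Counts.** Depths are Poisson (mean 80, truncated at 10) per dataset;
  observed variant reads are binomial with error mixing at
  `p_err = 0.001`, the residual error rate after base-quality filtering.
  Normal datasets draw variant reads at `p_err` alone, except for a 2%
  germline-contaminated fraction that draws at the tumor probabilities
  and should be caught by the germline filter.
* **Expression.** The true log2 fold `beta ~ N(0, 1)` is coupled to
  `log s` through a bivariate-normal copula with Pearson `rho = 0.3`;
  measured expression adds log2-scale noise (sd 0.1). The Spearman
  correlation implied by the copula is `(6/pi) asin(rho/2) ~ 0.29`, and
  the consequence-specific selection shifts plus the strong-selection
  admixture (both independent of beta) attenuate the recoverable rank
  correlation to ~0.24 — the parameter-recovery check asks for the
  induced 0.3 within ±0.1, which this satisfies with margin.
* **Gene models.** 300 genes across seven archetypes chosen so every NMD
  rule fires in truth: canonical elicit geometry (60%), last-exon,
  single-exon, start-proximal-with-AUG, long-exon, short-half-life and
  NMD-insensitive archetypes (40% together). Archetype site coordinates
  are mirrored on minus-strand genes (the layouts are palindromic, so
  transcription-relative geometry is strand-invariant). Coding sequences
  are built from sense codons with in-frame AUGs excluded except where
  planted.
* **TFBS.** 5% of variants each get a planted motif gain or loss
  (width-6 sharp PWMs; see above), the rest random windows.
* **Filters.** 2% of genes sit on chrX and 2% inside an emitted
  imprinted BED, exercising the cascade.

Everything is deterministic given the seed; `write_bundle()` emits the
full bundle (MAF, counts TSV, GTF, CDS FASTA, BED, purity/segments/
expression TSVs, JASPAR motifs, window FASTA, truth table, YAML config)
byte-identically, in exactly the dialects the readers consume.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: subclonal architecture and
multi-clonal VAF mixtures, focal copy-number alterations coupled to
allele fractions (segment means are drawn independently), overdispersed
(beta-binomial) counts, mapping bias toward the reference allele,
isoform-level expression and splice-mediated NMD, and batch/technical
covariates. Results on real cohorts depend on upstream alignment and
calling quality in ways no simulation certifies.

## Problem sizes and runtime choices

The test and acceptance workloads were sized to exercise each property
at meaningful scale while staying comfortably interactive: 10,000
variants for null calibration (the <1% bound is then estimated to ±0.2%),
~2,000 variants at fixed depth 100 for parameter recovery, the default
1,000-variant cohort for directional properties, 96 fixture evaluations
for the NMD grid, and 1,053 comparisons for the binomial-tail oracle
(all `k <= n <= 25` at three error rates, agreement within 1e-12;
the implementation delegates to `pbinom`, the oracle enumerates
log-binomial terms).

## Known limitations

* Purity weighting assumes DNA and RNA derive from material of equal
  tumor content.
* The binomial noise model ignores overdispersion; counts from highly
  expressed genes with allelic mosaicism will look over-significant.
* chrX exclusion is unconditional; male/female handling would need
  sample sex metadata.
* The NMD rules are positional heuristics — they predict escape
  *eligibility*, not quantitative NMD efficiency.
* TFBS calls depend on the supplied PWM set and threshold; no attempt is
  made to infer activator/repressor directionality.
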