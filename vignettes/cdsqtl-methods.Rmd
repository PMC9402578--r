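---
title: "Methods: CDS-focused splicing QTL mapping with cdsqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDS-focused splicing QTL mapping with cdsqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cdsqtl` maps genetic loci that alter splicing outcomes, with an emphasis on
those that change the encoded protein. The analysis distinguishes three
overlapping QTL classes for a gene with several isoforms:

* **gene eQTL** — the variant shifts the gene's total expression;
* **i-eQTL** — it shifts an individual isoform's expression level;
* **i-rQTL** — it shifts an isoform's *share* of the gene total
  (the splicing signal proper).

Two protein-centric refinements are layered on top. First, isoforms whose
translation sequences are byte-identical are **integrated**: their FPKM is
summed and the ratio phenotype recomputed on the integrated feature
(i²-eQTL / i²-rQTL). Any i²-rQTL signal then necessarily reflects a change
in the produced protein rather than a UTR rearrangement, and the summation
also cancels the unstable read assignment between isoforms that differ only
outside the CDS, which is a known weakness of isoform-level quantification.
Second, **CDS-incomplete (CDSI)** isoforms — annotation records whose CDS
is flagged truncated at the 5′ and/or 3′ end — are selected and analyzed
separately, because their ratio QTLs point at unannotated coding isoforms;
a set of long-read completion filters then decides which full-length
candidates plausibly complete them.

## Phenotype construction

For each analysis mode the cascade is fixed and logged:

1. **Gene filter**: FPKM strictly greater than 0.1 in *every* sample.
2. **Isoform filter**: isoforms of retained genes with FPKM > 1 in at
   least `ceiling(0.05 n)` samples. Both inequalities are strict, matching
   the stated thresholds; the 5 % rule is read conservatively as a ceiling.
3. **Integration** (i² modes): per-sample sum over each identical-CDS
   group. Groups are restricted to one gene, since a ratio across genes is
   undefined.
4. **Ratios** (ratio modes): feature FPKM over the per-gene total of the
   features present. Samples with a zero gene total yield missing ratios;
   features missing in more than 5 % of samples are dropped, the remainder
   mean-imputed (neutral under the subsequent rank transform).
5. **Quantile normalization** across samples (common distribution = mean
   of order statistics; ties share the mean of their targets).
6. **Inverse normal transform** per feature with Blom offsets,
   `qnorm((rank - 3/8)/(n + 1/4))`; zero-variance features (for example
   the constant ratio of a single-isoform gene) are dropped here.
7. **Latent-factor removal**: residualization on the top *k* principal
   components of the feature-standardized matrix. This is a deliberate,
   documented stand-in for the PEER model, which is an external Bayesian
   tool; PCA residualization is deterministic, seedless, and a standard
   surrogate. Default `k = 15`.

On synthetic data the generator plants no batch structure, so the matched
analysis uses `n_factors = 0`; with only tens of phenotypes, 15 components
would absorb the planted genetic signal itself rather than nuisance
variation. This is a property of desk-scale data, not of the method: at
cohort scale (thousands of features) the top components track technical
structure and `k = 15` is appropriate.

## Cis mapping and significance

Association is the Pearson correlation of the normalized phenotype with
alt-allele dosage; two-sided p-values come from
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. The cis window is the gene body
plus 1 Mb on each side; variants need MAF ≥ 0.05. The gene-level statistic
is the minimum nominal p in the window. Its null is obtained by permuting
the phenotype across samples — once per replicate, shared by all variants,
so the LD structure the minimum depends on is preserved — with a fixed
number of permutations (default `B = 1000`) rather than an adaptive
scheme, for deterministic desk-scale runtime. One permutation set is drawn
per run and shared across phenotypes, which makes results invariant to
phenotype ordering. The empirical p is `(1 + k)/(B + 1)`; a maximum-
likelihood Beta fit to the permutation minima supplies a smooth adjusted
p-value (the familiar permutation-pass approximation), falling back to the
empirical value when the minima are degenerate. Across phenotypes, false
discovery is controlled with Storey–Tibshirani q-values: `pi0` estimated
on the lambda grid 0.05–0.95 with a cubic smoothing-spline extrapolated at
the largest lambda, fixed at 1 (the Benjamini–Hochberg limit) when fewer
than 20 phenotypes are available. Lead-variant ties on nominal p are
broken by genomic position, then identifier, so results are reproducible
to the byte.

## Colocalization and curation

Regulatory trait concordance (RTC) asks whether a GWAS variant and a QTL
lead inside one recombination interval tag the same signal: for each of
the N interval variants the phenotype is residualized on that variant and
the QTL lead re-tested against the residuals; the GWAS variant's rank
among the resulting p-values (largest first — most signal removed) gives
`RTC = (N - rank)/N`. The self-correction identity (GWAS variant equal to
the lead gives RTC exactly 1) anchors the ordering convention. A pair
passes at RTC ≥ 0.8 and dosage LD r² ≥ 0.8. Interval definitions are an
input BED; the package does not compute recombination hotspots. When
several GWAS variants for one trait share an interval, each is scored and
the maximum per (trait, phenotype) is flagged, with all records retained —
the aggregation rule is a package convention, stated here because the
choice is genuinely open.

Ratio-QTL signals are additionally curated against junction-level
evidence: a record is kept when the ratio QTL has q ≤ 0.05, a matched
junction QTL (for integrated features, any member isoform's junction) has
q ≤ 0.05, and all matched junction slopes agree in sign with the ratio
slope.

## Characterization

Lead-variant positions are drawn on a standardized axis: the gene body is
rescaled to 30,000 bp (an average isoform length), flanks stay in raw bp,
and minus-strand genes are mirrored so upstream always means 5′. Only the
body is rescaled — flank distances are physically meaningful as printed.
Multimodality of the positional distribution is tested with Silverman's
critical-bandwidth bootstrap: the smallest Gaussian KDE bandwidth giving
at most `k_null` modes is found by binary search (modes counted on a
1,024-point grid over the data range ± 3 bandwidths, search tolerance
1e-3), and significance comes from the smoothed bootstrap with variance
rescaling. The null mode count is exposed as a parameter because the
choice (1 versus 2) is not fixed by the method. Cell-type specificity is
classified over exactly five subsets, on features expressed in all five:
significant in 1 subset = specific, 2–3 = intermediate, 4–5 = shared;
features significant nowhere are reported unclassified.

## Trans effects and GSEA

For an sQTL lead variant, trans effects are Pearson correlations with the
expression of distal genes, excluding genes within 1 Mb of the variant
(the same distance as the cis window, so cis/trans partition the genome —
the package's convention, since "distal" has no universal cutoff) and
genes with their own cis-eQTL at FDR ≤ 0.05. Class-level enrichment is
summarized by observed-versus-expected QQ tables of −log10 p and the ratio
of class medians. Gene-set level effects use GSEA with a *continuous*
phenotype label — the normalized isoform ratio of the driver gene — and
Pearson correlation as the ranking metric. The enrichment score is the
weighted Kolmogorov–Smirnov running sum (weight exponent 1 by default;
weight 0 recovers the classical KS statistic exactly). Significance
permutes the sample labels, never the genes, preserving inter-gene
correlation; the normalized score divides by the mean |ES| of sign-matched
permutations and the p-value is two-sided on |ES|.

## Long-read completion filters

Candidate full-length isoforms from long-read data pass completion when:
their 5′ end is within 50 bp (inclusive, measured to the nearest interval
edge and 0 inside) of a reference TSS and their 3′ end within 50 bp of a
reference TES; their longest forward-frame ATG…stop ORF exists (ties
broken 5′-most; the ORF scan is sense-strand only, since the input is the
spliced mRNA); and their coding probability — an input column from an
external coding-potential model — is at least 0.364, the published human
cutoff, inclusive at the boundary. CDSI-specific junctions are matched
exactly on (donor, acceptor) intron coordinates; the TSS-usage contingency
test is Pearson's chi-squared without continuity correction (the intended
use has large counts; a flag restores Yates). Per gene, the report sorts
passing candidates by read count and returns the smallest prefix covering
half the reads, with ties broken by candidate id.

# The synthetic data generator

`simulate_all()` emits a complete miniature dataset: VCF genotypes, a
GENCODE-dialect GTF plus translations FASTA, FPKM matrices, a GWAS
catalog, recombination intervals, CAGE-style TSS and polyadenylation-site
TES references, gene sets, and a junction-QTL table. The stated world:

* **Genotypes**: one locus per gene on a single synthetic chromosome,
  spaced 2 Mb so cis windows never overlap; 50 variants per locus in LD
  blocks of 10. Each block draws a latent haplotype pair per sample at a
  frequency uniform in (0.1, 0.5); variants copy the latent alleles with
  flip probability 0.02, giving within-block dosage r² around 0.85 —
  emulating the tight haplotype blocks in which human QTL leads tag causal
  variants at r² ≥ 0.8. Blocks are redrawn until every empirical MAF
  reaches the configured floor.
* **Expression**: gene totals are log-normal,
  `T = exp(mu + beta_e g + eps)`; isoform fractions are logistic-normal —
  softmax of Gaussian scores — so a planted genotype effect is additive on
  the logit scale and group-level (i²) effects are equal shifts on all
  members. Members of multi-member CDS groups receive extra score noise
  (`split_noise_sd`, default 1) emulating unstable read assignment between
  same-CDS isoforms. A pure within-group switch is implemented as a
  post-softmax reallocation between the two members, leaving gene and
  group totals exactly flat. Default effect sizes are one logit (ratios)
  and one log unit (totals) per standardized dosage with residual sd 0.5.
  Baseline expression sits near FPKM 20 so the 0.1/1 filters are passed by
  design, with a configurable fraction of genes pushed to FPKM ≈ 0.03 to
  exercise the filters.
* **Trans modules**: a driver isoform's ratio, standardized, multiplies
  the totals of 20 distal genes through slope 0.5.

What the generator does **not** emulate: population structure,
recombination-map realism, covariate confounding, quantification bias
shared across samples, and annotation errors. A green test therefore
establishes internal statistical correctness (calibration, power,
identities), not robustness to those real-data features.

# Numerical and design choices

* Boundary conventions are inclusive where stated inclusive
  (coding probability ≥ 0.364, proximity ≤ 50 bp) and strict where stated
  strict (FPKM > 0.1, > 1).
* Coordinates are 1-based inclusive internally (GTF convention); BED
  input/output converts at the reader/writer boundary.
* CDSI detection uses the GENCODE `cds_start_NF` / `cds_end_NF`
  transcript tags — GENCODE's machine-readable encoding of an incomplete
  CDS. Other encodings of incompleteness exist (e.g. `mRNA_start_NF`), so
  the tag set is a documented package choice, checkable against the full
  annotation with `scripts/gencode_checks.R`.
* Protein identity for integration is exact string equality after
  uppercasing and stripping terminal stops; no similarity threshold.
* Indels are treated exactly like SNPs wherever dosages exist.
* The association step uses Pearson correlation on fully normalized
  phenotypes (the rank transform has already happened), matching the
  standard permutation-pass linear model.
* `storey_qvalues(p, pi0 = 1)` is exactly Benjamini–Hochberg; the
  smoother-based `pi0` estimate can only shrink q-values, and the test
  suite asserts both facts.

# Known limitations

* PEER is replaced by PCA residualization (above); runs record
  `n_factors` in the manifest.
* No conditional/multi-signal cis mapping; one lead per phenotype.
* No Bayesian colocalization; RTC plus LD thresholds only.
* The GTF parser handles the GENCODE attribute dialect (including
  repeated `tag` keys) but is not a general-purpose GFF3 reader.
* Exact annotation counts against GENCODE v35 require downloading the
  pinned releases and are provided as an optional script, not as offline
  tests.
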