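---
title: "Methods: promoter motif scanning and cross-species regulatory convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif scanning and cross-species regulatory convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regconverge)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what a green test does and does not establish.

## 1. Promoter windows

The unit of analysis is one transcript's promoter: the genomic interval
from 2 kb upstream to 1 kb downstream of the transcription start site
(TSS), oriented 5'→3' on the transcript's sense strand. Conventions:

* The TSS of a transcript is its 5'-most transcribed coordinate on its
  strand. Extraction is per transcript by default, so a gene with three
  annotated isoforms contributes three (possibly overlapping) windows;
  `collapse = "gene"` instead keeps a single window anchored at the
  gene's 5'-most TSS. Per-isoform extraction is the default because the
  study design this emulates explicitly included all isoform promoters of
  a multi-isoform gene (ASIP); whether other genes were collapsed is
  unstated, so both behaviors are exposed.
* Coordinates: annotation input/output is GFF3 (1-based inclusive);
  internal window intervals are 0-based half-open. The TSS base is the
  first base of the downstream segment, so an untruncated window has
  exactly `upstream + downstream` = 3000 nt.
* Windows running off a contig are clipped and flagged `truncated`, never
  silently padded.
* IUPAC ambiguity codes other than A/C/G/T are normalized to N; N never
  matches any motif position.
* Promoters overlapping neighboring genes are *not* masked (the upstream
  procedure stated no masking).

An assembly-quality gate (`assembly_filter`) admits genomes with scaffold
N50 strictly above 500 kb and strictly fewer than 30,000 scaffolds,
mirroring the strict wording of the selection criteria it reimplements.

## 2. PWM scanning with exact p-values

A PWM is a 4 × L count (or probability) matrix. With pseudocount k, the
regularized probability is p′(i,b) = (c(i,b) + k) / (N(i) + 4k) (default
k = 0.1), and the log-odds score of window w is
s(w) = Σᵢ log₂(p′(i, wᵢ) / π(wᵢ)) in bits, with background π. Both
strands are scanned; a minus-strand hit at offset o means the motif's
reverse complement matches the window starting at o.

**Exact p-values.** P[S ≥ s] for a random window drawn i.i.d. from π is
computed by dynamic programming over the per-position score distribution,
after discretizing scores to 1e-4-bit units. The same discretized matrix
is used for scanning, so reported scores and p-values are exactly
consistent, and the DP equals exhaustive enumeration over all 4^L windows
*identically* (verified to 1e-9 in tests). The discretization error on a
10-mer score is at most 5e-4 bits. Bases with zero regularized
probability score −Inf: windows containing them (or any N) have p = 1 and
can never be hits. The convolution runs in C++ (`src/score_dp.cpp`); a
pure-R route is kept internally and compared in tests.

**Multiple testing.** The BH family is every scored window — all offsets,
both strands, all promoters — of one TF's scan run, the most conservative
reproducible choice given that the upstream tool's padj scope is
unstated. `binding_strength` then counts hits with padj strictly below
0.05 per (TF, gene). Overlapping hits are all counted (no greedy
collapsing: the hit-count statistic stays monotone), but hits at the same
genomic coordinate shared by overlapping isoform windows of one gene are
deduplicated, so shared promoter sequence is not double-counted while all
isoform-specific sequence still contributes. Genes absent from a species'
annotation are masked NA, never zero — absence of evidence is not a count
of zero.

**Background.** Default for promoter-set scans is the pooled nucleotide
composition of the scanned promoters (add-one smoothed); uniform and
user-supplied backgrounds are available. Single-promoter `scan_promoter`
defaults to uniform. The forward and reverse-complement orientations get
separate DP distributions, since a non-symmetric background breaks strand
symmetry of the null.

## 3. Expression-side processing

* `tpm`: count / (length in kb), scaled so each sample sums to 1e6.
* `upper_quartile_normalize`: each sample is scaled so its 75th
  percentile over genes *nonzero in that sample* equals the geometric
  mean of all samples' upper quartiles. The rescaling constant is not
  dictated by the upstream description; the geometric mean is scale-free
  and symmetric in the samples, and the choice only shifts all samples by
  a common factor.
* `filter_expressed`: mean TPM strictly greater than 1.
* `deg_filter`: log₂FC > 1 or < −1, padj < 0.05 — all strict, so
  boundary rows are excluded (the thresholds reimplement "greater
  than"/"less than" wording literally).
* `de_test_standin`: a clearly labeled substitute for the external
  negative-binomial Wald analysis whose output table this package
  normally consumes. Counts are UQ-normalized, log2(x+1)-transformed and
  tested with limma's moderated t (trend = TRUE); p-values are BH
  adjusted; the reported log2fc is the ratio of group means of normalized
  counts (offset 0.5). Variance moderation is what makes n = 3/group
  viable; the stand-in is pluggable — supply an external DEG table
  whenever one exists. It does not reimplement median-of-ratios
  normalization, shrinkage, or the Wald test.
* `transform_for_clustering`: log2(normalized + 1), a documented stand-in
  for a regularized-log transform; the substitution is recorded in the
  returned matrix's `transform` attribute.
* `ward_cluster`: Ward.D2 agglomeration (squared-Euclidean merge cost
  with the D2 update) on Euclidean distances via `stats::hclust`, cut at
  a user-chosen k. The upstream analysis states the agglomeration method
  but neither the distance metric nor k; both are parameters. Merge
  heights are verified against a direct Lance–Williams recursion in
  tests.

## 4. Sex-chromosome enrichment and dosage

`chromosome_ratios` computes, per chromosome with at least one expressed
gene, the fraction of expressed genes that are DEGs; Z and W are class
"sex", numeric labels "autosome", anything else (unplaced scaffolds) is
excluded and reported. The enrichment test permutes the sex/autosome
labels over chromosomes: for a two-class comparison the packaged
"permutation test for linear models" it replaces reduces exactly to a
label-permutation test on the difference of class means. The one-sided
p-value uses add-one smoothing, p = (1 + #{perm ≥ obs}) / (1 + n_perm),
so p = 0 is impossible and the test is valid (P(p ≤ α) ≤ α under the
null, verified by a 1000-dataset calibration in the acceptance suite).
Exact ties are counted with a 1e-12 relative tolerance — without it, an
all-equal input returns p ≈ 1/(n_perm + 1) instead of the correct 1.

`classify_dosage` splits Z-linked male-biased DEGs at the stated "around
1 to 1.5" band, fixed deterministically as (1, 1.5]: dosage
(explainable by two Z copies vs one) versus exceeds_dosage, with an
additional strong_male_biased flag above |log₂FC| = 2 (over four-fold).
Both cutoffs are parameters; the source counts (53/18) are not
reproduction targets since the underlying expression table is not
available.

## 5. Cross-species convergence

Each species' TF × gene matrix is flattened in fixed TF-major, gene-minor
order over cells annotated (non-NA) in both species of a pair; Pearson
correlation is computed on raw hit counts ("based on the hit number"; a
log1p option exists but is off by default). A PCC is defined only with
≥ 3 shared cells and two non-constant vectors; undefined values are
reported NA with a reason, never imputed. Patristic distances come from
branch lengths (`ape::cophenetic.phylo`), with a unit-edge fallback and
warning for trees without lengths.

`convergence_report` provides three read-outs:

1. per-species PCC to the reference with distance and phenotype;
2. the Spearman correlation between PCC and patristic distance —
   negative under neutral Brownian divergence;
3. a convergent-pair flag: over all species pairs, fit pair similarity
   against patristic distance with a Theil–Sen line and standardize
   residuals by median/MAD; non-sister pairs with robust z > 3.5 are
   flagged. The fit and residuals use Fisher-z transformed PCCs
   (atanh): under realistic noise the pairwise PCCs crowd near 1, where
   raw-PCC residuals are compressed and a strongly convergent pair is
   statistically invisible; Fisher z is the standard
   variance-stabilizing scale for comparing correlations. 3.5 is a
   conventional robust-outlier cutoff, adopted before the recovery
   experiments were run.

The report also flags the descriptive signature of convergence-not-
parallelism: a phenotype-matched species farther from the reference with
*lower* PCC than a phenotype-mismatched closer relative. This is a
descriptive pattern plus rank statistics, deliberately not a formal
Ornstein–Uhlenbeck comparative test — the analysis it reimplements argues
from the PCC/phylogeny pattern alone.

## 6. The synthetic world

The generators state a world once; tests then live in it.

* **Genomes**: i.i.d. nucleotides, default GC 0.41 (typical avian
  genome-wide value). Gene models are packed into equal per-contig slots
  sized so every promoter window fits untruncated whatever the strand;
  gene bodies are a nominal 600 bp (gene structure beyond the TSS is
  irrelevant here and out of scope).
* **Planted motifs**: the PWM consensus (argmax per column, ties to the
  first base in A<C<G<T order) is written at non-overlapping random
  offsets inside the target promoter, reverse-complemented on minus-strand
  promoters so the sense-strand window always contains the consensus.
  Consensus planting guarantees the maximal score, making recovery tests
  sharp: with the default demo PWMs (length 10, count 20-vs-1 per column)
  the consensus p-value ≈ 6e-7 survives BH over a 20-promoter scan family
  with room to spare.
* **Counts**: NB(μ, α) with Var = μ + αμ², the family assumed by the
  external DE tool the stand-in replaces. Defaults: base mean 100,
  dispersion 0.1, two groups of three replicates (the study used two to
  three), 10% DE genes at |log₂FC| = 2 with random sign, log-normal
  per-gene baseline spread (sdlog 0.5, mean-preserving), log-normal gene
  lengths with median ≈ 2 kb, chromosome labels uniform over 1–28, Z, W.
  Library sizes and dispersion of the real data are unpublished; these
  are free parameters of the stated world, not estimates of the study.
* **Species sets**: a root TF × gene profile (default 3 TFs × 10 color
  genes, the scale of the regional-TF versus melanogenesis-gene
  comparison; cells N(10, 5²) truncated at 0) evolves along the tree by
  Brownian motion, adding N(0, σ²·branch length) per cell with σ = 3 —
  about half the root spread, so leaf PCCs fall in a realistic 0.5–0.95
  band rather than collapsing to 0 or 1. A convergent pair is pulled
  toward its joint mean profile by strength w ∈ [0, 1]; w = 1 makes the
  pair identical. Pulling toward the pair mean (not an independent
  target) preserves each species' correlation with the rest of the tree,
  which is what phenotypic convergence through partial regulatory
  rewiring looks like.

What the generator does **not** emulate: real promoter base composition
and repeats, overlapping genes, isoform structure beyond TSS jitter,
library-size variation, count outliers, and correlated evolution between
cells of the binding matrix. A green closed-loop test therefore
establishes internal correctness of the pipeline's logic and statistics —
not that the biological conclusions of any particular study are right.

## 7. Determinism and numerical choices

* Every generator takes a seed, uses an isolated RNG stream
  (`.Random.seed` is saved and restored), and is byte-identical across
  runs; the pipeline manifest records MD5 checksums and reruns reproduce
  them.
* Score discretization 1e-4 bits; DP and scanning share the discretized
  matrix, so oracle comparisons are exact rather than tolerance-based.
* BH is the standard step-up with the cumulative-minimum monotonicity
  fix, capped at 1; implemented directly and cross-checked against
  `stats::p.adjust` on random inputs.
* Ward tie-breaking follows `stats::hclust`'s deterministic order; input
  order is part of the contract.
* Upper-quartile target: geometric mean of per-sample UQs (see §3).
* p-value tail sums are clamped to [0, 1] against floating-point
  accumulation.

## 8. Known limitations

* The motif models, scoring and multiple-testing scope of the external
  motif-database tool this package replaces are unrecoverable from its
  description; binding-strength values are a principled reimplementation,
  not a numeric reproduction of that tool.
* Order-0 background only; no dinucleotide/Markov backgrounds, no motif
  discovery, no ChIP-informed priors.
* The DE stand-in is a convenience for closed-loop testing, not a
  replacement for a dedicated count model on real data.
* The convergence flag is a screening heuristic on one reference-anchored
  statistic; formal comparative modeling (e.g. OU tests) is out of scope.
* `chromosome_ratios` treats any non-numeric, non-Z/W label as unplaced;
  genome-specific naming schemes may need a `chrom_map` at parse time.
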