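---
title: "Mapping apaQTLs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping apaQTLs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaqtl)
```

## The phenotype: relative expression of alternative 3' UTR isoforms

Most human genes carry more than one polyadenylation site. In the simplest
and most frequent configuration — tandem 3' UTR APA — two sites in the same
terminal exon produce a short and a long isoform of the same protein,
differing only in 3' UTR length. Because the 3' UTR carries microRNA and
RNA-binding-protein (RBP) sites, the short/long balance affects transcript
stability, translation and localisation without changing the protein.

`apaqtl` quantifies that balance from standard RNA-seq. For each gene the
terminal exon is split at the proximal poly(A) site into a **PRE** segment
(shared by both isoforms) and a **POST** segment (long isoform only). With
segment lengths $l_{PRE}, l_{POST}$ and read counts $r_{PRE}, r_{POST}$ for
one individual, the ratio of short-to-long isoform expression is estimated
as

$$ m/M \;=\; \frac{l_{POST}\, r_{PRE}}{l_{PRE}\, r_{POST}} - 1 . $$

The subtraction removes the long-isoform contribution to the PRE segment:
if both segments have equal read density the short isoform is absent and
$m/M = 0$. The estimator assumes uniform coverage within segments and
exactly two isoforms; its failure modes are handled by masking:

* $r_{POST} = 0$ gives an infinite ratio — masked;
* a **negative** value (PRE density below POST density) is unphysical under
  the two-isoform model, typically sampling noise or mis-annotation —
  masked;
* $m/M = 0$ is a legitimate value (pure long isoform) and is kept, but it
  has no log2 image, so the log2 view masks it too. The missingness count
  used by the gene filter does **not** include zeros.

Genes are analysed only on the autosomes and only when fewer than
`maxMissing` cells are masked; the default `ceiling(0.27 * n_samples)`
generalises an absolute cut of 100 missing values in a 373-individual
cohort, and an absolute value can be forced.

### Annotation choices

Transcripts of a gene are collapsed by exon-interval union; the coding span
runs from the most proximal coding start to the most distal coding end in
transcript orientation. The proximal poly(A) site is chosen from a
catalog, restricted to the **terminal exon** (the 3'-most exon of the
collapsed model): restricting PRE to the last exon avoids confounding by
alternative splicing upstream. Catalog sites in the 3' UTR are preferred
over coding-exon sites; among eligible sites the transcript-orientation
most proximal wins, with lexicographic site-id tie-breaking for
determinism. Internal-exon and intronic poly(A) sites are out of scope, as
is any model with more than two sites. All internal coordinates are
0-based half-open; GTF/BED I/O converts explicitly.

A read overlapping both PRE and POST increments POST only: a read covering
the proximal cleavage point can only come from the long isoform.
Read-counting tools commonly used for this quantification do not document a
rule for boundary-straddling reads; ours is a deliberate, stated choice.

## The association model

For each gene $a$ and each variant $j$ inside the gene's cis window (gene
body ± 1 Mbp from TSS and TES), an ordinary least-squares model is fitted
over individuals $i$:

$$ \log_2(m/M_{a,i}) = \beta_0 + \beta_1 g_{j,i} + \beta_2 I_i +
   \sum_{n=1}^{k} \alpha_n\, gPC_{n,i} + \varepsilon_{a,i} $$

with $g$ the 0/1/2 alternative-allele dosage, $I$ the imputation-status
indicator and $gPC_{1..k}$ the leading genotype principal components
($k = 3$ by default), guarding against population stratification and
imputation batch effects. Significance of $\beta_1$ is a two-sided t test
with $df = n - 2 - \#\text{covariates}$. Variants whose dosage is constant
(or collinear with covariates) after missing-data removal are flagged
`untestable` and excluded from p-value accounting.

Only common variants enter (conservative MAF strictly > 0.05). The
conservative MAF imputes missing genotypes with the cohort-major
homozygote, so a variant can only move *below* the threshold — no rare
variant sneaks in through missingness. Enrichment analyses instead use the
observed MAF (missing individuals dropped) as a covariate.

### Permutation calibration

Nominal p-values in cis designs are inflated by LD. Significance is
therefore calibrated empirically: in each of `permutations` rounds
(default 100) the gene's phenotype vector is reshuffled across individuals
— one shuffle per gene per round, shared by all its variants, which
preserves the within-gene LD structure of the null — and every model is
refitted. The empirical p-value of a pair is the fraction of permutation
p-values in the chosen pool that fall below its nominal p-value.

The pool is configurable because "the total number of random tests" admits
three readings; all are implemented:

* `per_gene_pooled` (default): all permutation p-values of the gene's
  variants, across rounds. This is the stablest pool at 100 rounds (a
  per-pair pool of 100 values has a granularity of 0.01).
* `per_pair`: each pair against its own rounds only.
* `global_pooled`: everything.

The literal counting rule can return exactly 0; an optional
$(k+1)/(N+1)$ correction is available but off by default, matching the
literal formula. Empirical p-values are then Benjamini–Hochberg adjusted
jointly across all pairs; pairs with corrected empirical p < 0.05 are
significant. Variants are classified **apaQTL** (significant for ≥ 1
gene), **null** (nominal p > 0.1 in every model) or **gray** (suggestive
but not significant); gray variants are dropped from enrichment contrasts
because they mix true and false negatives.

### Genotype principal components

Before PCA, variants inside 24 long-range LD regions (bundled, hg19) are
removed — such regions otherwise dominate the leading components — and the
remainder is LD-pruned in 50-SNP windows stepped by 5 at r² > 0.8. The
pruning removal rule (drop the lower-observed-MAF member, ties to the
later position) determinises behaviour the reference tool leaves
unspecified. Columns are centred and scaled by $\sqrt{p(1-p)}$ (the
variance of a binomial allele count; missing dosages mean-imputed), and the
top-k eigenvectors of the individual×individual covariance are returned
with a deterministic sign convention (largest-magnitude loading positive).
The $p(1-p)$ normalisation is the standard convention for genotype PCA and
is stated here explicitly because reference tools leave it implicit.

## Enrichment analyses

Functional enrichment of apaQTLs is always estimated by multivariate
logistic regression rather than a 2×2 test, so covariates can be held
fixed:

$$ t_j = \beta_0 + \beta_1\,\text{Feature}_j + \text{covariates} +
   \epsilon_j, \qquad \Pr(\text{apaQTL})_j = \frac{1}{1 + e^{-t_j}} $$

fitted by IRLS (≤ 50 iterations, tolerance $10^{-8}$) with Wald 95%
confidence intervals and p-values on $\text{OR} = e^{\beta_1}$. Without
covariates the MLE equals the sample cross-product ratio, which the tests
exploit as an oracle. Observed MAF is always a covariate (common variants
are more discoverable); the CRD analysis adds distance to the nearest
analysed gene. Non-convergence and separation are flagged, not silently
reported.

Each analysis defines its own candidates, which are LD-pruned *before*
feature assignment: chromatin states use all state-annotated, non-SV
tested variants; gene regions use intragenic variants (gene span + 1 kb
past the end, absorbing 3' UTR mis-annotation); CRDs use extragenic
variants; motif and GWAS features are propagated from tagging variants
(r² > 0.8, strict) — a pruned candidate inherits a feature its LD proxy
carries. An optional exclusion interval (e.g. the MHC/HLA region) removes
candidates and tags before fitting, for sensitivity analyses.

The CRD concordance test asks a sharper question than enrichment: do
extragenic apaQTLs fall inside CRDs assigned to *their own* target genes?
The null reassigns each apaQTL a uniformly random analysed gene whose cis
window contains it (100 rounds by default) and the empirical p uses the
$(\#\{null \ge obs\}+1)/(N+1)$ convention.

## Motif alteration

For SNPs inside analysed genes, the reference and alternative allele
sequences of the ±10 bp window are reconstructed on the gene strand.
Only motif occurrences overlapping the variant position are compared —
a variant cannot alter an occurrence it does not touch.

* **PAS**: a variant is a candidate when its nearest
  transcript-orientation-downstream poly(A) site lies in the gene's
  PRE/POST span, 10–100 nt away (the signal must sit upstream of the
  cleavage site at a workable distance; the distance is measured from the
  variant to the site). Hexamers from an 18-motif catalog found in exactly
  one allele give `created`/`destroyed`; different hexamers in the two
  alleles give `interconverted` — signals differ in strength, so swaps
  matter.
* **microRNA seeds**: candidates are SNPs in the POST segment, where a
  site affects only the long isoform. Sites are classified 8mer >
  7mer-m8 > 7mer-A1 at a common 8-nt window anchored at the seed-match
  position, so a change at the m8 or A1 position registers as a class
  transition (`strengthened`/`weakened`) rather than a creation. 6-mers
  are not scanned; a transition from an unscanned match into a scanned
  class counts as creation. Only conserved, expressed families are used
  (expressed = value > 0 in ≥ 50% of samples; a family is expressed if any
  member is).
* **RBP PWMs**: log2-odds scanning against a background floored at
  $10^{-6}$; a motif is altered when best-score/perfect-score exceeds 0.8
  *strictly* in exactly one allele. RNA motifs act on the mRNA, so only
  the sense strand is scanned; U/T normalisation happens at load. The
  expressed-RBP filter reuses the microRNA rule unless a list is supplied,
  since no threshold is published for that filter.

Swapping REF and ALT flips `created`/`destroyed` (and
`strengthened`/`weakened`) in every mechanism — a symmetry the test suite
asserts.

## Read-based genotyping (validation cohorts)

When genotypes are unavailable, a SNP can be called from RNA-seq base
counts at its position: homozygous when all reads carry one allele,
heterozygous as soon as both appear. Genotype-QC tools for this setting
rarely document their filters; our QC stage requires depth ≥ 5 and, for heterozygotes, a minor-allele
fraction ≥ 0.2 *or* a binomial test rejecting a 1% sequencing-error origin
— all parameters exposed. Hardy–Weinberg equilibrium is checked by plain
Pearson chi-square (df 1; an exact test is also provided — the published
p-value for the 11/22/14 example is not exactly reproduced by either
convention and is not asserted), and genotype–phenotype contrasts use the
tie-corrected Kruskal–Wallis test.

## The synthetic-data generator

The simulator emulates the statistical structure of the emulated study
design — a 373-individual cohort with RNA-seq and whole-genome genotypes:

* genotypes: biallelic SNPs with target MAF uniform on [0.05, 0.5] drawn
  per haplotype block, LD by a haplotype-copying process (copy probability
  0.9 within blocks of 10) — simpler than coalescent simulation and
  sufficient for pruning/tagging behaviour; optional divergent
  subpopulations with Hardy–Weinberg sampling within each;
* phenotype: latent $\log_2(m/M) = \beta_0 + \beta_1 g\,(+\,\text{shift})
  + \mathcal{N}(0, 0.5)$;
* counts: expected $r_{POST} = c\, l_{POST} M$, $r_{PRE} = c\, l_{PRE}
  (m + M)$ with $m = \rho M$, Poisson-sampled at a depth giving tens of
  reads per segment. Poisson (not negative binomial) is the default —
  sufficient for calibration, with the latent noise absorbing biological
  overdispersion; with noise and Poisson disabled the m/M computation
  inverts the generative model exactly;
* feature tracks with planted enrichment odds ratios, realised through the
  status-conditional feature frequencies.

Presets fix the study conditions: `null` (200 genes, no effect anywhere),
`powered` (100 genes, all causal, $\beta_1 = 0.5$ on log2 m/M, causal MAF
0.3, noise sd 0.5), `structured` (two subpopulations, divergence 0.15,
phenotype shift 0.5).

What passing tests on these data do **not** show about real data: uniform
within-segment coverage (no 3' bias or coverage waves), no alternative
splicing or intron retention inside the 3' UTR, no reference bias, known
truth for the poly(A) catalog, and LD far simpler than human haplotypes.
Calibration and power results transfer only to the extent those
assumptions hold.

## Numerical notes and verification scale

* The per-gene mapping engine residualises the phenotype and the window's
  dosage matrix against the covariate basis (QR) and computes all variant
  t statistics as partial correlations — algebraically identical to
  per-pair OLS (asserted to $10^{-8}$ against a normal-equations oracle)
  but vectorised, with permutations batched as matrix products. Genes with
  missing dosages fall back to per-pair fits.
* Calibration checks run at the full emulated scale (200 genes × 373
  individuals × 50 variants × 100 permutations — about one million model
  fits in seconds); enrichment coverage uses 200 replicates per planted OR
  at 5,000 candidates. CI coverage of the Wald interval is assessed pooled
  across the four planted odds ratios: per-condition coverage at 200
  replicates has a binomial standard error of ~1.5%, wider than the band
  being checked, while the pooled estimate (800 replicates) resolves it.
* The KS uniformity check on empirical p-values is read at fixed seed:
  within a gene the 50 variants share one phenotype vector, so the pooled
  10,000 empirical p-values are positively correlated and their KS
  statistic fluctuates more between seeds than independent sampling would
  suggest (with no bias — the mean and all deciles sit at their uniform
  values).
* Ties in site choice, pruning and component signs are all broken
  deterministically (site id, position, largest loading), so identical
  inputs give byte-identical outputs everywhere.

## Limitations

Two-site models only; annotation-dependent (unannotated proximal sites are
invisible); unstranded counting by default (a switch covers stranded
protocols); no conditional or multi-variant fine-mapping, no trans
analysis; the direction-of-effect concordance for microRNA calls is
descriptive, not a test; the enrichment engine assumes pruned candidates
are approximately independent.
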