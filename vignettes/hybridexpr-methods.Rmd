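---
title: "Methods: comparative brain transcriptomics of sister species and their hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative brain transcriptomics of sister species and their hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The study design this package models

`hybridexpr` re-implements, as reusable and tested components, an analysis
workflow for comparing gene expression between two closely related songbird
species — the collared flycatcher (CF, *Ficedula albicollis*) and the pied
flycatcher (PF, *F. hypoleuca*) — and their naturally occurring F1 hybrids.
The design it assumes throughout: 5 CF males, 5 PF males and 3 F1 males (all
with CF fathers and PF mothers), each sampled in five tissues, with the
caudal telencephalon — the portion of the forebrain containing the auditory
lobule and the song nuclei HVC and RA — as the focal "brain" tissue.
Downstream stages consume population re-sequencing data (19 individuals per
species), phased allele-specific read counts for the hybrids, protein-domain
tables, and a rooted phylogeny carrying a single amino-acid character.

Because the real sequence data live in an archive, the package ships a
synthetic-data generator that emulates the whole design with planted ground
truth, so that every stage can be exercised and its error rates measured
without downloading anything.

# Expression units and tissue enrichment

Counts are converted to transcripts per million (TPM) per sample:
$\mathrm{tpm}_g = 10^6 \, (c_g/L_g) / \sum_h (c_h/L_h)$, where $L_g$ is the
summed exon length of the gene. Two choices here were genuinely open and are
fixed as follows:

* **Transcript length** is the summed CDS+UTR exon length per gene; no
  isoform-level resolution is attempted.
* **TPM is computed per sample**, not per pooled tissue library; sample
  columns each sum to $10^6$ by construction.

A gene is *expressed* in a tissue when the mean of $\log_2(\mathrm{tpm}+1)$
over that tissue's samples is at least 1 — the threshold is inclusive
("at least"). *Fold enrichment* in the focal tissue is the ratio of mean raw
TPM in the focal tissue to the highest mean raw TPM among the other tissues;
genes at or above 5× are *enriched* and at or above 50× *highly enriched*.
The fold is computed on raw TPM rather than on the log transform — a ratio
of logs would not be a fold of expression — and the per-tissue means pool
all individuals (both species and hybrids), matching how the enrichment sets
feed the gene-ontology stage. When no other tissue shows any expression the
fold is $+\infty$ and the gene is focal-only.

# Differential expression

The two-group test is a negative-binomial Wald test operating on
median-of-ratios size-factor-normalized counts, with
$\mathrm{Var} = \mu + \alpha\mu^2$. Two numerical choices matter:

* **Dispersion is shared across genes** (a 5%-trimmed mean of per-gene
  moment estimates over genes with mean normalized count above 5). With five
  samples per group a per-gene variance estimate has so few degrees of
  freedom that plugging it into a Wald statistic is either anti-conservative
  (normal reference) or severely underpowered (t reference). A single common
  dispersion restores both type-I calibration and power; per-gene plug-in
  remains available via `dispersion = "per_gene"`. This is a
  common-dispersion estimate in the edgeR tradition, not empirical-Bayes
  shrinkage, which is out of scope.
* **Fold changes use a pseudo-count of 0.5** and the Wald statistic is
  referred to the standard normal; p-values are adjusted by
  Benjamini–Hochberg, and "differentially expressed" means adjusted
  p < 0.05 by default (the threshold is configurable; comparable studies
  print adjusted p-values without naming a cutoff).

The *focal-tissue specificity rule* then classifies a species-DE gene as
brain-specific when it is either not DE in any other tissue, or DE in other
tissues only in the opposite direction (e.g. CF > PF in brain but PF > CF in
liver).

*Hybrid inheritance patterns* order the three group means (C, P, H) into a
pattern string ("P > C > H") and call the mode: *intermediate* when the
hybrid mean falls strictly between the parental means, *transgressive*
(high/low) when it falls outside, *tied* on exact equality — ties use exact
numeric equality since group means of real data are effectively continuous.
*Variance partitioning* reports SSspecies/SStotal of the one-way ANOVA
decomposition, computed from group summary statistics (mean, sd, n), which
is algebraically identical to the decomposition on raw values.

# Gene-set tests

Over-representation uses the one-sided hypergeometric upper tail (Fisher's
exact test) against a declared gene universe with BH adjustment across sets.
The directional test converts each gene's (adjusted) p-value and direction
into a signed normal score $z_g = \mathrm{sign}(d_g)\,\Phi^{-1}(1-p_g/2)$
(p floored at $10^{-15}$), scores a set by the mean over members, and builds
the null by resampling same-sized gene sets without replacement, with the
add-one correction $(1+\#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)$ so no
p-value is zero. The published pipeline's resampling configuration is not
printed; this scheme is declared as the implemented definition. Whether raw
or adjusted p feeds the score is switchable; adjusted is the default.

# Co-expression modules

The network is signed-hybrid: $a_{ij} = \mathrm{cor}(i,j)^\beta$ for
positive Pearson correlations and 0 otherwise, with soft power $\beta = 4$.
Similarity is the topological overlap matrix (TOM), and modules are branches
of an average-linkage dendrogram of $1-\mathrm{TOM}$, cut at a fixed
fraction of the maximum merge height; clusters below the minimum module size
(30) fall into module 0, the unassigned "grey" pool. Two defaults reflect
the ten-sample reality of the design rather than library folklore:

* **Cut height 0.75 × max.** With ten samples, correlation noise keeps
  merge heights of unrelated genes well below 1 and spread over a wide
  band; a cut near the maximum height swallows noise genes into real
  modules. 0.75 separates planted blocks from the noise background across
  seeds.
* **kME pruning at 0.6.** After the cut, members whose correlation with
  their own module eigengene falls below 0.6 are returned to module 0.
  This is the standard module-membership cleanup of WGCNA practice; module
  *merging* by eigengene similarity is deliberately not implemented.

Module eigengenes are the leading principal direction of the
gene-standardized module submatrix, unit-norm, oriented to correlate
non-negatively with the module's mean profile (so flipping every profile
flips the eigengene with them). Module–trait association is the Pearson
correlation of the eigengene with species identity (CF = 0, PF = 1), with
p from the Student t distribution on $n-2$ df; module membership and gene
significance reuse the same correlation contract per gene. The expression
input is $\log_2(\mathrm{tpm}+1)$ filtered at mean ≥ 1 over the ten pure
species individuals; base-2 logs are used consistently everywhere.

# Allele-specific expression and cis/trans inference

For each gene and hybrid, maternal and paternal reads are summed over the
phased SNPs and tested against 1:1 by a two-sided exact binomial test;
hybrids are combined by Fisher's method ($\chi^2$ with $2k$ df). Phasing is
assumed resolved upstream — the read-backed phasing model of specialised ASE
callers is not reproduced; the testable contract here is calibration and
recovery. A beta-binomial variant with fixed intra-class correlation is
available for overdispersed data but off by default.

A species-DE gene is called *cis* when the BH-adjusted combined p falls
below 0.05 **and** the allelic imbalance is concordant with the species
difference given the cross (CF fathers: the paternal allele is the CF
allele); *trans-consistent* when ASE is non-significant despite at least 20
informative reads (absence of imbalance, with power, is the trans
signature); *undetermined* otherwise. The 20-read floor guards the
"no ASE ⇒ trans" inference against low power; the threshold is
configurable since no published value exists for it.

# Fixed differences and protein consequences

Sites failing the coverage filter are removed first. The filter's published
wording ("not covered by at least 1 read over all individuals") is
ambiguous; the strict reading — every individual covered — is the default,
and a summed-depth mode (`mode = "total"`) implements the looser reading. A
biallelic site is a fixed difference when all covered individuals of one
species are homozygous for one allele and all of the other species for the
alternative; individuals with missing genotypes are excluded, and a site
needs at least one covered individual per species.

Sites are assigned to regions with precedence gene body (with 5'/3' UTR
sublabels) > flank > intergenic; flanks are ±5 kb and strand-aware
(flank_up is the 5' side). All internal coordinates are 0-based half-open —
GFF3 and VCF are converted on read — which keeps the flank-window arithmetic
free of off-by-one cases. Coding changes are annotated by rebuilding the
affected codon from the spliced CDS (strand- and frame-aware), substituting
the alternative allele, and translating both codons with the standard
genetic code; nonsynonymous changes are located relative to protein domains,
with an explicit *within-10-residues-of-the-domain-start* proximity class
alongside *inside* and *outside*.

# Ancestral reconstruction

A single amino-acid site on a rooted tree is reconstructed two ways: Fitch
parsimony (intersection/union pass, returning the root state set and the
minimal change count; polytomies are resolved deterministically with
zero-length branches; missing tips contribute the whole alphabet) and
marginal maximum likelihood by Felsenstein pruning under the symmetric
k-state model, $P(\mathrm{stay}) = 1/k + (1-1/k)e^{-k\mu t/(k-1)}$, with a
uniform root prior. The substitution model behind the published library
calls is not printed; the symmetric equal-rates model is the package's
choice, and rate and branch lengths are inputs rather than estimated.

# The synthetic study and what it does (not) show

`simulate_counts()` draws per-gene baseline levels (log-normal), tissue
profiles, species effects in the focal tissue
($\pm\mathrm{lfc}/2$ on the log2 scale), hybrid means per inheritance mode
(additive = mid-parent on log2; dominant = the matching parent;
transgressive = outside the parental range by the effect size), planted
brain-enrichment (other tissues set to brain/fold, so the fold survives
per-tissue TPM renormalization), and module structure via shared latent
factors. Counts are negative binomial with $\alpha = 0.05$
(Var $= \mu + \alpha\mu^2$; typical bulk RNA-seq) and log-normal library
sizes ($\sigma = 0.2$) to exercise normalization. Truth labels are obtained
by applying the pipeline's own classification rules to the noise-free
expected TPM, so every label is recoverable in expectation. Allele counts
split reads multinomially over 1–12 phased SNPs with the allelic-ratio
parameter tied to the planted architecture; the genotype simulator plants
fixed differences (coding and noncoding, including a serine→threonine
change within 10 residues of a domain start), shared and private
polymorphisms, and a deliberately uncovered site. All generators are pure
functions of (config, seed).

Features of real data the generator does **not** emulate: isoform
structure, GC and mapping biases, batch effects, linkage disequilibrium,
indels, cell-type composition differences between individuals, and
phylogenetic non-independence beyond the single simulated site. Passing
recovery tests therefore demonstrates the correctness and calibration of
the statistical machinery under the declared noise model, not robustness to
every artifact of sequencing.

Problem sizes used by the test-suite and the acceptance script — chosen so
a desk machine reproduces them in minutes: null calibration on 2000 genes
(DE) and 1000 genes (ASE); recovery on ten 500-gene replicate studies (DE),
one 2000-gene study (tissue classes), five planted-partition networks of
210 genes (modules), ten 200-gene studies (cis/trans), and 100 replicate
trees of 12 tips (ancestral reconstruction).

# Pipeline orchestration

`run_pipeline()` runs the stages in dependency order (TPM → enrichment →
DE → patterns/variance → gene sets → modules → ASE → variants → ancestral)
from a single configuration with one seed; identical configuration and seed
give byte-identical TSV outputs. The configuration is YAML (the
configuration-file convention of the R ecosystem); every stage can be
toggled off, and each output header records the defaults that stand in for
unpublished settings. A thin command-line front end
(`inst/cli/hybridexpr.R`) exposes the main stages as subcommands.

# Known limitations

* The DE stage is a calibrated stand-in for a full GLM framework: no
  per-gene dispersion shrinkage, no outlier handling, no independent
  filtering. Its contract is honest error rates at the study's sample
  sizes, not numerical equality with any specific package.
* Cis/trans classification is binary (cis-containing vs trans-consistent)
  and does not quantify mixed cis+trans architectures.
* The static dendrogram cut with kME pruning recovers well-separated
  modules; heavily overlapping modules would require dynamic tree cutting.
* Ancestral reconstruction treats branch lengths and the rate as known.
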