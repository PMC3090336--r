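---
title: "From EST contigs to a validated SNP panel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EST contigs to a validated SNP panel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetsnp)
```

## Scope

`hetsnp` implements the in-silico stages of SNP marker development for
highly heterozygous, multi-species genomes (the motivating setting is
outbred forest trees, where nucleotide diversity can reach one SNP per
~16 bp): discovery of candidate SNPs from quality-annotated EST contig
alignments, a sequential filter cascade that selects assayable sites,
GoldenGate-style genotyping QC, and two independent validation routes
(Mendelian transmission in trios, and exact-binomial comparison with
shotgun read counts). Assembly itself, spliced alignment, and the
Illumina clustering/scoring algorithms are *consumed as inputs*, never
recomputed: alignments arrive as a documented JSON placement dialect
plus FASTA/QUAL, exon and repeat annotation as a GFF3 subset, and
GenCall/GenTrain/ADT scores as columns of the genotype CSV.

All coordinates are 0-based half-open inside the package and 1-based
inclusive in every file read or written. This split keeps flank
arithmetic free of off-by-one errors while matching the conventions of
GFF and human-readable reports.

## The polymorphism posterior

At each alignment column we observe bases $b_1,\dots,b_n$ with Phred
qualities $q_1,\dots,q_n$, hence per-base error probabilities
$e_i = 10^{-q_i/10}$. With
$f(b \mid a) = 1 - e_i$ if $b = a$ and $e_i/3$ otherwise, the column is
scored under two hypotheses:

* **monomorphic**: $L_{\text{mono}} = \max_a \prod_i f(b_i \mid a)$
  over the four nucleotides;
* **polymorphic**: $L_{\text{poly}} = \prod_i \tfrac12\,[f(b_i \mid a_1)
  + f(b_i \mid a_2)]$ over the two most frequent observed bases, i.e.
  a balanced two-allele mixture.

With prior $\pi$ on polymorphism the posterior is
$\pi L_{\text{poly}} / (\pi L_{\text{poly}} + (1-\pi) L_{\text{mono}})$,
computed on the log scale. The defaults are $\pi = 0.01$ (one SNP per
hundred bases expected) and a selection cutoff of $0.99$. Columns with
fewer than two distinct observed bases return 0: the mixture halves
every factor, so a monomorphic column can never reach the prior, let
alone the cutoff.

The balanced mixture has a practical consequence worth knowing:
$L_{\text{poly}}$ pays a factor $\approx 2^{-n}$ relative to
$L_{\text{mono}}$ on major-allele reads, so the minor allele must be
seen several times before the posterior clears 0.99. At Q30 the
guaranteed-detection region works out to roughly
$k \gtrsim 0.09\,n + 1.3$ minor reads at depth $n$; the test suite
therefore asserts full sensitivity for sites with depth $\ge 12$, at
least 3 minor reads and in-silico MAF $\ge 0.2$ (the cascade's own MAF
bar), and zero false calls on error-free data. Columns supported by a
single stray read are *meant* to be missed.

### SNP-block tagging

The second caller emulates neighbourhood-quality ("SNP block")
tagging: each allele's group score is the sum, over its supporting
reads, of the minimum Phred value in a 7-base window centred on the
column and clipped to the read. A column is tagged when the minor
allele has $\ge 2$ supporting reads and both group scores reach 40
(two clean Q20 reads). The mechanism is specified by behaviour rather
than by a published formula, so the window, the read floor and the
score threshold are all exposed in `filter_config()`; with
`tag_min_minor_reads = 1` a single confident discrepancy in a clean
neighbourhood is enough to tag, which is exactly the behaviour the
window-quality rationale implies.

## The filter cascade

`apply_filters()` reproduces the sequential selection used for assay
design. Writing $d$ for A/C/G/T depth and $k$ for minor-allele reads:

| level | rule (cumulative) |
|------|--------------------|
| F0 | biallelic, $d \ge 5$, $k \ge 1$, 60 bases available each side |
| F1 | F0 and in-silico MAF $\ge 0.2$ |
| F2 | F1 and $\ge 1$ read from a required taxon set |
| F3 | F2 and 100 repeat-free + 20 SNP-free bases each side |
| F4 | F3 with the SNP-free flank raised to 60 bases |
| CG | biallelic, $k \ge 2$, 60 bases available (relaxed candidate-gene rule) |

A site whose 30-base flanks straddle an exon boundary is excluded at
*every* level, because oligos designed across an intron/exon junction
fail on genomic DNA; when no exon map is supplied the check is
*indeterminate* and excludes nothing, so the cascade runs unchanged on
purely synthetic contigs. Nesting F4 ⊆ F3 ⊆ F2 ⊆ F1 ⊆ F0 holds by
construction and is property-tested on random candidates.

Two points were genuinely open and are settled here as configuration:

* **What counts as an "additional SNP" in a flank.** Default: other
  candidates at the posterior cutoff (`posterior_cutoff`). The
  alternative `any_minor_ge2` counts any column with two or more
  minor reads, which is stricter on noisy contigs. Both are exposed
  because the choice changes F3/F4 membership, not the cascade logic.
* **Whether repeat constraints apply below F3.** They do not: repeat
  and SNP-free flank rules enter at F3 exactly as the level
  definitions state.

Repeat masks are consumed as annotation (GFF3 intervals), never
computed: repeat detection is a solved upstream problem and any
detector can feed the mask.

## Genotyping QC

Per SNP: call rate is the fraction of datapoints with GenCall
$\ge 0.25$ (no-calls count as failures; the boundary is inclusive);
GC50 is the median GenCall over typed samples, with the even-$n$
median taken as the midpoint of the central order statistics (the
natural reading of "50th percentile"); a SNP is **reliable** when
GC50 $\ge 0.40$, call rate $\ge 0.95$ and, where present, GenTrain
$\ge 0.40$ — GenTrain is pass-through metadata because it comes from
proprietary clustering. Assayed MAF is the allele-count frequency over
called genotypes; **polymorphic** means MAF $\ge 0.05$ by default,
with 0.01 exposed as the less conservative alternative. The
**conversion rate** is the polymorphic fraction, over all SNPs or the
reliable subset.

Species genotyped in fewer than 16 individuals (32 chromosomes) are
excluded from per-species polymorphism tables: below that, a MAF-0.05
allele is more likely missed than seen. Call-rate denominators include
every panel sample, failures and all; whether excluded DNAs should be
dropped instead is not decidable from the definitions, so the simplest
rule is used and stated.

## Validation

**Trios.** Each complete parent-parent-offspring trio contributes two
allelic transmissions. The child's alleles are assigned to parents in
whichever of the two orderings minimises violations; a slot whose
allele is absent from its parent's genotype is inconsistent. This
matches a brute-force enumeration over all assignments (tested
exhaustively on the 27 complete genotype combinations). Trios with any
no-call contribute nothing; a 768-SNP × 24-trio family with complete
calls therefore yields 36,864 transmissions. The concentration
statistic reports the smallest set of SNPs holding 80% of all
miscalls, ranking ties by SNP id for determinism.

**Shotgun counts.** With at least five reads over the two assay
alleles, a two-sided exact binomial test of the 1:1 heterozygote
expectation is run at $\alpha = 0.1$; rejection declares a homozygote
for the majority allele, otherwise a heterozygote. The generous
$\alpha$ trades type-I error for power at the 2× coverage this
evidence typically has. Two-sidedness is our documented choice (a 1:1
null has a symmetric alternative); the p-value is the doubled smaller
tail, capped at 1. Reads carrying neither assay allele go to
`other_count` and never enter the test. Note an inherent ceiling:
because the test rejects true heterozygotes at its exact type-I rate,
concordance with truth is below 1 even on error-free data — at depth
30 the exact rejection mass is 0.0987, and the test suite asserts
*that* value, not perfection.

## The statistics module

Implemented from first principles with base distribution functions
supplying tail areas: Pearson 2×2 chi-square **without** continuity
correction (the uncorrected statistic is what the pooled filter-level
comparisons require — with Yates' correction the pooled call-rate
comparison drops from 17.39 to a visibly different value);
Mann-Whitney U with midranks, tie-corrected normal approximation and
full enumeration when both samples have ≤ 8 observations; the
two-sided exact binomial above; the normal-approximation sample size
$n_{\text{alleles}} = \lceil z^2 p(1-p)/h^2 \rceil$ for estimating an
allele frequency (0.05 ± 0.025 at 95% gives 292 alleles = 146
diploids); and logistic regression by IRLS with explicit
rank-deficiency errors and complete-separation detection. Each has an
independent oracle in the tests (enumeration, grid search, or the
corresponding reference fitter), and the reference implementations
(`chisq.test`, `wilcox.test`, `glm`) serve as cross-checks only.

## What the simulator does and does not emulate

`simulate_haplotypes()` places sites by a Bernoulli process (default
density 1/16 per bp, the upper end of reported diversity in the
motivating genus); a configurable fraction of sites segregates in all
species with a common frequency — polymorphism predating speciation,
the property that makes cross-species assays possible — and the rest
are private. Minor allele frequencies are drawn uniformly on
[0.05, 0.5]: no site-frequency spectrum is claimed for the study
populations, so a flat prior is used and stated rather than asserted.
Individuals are Hardy-Weinberg draws from species frequencies, and
genotype panels likewise — a simplification (no inbreeding, no
population structure, no linkage). Reads carry flat per-technology
qualities and substitution-only errors at $10^{-q/10}$; 454
homopolymer indels are deliberately not modelled because no downstream
stage consumes indels. GenCall scores are Beta-distributed around a
per-SNP cluster-quality mean (concentration 30 keeps scores
plausibly tight), so low-quality SNPs produce the low-score,
far-from-cluster datapoints the QC statistics react to.

Trio corruption flips the transmitted allele at distinct
`(snp, trio, parent)` slots, restricted to cells where both parents
are homozygous and to one slot per cell. The restriction is what makes
the injected count *provably* equal the detected count: a flip at a
heterozygous parent produces an allele the parent also carries, and
flipping both slots of an AA × BB cross yields a perfectly legal AB
child — both would silently deflate the recovered count. Eligible
slots are abundant in realistic panels (both-homozygous probability
$(1-2pq)^2$ per SNP), and requests beyond the eligible set raise an
error rather than degrade.

Consequently, passing tests demonstrate internal consistency of the
pipeline under its own generative assumptions — they do not establish
performance on real EST assemblies, where alignment artefacts,
paralogy and base-caller miscalibration violate those assumptions in
ways the simulator does not reproduce.

## Numerical and size choices

Random streams are seeded per generator call and the global RNG state
is restored afterwards, so generators are pure functions of
(parameters, seed). Allele ties break lexicographically everywhere.
The posterior is evaluated in log space. Problem sizes in the test
suite — contigs of 2–10 kb at depth ~20, panels of tens of SNPs by ≤
500 samples, 10⁴ Monte-Carlo columns/replicates, 50-seed bias checks —
were chosen as the smallest sizes at which the binomial/Poisson
tolerances quoted in the tests are meaningful; every stochastic
assertion states its tolerance as a multiple of the exact standard
error at that size.

## Known limitations

* No indel or paralog handling: the caller targets substitutions and
  assumes orthologous alignment columns (no paralog screen is
  implemented; whether one was applied upstream in the motivating
  study is unstated).
* ACE/SAM alignments are out of scope by design; placements travel in
  the JSON dialect.
* The two-hypothesis posterior is a concrete stand-in for the
  published decision rule of the original Bayesian caller, whose
  internals are not restated here; it is parameterised by the same
  prior and cutoff and reproduces the same accept/reject behaviour on
  the documented examples.
* Uniform within-species frequencies and Hardy-Weinberg panels are
  simplifications; ascertainment bias of real discovery panels is not
  modelled.
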