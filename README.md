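# hetsnp

SNP discovery, filtering and validation for highly heterozygous,
multi-species genomes.

Developing a genotyping panel from EST resources in an outbred genus is
a funnel: thousands of alignment-column discrepancies must be reduced
to a few hundred sites that (i) are real polymorphisms rather than
sequencing error, (ii) sit in sequence that an allele-specific assay
can be designed against, and (iii) remain informative across related
species. `hetsnp` implements that funnel — and the statistics used to
judge its output — as a tested, reusable R package, together with a
synthetic-data module that emulates the whole data structure so every
stage can be exercised end to end without external data.

## What it computes

**Discovery.** For each alignment column with observed bases $b_i$ and
Phred qualities $q_i$ (error rates $e_i = 10^{-q_i/10}$), a
two-hypothesis Bayesian posterior contrasts a single-allele model,
$L_\text{mono} = \max_a \prod_i f(b_i\mid a)$, with a balanced
two-allele mixture over the two most frequent bases,
$L_\text{poly} = \prod_i \frac12[f(b_i\mid a_1)+f(b_i\mid a_2)]$, where
$f(b\mid a)=1-e_i$ if $b=a$, else $e_i/3$. With prior 0.01 (one SNP per
100 bp expected), columns with posterior ≥ 0.99 become candidate SNPs;
contigs with fewer than five reads are skipped. A second,
neighbourhood-quality caller tags columns whose minor allele is backed
by enough summed window-minimum quality (a "SNP block").

**Filtering.** The sequential cascade F0–F4 (depth ≥ 5 and one
alternative read; in-silico MAF ≥ 0.2; one read from a required taxon
group; 100 repeat-free and 20 SNP-free flanking bases per side; SNP-free
flank raised to 60), plus the relaxed candidate-gene rule (any biallelic
site with ≥ 2 alternative reads), 60 available bases per side
throughout, and a same-exon check on 30-base flanks. ADT design scores
are summarised per level and selected at ≥ 0.8.

**Genotyping QC.** Call rate at GenCall ≥ 0.25 per datapoint, GC50 (the
median GenCall score), assayed MAF, the reliable (GC50 ≥ 0.40, call
rate ≥ 0.95, GenTrain ≥ 0.40 where present) and polymorphic
(MAF ≥ 0.05, optionally 0.01) classifications, conversion rate, shared
polymorphism over every species subset, cross-species transferability
tables, and the caller-concordance 2×2 comparison.

**Validation.** Mendelian transmission checking in parent–parent–
offspring trios (two transmissions per complete trio, child alleles
assigned to minimise violations), per-SNP heritability and miscall
concentration; and sequence-based genotype validation by a two-sided
exact binomial test of the 1:1 heterozygote read ratio (≥ 5 reads,
α = 0.1).

**Statistics.** Pearson 2×2 chi-square (no continuity correction),
Mann-Whitney U (midranks, exact for small samples), the exact binomial
test, the sample size needed to estimate an allele frequency, and
logistic regression by IRLS — all written from first principles and
cross-checked against independent oracles in the test suite.

## Worked example

```r
library(hetsnp)

# two species, eight diploids each, one 4 kb contig
truth <- simulate_haplotypes(n_species = 2, individuals_per_species = 8,
                             contig_length = 4000,
                             snp_density_per_bp = 1/150,
                             shared_site_fraction = 0.8, seed = 11)
reads <- simulate_est_reads(truth, depth_mean = 30,
                            error_from_quality = FALSE, seed = 12)
cand  <- discover_snps(reads)
nrow(truth$sites); nrow(cand)
#> [1] 26
#> [1] 19
res <- apply_filters(cand, filter_config(required_taxa = "sp02"))
res$funnel
#>   level n_snps n_contigs
#> 1    F0     19         1
#> 2    F1     14         1
#> 3    F2     14         1
#> 4    F3      9         1
#> 5    F4      8         1
#> 6    CG     19         1
```

19 of the 26 simulated sites are recovered — the posterior deliberately
ignores sites whose minor allele was sampled in fewer than ~3 reads —
and the funnel then narrows them to 8 fully flank-clean F4 sites. On to
genotyping and validation:

```r
panel <- simulate_genotype_panel(truth, seed = 13)
qc    <- snp_qc(panel)
sprintf("conversion rate (reliable SNPs): %.1f%%",
        100 * conversion_rate(qc))
#> [1] "conversion rate (reliable SNPs): 96.2%"

parents <- attr(panel, "true_genotypes")[, 1:2]
trios <- simulate_trios(
  data.frame(snp_id = rownames(parents),
             father = parents[, 1], mother = parents[, 2]),
  n_trios = 24, n_inject = 15, seed = 14)
trio_heritability(trios)
#> TrioSummary: 15 inconsistencies / 1248 transmissions (miscall rate 1.20%)
#> 15 SNP(s) with full heritability; 80% of miscalls in 8 SNP(s)

seq_genotype_call(ref_count = 5, alt_count = 0)[c("p_value", "seq_genotype")]
#> $p_value
#> [1] 0.0625
#> $seq_genotype
#> [1] "hom"
```

The 15 injected transmission corruptions are recovered exactly (26
SNPs × 24 trios × 2 slots = 1248 transmissions), and five reads of a
single allele are just enough evidence to call a homozygote at
α = 0.1 (p = 2·(1/2)⁵ = 0.0625).

A command-line front end chaining the same stages
(`simulate | call | filter | qc | validate-trio | validate-seq`) ships
in `inst/cli/hetsnp.R`.

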