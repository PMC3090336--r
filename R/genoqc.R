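# Assay-quality statistics for a GoldenGate-style genotype panel: per-SNP
# call rate (GenCall >= 0.25 per datapoint), GenCall50 (the median
# GenCall score), assayed minor allele frequency, the reliable /
# polymorphic classification, conversion rate, shared polymorphism
# across species subsets, cross-species transferability and the
# caller-concordance cross-tabulation.

#' Per-SNP call rate
#'
#' Fraction of panel datapoints whose GenCall score reaches the cutoff
#' (0.25, the recommended per-datapoint bar). No-calls carry a missing
#' score and count as failures; the boundary is inclusive.
#'
#' @param gencall_row Numeric GenCall scores for one SNP across samples
#'   (`NA` = no-call).
#' @param cutoff Per-datapoint score cutoff.
#' @return Fraction in `[0, 1]`.
#' @export
call_rate <- function(gencall_row, cutoff = 0.25) {
  if (length(gencall_row) == 0L) stop("empty gencall row", call. = FALSE)
  mean(!is.na(gencall_row) & gencall_row >= cutoff)
}

#' GenCall50 score
#'
#' Median GenCall score of a SNP over its typed samples (even counts
#' average the two central order statistics). `NA` when every sample is
#' a no-call; such SNPs are unreliable by definition.
#'
#' @inheritParams call_rate
#' @return Score in `[0, 1]`, or `NA`.
#' @export
gc50 <- function(gencall_row) {
  x <- gencall_row[!is.na(gencall_row)]
  if (length(x) == 0L) return(NA_real_)
  median(x)
}

#' Assayed minor allele frequency
#'
#' Allele-count MAF over called genotypes:
#' `freq_B = (2 n_BB + n_AB) / (2 n_called)`, reported as
#' `min(freq_B, 1 - freq_B)`. `NA` when no genotype is called in the
#' subset.
#'
#' @param genotype_row Character genotypes over `{AA, AB, BB, NC}` for
#'   one SNP.
#' @param subset Optional logical/integer index selecting samples.
#' @return Frequency in `[0, 0.5]`, or `NA`.
#' @export
assayed_maf <- function(genotype_row, subset = NULL) {
  g <- if (is.null(subset)) genotype_row else genotype_row[subset]
  n_aa <- sum(g == "AA"); n_ab <- sum(g == "AB"); n_bb <- sum(g == "BB")
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  f_b <- (2 * n_bb + n_ab) / (2 * n)
  min(f_b, 1 - f_b)
}

#' Per-SNP QC records for a panel
#'
#' Computes call rate, GenCall50, overall and per-species assayed MAF,
#' and the reliable / polymorphic classification for every SNP. A SNP is
#' reliable when GenCall50 >= 0.40, call rate >= 0.95 and (where a
#' GenTrain score is present) GenTrain >= 0.40; polymorphic when its
#' overall MAF reaches `maf_threshold` (0.05 by default; 0.01 gives the
#' less conservative estimate).
#'
#' @param panel A [genotype_panel()].
#' @param maf_threshold MAF bar for the polymorphic flag.
#' @param callrate_cutoff Per-datapoint GenCall cutoff for the call
#'   rate.
#' @param min_gc50,min_callrate,min_gentrain Reliability thresholds.
#' @return `data.frame` with one row per SNP: `snp_id`, `call_rate`,
#'   `gc50`, `gentrain`, `adt`, `maf_overall`, one `maf_<species>`
#'   column per species, `reliable`, `polymorphic`.
#' @export
snp_qc <- function(panel, maf_threshold = 0.05, callrate_cutoff = 0.25,
                   min_gc50 = 0.40, min_callrate = 0.95,
                   min_gentrain = 0.40) {
  stopifnot(inherits(panel, "GenotypePanel"))
  cr <- apply(panel$gencall, 1L, call_rate, cutoff = callrate_cutoff)
  g50 <- apply(panel$gencall, 1L, gc50)
  maf_all <- apply(panel$genotypes, 1L, assayed_maf)
  out <- data.frame(snp_id = panel$snp_ids, call_rate = cr, gc50 = g50,
                    gentrain = unname(panel$gentrain),
                    adt = unname(panel$adt),
                    maf_overall = maf_all,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (sp in unique(panel$samples$species)) {
    sel <- panel$samples$species == sp
    out[[paste0("maf_", sp)]] <-
      apply(panel$genotypes, 1L, assayed_maf, subset = sel)
  }
  out$reliable <- !is.na(g50) & g50 >= min_gc50 & cr >= min_callrate &
    (is.na(out$gentrain) | out$gentrain >= min_gentrain)
  out$polymorphic <- !is.na(maf_all) & maf_all >= maf_threshold
  out
}

#' Panel conversion rate
#'
#' Proportion of SNPs that are polymorphic (MAF at or above the
#' threshold), over all SNPs or over the reliable subset only.
#'
#' @param records Output of [snp_qc()].
#' @param reliable_only Restrict the denominator to reliable SNPs.
#' @param maf_threshold Polymorphism bar, re-applied to `maf_overall`.
#' @return Proportion in `[0, 1]` (`NA` for an empty denominator).
#' @export
conversion_rate <- function(records, reliable_only = TRUE,
                            maf_threshold = 0.05) {
  stopifnot(nrow(records) > 0L)
  den <- if (reliable_only) records[records$reliable, , drop = FALSE]
         else records
  if (nrow(den) == 0L) return(NA_real_)
  mean(!is.na(den$maf_overall) & den$maf_overall >= maf_threshold)
}

#' Shared polymorphism across species subsets
#'
#' For every non-empty subset of the analysed species, counts the
#' reliable SNPs that are simultaneously polymorphic (per-species MAF at
#' or above the threshold) in all species of the subset. Species
#' genotyped in fewer than `min_samples` individuals cannot support a
#' MAF estimate and are dropped with a warning. With five species the
#' table has 31 rows: 5 single-species counts and 26 multi-species
#' combinations.
#'
#' @param panel A [genotype_panel()].
#' @param records Output of [snp_qc()] on the same panel.
#' @param species_list Species to consider (default: all in the panel).
#' @param maf_threshold Per-species polymorphism bar.
#' @param min_samples Minimum individuals per species.
#' @return `data.frame`: `species_set` (`+`-joined labels), `n_species`,
#'   `n_polymorphic`, `pct_of_reliable`.
#' @export
shared_polymorphism_table <- function(panel, records,
                                      species_list = NULL,
                                      maf_threshold = 0.05,
                                      min_samples = 16L) {
  stopifnot(inherits(panel, "GenotypePanel"))
  if (is.null(species_list)) {
    species_list <- unique(panel$samples$species)
  }
  n_by_sp <- table(panel$samples$species)[species_list]
  small <- species_list[is.na(n_by_sp) | n_by_sp < min_samples]
  if (length(small)) {
    warning("species with fewer than ", min_samples,
            " samples excluded: ", paste(small, collapse = ", "),
            call. = FALSE)
    species_list <- setdiff(species_list, small)
  }
  if (length(species_list) == 0L) {
    stop("no species with enough samples", call. = FALSE)
  }
  rel <- records[records$reliable, , drop = FALSE]
  poly <- sapply(species_list, function(sp) {
    m <- rel[[paste0("maf_", sp)]]
    !is.na(m) & m >= maf_threshold
  })
  poly <- matrix(poly, nrow = nrow(rel),
                 dimnames = list(NULL, species_list))
  subsets <- unlist(lapply(seq_along(species_list), function(k)
    utils::combn(species_list, k, simplify = FALSE)), recursive = FALSE)
  data.frame(
    species_set = vapply(subsets, paste, "", collapse = "+"),
    n_species = lengths(subsets),
    n_polymorphic = vapply(subsets, function(s)
      sum(rowSums(poly[, s, drop = FALSE]) == length(s)), integer(1L)),
    pct_of_reliable = vapply(subsets, function(s)
      100 * mean(rowSums(poly[, s, drop = FALSE]) == length(s)),
      numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-species transferability summary
#'
#' For each species sub-panel (with its section and subgenus) and each
#' SNP group, counts the SNPs whose within-species call rate reaches
#' 0.95 and whose within-species GenCall50 reaches 0.40 -- the summary
#' used to judge how well assays designed in one species transfer to
#' relatives.
#'
#' @param panel A [genotype_panel()].
#' @param snp_grouping Character vector assigning each SNP to exactly
#'   one group (for example flank-constrained versus unconstrained
#'   designs); default a single group.
#' @param min_callrate,min_gc50 Transferability thresholds.
#' @return `data.frame`: one row per (subgenus, section, species,
#'   group) with sample and SNP counts and percentages.
#' @export
transferability_summary <- function(panel, snp_grouping = NULL,
                                    min_callrate = 0.95,
                                    min_gc50 = 0.40) {
  stopifnot(inherits(panel, "GenotypePanel"))
  n_snp <- length(panel$snp_ids)
  if (is.null(snp_grouping)) snp_grouping <- rep("all", n_snp)
  stopifnot(length(snp_grouping) == n_snp)
  sp_tab <- unique(panel$samples[c("subgenus", "section", "species")])
  rows <- list()
  for (i in seq_len(nrow(sp_tab))) {
    sp <- sp_tab$species[i]
    sel <- panel$samples$species == sp
    cr <- apply(panel$gencall[, sel, drop = FALSE], 1L, call_rate)
    g50 <- apply(panel$gencall[, sel, drop = FALSE], 1L, gc50)
    for (grp in unique(snp_grouping)) {
      snp_sel <- snp_grouping == grp
      n <- sum(snp_sel)
      rows[[length(rows) + 1L]] <- data.frame(
        subgenus = sp_tab$subgenus[i], section = sp_tab$section[i],
        species = sp, group = grp, n_samples = sum(sel), n_snps = n,
        n_callrate = sum(cr[snp_sel] >= min_callrate),
        pct_callrate = if (n > 0L)
          100 * mean(cr[snp_sel] >= min_callrate) else NA_real_,
        n_gc50 = sum(!is.na(g50[snp_sel]) & g50[snp_sel] >= min_gc50),
        pct_gc50 = if (n > 0L)
          100 * mean(!is.na(g50[snp_sel]) & g50[snp_sel] >= min_gc50)
          else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Concordance of the two in-silico SNP callers with assay polymorphism
#'
#' Among reliable SNPs, cross-tabulates whether a SNP was also tagged by
#' the neighbourhood-quality caller against whether it proved
#' polymorphic in the assay, and tests independence with the Pearson
#' chi-square (no continuity correction). Reports the conversion rate
#' within each caller class. With a degenerate margin the statistic is
#' undefined and returned as `NA` with a note.
#'
#' @param records Output of [snp_qc()].
#' @param tagged_flags Logical vector aligned with `records`: tagged by
#'   the second caller.
#' @param maf_threshold Polymorphism bar.
#' @return List: `table` (2 x 2 counts), `chi_square`, `p_value`,
#'   `conversion_tagged`, `conversion_untagged`, `note`.
#' @export
caller_concordance <- function(records, tagged_flags,
                               maf_threshold = 0.05) {
  stopifnot(nrow(records) == length(tagged_flags))
  rel <- records$reliable
  tg <- tagged_flags[rel]
  poly <- !is.na(records$maf_overall[rel]) &
    records$maf_overall[rel] >= maf_threshold
  tab <- matrix(c(sum(tg & poly), sum(tg & !poly),
                  sum(!tg & poly), sum(!tg & !poly)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(caller = c("tagged", "untagged"),
                                assay = c("polymorphic", "monomorphic")))
  chi <- pearson_chi2_2x2(tab)
  list(table = tab, chi_square = chi$statistic, p_value = chi$p_value,
       conversion_tagged = if (sum(tg) > 0L) mean(poly[tg]) else NA_real_,
       conversion_untagged = if (sum(!tg) > 0L) mean(poly[!tg])
                             else NA_real_,
       note = chi$note)
}
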