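# Marker validation on two independent lines of evidence: Mendelian
# transmission in parent-parent-offspring trios, and exact-binomial
# comparison of assay genotypes with shotgun read counts.

GT_ALPHABET <- c("AA", "AB", "BB", "NC")

.gt_alleles <- function(g) c(substr(g, 1L, 1L), substr(g, 2L, 2L))

#' Mendelian consistency of one trio at one SNP
#'
#' Each complete trio contributes two allelic transmissions (one per
#' parental slot). The child's two alleles are assigned to the parents
#' in whichever of the two orderings yields the fewest violations; a
#' slot is inconsistent when its assigned allele is absent from that
#' parent's genotype. A trio with any no-call contributes nothing.
#'
#' @param father_gt,mother_gt,child_gt Genotypes over
#'   `{AA, AB, BB, NC}`.
#' @return Integer vector `c(n_assessed, n_inconsistent)` -- `(2, k)`
#'   for a complete trio, `(0, 0)` otherwise.
#' @export
trio_consistency <- function(father_gt, mother_gt, child_gt) {
  gts <- c(father_gt, mother_gt, child_gt)
  if (!all(gts %in% GT_ALPHABET)) {
    stop("invalid genotype token: ",
         paste(setdiff(gts, GT_ALPHABET), collapse = ", "),
         call. = FALSE)
  }
  if (any(gts == "NC")) {
    return(c(n_assessed = 0L, n_inconsistent = 0L))
  }
  f <- .gt_alleles(father_gt); m <- .gt_alleles(mother_gt)
  ch <- .gt_alleles(child_gt)
  bad1 <- sum(!(ch[1L] %in% f), !(ch[2L] %in% m))
  bad2 <- sum(!(ch[2L] %in% f), !(ch[1L] %in% m))
  c(n_assessed = 2L, n_inconsistent = as.integer(min(bad1, bad2)))
}

#' Trio-based heritability of allelic transmission
#'
#' Sums [trio_consistency()] over every (SNP, trio) record. Heritability
#' per SNP is the fraction of its assessed transmissions consistent with
#' Mendelian inheritance; the panel-level miscall rate is the complement
#' over all transmissions. Also reports how many SNPs show full
#' heritability and in how few SNPs 80% of the miscalls concentrate.
#'
#' @param trios Data frame with columns `snp_id`, `trio_id`, `father`,
#'   `mother`, `child` (as from [simulate_trios()] or [read_trios()]).
#' @param concentration_fraction Fraction for
#'   [miscall_concentration()].
#' @return A `TrioSummary` list: `n_transmissions_assessed`,
#'   `n_inconsistent`, `miscall_rate`, `per_snp` (data.frame with
#'   heritability per SNP), `n_snps_full_heritability`,
#'   `concentration_k`.
#' @export
trio_heritability <- function(trios, concentration_fraction = 0.8) {
  stopifnot(is.data.frame(trios), nrow(trios) > 0L)
  # vectorised over rows; the per-trio function stays the oracle-checked
  # reference path
  complete <- trios$father != "NC" & trios$mother != "NC" &
    trios$child != "NC"
  bad_tok <- !(trios$father %in% GT_ALPHABET &
                 trios$mother %in% GT_ALPHABET &
                 trios$child %in% GT_ALPHABET)
  if (any(bad_tok)) stop("invalid genotype token in trio table",
                         call. = FALSE)
  inc <- integer(nrow(trios))
  if (any(complete)) {
    f1 <- substr(trios$father, 1L, 1L); f2 <- substr(trios$father, 2L, 2L)
    m1 <- substr(trios$mother, 1L, 1L); m2 <- substr(trios$mother, 2L, 2L)
    c1 <- substr(trios$child, 1L, 1L); c2 <- substr(trios$child, 2L, 2L)
    in_par <- function(a, p1, p2) a == p1 | a == p2
    bad1 <- (!in_par(c1, f1, f2)) + (!in_par(c2, m1, m2))
    bad2 <- (!in_par(c2, f1, f2)) + (!in_par(c1, m1, m2))
    inc[complete] <- pmin(bad1, bad2)[complete]
  }
  assessed <- ifelse(complete, 2L, 0L)
  per_snp <- data.frame(
    snp_id = sort(unique(trios$snp_id)), stringsAsFactors = FALSE)
  agg_a <- tapply(assessed, trios$snp_id, sum)
  agg_i <- tapply(inc, trios$snp_id, sum)
  per_snp$n_assessed <- as.integer(agg_a[per_snp$snp_id])
  per_snp$n_inconsistent <- as.integer(agg_i[per_snp$snp_id])
  per_snp$heritability <- ifelse(per_snp$n_assessed > 0L,
                                 1 - per_snp$n_inconsistent /
                                   per_snp$n_assessed, NA_real_)
  total_a <- sum(assessed); total_i <- sum(inc)
  structure(
    list(n_transmissions_assessed = total_a,
         n_inconsistent = as.integer(total_i),
         miscall_rate = if (total_a > 0L) total_i / total_a else NA_real_,
         per_snp = per_snp,
         n_snps_full_heritability = sum(per_snp$n_assessed > 0L &
                                          per_snp$n_inconsistent == 0L),
         concentration_k = miscall_concentration(
           setNames(per_snp$n_inconsistent, per_snp$snp_id),
           fraction = concentration_fraction)),
    class = "TrioSummary")
}

#' @export
print.TrioSummary <- function(x, ...) {
  cat("TrioSummary: ", x$n_inconsistent, " inconsistencies / ",
      x$n_transmissions_assessed, " transmissions (miscall rate ",
      sprintf("%.2f%%", 100 * x$miscall_rate), ")\n",
      x$n_snps_full_heritability, " SNP(s) with full heritability; 80% ",
      "of miscalls in ", x$concentration_k, " SNP(s)\n", sep = "")
  invisible(x)
}

#' Concentration of inheritance miscalls
#'
#' Smallest number `k` of SNPs whose combined inconsistency counts reach
#' the given fraction of all inconsistencies, ranking SNPs by count
#' (ties broken by SNP id for determinism). Zero when there are no
#' miscalls.
#'
#' @param per_snp_inconsistencies Named integer vector of inconsistency
#'   counts per SNP.
#' @param fraction Target fraction in `(0, 1]`.
#' @return Integer `k`.
#' @export
miscall_concentration <- function(per_snp_inconsistencies,
                                  fraction = 0.8) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  x <- per_snp_inconsistencies
  total <- sum(x)
  if (total == 0L) return(0L)
  ids <- names(x) %||% as.character(seq_along(x))
  ord <- order(-x, ids)
  unname(which(cumsum(x[ord]) >= fraction * total)[1L])
}

#' Sequence-based genotype call from allele read counts
#'
#' Declares a genotype from shotgun read counts at an assayed SNP with a
#' two-sided exact binomial test of the 1:1 read ratio expected from a
#' heterozygote. Sites with fewer than `min_depth` reads over the two
#' assay alleles are not called (five reads give probability 0.9375 of
#' observing both alleles of a heterozygote). A rejected null
#' (`p < alpha`, default 0.1 to favour power at the low depths
#' available) declares a homozygote for the majority allele; otherwise a
#' heterozygote is declared.
#'
#' @param ref_count,alt_count Reads carrying each assay allele.
#' @param alpha Rejection level (strictly-less-than boundary).
#' @param min_depth Minimum `ref_count + alt_count` to call.
#' @return List: `depth`, `depth_pass`, `p_value` (`NA` below depth),
#'   `seq_genotype` (`"hom"`, `"het"` or `"no_call"`), `majority`
#'   (`"A"`, `"B"` or `NA`).
#' @export
seq_genotype_call <- function(ref_count, alt_count, alpha = 0.1,
                              min_depth = 5L) {
  stopifnot(ref_count >= 0L, alt_count >= 0L)
  depth <- ref_count + alt_count
  if (depth < min_depth) {
    return(list(depth = depth, depth_pass = FALSE, p_value = NA_real_,
                seq_genotype = "no_call", majority = NA_character_))
  }
  p <- exact_binomial_two_sided(min(ref_count, alt_count), depth)
  gt <- if (p < alpha) "hom" else "het"
  majority <- if (ref_count > alt_count) "A"
              else if (alt_count > ref_count) "B" else NA_character_
  list(depth = depth, depth_pass = TRUE, p_value = p,
       seq_genotype = gt, majority = majority)
}

#' Validate assay genotypes against shotgun counts
#'
#' Runs [seq_genotype_call()] over a count table and compares the
#' sequence-based genotypes with the assay calls. Concordant means a
#' heterozygote call against `AB`, or a homozygote call whose majority
#' allele matches the assay homozygote. Records without a sequence call
#' (insufficient depth) or without an assay call (`NC`) are excluded
#' from the concordance denominator.
#'
#' @param counts Data frame with `snp_id`, `ref_count`, `alt_count` (and
#'   optionally `other_count`).
#' @param gggt_genotypes Named character vector of assay genotypes over
#'   `{AA, AB, BB, NC}`, indexed by `snp_id`.
#' @param alpha,min_depth Passed to [seq_genotype_call()].
#' @return List: `records` (one row per SNP with the test results and
#'   `concordant` flag), `n_compared`, `n_concordant`,
#'   `fraction_concordant` (`NA` for an empty denominator), `divergent`
#'   (subset of records with a direction label).
#' @export
concordance_summary <- function(counts, gggt_genotypes, alpha = 0.1,
                                min_depth = 5L) {
  stopifnot(is.data.frame(counts),
            all(c("snp_id", "ref_count", "alt_count") %in% names(counts)))
  recs <- lapply(seq_len(nrow(counts)), function(i) {
    r <- seq_genotype_call(counts$ref_count[i], counts$alt_count[i],
                           alpha = alpha, min_depth = min_depth)
    data.frame(snp_id = counts$snp_id[i],
               ref_count = counts$ref_count[i],
               alt_count = counts$alt_count[i],
               other_count = counts$other_count[i] %||% NA_integer_,
               depth_pass = r$depth_pass, p_value = r$p_value,
               seq_genotype = r$seq_genotype, majority = r$majority,
               stringsAsFactors = FALSE)
  })
  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(snp_id = character(), ref_count = integer(),
               alt_count = integer(), other_count = integer(),
               depth_pass = logical(), p_value = numeric(),
               seq_genotype = character(), majority = character(),
               stringsAsFactors = FALSE)
  recs$gggt_genotype <- unname(gggt_genotypes[recs$snp_id])
  assay_called <- !is.na(recs$gggt_genotype) & recs$gggt_genotype != "NC"
  comparable <- recs$seq_genotype != "no_call" & assay_called
  hom_match <- recs$seq_genotype == "hom" &
    ((recs$majority == "A" & recs$gggt_genotype == "AA") |
       (recs$majority == "B" & recs$gggt_genotype == "BB"))
  het_match <- recs$seq_genotype == "het" & recs$gggt_genotype == "AB"
  recs$concordant <- ifelse(comparable, hom_match | het_match, NA)
  div <- recs[comparable & !(hom_match | het_match), , drop = FALSE]
  if (nrow(div)) {
    div$direction <- ifelse(
      div$seq_genotype == "het" & div$gggt_genotype != "AB",
      "hom_by_assay_het_by_seq",
      ifelse(div$seq_genotype == "hom" & div$gggt_genotype == "AB",
             "het_by_assay_hom_by_seq", "opposite_homozygotes"))
  } else div$direction <- character(0)
  n_cmp <- sum(comparable)
  list(records = recs, n_compared = n_cmp,
       n_concordant = sum(recs$concordant, na.rm = TRUE),
       fraction_concordant = if (n_cmp > 0L)
         sum(recs$concordant, na.rm = TRUE) / n_cmp else NA_real_,
       divergent = div)
}
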