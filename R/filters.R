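# The sequential in-silico selection cascade applied to candidate SNPs
# ahead of assay design. F0 keeps well-supported biallelic sites with
# design room (60 bases each side); F1 adds the in-silico MAF bar; F2
# demands representation of a phylogenetically distinct taxon group; F3
# and F4 tighten repeat-free and SNP-free flank requirements (oligo
# hybridisation is sensitive to polymorphic or repetitive flanks). The
# relaxed candidate-gene (CG) rule keeps any biallelic site with two
# alternative reads. A site whose 30-base flanks straddle an exon
# boundary is excluded at every level: assays designed across an
# intron/exon junction fail on genomic DNA.

#' Filter-cascade configuration
#'
#' Thresholds for [apply_filters()] and the SNP-block tagging defaults
#' used by [discover_snps()]. Defaults encode the published cascade:
#' depth 5, one alternative read at F0, in-silico MAF 0.2 at F1, 100
#' repeat-free bases and 20 SNP-free bases per side at F3, 60 SNP-free
#' bases at F4, 60 available bases per side throughout, and 30-base
#' same-exon flanks.
#'
#' @param min_depth Minimum reads covering the SNP column.
#' @param min_alt_reads_f0 Minimum minor-allele reads at F0.
#' @param min_insilico_maf Minor allele frequency bar at F1.
#' @param required_taxa Taxa of which at least one read is required at
#'   F2; empty means F2 adds no constraint.
#' @param repeatfree_span Repeat-free bases required each side at F3+.
#' @param clean_flank_f3,clean_flank_f4 SNP-free bases required each
#'   side at F3 and F4 (`clean_flank_f4 >= clean_flank_f3`).
#' @param flank_available Contig bases required each side for oligo
#'   design.
#' @param exon_flank Bases each side that must lie in one exon.
#' @param cg_min_alt_reads Minimum minor-allele reads under the relaxed
#'   candidate-gene rule.
#' @param neighbor_snp_definition What counts as an "additional SNP" in
#'   a flank: other candidates at the posterior cutoff
#'   (`"posterior_cutoff"`, default) or any column with two or more
#'   minor reads (`"any_minor_ge2"`).
#' @param tag_window,tag_min_minor_reads,tag_min_group_score SNP-block
#'   tagging parameters passed to [mira_tag()].
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 5L, min_alt_reads_f0 = 1L,
                          min_insilico_maf = 0.2,
                          required_taxa = character(),
                          repeatfree_span = 100L,
                          clean_flank_f3 = 20L, clean_flank_f4 = 60L,
                          flank_available = 60L, exon_flank = 30L,
                          cg_min_alt_reads = 2L,
                          neighbor_snp_definition = c("posterior_cutoff",
                                                      "any_minor_ge2"),
                          tag_window = 7L, tag_min_minor_reads = 2L,
                          tag_min_group_score = 40) {
  neighbor_snp_definition <- match.arg(neighbor_snp_definition)
  if (clean_flank_f4 < clean_flank_f3) {
    stop("clean_flank_f4 must be >= clean_flank_f3", call. = FALSE)
  }
  cfg <- list(min_depth = min_depth, min_alt_reads_f0 = min_alt_reads_f0,
              min_insilico_maf = min_insilico_maf,
              required_taxa = required_taxa,
              repeatfree_span = repeatfree_span,
              clean_flank_f3 = clean_flank_f3,
              clean_flank_f4 = clean_flank_f4,
              flank_available = flank_available, exon_flank = exon_flank,
              cg_min_alt_reads = cg_min_alt_reads,
              neighbor_snp_definition = neighbor_snp_definition,
              tag_window = tag_window,
              tag_min_minor_reads = tag_min_minor_reads,
              tag_min_group_score = tag_min_group_score)
  if (any(vapply(cfg[c(1:3, 5:10)], function(x) any(x < 0),
                 logical(1L)))) {
    stop("filter thresholds must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

#' In-silico minor allele frequency of a column
#'
#' Minor-allele reads over A/C/G/T depth. When more than two bases are
#' observed the frequency is computed over the two most frequent only
#' (such columns fail the biallelic rule regardless).
#'
#' @param profile An [column_profile()] result with `depth >= 1`.
#' @return Frequency in `[0, 0.5]`.
#' @export
in_silico_maf <- function(profile) {
  stopifnot(inherits(profile, "AlleleProfile"))
  if (profile$depth < 1L) stop("depth 0 column", call. = FALSE)
  k <- length(profile$counts)
  if (k < 2L) return(0)
  if (k == 2L) return(profile$minor_count / profile$depth)
  profile$counts[[2L]] / (profile$counts[[1L]] + profile$counts[[2L]])
}

#' SNP-free flank lengths around a candidate
#'
#' Number of consecutive bases immediately left and right of `position`
#' that contain no other SNP from `neighbor_positions`, capped at the
#' contig edges.
#'
#' @param position 0-based candidate position.
#' @param neighbor_positions 0-based positions counted as SNPs
#'   (`position` itself is ignored).
#' @param contig_length Contig length in bases.
#' @return Integer vector `c(left, right)`.
#' @export
clean_flank <- function(position, neighbor_positions, contig_length) {
  nb <- setdiff(as.integer(neighbor_positions), as.integer(position))
  left_nb <- nb[nb < position]
  right_nb <- nb[nb > position]
  c(left = if (length(left_nb)) position - max(left_nb) - 1L
           else as.integer(position),
    right = if (length(right_nb)) min(right_nb) - as.integer(position) - 1L
            else as.integer(contig_length - position - 1L))
}

#' Repeat-free flank lengths around a candidate
#'
#' Distance from the candidate to the nearest repeat-masked base on each
#' side, capped at the contig edges; `(0, 0)` when the candidate itself
#' lies in a masked interval.
#'
#' @param position 0-based candidate position.
#' @param repeat_mask Two-column matrix of 0-based half-open masked
#'   intervals (sorted, non-overlapping), or `NULL`.
#' @param contig_length Contig length in bases.
#' @return Integer vector `c(left, right)`.
#' @export
repeatfree_span <- function(position, repeat_mask, contig_length) {
  position <- as.integer(position)
  if (is.null(repeat_mask) || NROW(repeat_mask) == 0L) {
    return(c(left = position,
             right = as.integer(contig_length - position - 1L)))
  }
  s <- repeat_mask[, 1L]; e <- repeat_mask[, 2L]
  if (any(s <= position & position < e)) return(c(left = 0L, right = 0L))
  left_e <- e[e <= position]
  right_s <- s[s > position]
  c(left = if (length(left_e)) position - max(left_e)
           else position,
    right = if (length(right_s)) min(right_s) - position - 1L
            else as.integer(contig_length - position - 1L))
}

#' Same-exon flank check
#'
#' `TRUE` when the candidate and `flank` bases on each side all fall
#' within a single exon of the reference gene model, `FALSE` when an
#' exon boundary intrudes, and `NA` (indeterminate -- the candidate is
#' not excluded) when no exon map is available.
#'
#' @param position 0-based candidate position.
#' @param exon_map `data.frame` with half-open `start`/`end` columns, or
#'   `NULL`.
#' @param flank Required bases on each side (default 30).
#' @return Logical scalar, possibly `NA`.
#' @export
same_exon_check <- function(position, exon_map, flank = 30L) {
  if (is.null(exon_map) || nrow(exon_map) == 0L) return(NA)
  any(exon_map$start <= position - flank &
        exon_map$end >= position + flank + 1L)
}

#' Apply the sequential filter cascade
#'
#' Populates logical columns `F0`..`F4` and `CG` on a candidate table
#' from [discover_snps()] and tabulates the selection funnel. The levels
#' nest by construction: every F4 SNP passes F3, and so on down to F0.
#' Candidates whose flanks straddle an exon boundary
#' (`same_exon == FALSE`) are excluded at every level; an absent exon
#' map (`NA`) excludes nothing.
#'
#' @param candidates Candidate table from [discover_snps()].
#' @param config A [filter_config()].
#' @return List with `candidates` (input plus filter columns) and
#'   `funnel` (per-level SNP and contig counts).
#' @export
apply_filters <- function(candidates, config = filter_config()) {
  stopifnot(is.data.frame(candidates))
  cd <- candidates
  n <- nrow(cd)
  if (n == 0L) {
    cd[c("F0", "F1", "F2", "F3", "F4", "CG")] <- logical(0)
    return(list(candidates = cd, funnel = .funnel(cd)))
  }
  exon_ok <- is.na(cd$same_exon) | cd$same_exon
  biallelic <- cd$n_alleles == 2L
  flank_ok <- cd$flank_avail_left >= config$flank_available &
    cd$flank_avail_right >= config$flank_available
  taxa_ok <- if (length(config$required_taxa) == 0L) rep(TRUE, n) else
    vapply(strsplit(cd$taxa, ",", fixed = TRUE),
           function(tx) length(intersect(tx, config$required_taxa)) > 0L,
           logical(1L))
  cd$F0 <- exon_ok & biallelic & flank_ok &
    cd$depth >= config$min_depth &
    cd$minor_count >= config$min_alt_reads_f0
  cd$F1 <- cd$F0 & cd$insilico_maf >= config$min_insilico_maf
  cd$F2 <- cd$F1 & taxa_ok
  cd$F3 <- cd$F2 &
    cd$repeatfree_left >= config$repeatfree_span &
    cd$repeatfree_right >= config$repeatfree_span &
    cd$clean_flank_left >= config$clean_flank_f3 &
    cd$clean_flank_right >= config$clean_flank_f3
  cd$F4 <- cd$F3 &
    cd$clean_flank_left >= config$clean_flank_f4 &
    cd$clean_flank_right >= config$clean_flank_f4
  cd$CG <- exon_ok & biallelic & flank_ok &
    cd$minor_count >= config$cg_min_alt_reads
  list(candidates = cd, funnel = .funnel(cd))
}

.funnel <- function(cd) {
  levels <- c("F0", "F1", "F2", "F3", "F4", "CG")
  data.frame(
    level = levels,
    n_snps = vapply(levels, function(l) sum(cd[[l]]), integer(1L)),
    n_contigs = vapply(levels, function(l)
      length(unique(cd$contig_id[cd[[l]]])), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' ADT design-score summary and selection
#'
#' Tabulates, per filter level, how many candidates reach each assay
#' design-tool score threshold (0.6 is the conventional bar for a likely
#' successful assay; 0.8 the stringent selection bar; 0.9 near-certain).
#' Candidates without a score are dropped from the denominator with a
#' warning.
#'
#' @param adt_scores Numeric ADT scores in `[0, 1]` (`NA` allowed).
#' @param levels Optional filter-level label per candidate; default one
#'   pooled `"ALL"` group.
#' @param thresholds Score thresholds to tabulate.
#' @return `data.frame` with one row per level: `n`, then `n_ge_<t>` and
#'   `prop_ge_<t>` per threshold.
#' @export
adt_summary <- function(adt_scores, levels = NULL,
                        thresholds = c(0.6, 0.8, 0.9)) {
  if (is.null(levels)) levels <- rep("ALL", length(adt_scores))
  stopifnot(length(levels) == length(adt_scores))
  keep <- !is.na(adt_scores)
  if (any(!keep)) {
    warning(sum(!keep), " candidate(s) without ADT score excluded",
            call. = FALSE)
  }
  adt_scores <- adt_scores[keep]
  levels <- levels[keep]
  lv <- unique(levels)
  out <- data.frame(level = lv,
                    n = vapply(lv, function(l) sum(levels == l),
                               integer(1L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (t in thresholds) {
    ge <- vapply(lv, function(l) sum(adt_scores[levels == l] >= t),
                 integer(1L))
    out[[sprintf("n_ge_%g", t)]] <- ge
    out[[sprintf("prop_ge_%g", t)]] <- ifelse(out$n > 0, ge / out$n, NA)
  }
  out
}

#' @rdname adt_summary
#' @param candidates Candidate table with an `adt_score` column.
#' @param min_adt Selection bar (default 0.8).
#' @return `adt_select()`: the rows with `adt_score >= min_adt`.
#' @export
adt_select <- function(candidates, min_adt = 0.8) {
  stopifnot(is.data.frame(candidates), "adt_score" %in% names(candidates))
  candidates[!is.na(candidates$adt_score) &
               candidates$adt_score >= min_adt, , drop = FALSE]
}
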