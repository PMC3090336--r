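# Per-column allele profiling, the Bayesian two-hypothesis polymorphism
# posterior, and neighbourhood-quality ("SNP block") tagging.

.read_len <- function(r) nchar(r$bases)

.obs_table <- function(alignment) {
  # long-format pileup: one row per aligned base
  reads <- alignment$reads
  if (!length(reads)) {
    return(data.frame(pos = integer(), base = character(),
                      qual = integer(), read_id = character(),
                      taxon = character(), read = integer(),
                      stringsAsFactors = FALSE))
  }
  lens <- vapply(reads, .read_len, integer(1L))
  data.frame(
    pos = unlist(lapply(reads, function(r)
      seq.int(r$start, length.out = .read_len(r)))),
    base = unlist(lapply(reads, function(r)
      strsplit(r$bases, "", fixed = TRUE)[[1L]])),
    qual = unlist(lapply(reads, `[[`, "quals")),
    read_id = rep(vapply(reads, `[[`, "", "read_id"), lens),
    taxon = rep(vapply(reads, `[[`, "", "taxon"), lens),
    read = rep(seq_along(reads), lens),
    stringsAsFactors = FALSE)
}

.profile_from_obs <- function(obs, contig_id, position) {
  acgt <- obs$base %in% BASES
  tab <- table(factor(obs$base[acgt], levels = BASES))
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[counts > 0L]
  counts <- counts[order(-counts, names(counts))]
  structure(
    list(contig_id = contig_id, position = position,
         observations = data.frame(base = obs$base[acgt],
                                   phred = obs$qual[acgt],
                                   read_id = obs$read_id[acgt],
                                   taxon = obs$taxon[acgt],
                                   stringsAsFactors = FALSE),
         n_excluded = sum(!acgt),
         counts = counts, depth = sum(counts),
         major_allele = if (length(counts)) names(counts)[1L]
                        else NA_character_,
         minor_allele = if (length(counts) >= 2L) names(counts)[2L]
                        else NA_character_,
         minor_count = if (length(counts) >= 2L) counts[[2L]] else 0L),
    class = "AlleleProfile")
}

#' Allele profile of one alignment column
#'
#' Tallies the aligned bases covering a position. Gaps (`-`) and `N` are
#' recorded (`n_excluded`) but excluded from allele counts, so `depth`
#' counts A/C/G/T observations only. The major allele is the most
#' frequent base and the minor allele the second most frequent; ties are
#' broken lexicographically for determinism.
#'
#' @param alignment A [contig_alignment()].
#' @param position 0-based column index in `[0, length)`.
#' @return An `AlleleProfile`: observation table, per-base `counts`
#'   (decreasing), `depth`, `major_allele`, `minor_allele`,
#'   `minor_count`, `n_excluded`.
#' @export
column_profile <- function(alignment, position) {
  stopifnot(inherits(alignment, "ContigAlignment"))
  if (position < 0L || position >= alignment$length) {
    stop("position ", position, " outside [0, ", alignment$length, ")",
         call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(alignment$reads)) {
    r <- alignment$reads[[i]]
    off <- position - r$start
    if (off >= 0L && off < .read_len(r)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pos = position, base = substr(r$bases, off + 1L, off + 1L),
        qual = r$quals[off + 1L], read_id = r$read_id, taxon = r$taxon,
        read = i, stringsAsFactors = FALSE)
    }
  }
  obs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(), base = character(), qual = integer(),
               read_id = character(), taxon = character(),
               read = integer(), stringsAsFactors = FALSE)
  .profile_from_obs(obs, alignment$contig_id, position)
}

#' Bayesian polymorphism posterior for one column
#'
#' Two-hypothesis mixture model over the base calls at a column. Each
#' observation `b_i` with Phred `q_i` has error probability
#' `e_i = 10^(-q_i/10)` and likelihood `f(b | a) = 1 - e_i` when
#' `b == a`, else `e_i / 3`. The monomorphic likelihood maximises
#' `prod f(b_i | a)` over the four bases; the polymorphic likelihood
#' averages the two most frequent observed bases,
#' `prod_i (f(b_i|a1) + f(b_i|a2)) / 2`. The posterior is
#' `prior * L_poly / (prior * L_poly + (1 - prior) * L_mono)`. Columns
#' with fewer than two distinct observed bases return 0. The default
#' prior 0.01 encodes an expected density of one SNP per hundred bases.
#'
#' @param profile An [column_profile()] result with `depth >= 1`.
#' @param prior Prior probability that a column is polymorphic.
#' @return Posterior probability in `[0, 1]`.
#' @export
polybayes_posterior <- function(profile, prior = 0.01) {
  stopifnot(inherits(profile, "AlleleProfile"))
  if (profile$depth < 1L) stop("empty profile", call. = FALSE)
  if (prior <= 0) return(0)
  if (length(profile$counts) < 2L) return(0)
  b <- profile$observations$base
  e <- 10^(-profile$observations$phred / 10)
  log_lik <- function(a) sum(log(ifelse(b == a, 1 - e, e / 3)))
  l_mono <- max(vapply(BASES, log_lik, numeric(1L)))
  a1 <- profile$major_allele; a2 <- profile$minor_allele
  l_poly <- sum(log((ifelse(b == a1, 1 - e, e / 3) +
                       ifelse(b == a2, 1 - e, e / 3)) / 2))
  # posterior on the log scale to survive deep columns
  1 / (1 + (1 - prior) / prior * exp(l_mono - l_poly))
}

.window_min_quals <- function(alignment, position, window) {
  half <- (window - 1L) %/% 2L
  out <- list()
  for (r in alignment$reads) {
    off <- position - r$start
    len <- .read_len(r)
    if (off < 0L || off >= len) next
    lo <- max(0L, off - half); hi <- min(len - 1L, off + half)
    out[[length(out) + 1L]] <- list(
      base = substr(r$bases, off + 1L, off + 1L),
      wmin = min(r$quals[(lo + 1L):(hi + 1L)]))
  }
  out
}

#' Neighbourhood-quality SNP tagging
#'
#' Scores each allele at a column by the summed quality of its
#' supporting reads over a small window (the "SNP block"): each
#' supporting read contributes the minimum Phred value within `window`
#' bases centred on the column, clipped to the read's extent. The column
#' is tagged as a SNP hint when the minor allele is seen in at least
#' `min_minor_reads` reads and both group scores reach
#' `min_group_score`. The default threshold of 40 corresponds to two
#' clean Q20 reads; with `min_minor_reads = 1` a single high-quality
#' discrepancy suffices, reflecting that one confident base in an
#' otherwise clean neighbourhood already hints at a SNP.
#'
#' @param alignment A [contig_alignment()].
#' @param position 0-based column index.
#' @param window Odd window width in bases.
#' @param min_minor_reads Minimum reads carrying the minor allele.
#' @param min_group_score Minimum summed window-minimum quality for each
#'   allele group.
#' @return List: `tagged` (logical), `major_score`, `minor_score`.
#' @export
mira_tag <- function(alignment, position, window = 7L,
                     min_minor_reads = 2L, min_group_score = 40) {
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  prof <- column_profile(alignment, position)
  wm <- .window_min_quals(alignment, position, window)
  score_for <- function(allele) {
    if (is.na(allele)) return(0)
    sum(vapply(wm, function(x) if (x$base == allele) x$wmin else 0,
               numeric(1L)))
  }
  major_score <- score_for(prof$major_allele)
  minor_score <- score_for(prof$minor_allele)
  list(tagged = prof$minor_count >= min_minor_reads &&
         minor_score >= min_group_score && major_score >= min_group_score,
       major_score = major_score, minor_score = minor_score)
}

#' Discover candidate SNPs on contig alignments
#'
#' Scores every column of each contig with [polybayes_posterior()] and
#' returns the columns at or above the posterior cutoff as candidate
#' SNPs, annotated with their allele profile, tagging scores, taxa
#' present among the reads, and the flank statistics the downstream
#' filter cascade consumes. Contigs with fewer than
#' `min_reads_per_contig` reads are skipped entirely (shallow contigs
#' cannot support the depth-based filters and inflate false calls).
#'
#' @param alignments A [contig_alignment()] or list of them.
#' @param prior,cutoff Posterior prior and selection cutoff (defaults
#'   0.01 and 0.99).
#' @param min_reads_per_contig Minimum reads for a contig to be
#'   considered (default 5).
#' @param config A [filter_config()]; sets the neighbour-SNP definition
#'   used for clean-flank distances and the tagging parameters.
#' @return `data.frame` of candidate SNPs, one row per site, with
#'   0-based `position`; see [apply_filters()] for the filter columns
#'   added downstream.
#' @export
discover_snps <- function(alignments, prior = 0.01, cutoff = 0.99,
                          min_reads_per_contig = 5L,
                          config = filter_config()) {
  if (inherits(alignments, "ContigAlignment")) {
    alignments <- list(alignments)
  }
  out <- lapply(alignments, .discover_one, prior = prior,
                cutoff = cutoff,
                min_reads_per_contig = min_reads_per_contig,
                config = config)
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_candidates()
  rownames(res) <- NULL
  res
}

.empty_candidates <- function() {
  data.frame(contig_id = character(), position = integer(),
             major_allele = character(), minor_allele = character(),
             depth = integer(), minor_count = integer(),
             n_alleles = integer(),
             insilico_maf = numeric(), posterior = numeric(),
             mira_tagged = logical(), major_score = numeric(),
             minor_score = numeric(), taxa = character(),
             n_taxa = integer(),
             clean_flank_left = integer(), clean_flank_right = integer(),
             repeatfree_left = integer(), repeatfree_right = integer(),
             flank_avail_left = integer(), flank_avail_right = integer(),
             same_exon = logical(), adt_score = numeric(),
             stringsAsFactors = FALSE)
}

.discover_one <- function(alignment, prior, cutoff, min_reads_per_contig,
                          config) {
  stopifnot(inherits(alignment, "ContigAlignment"))
  if (length(alignment$reads) < min_reads_per_contig) {
    return(NULL)
  }
  obs <- .obs_table(alignment)
  acgt <- obs[obs$base %in% BASES, , drop = FALSE]
  if (!nrow(acgt)) return(NULL)
  by_pos <- split(seq_len(nrow(acgt)), acgt$pos)
  positions <- as.integer(names(by_pos))
  post <- numeric(length(positions))
  minor2 <- logical(length(positions))
  profs <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    p <- .profile_from_obs(acgt[by_pos[[i]], , drop = FALSE],
                           alignment$contig_id, positions[i])
    profs[[i]] <- p
    post[i] <- polybayes_posterior(p, prior)
    minor2[i] <- p$minor_count >= 2L
  }
  hit <- post >= cutoff
  if (!any(hit)) return(NULL)
  neighbor_pos <- switch(config$neighbor_snp_definition,
    posterior_cutoff = positions[hit],
    any_minor_ge2 = positions[minor2])
  rows <- lapply(which(hit), function(i) {
    p <- profs[[i]]
    pos <- positions[i]
    tag <- mira_tag(alignment, pos, window = config$tag_window,
                    min_minor_reads = config$tag_min_minor_reads,
                    min_group_score = config$tag_min_group_score)
    cf <- clean_flank(pos, neighbor_pos, alignment$length)
    rf <- repeatfree_span(pos, alignment$repeat_mask, alignment$length)
    se <- same_exon_check(pos, alignment$exon_map,
                          flank = config$exon_flank)
    data.frame(
      contig_id = alignment$contig_id, position = pos,
      major_allele = p$major_allele, minor_allele = p$minor_allele,
      depth = p$depth, minor_count = p$minor_count,
      n_alleles = length(p$counts),
      insilico_maf = in_silico_maf(p), posterior = post[i],
      mira_tagged = tag$tagged, major_score = tag$major_score,
      minor_score = tag$minor_score,
      taxa = paste(sort(unique(p$observations$taxon)), collapse = ","),
      n_taxa = length(unique(p$observations$taxon)),
      clean_flank_left = cf[[1L]], clean_flank_right = cf[[2L]],
      repeatfree_left = rf[[1L]], repeatfree_right = rf[[2L]],
      flank_avail_left = pos,
      flank_avail_right = alignment$length - pos - 1L,
      same_exon = se, adt_score = NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
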