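# Synthetic data emulating the structure the pipeline consumes:
# multi-species diploid haplotypes at EST-like SNP density, reads with
# quality-driven substitution errors, GoldenGate-style genotype panels,
# parent-parent-offspring trios with injected transmission miscalls, and
# low-coverage shotgun allele counts. Every generator is a pure function
# of (parameters, seed): the global RNG state is saved and restored.

with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("an explicit seed is required",
                                         call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

BASES <- c("A", "C", "G", "T")

#' Simulate multi-species diploid haplotypes
#'
#' Places polymorphic sites along each contig by a Bernoulli process at
#' `snp_density_per_bp` (default 1/16, the density reported for the most
#' diverse eucalypt species and an upper bound for outbred trees). A
#' fraction of the sites is shared across all species (one common minor
#' allele frequency, emulating polymorphism that pre-dates speciation);
#' the rest are private to one species. Minor allele frequencies are
#' drawn uniformly on `[0.05, 0.5]` per segregating species. Diploid
#' individuals then receive two haplotypes by independent Bernoulli draws
#' from their species' site frequencies.
#'
#' @param n_species Number of species.
#' @param individuals_per_species Diploid individuals simulated per
#'   species.
#' @param contig_length Length of each contig in bases.
#' @param snp_density_per_bp Per-base probability of a polymorphic site,
#'   in `(0, 0.25]`.
#' @param shared_site_fraction Probability that a site segregates in all
#'   species rather than one, in `[0, 1]`.
#' @param n_contigs Number of independent contigs.
#' @param seed Integer seed; the same seed reproduces the object exactly.
#' @return A `SimTruth` list: `sites` (data.frame with `contig_id`,
#'   0-based `position`, `major`, `minor`, and one `freq_<species>`
#'   column per species), `refs` (reference sequence per contig),
#'   `haplotypes` (per individual, two full sequences per contig),
#'   `individuals` (individual/species table), `panel_maf` (site-by-
#'   species true MAF matrix) and `injected_miscalls` (0 here).
#' @export
simulate_haplotypes <- function(n_species, individuals_per_species,
                                contig_length,
                                snp_density_per_bp = 1 / 16,
                                shared_site_fraction = 0.5,
                                n_contigs = 1L, seed) {
  if (contig_length < 1L) stop("contig_length must be >= 1", call. = FALSE)
  if (snp_density_per_bp <= 0 || snp_density_per_bp > 0.25) {
    stop("snp_density_per_bp must lie in (0, 0.25]", call. = FALSE)
  }
  if (shared_site_fraction < 0 || shared_site_fraction > 1) {
    stop("shared_site_fraction must lie in [0, 1]", call. = FALSE)
  }
  species <- sprintf("sp%02d", seq_len(n_species))
  individuals <- data.frame(
    individual = paste0(rep(species, each = individuals_per_species), "_i",
                        sprintf("%02d", seq_len(individuals_per_species))),
    species = rep(species, each = individuals_per_species),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    refs <- list(); site_list <- list(); haps <- list()
    for (k in seq_len(n_contigs)) {
      cid <- sprintf("contig%03d", k)
      ref <- sample(BASES, contig_length, replace = TRUE)
      refs[[cid]] <- paste(ref, collapse = "")
      pos <- which(runif(contig_length) < snp_density_per_bp) - 1L
      n <- length(pos)
      freqs <- matrix(0, nrow = n, ncol = n_species,
                      dimnames = list(NULL, species))
      minor <- character(n)
      if (n > 0L) {
        shared <- runif(n) < shared_site_fraction
        for (i in seq_len(n)) {
          minor[i] <- sample(setdiff(BASES, ref[pos[i] + 1L]), 1L)
          f <- runif(1L, 0.05, 0.5)
          if (shared[i]) {
            freqs[i, ] <- f
          } else {
            freqs[i, sample(n_species, 1L)] <- f
          }
        }
      }
      site_list[[cid]] <- data.frame(
        contig_id = rep(cid, n), position = pos,
        major = if (n) ref[pos + 1L] else character(0), minor = minor,
        stringsAsFactors = FALSE)
      site_list[[cid]] <- cbind(site_list[[cid]],
                                as.data.frame(freqs))
      names(site_list[[cid]])[-(1:4)] <- paste0("freq_", species)
      for (ind in individuals$individual) {
        sp <- individuals$species[individuals$individual == ind]
        pair <- vapply(1:2, function(h) {
          s <- ref
          if (n > 0L) {
            carry <- runif(n) < freqs[, sp]
            s[pos[carry] + 1L] <- minor[carry]
          }
          paste(s, collapse = "")
        }, character(1L))
        haps[[ind]][[cid]] <- pair
      }
    }
    sites <- do.call(rbind, site_list)
    rownames(sites) <- NULL
    maf <- as.matrix(sites[paste0("freq_", species)])
    colnames(maf) <- species
    structure(
      list(sites = sites, refs = refs, haplotypes = haps,
           individuals = individuals, species = species,
           panel_maf = maf, injected_miscalls = 0L),
      class = "SimTruth")
  })
}

#' Simulate EST reads over simulated haplotypes
#'
#' Draws reads from the individuals' haplotypes at Poisson coverage and,
#' optionally, corrupts each base with its Phred-implied substitution
#' probability `10^(-q/10)`. Technologies are sampled per read and set
#' the read length and the flat quality assigned to its bases (a
#' deliberate simplification of chromatogram quality profiles).
#'
#' @param truth A `SimTruth` from [simulate_haplotypes()].
#' @param depth_mean Target mean per-base coverage (> 0).
#' @param read_length Named integer vector of read lengths per
#'   technology.
#' @param tech_mix Named sampling weights over the technologies in
#'   `read_length`.
#' @param quality_profile Named flat Phred quality per technology.
#' @param error_from_quality If `FALSE`, reads are exact haplotype
#'   substrings.
#' @param seed Integer seed.
#' @return Named list of [contig_alignment()] objects (empty when the
#'   truth has no contigs).
#' @export
simulate_est_reads <- function(truth, depth_mean = 10,
                               read_length = c(sanger = 500L,
                                               pyro454 = 250L),
                               tech_mix = c(sanger = 0.5, pyro454 = 0.5),
                               quality_profile = c(sanger = 30L,
                                                   pyro454 = 25L),
                               error_from_quality = TRUE, seed) {
  stopifnot(inherits(truth, "SimTruth"))
  if (depth_mean <= 0) stop("depth_mean must be > 0", call. = FALSE)
  techs <- names(read_length)
  stopifnot(!is.null(techs), all(techs %in% names(quality_profile)),
            all(techs %in% names(tech_mix)))
  inds <- truth$individuals
  with_seed(seed, {
    out <- list()
    for (cid in names(truth$refs)) {
      clen <- nchar(truth$refs[[cid]])
      mean_len <- sum(tech_mix[techs] / sum(tech_mix) *
                        pmin(read_length[techs], clen))
      n_reads <- rpois(1L, depth_mean * clen / mean_len)
      reads <- vector("list", n_reads)
      for (j in seq_len(n_reads)) {
        i <- sample(nrow(inds), 1L)
        hap <- sample(2L, 1L)
        tech <- sample(techs, 1L, prob = tech_mix[techs])
        len <- min(read_length[[tech]], clen)
        start <- sample.int(clen - len + 1L, 1L) - 1L
        seq <- substring(truth$haplotypes[[inds$individual[i]]][[cid]][hap],
                         start + 1L, start + len)
        q <- rep(as.integer(quality_profile[[tech]]), len)
        if (error_from_quality) {
          b <- strsplit(seq, "", fixed = TRUE)[[1L]]
          err <- runif(len) < 10^(-q / 10)
          if (any(err)) {
            b[err] <- vapply(b[err],
                             function(x) sample(setdiff(BASES, x), 1L), "")
            seq <- paste(b, collapse = "")
          }
        }
        reads[[j]] <- aligned_read(
          sprintf("%s_r%05d", cid, j), start = start, bases = seq,
          quals = q, taxon = inds$species[i],
          individual = inds$individual[i], technology = tech)
      }
      out[[cid]] <- contig_alignment(cid, clen, reads)
    }
    out
  })
}

#' Simulate a GoldenGate-style genotype panel
#'
#' True genotypes are Hardy-Weinberg draws from each species' true minor
#' allele frequency in `truth` (the major allele is `A`, the minor `B`
#' on the assay abstraction). GenCall scores are drawn from a Beta
#' distribution whose mean is the SNP's cluster-quality parameter, so
#' poorly clustering SNPs produce low-score datapoints far from the
#' cluster centre. A species-level assay failure probability turns
#' datapoints into `NC`.
#'
#' @param truth A `SimTruth`.
#' @param samples Sample sheet `data.frame` (`sample_id`, `species`,
#'   `section`, `subgenus`); species must appear in `truth`. Default: 24
#'   samples per truth species, one section/subgenus per species.
#' @param gencall_quality_by_snp Per-SNP Beta mean in `(0, 1]` (recycled;
#'   default 0.9).
#' @param failure_prob_by_species Named per-species probability that a
#'   datapoint fails outright (default 0).
#' @param concentration Beta concentration (shape1 + shape2) for GenCall
#'   scores.
#' @param adt Optional per-SNP ADT design scores to carry through.
#' @param seed Integer seed.
#' @return A [genotype_panel()]; attribute `true_genotypes` holds the
#'   uncorrupted SNP-by-sample genotype matrix.
#' @export
simulate_genotype_panel <- function(truth, samples = NULL,
                                    gencall_quality_by_snp = 0.9,
                                    failure_prob_by_species = NULL,
                                    concentration = 30, adt = NULL,
                                    seed) {
  stopifnot(inherits(truth, "SimTruth"))
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = paste0(rep(truth$species, each = 24L), "_s",
                         sprintf("%02d", seq_len(24L))),
      species = rep(truth$species, each = 24L),
      stringsAsFactors = FALSE)
    samples$section <- samples$species
    samples$subgenus <- "subgenus1"
  }
  bad <- setdiff(unique(samples$species), truth$species)
  if (length(bad)) {
    stop("sample species absent from truth: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_snp <- nrow(truth$sites)
  if (n_snp == 0L) stop("truth contains no SNP sites", call. = FALSE)
  snp_ids <- paste0(truth$sites$contig_id, "_",
                    truth$sites$position + 1L)
  qual <- rep_len(gencall_quality_by_snp, n_snp)
  if (any(qual <= 0 | qual > 1)) {
    stop("gencall_quality_by_snp values must lie in (0, 1]", call. = FALSE)
  }
  fail <- setNames(rep(0, length(truth$species)), truth$species)
  if (!is.null(failure_prob_by_species)) {
    stopifnot(!is.null(names(failure_prob_by_species)))
    if (any(failure_prob_by_species < 0 | failure_prob_by_species > 1)) {
      stop("failure probabilities must lie in [0, 1]", call. = FALSE)
    }
    fail[names(failure_prob_by_species)] <- failure_prob_by_species
  }
  with_seed(seed, {
    n_s <- nrow(samples)
    gts <- matrix("AA", n_snp, n_s)
    p <- truth$panel_maf[, samples$species, drop = FALSE]  # minor = B
    nB <- matrix(rbinom(n_snp * n_s, 2L, as.vector(p)), n_snp, n_s)
    gts[nB == 1L] <- "AB"
    gts[nB == 2L] <- "BB"
    true_gts <- gts
    sc <- matrix(NA_real_, n_snp, n_s)
    for (i in seq_len(n_snp)) {
      if (qual[i] >= 1) {
        sc[i, ] <- 1
      } else {
        sc[i, ] <- rbeta(n_s, qual[i] * concentration,
                         (1 - qual[i]) * concentration)
      }
    }
    nc <- matrix(runif(n_snp * n_s), n_snp, n_s) <
      matrix(fail[samples$species], n_snp, n_s, byrow = TRUE)
    gts[nc] <- "NC"
    sc[nc] <- NA_real_
    panel <- genotype_panel(snp_ids, samples, gts, sc,
                            gentrain = qual,
                            adt = if (is.null(adt)) NULL
                                  else rep_len(adt, n_snp))
    attr(panel, "true_genotypes") <-
      matrix(true_gts, n_snp, n_s,
             dimnames = list(snp_ids, samples$sample_id))
    panel
  })
}

#' Simulate parent-parent-offspring trios with injected miscalls
#'
#' Offspring receive one random allele from each parent at every SNP.
#' Exactly `n_inconsistent_to_inject` transmissions are then corrupted by
#' flipping the transmitted allele to the other assay allele, at distinct
#' `(snp, trio, parent)` slots chosen without replacement. Slots are
#' drawn only where both parents are homozygous and at most one parent
#' slot per `(snp, trio)` cell, which guarantees that every injected
#' corruption is detected as exactly one Mendelian inconsistency by
#' [trio_consistency()] -- corruptions at heterozygous parents, or on
#' both sides of an AA x BB cross, can masquerade as legal transmissions
#' and would break the injected == detected accounting.
#'
#' @param parent_genotypes Data frame or matrix with per-SNP `father` and
#'   `mother` genotypes over `{AA, AB, BB}`; row names or a `snp_id`
#'   column give SNP identifiers.
#' @param n_trios Number of offspring trios per family.
#' @param n_inject Number of transmissions to corrupt.
#' @param seed Integer seed.
#' @return Data frame of trio records (`snp_id`, `trio_id`, `father`,
#'   `mother`, `child`) with attributes `injected` (slot table) and
#'   `injected_miscalls` (the count).
#' @export
simulate_trios <- function(parent_genotypes, n_trios, n_inject = 0L,
                           seed) {
  pg <- as.data.frame(parent_genotypes, stringsAsFactors = FALSE)
  if (!all(c("father", "mother") %in% names(pg))) {
    stop("parent_genotypes needs 'father' and 'mother' columns",
         call. = FALSE)
  }
  snp_ids <- if ("snp_id" %in% names(pg)) as.character(pg$snp_id)
             else if (!is.null(rownames(parent_genotypes)))
               rownames(parent_genotypes)
             else sprintf("snp%05d", seq_len(nrow(pg)))
  ok <- c("AA", "AB", "BB")
  if (!all(pg$father %in% ok) || !all(pg$mother %in% ok)) {
    stop("parent genotypes must be AA, AB or BB", call. = FALSE)
  }
  n_snp <- nrow(pg)
  alleles <- function(g) c(substr(g, 1L, 1L), substr(g, 2L, 2L))
  flip <- function(a) ifelse(a == "A", "B", "A")
  with_seed(seed, {
    # transmitted alleles: [snp, trio, parent]
    tf <- matrix("", n_snp, n_trios)
    tm <- matrix("", n_snp, n_trios)
    for (i in seq_len(n_snp)) {
      tf[i, ] <- sample(alleles(pg$father[i]), n_trios, replace = TRUE)
      tm[i, ] <- sample(alleles(pg$mother[i]), n_trios, replace = TRUE)
    }
    hom <- which(pg$father %in% c("AA", "BB") &
                   pg$mother %in% c("AA", "BB"))
    cells <- expand.grid(snp = hom, trio = seq_len(n_trios))
    if (n_inject > nrow(cells)) {
      stop("cannot inject ", n_inject, " miscalls: only ", nrow(cells),
           " eligible (snp, trio) slots with both parents homozygous",
           call. = FALSE)
    }
    injected <- NULL
    if (n_inject > 0L) {
      pick <- cells[sample.int(nrow(cells), n_inject), , drop = FALSE]
      pick$parent <- sample(c("father", "mother"), n_inject,
                            replace = TRUE)
      for (r in seq_len(n_inject)) {
        i <- pick$snp[r]; j <- pick$trio[r]
        if (pick$parent[r] == "father") tf[i, j] <- flip(tf[i, j])
        else tm[i, j] <- flip(tm[i, j])
      }
      injected <- data.frame(snp_id = snp_ids[pick$snp],
                             trio_id = sprintf("trio%03d", pick$trio),
                             parent = pick$parent,
                             stringsAsFactors = FALSE)
    }
    child <- matrix(paste0(pmin(tf, tm), pmax(tf, tm)), n_snp, n_trios)
    out <- data.frame(
      snp_id = rep(snp_ids, times = n_trios),
      trio_id = rep(sprintf("trio%03d", seq_len(n_trios)),
                    each = n_snp),
      father = rep(pg$father, times = n_trios),
      mother = rep(pg$mother, times = n_trios),
      child = as.vector(child),
      stringsAsFactors = FALSE)
    attr(out, "injected") <- injected
    attr(out, "injected_miscalls") <- as.integer(n_inject)
    out
  })
}

#' Simulate shotgun allele read counts at assayed SNPs
#'
#' Emulates low-coverage genome shotgun evidence at known SNP positions:
#' read depth is Poisson with mean `mean_coverage * min_qual_pass_rate`
#' (the pass rate models reads discarded below the mapping/base quality
#' bar), heterozygotes yield Binomial(depth, 1/2) allele counts, and
#' homozygotes yield alternative-allele reads only through sequencing
#' error (an erroneous base is the other assay allele with probability
#' 1/3, otherwise a third base tallied in `other_count`).
#'
#' @param genotypes Character vector over `{AA, AB, BB}`, optionally
#'   named by SNP id.
#' @param mean_coverage Mean raw coverage (> 0).
#' @param base_error Per-read error probability in `[0, 0.5)`.
#' @param min_qual_pass_rate Fraction of reads surviving the quality
#'   filter, in `(0, 1]`.
#' @param fixed_depth If given, every SNP receives exactly this depth
#'   instead of a Poisson draw (used to study detectability at a fixed
#'   read count).
#' @param seed Integer seed.
#' @return Data frame: `snp_id`, `true_genotype`, `ref_count`,
#'   `alt_count`, `other_count`.
#' @export
simulate_shotgun_counts <- function(genotypes, mean_coverage = 2,
                                    base_error = 0.01,
                                    min_qual_pass_rate = 1,
                                    fixed_depth = NULL, seed) {
  if (is.null(fixed_depth) && mean_coverage <= 0) {
    stop("mean_coverage must be > 0", call. = FALSE)
  }
  if (base_error < 0 || base_error >= 0.5) {
    stop("base_error must lie in [0, 0.5)", call. = FALSE)
  }
  stopifnot(all(genotypes %in% c("AA", "AB", "BB")))
  n <- length(genotypes)
  ids <- names(genotypes) %||% sprintf("snp%05d", seq_len(n))
  with_seed(seed, {
    depth <- if (is.null(fixed_depth)) {
      rpois(n, mean_coverage * min_qual_pass_rate)
    } else rep_len(as.integer(fixed_depth), n)
    # ref_count tallies the A assay allele, alt_count the B allele
    het <- genotypes == "AB"
    ref <- alt <- other <- integer(n)
    alt[het] <- rbinom(sum(het), depth[het], 0.5)
    ref[het] <- depth[het] - alt[het]
    for (g in c("AA", "BB")) {
      idx <- which(genotypes == g)
      if (!length(idx)) next
      n_err <- rbinom(length(idx), depth[idx], base_error)
      cross <- rbinom(length(idx), n_err, 1 / 3)  # error lands on the
      own <- depth[idx] - n_err                   # other assay allele
      other[idx] <- n_err - cross
      if (g == "AA") { ref[idx] <- own; alt[idx] <- cross }
      else           { alt[idx] <- own; ref[idx] <- cross }
    }
    data.frame(snp_id = ids, true_genotype = unname(genotypes),
               ref_count = ref, alt_count = alt, other_count = other,
               stringsAsFactors = FALSE)
  })
}
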