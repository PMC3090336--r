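# In-code fixture builders shared across test files.

# A read of uniform quality; `bases` as a plain string.
qread <- function(id, start, bases, q = 30L, taxon = "spA",
                  individual = "ind1", tech = "sanger") {
  aligned_read(id, start = start, bases = bases,
               quals = rep(q, nchar(bases)), taxon = taxon,
               individual = individual, technology = tech)
}

# A single-column contig: n reads of length 1 at position 0, one base
# and quality per read.
column_contig <- function(bases, quals, taxa = NULL) {
  n <- length(bases)
  if (is.null(taxa)) taxa <- rep("spA", n)
  reads <- lapply(seq_len(n), function(i)
    aligned_read(sprintf("r%02d", i), start = 0L, bases = bases[i],
                 quals = quals[i], taxon = taxa[i]))
  contig_alignment("col", 1L, reads)
}

# Deep contig: each read spans the whole template; `variants` is a list
# read_index -> named vector position(0-based) -> base.
template_contig <- function(template, n_reads, q = 30L,
                            variants = list(), taxa = NULL,
                            contig_id = "ctg", repeat_mask = NULL,
                            exon_map = NULL) {
  if (is.null(taxa)) taxa <- rep("spA", n_reads)
  reads <- lapply(seq_len(n_reads), function(i) {
    b <- strsplit(template, "", fixed = TRUE)[[1L]]
    v <- variants[[as.character(i)]]
    if (!is.null(v)) b[as.integer(names(v)) + 1L] <- v
    qread(sprintf("%s_r%02d", contig_id, i), 0L,
          paste(b, collapse = ""), q = q, taxon = taxa[i])
  })
  contig_alignment(contig_id, nchar(template), reads,
                   repeat_mask = repeat_mask, exon_map = exon_map)
}

random_template <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# Minimal SimTruth with prescribed per-species minor allele
# frequencies; enough structure for simulate_genotype_panel().
make_truth <- function(maf, species = colnames(maf)) {
  maf <- as.matrix(maf)
  if (is.null(species)) {
    species <- sprintf("sp%02d", seq_len(ncol(maf)))
  }
  colnames(maf) <- species
  n <- nrow(maf)
  sites <- data.frame(contig_id = rep("contig001", n),
                      position = seq_len(n) * 10L,
                      major = rep("A", n), minor = rep("G", n),
                      stringsAsFactors = FALSE)
  for (sp in species) sites[[paste0("freq_", sp)]] <- maf[, sp]
  structure(list(sites = sites,
                 refs = list(contig001 = random_template(10L * n + 20L)),
                 haplotypes = list(), species = species,
                 individuals = data.frame(individual = character(),
                                          species = character()),
                 panel_maf = maf, injected_miscalls = 0L),
            class = "SimTruth")
}

# A hand-assembled candidate-SNP row with sensible defaults.
make_candidate <- function(position = 150L, depth = 5L,
                           minor_count = 1L, n_alleles = 2L,
                           maf = minor_count / depth, taxa = "spA",
                           clean = c(70L, 70L), repeatfree = c(120L, 120L),
                           avail = c(150L, 150L), same_exon = TRUE,
                           contig_id = "c1", adt = NA_real_) {
  data.frame(contig_id = contig_id, position = position,
             major_allele = "A", minor_allele = "G", depth = depth,
             minor_count = minor_count, n_alleles = n_alleles,
             insilico_maf = maf, posterior = 0.999, mira_tagged = TRUE,
             major_score = 100, minor_score = 60, taxa = taxa,
             n_taxa = length(strsplit(taxa, ",")[[1]]),
             clean_flank_left = clean[1], clean_flank_right = clean[2],
             repeatfree_left = repeatfree[1],
             repeatfree_right = repeatfree[2],
             flank_avail_left = avail[1], flank_avail_right = avail[2],
             same_exon = same_exon, adt_score = adt,
             stringsAsFactors = FALSE)
}

# Random candidate rows spanning the cascade's decision space.
random_candidates <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    depth <- sample(1:30, 1L)
    minor <- sample(0:(depth %/% 2), 1L)
    make_candidate(
      position = sample(60:400, 1L), depth = depth, minor_count = minor,
      n_alleles = sample(1:3, 1L, prob = c(0.2, 0.6, 0.2)),
      maf = if (depth > 0) minor / depth else 0,
      taxa = paste(sample(c("spA", "spB", "spC"),
                          sample(1:3, 1L)), collapse = ","),
      clean = sample(0:150, 2L, replace = TRUE),
      repeatfree = sample(0:200, 2L, replace = TRUE),
      avail = sample(0:400, 2L, replace = TRUE),
      same_exon = sample(c(TRUE, FALSE, NA), 1L),
      contig_id = sample(sprintf("c%02d", 1:10), 1L))
  }))
}

# Brute-force Mendelian-consistency oracle: enumerate both parental
# assignments of the child's alleles explicitly.
trio_oracle <- function(father, mother, child) {
  if (any(c(father, mother, child) == "NC")) return(c(0L, 0L))
  al <- function(g) c(substr(g, 1, 1), substr(g, 2, 2))
  f <- al(father); m <- al(mother); ch <- al(child)
  best <- 2L
  for (ord in list(ch, rev(ch))) {
    bad <- as.integer(!(ord[1] %in% f)) + as.integer(!(ord[2] %in% m))
    best <- min(best, bad)
  }
  c(2L, best)
}
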