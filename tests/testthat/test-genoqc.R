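test_that("call rate counts datapoints at or above the cutoff", {
  expect_equal(call_rate(rep(0.5, 96)), 1.0)
  expect_equal(call_rate(c(0.25, 0.24)), 0.5)   # boundary inclusive
  row <- c(rep(0.5, 91), rep(0.1, 5))
  expect_equal(call_rate(row), 91 / 96)
  expect_lt(call_rate(row), 0.95)               # fails the reliability bar
  expect_equal(call_rate(c(0.5, NA)), 0.5)      # NC counts as failure
  expect_error(call_rate(numeric(0)), "empty")
})

test_that("GenCall50 is the median over typed samples", {
  expect_equal(gc50(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(gc50(c(0.2, 0.6)), 0.4)          # even-n midpoint
  expect_equal(gc50(0.39), 0.39)
  expect_equal(gc50(c(0.2, NA, 0.6)), 0.4)
  expect_true(is.na(gc50(c(NA_real_, NA_real_))))
})

test_that("assayed MAF is the allele-count frequency", {
  expect_equal(assayed_maf(rep("AA", 10)), 0)
  expect_equal(assayed_maf(c(rep("AA", 6), rep("AB", 4))), 0.2)
  expect_equal(assayed_maf(c(rep("AA", 5), rep("BB", 5))), 0.5)
  expect_equal(assayed_maf(c("AA", "BB", "NC"), subset = c(1, 3)), 0)
  expect_true(is.na(assayed_maf(rep("NC", 4))))
})

test_that("reliability and polymorphism classification re-derive", {
  truth <- make_truth(matrix(runif(80, 0.02, 0.5), 80, 2))
  panel <- simulate_genotype_panel(
    truth, gencall_quality_by_snp = runif(80, 0.3, 1), seed = 21)
  qc <- snp_qc(panel)
  re <- !is.na(qc$gc50) & qc$gc50 >= 0.40 & qc$call_rate >= 0.95 &
    (is.na(qc$gentrain) | qc$gentrain >= 0.40)
  expect_equal(qc$reliable, re)
  expect_equal(qc$polymorphic,
               !is.na(qc$maf_overall) & qc$maf_overall >= 0.05)
  # invariant to sample ordering
  perm <- sample(nrow(panel$samples))
  panel2 <- genotype_panel(panel$snp_ids, panel$samples[perm, ],
                           panel$genotypes[, perm],
                           panel$gencall[, perm],
                           panel$gentrain, panel$adt)
  qc2 <- snp_qc(panel2)
  expect_equal(qc2$call_rate, qc$call_rate)
  expect_equal(qc2$gc50, qc$gc50)
  expect_equal(qc2$maf_overall, qc$maf_overall)
})

test_that("assayed MAF is unbiased on Hardy-Weinberg panels", {
  truth <- make_truth(matrix(0.25, 20, 1), species = "spA")
  samples <- data.frame(sample_id = sprintf("s%02d", 1:96),
                        species = "spA", section = "sec1",
                        subgenus = "sub1", stringsAsFactors = FALSE)
  est <- vapply(1:50, function(s) {
    panel <- simulate_genotype_panel(truth, samples, seed = 500 + s)
    mean(apply(panel$genotypes, 1, assayed_maf))
  }, numeric(1))
  # each panel mean averages 20 SNPs x 192 alleles; MC tolerance on the
  # grand mean over 50 seeds
  se <- sqrt(0.25 * 0.75 / 192 / 20 / 50)
  expect_lt(abs(mean(est) - 0.25), 4 * se)
})

test_that("conversion rate divides polymorphic by the denominator", {
  rec <- data.frame(
    snp_id = sprintf("s%03d", 1:800),
    maf_overall = c(rep(0.2, 505), rep(0.01, 206), rep(0.3, 89)),
    reliable = c(rep(TRUE, 711), rep(FALSE, 89)))
  cr <- conversion_rate(rec, reliable_only = TRUE)
  expect_equal(round(100 * cr, 1), 71.0)
  expect_equal(cr, 505 / 711)
  expect_equal(conversion_rate(
    data.frame(maf_overall = rep(0.01, 5), reliable = TRUE)), 0)
  # threshold 0.01 can only enlarge the polymorphic set
  expect_gte(conversion_rate(rec, maf_threshold = 0.01),
             conversion_rate(rec, maf_threshold = 0.05))
})

test_that("shared polymorphism counts intersect across species", {
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:32),
    species = rep(c("spA", "spB"), each = 16),
    section = "sec1", subgenus = "sub1", stringsAsFactors = FALSE)
  gts <- rbind(c(rep("AB", 16), rep("AB", 16)),   # polymorphic in both
               c(rep("AB", 16), rep("AA", 16)),   # spA only
               c(rep("AA", 16), rep("AA", 16)))   # neither
  panel <- genotype_panel(sprintf("snp%d", 1:3), samples, gts,
                          matrix(0.9, 3, 32))
  qc <- snp_qc(panel)
  tab <- shared_polymorphism_table(panel, qc)
  expect_equal(nrow(tab), 3L)  # spA, spB, spA+spB
  expect_equal(tab$n_polymorphic[tab$species_set == "spA+spB"], 1L)
  expect_equal(tab$n_polymorphic[tab$species_set == "spA"], 2L)
  # monotone under intersection
  expect_lte(tab$n_polymorphic[tab$species_set == "spA+spB"],
             min(tab$n_polymorphic[tab$n_species == 1]))
})

test_that("five species give 31 subset rows and small ones are dropped", {
  truth <- make_truth(matrix(runif(30 * 5, 0.1, 0.5), 30, 5))
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:88),
    species = rep(truth$species, times = c(20, 20, 20, 20, 8)),
    section = "sec1", subgenus = "sub1", stringsAsFactors = FALSE)
  panel <- simulate_genotype_panel(truth, samples, seed = 77)
  qc <- snp_qc(panel)
  expect_warning(tab4 <- shared_polymorphism_table(panel, qc), "sp05")
  expect_equal(nrow(tab4), 2^4 - 1)
  samples$species <- rep(truth$species, times = c(18, 18, 18, 17, 17))
  panel5 <- simulate_genotype_panel(truth, samples, seed = 78)
  tab5 <- shared_polymorphism_table(panel5, snp_qc(panel5))
  expect_equal(nrow(tab5), 31L)
  expect_equal(sum(tab5$n_species > 1), 26L)
})

test_that("independent per-species polymorphism intersects like 0.4^5", {
  # 5 species, each SNP polymorphic in each species independently with
  # probability ~0.4: the 5-way shared fraction concentrates near 0.4^5
  n_snp <- 400L
  set.seed(99)
  maf <- matrix(ifelse(runif(n_snp * 5) < 0.4,
                       0.3, 0.0), n_snp, 5)
  truth <- make_truth(maf)
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:150),
    species = rep(truth$species, each = 30),
    section = "sec1", subgenus = "sub1", stringsAsFactors = FALSE)
  panel <- simulate_genotype_panel(truth, samples,
                                   gencall_quality_by_snp = 1, seed = 98)
  qc <- snp_qc(panel)
  tab <- shared_polymorphism_table(panel, qc)
  shared5 <- tab$n_polymorphic[tab$n_species == 5] / n_snp
  p5 <- 0.4^5
  # extra slack beyond the design 0.4^5: a MAF=0.3 species can still
  # drift below the 0.05 bar in a 30-sample draw
  expect_lt(abs(shared5 - p5), 3 * sqrt(p5 * (1 - p5) / n_snp) + 0.01)
})

test_that("transferability summary reflects per-species assay failure", {
  truth <- make_truth(matrix(0.3, 40, 2))
  perfect <- simulate_genotype_panel(truth, gencall_quality_by_snp = 1,
                                     seed = 11)
  tab <- transferability_summary(perfect)
  expect_true(all(tab$pct_callrate == 100))
  expect_true(all(tab$pct_gc50 == 100))

  med_diff <- vapply(1:10, function(s) {
    panel <- simulate_genotype_panel(
      truth, failure_prob_by_species = c(sp01 = 0.05, sp02 = 0.4),
      seed = 200 + s)
    t2 <- transferability_summary(panel)
    t2$pct_callrate[t2$species == "sp01"] -
      t2$pct_callrate[t2$species == "sp02"]
  }, numeric(1))
  expect_gt(median(med_diff), 0)

  # empty group is a zero row, not an error
  grp <- rep(c("g1", "g2"), c(40, 0))
  tab3 <- transferability_summary(perfect, snp_grouping = grp)
  expect_false(any(!is.finite(tab3$pct_callrate)))
})

test_that("caller concordance cross-tabulates and tests independence", {
  rec <- data.frame(snp_id = sprintf("s%03d", 1:100),
                    maf_overall = rep(c(0.2, 0.01), times = c(40, 60)),
                    reliable = TRUE)
  # hand table: tagged 30/50 polymorphic, untagged 10/50
  tagged <- c(rep(TRUE, 30), rep(FALSE, 10),
              rep(TRUE, 20), rep(FALSE, 40))
  cc <- caller_concordance(rec, tagged)
  expect_equal(unname(cc$table["tagged", "polymorphic"]), 30L)
  expect_equal(unname(cc$table["untagged", "polymorphic"]), 10L)
  o <- matrix(c(30, 20, 10, 40), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(cc$chi_square, sum((o - e)^2 / e))
  expect_equal(cc$conversion_tagged, 0.6)
  expect_equal(cc$conversion_untagged, 0.2)

  # degenerate margin
  cc2 <- caller_concordance(
    data.frame(maf_overall = rep(0.3, 5), reliable = TRUE),
    rep(TRUE, 5))
  expect_true(is.na(cc2$chi_square))
  expect_match(cc2$note, "degenerate")
})

test_that("independent tagging rejects at close to the nominal rate", {
  set.seed(321)
  n_rec <- 200L
  rej <- vapply(1:200, function(s) {
    poly <- runif(n_rec) < 0.4
    tagged <- runif(n_rec) < 0.5
    rec <- data.frame(maf_overall = ifelse(poly, 0.3, 0.01),
                      reliable = TRUE)
    p <- caller_concordance(rec, tagged)$p_value
    !is.na(p) && p < 0.05
  }, logical(1))
  # binomial tolerance around 5% over 200 replicates
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
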