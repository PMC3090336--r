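test_that("trio consistency matches brute force on all 27 combinations", {
  gts <- c("AA", "AB", "BB")
  for (f in gts) for (m in gts) for (ch in gts) {
    expect_equal(unname(trio_consistency(f, m, ch)),
                 unname(trio_oracle(f, m, ch)),
                 info = paste(f, m, ch))
  }
  # the canonical cases
  expect_equal(unname(trio_consistency("AA", "BB", "AB")), c(2L, 0L))
  expect_equal(unname(trio_consistency("AA", "BB", "AA")), c(2L, 1L))
  expect_equal(unname(trio_consistency("AA", "AA", "BB")), c(2L, 2L))
  # no-calls contribute nothing
  expect_equal(unname(trio_consistency("AA", "NC", "AB")), c(0L, 0L))
  expect_error(trio_consistency("AA", "XX", "AB"), "invalid")
})

test_that("heritability summary counts two transmissions per trio", {
  set.seed(42)
  pg <- data.frame(snp_id = sprintf("snp%03d", 1:768),
                   father = sample(c("AA", "AB", "BB"), 768, TRUE),
                   mother = sample(c("AA", "AB", "BB"), 768, TRUE),
                   stringsAsFactors = FALSE)
  trios <- simulate_trios(pg, 24, 0L, seed = 1)
  ts <- trio_heritability(trios)
  expect_equal(ts$n_transmissions_assessed, 768L * 24L * 2L)
  expect_equal(ts$n_transmissions_assessed, 36864L)
  expect_equal(ts$n_inconsistent, 0L)
  expect_equal(ts$miscall_rate, 0)
  expect_equal(ts$n_snps_full_heritability, 768L)

  # a trio with an NC member contributes (0, 0)
  trios$child[1] <- "NC"
  ts2 <- trio_heritability(trios)
  expect_equal(ts2$n_transmissions_assessed, 36862L)

  # vectorised path agrees with the per-trio function on noisy data
  noisy <- simulate_trios(pg, 4, 100L, seed = 2)
  ts3 <- trio_heritability(noisy)
  ref <- rowSums(vapply(seq_len(nrow(noisy)), function(i)
    trio_consistency(noisy$father[i], noisy$mother[i], noisy$child[i]),
    integer(2)))
  expect_equal(ts3$n_transmissions_assessed, unname(ref[1]))
  expect_equal(ts3$n_inconsistent, unname(ref[2]))
})

test_that("injected corruptions are recovered exactly across seeds", {
  set.seed(7)
  pg <- data.frame(snp_id = sprintf("snp%03d", 1:300),
                   father = sample(c("AA", "AB", "BB"), 300, TRUE,
                                   prob = c(0.4, 0.2, 0.4)),
                   mother = sample(c("AA", "AB", "BB"), 300, TRUE,
                                   prob = c(0.4, 0.2, 0.4)),
                   stringsAsFactors = FALSE)
  for (s in 1:20) {
    k <- sample(0:150, 1L)
    trios <- simulate_trios(pg, 8, k, seed = s)
    expect_equal(trio_heritability(trios)$n_inconsistent, k,
                 info = paste("seed", s))
  }
})

test_that("miscall concentration finds the smallest covering set", {
  expect_equal(miscall_concentration(c(a = 10, b = 5, c = 3, d = 1,
                                       e = 1)), 3L)
  expect_equal(miscall_concentration(c(a = 0, b = 0)), 0L)
  expect_equal(miscall_concentration(c(a = 7)), 1L)
  # ties broken by id: both orderings cover at k = 2
  expect_equal(miscall_concentration(c(b = 5, a = 5), fraction = 1), 2L)
  expect_error(miscall_concentration(c(a = 1), fraction = 0), "fraction")
})

test_that("sequence-based genotype calls follow the binomial rule", {
  r <- seq_genotype_call(5L, 0L)
  expect_equal(r$p_value, 0.0625)
  expect_equal(r$seq_genotype, "hom")
  expect_equal(r$majority, "A")

  r <- seq_genotype_call(4L, 1L)
  expect_equal(r$p_value, 0.375)
  expect_equal(r$seq_genotype, "het")

  r <- seq_genotype_call(3L, 1L)
  expect_equal(r$seq_genotype, "no_call")
  expect_true(is.na(r$p_value))

  r <- seq_genotype_call(0L, 0L)
  expect_equal(r$seq_genotype, "no_call")

  # symmetry in the two alleles
  for (k in 0:8) {
    a <- seq_genotype_call(k, 8L - k)
    b <- seq_genotype_call(8L - k, k)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$seq_genotype, b$seq_genotype)
  }
})

test_that("het rejection probability equals the exact binomial mass", {
  for (n in 5:20) {
    # enumeration oracle: mass of outcomes the two-sided test rejects
    p_rej <- sum(dbinom(0:n, n, 0.5)[
      vapply(0:n, function(k)
        exact_binomial_two_sided(k, n) < 0.1, logical(1))])
    cnt <- simulate_shotgun_counts(
      setNames(rep("AB", 3000), sprintf("s%04d", 1:3000)),
      fixed_depth = n, base_error = 0, seed = 1000 + n)
    rej <- mean(vapply(seq_len(nrow(cnt)), function(i)
      seq_genotype_call(cnt$ref_count[i], cnt$alt_count[i],
                        min_depth = n)$seq_genotype == "hom",
      logical(1)))
    expect_lt(abs(rej - p_rej),
              3 * sqrt(max(p_rej * (1 - p_rej), 1e-4) / 3000))
  }
})

test_that("concordance excludes no-calls and labels divergences", {
  counts <- data.frame(
    snp_id = sprintf("s%02d", 1:9),
    ref_count = c(10L, 0L, 6L, 6L, 0L, 10L, 3L, 10L, 5L),
    alt_count = c(0L, 10L, 6L, 5L, 0L, 0L, 1L, 0L, 5L),
    other_count = 0L)
  gggt <- setNames(c("AA", "BB", "AB", "AB", "AA", "AB", "AA", "BB",
                     "NC"),
                   counts$snp_id)
  cs <- concordance_summary(counts, gggt)
  # s05 (depth 0), s07 (depth 4) and s09 (assay NC) drop out
  expect_equal(cs$n_compared, 6L)
  expect_equal(cs$n_concordant, 4L)
  expect_equal(cs$fraction_concordant, 4 / 6)
  expect_setequal(cs$divergent$snp_id, c("s06", "s08"))
  expect_equal(
    cs$divergent$direction[cs$divergent$snp_id == "s06"],
    "het_by_assay_hom_by_seq")
  expect_equal(
    cs$divergent$direction[cs$divergent$snp_id == "s08"],
    "opposite_homozygotes")

  empty <- concordance_summary(counts[0, ], gggt)
  expect_true(is.na(empty$fraction_concordant))
  expect_equal(nrow(empty$divergent), 0L)
})

test_that("deep error-free counts validate true genotypes as expected", {
  g <- setNames(sample(c("AA", "AB", "BB"), 300, TRUE),
                sprintf("s%03d", 1:300))
  cnt <- simulate_shotgun_counts(g, mean_coverage = 30, base_error = 0,
                                 seed = 13)
  cs <- concordance_summary(cnt, g)
  hom <- cs$records$gggt_genotype %in% c("AA", "BB") &
    !is.na(cs$records$concordant)
  # homozygotes can never diverge without sequencing error
  expect_true(all(cs$records$concordant[hom]))
  # heterozygotes diverge at the test's type-I rate, never more than ~alpha
  het <- cs$records$gggt_genotype == "AB" & !is.na(cs$records$concordant)
  expect_gt(mean(cs$records$concordant[het]), 1 - 0.1 - 0.05)
})
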