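test_that("fixed/variable partition requires non-missing identity everywhere", {
  cs <- toy_callset(rbind(c("0/1", "0/1", "0/1"),
                          c("0/1", "0/1", "1/1"),
                          c("0/1", "./.", "0/1"),
                          c("1|0", "0/1", "0/1")))  # phasing irrelevant
  p <- classify_sites(cs)
  expect_equal(p$fixed_sites, c(1L, 4L))
  expect_equal(p$variable_sites, c(2L, 3L))
  expect_equal(sort(c(p$fixed_sites, p$variable_sites)), 1:4)  # conservation
})

test_that("private sites are genotypes found in no other sample", {
  cs <- toy_callset(rbind(c("0/1", "0/1", "1/1"),
                          c("0/1", "1/1", "1/2"),
                          c("0/1", "0/1", "0/1"),
                          c("./.", "0/1", "1/1")))
  expect_equal(private_sites(cs, "S1"), 2L)
  expect_equal(private_sites(cs, "S2"), c(2L, 4L))  # at site 4 S2's 0/1 is unshared
  expect_equal(private_sites(cs, "S3"), c(1L, 2L, 4L))
  # a missing call is never private
  expect_false(4L %in% private_sites(cs, "S1"))
})

test_that("deviant sites follow the modal genotype with deterministic tie-breaks", {
  cs <- toy_callset(rbind(c("0/1", "0/1", "1/1"),
                          c("0/1", "1/1", "1/1")))
  expect_equal(deviant_sites(cs, "S1"), 2L)       # mode 1/1 at site 2
  expect_length(deviant_sites(cs, "S2"), 0)       # matches the mode everywhere
  expect_equal(deviant_sites(cs, "S3"), 1L)       # mode 0/1 at site 1

  tie <- toy_callset(matrix(c("0/1", "0/1", "1/1", "1/1"), 1, 4))
  # counts tie 2 vs 2: mode = 0/1 (recode 1 < 2)
  expect_equal(modal_genotypes(tie), "0/1")
  expect_length(deviant_sites(tie, "S1"), 0)
  expect_equal(deviant_sites(tie, "S3"), 1L)
  expect_equal(deviant_sites(tie, "S4"), 1L)

  # all genotypes distinct: no consensus, everyone deviant
  nocons <- toy_callset(matrix(c("0/1", "1/1", "2/2"), 1, 3))
  expect_true(is.na(modal_genotypes(nocons)))
  for (s in c("S1", "S2", "S3")) expect_equal(deviant_sites(nocons, s), 1L)

  # a missing call is deviant at a variable site
  miss <- toy_callset(matrix(c("0/1", "0/1", "./."), 1, 3))
  expect_equal(deviant_sites(miss, "S3"), 1L)
  expect_length(deviant_sites(miss, "S1"), 0)
})

test_that("genotype recoding matches the published mapping, order-insensitively", {
  pairs <- list(c(0, 0), c(0, 1), c(1, 1), c(0, 2), c(1, 2), c(2, 2), c(0, 3))
  codes <- 0:6
  for (i in seq_along(pairs)) {
    expect_equal(recode_genotype(pairs[[i]][1], pairs[[i]][2]), codes[i])
    expect_equal(recode_genotype(pairs[[i]][2], pairs[[i]][1]), codes[i])  # swap
  }
  expect_equal(recode_genotype(c(1, 2, 0), c(0, 1, 3)), c(1L, 4L, 6L))
  expect_warning(out <- recode_genotype(3, 3), "sentinel")
  expect_true(is.na(out))                       # outside the mapping
  expect_true(is.na(recode_genotype(NA, 1)))    # missing, silent
  m <- suppressWarnings(recode_matrix(toy_callset(rbind(c("0/1", "3/3")))))
  expect_identical(as.vector(m), c(1L, NA))
})

test_that("differences versus a reference count unordered genotype mismatches", {
  cs <- toy_callset(rbind(c("0/1", "0/1"),
                          c("1/1", "0/1"),
                          c("./.", "0/1"),
                          c("./.", "./."),
                          c("1|0", "0/1")))
  expect_equal(diff_vs_reference(cs, "S1", "S1"), 0)       # identity
  expect_equal(diff_vs_reference(cs, "S1", "S2"), 2)       # site 2 + one-sided missing
  expect_equal(diff_vs_reference(cs, "S2", "S1"),
               diff_vs_reference(cs, "S1", "S2"))          # symmetry
  two <- toy_callset(rbind(c("0/1", "0/1"), c("1/1", "0/1")))
  expect_equal(diff_vs_reference(two, "S1", "S2"), 1)
})

test_that("set-inclusion chain private <= deviant <= variable holds on 200 random callsets", {
  set.seed(2024)
  gts <- c("0/0", "0/1", "1/1", "0/2", "1/2", "2/2", "0/3", "./.")
  for (rep in 1:200) {
    n <- sample(5:25, 1)
    m <- sample(3:6, 1)
    gt <- matrix(sample(gts, n * m, replace = TRUE,
                        prob = c(4, 8, 4, 1, 1, 1, 1, 1)), n, m)
    cs <- toy_callset(gt)
    part <- classify_sites(cs)
    expect_equal(length(part$fixed_sites) + length(part$variable_sites), n)
    modes <- modal_genotypes(cs)
    k <- geno_key(cs)
    for (s in cs$samples) {
      priv <- private_sites(cs, s)
      dev <- deviant_sites(cs, s, partition = part, modes = modes)
      expect_true(all(priv %in% dev))
      expect_true(all(dev %in% part$variable_sites))
    }
    # unanimous sites contribute to no deviant set
    agree <- part$fixed_sites
    for (s in cs$samples) {
      expect_length(intersect(agree, deviant_sites(cs, s, part, modes)), 0)
    }
  }
})

test_that("the passage table aggregates a small callset exactly as computed by hand", {
  # 3 samples, 6 sites; REF = P0 is the reference sample
  gt <- rbind(
    c("0/1", "0/1", "0/1"),   # fixed
    c("0/1", "0/1", "1/1"),   # S3 deviant+private (1/1)
    c("0/0", "0/1", "0/1"),   # S1 deviant+private (0/0 -> "other")
    c("0/1", "./.", "0/1"),   # S2 deviant (missing -> "other"), not private
    c("1/2", "0/1", "0/1"),   # S1 deviant+private, "other"
    c("0/1", "0/1", "0/1"))   # fixed
  dp <- matrix(c(10L, 20L, 30L, 40L, 50L, 60L), 6, 3)
  gq <- matrix(c(99L, 99L, 90L, 80L, 99L, 99L), 6, 3)
  cs <- toy_callset(gt, samples = c("A", "P0", "B"), dp = dp, gq = gq)
  tab <- passage_table(cs, "P0", genome_size = 1e6)

  expect_equal(tab$sample, c("A", "P0", "B"))
  expect_equal(tab$nonfixed_count, c(2, 1, 1))
  expect_equal(tab$private_count, c(2, 0, 1))
  expect_equal(tab$het01_count, c(0, 0, 0))
  expect_equal(tab$other_count, c(2, 1, 0))  # B's deviant genotype is 1/1
  expect_equal(tab$pct_of_genome, round(100 * c(2, 1, 1) / 1e6, 4))
  expect_equal(tab$pct_nonfixed, round(100 * c(2, 1, 0) / 6, 3))
  # A vs P0: sites 3, 4 (one-sided missing), 5 differ; B vs P0: 2, 4
  expect_equal(tab$diff_vs_p0, c(3, NA, 2))
  expect_equal(tab$pct_diff_vs_p0, c(round(100 * 3 / 6, 2), NA, round(100 * 2 / 6, 2)))
  # medians over calls with a non-missing genotype
  expect_equal(tab$median_dp[1], median(dp[, 1]))
  expect_equal(tab$median_dp[2], median(dp[-4, 2]))
  expect_equal(tab$median_gq[2], median(gq[-4, 2]))
  expect_error(passage_table(cs, "nope", 1e6), "not found")
})

test_that("percentage helpers round half-to-even at the stated precision", {
  expect_equal(pct_of_total(58620, 885159), 6.62)
  expect_equal(pct_of_genome(103086, 1381008983), 0.0075)
  expect_equal(pct_of_total(1, 16), 6.25)            # 6.25 exact, no bias
  expect_equal(pct_of_total(125, 100000, 2), 0.12)   # 0.125 -> even digit
  expect_equal(pct_of_genome(3125, 1e7), 0.0312)     # exact 0.03125 -> even digit
})

test_that("private-site quality comparison builds the right groups and errors usefully", {
  gt <- rbind(
    c("0/1", "0/1", "0/1"),
    c("1/1", "0/1", "0/1"),   # private for S1
    c("1/2", "0/1", "0/1"),   # private for S1
    c("0/1", "0/1", "0/1"),
    c("0/1", "0/1", "0/1"))
  dp <- matrix(30L, 5, 3)
  dp[, 1] <- c(10L, 2L, 3L, 11L, 12L)  # S1 private sites have the lowest depth
  cs <- toy_callset(gt, dp = dp)
  res <- compare_private_quality(cs, "S1", "depth")
  expect_s3_class(res, "rank_sum_result")
  expect_equal(res$n_private, 2)
  expect_equal(res$n_other, 3)
  expect_equal(res$statistic, 0)  # both private depths below every other depth
  expect_equal(res$method, "exact")
  expect_equal(res$p_two_sided, 2 / choose(5, 2))
  expect_error(compare_private_quality(cs, "S2", "depth"), "no private site")
})
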