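test_that("reference depth is matched with a floor of 2", {
  expect_equal(matched_reference_depth(1), 2L)
  expect_equal(matched_reference_depth(2), 2L)
  expect_equal(matched_reference_depth(5), 5L)
  expect_error(matched_reference_depth(-1), ">= 0")
})

test_that("cell classification equals the 16-pair oracle", {
  tab <- oracle_classify_table()
  got <- classify_cell(tab$skim, tab$ref)
  expect_identical(got, tab$class)
  expect_equal(classify_cell(1L, 1L), "MATCH")
  expect_equal(classify_cell(NA_integer_, 0L), "MISSING_IN_SKIM")
  expect_equal(classify_cell(0L, NA_integer_), "NOT_EVALUABLE")
})

test_that("concordance partitions every cell and handles edge cases", {
  g <- matrix(c(0L, 1L, 2L, NA), 4, 5)
  skim <- toy_gm(g)
  ref_adm <- flat_adm(4, 5, 10L)
  self <- concordance(toy_gm(matrix(c(0L, 1L, 2L, 0L), 4, 5)),
                      toy_gm(matrix(c(0L, 1L, 2L, 0L), 4, 5)), 2, ref_adm)
  expect_equal(self$overall_match_pct, 100)
  expect_equal(self$called_accuracy, 1)

  allmiss <- concordance(toy_gm(matrix(NA_integer_, 4, 5)),
                         toy_gm(matrix(0L, 4, 5)), 2, ref_adm)
  expect_equal(allmiss$missing_pct, 100)
  expect_true(is.na(allmiss$called_accuracy))

  mixed <- concordance(skim, toy_gm(matrix(0L, 4, 5)), 2, ref_adm)
  counts <- with(mixed, n_match + n_mismatch + n_missing_in_skim +
                   n_not_evaluable)
  expect_equal(counts, 20)

  # shallow reference cells become not-evaluable under matched masking
  shallow <- toy_adm(matrix(c(1L, 10L, 10L, 10L), 4, 5))
  res <- concordance(skim, toy_gm(matrix(0L, 4, 5)), 2, shallow)
  expect_equal(res$n_not_evaluable, 5)
})

test_that("concordance requires the reference to cover the skim sites", {
  skim <- toy_gm(matrix(0L, 4, 2))
  small_ref <- toy_gm(matrix(0L, 2, 2))
  expect_error(concordance(skim, small_ref, 2, flat_adm(2, 2, 10L)),
               "cover")
})

test_that("cumulative accuracy bins use strict upper edges", {
  # per-site missing fractions 0, .15, .25, .35, .45, .55 over 20 samples
  g <- matrix(0L, 6, 20)
  miss_n <- c(0, 3, 5, 7, 9, 11)
  for (i in 1:6) if (miss_n[i] > 0) g[i, seq_len(miss_n[i])] <- NA
  skim <- toy_gm(g)
  ref <- toy_gm(matrix(0L, 6, 20))
  tab <- cumulative_accuracy_table(skim, ref, 2, flat_adm(6, 20, 10L))
  expect_equal(tab$snp_count, c(1L, 2L, 3L, 4L, 5L))
  expect_true(all(diff(tab$snp_count) >= 0))
  expect_equal(tab$called_accuracy_pct, rep(100, 5))
})

test_that("density summary normalizes by the densest chromosome", {
  lens <- data.frame(chrom = c("chr1", "chr2"), length = c(2e6, 2e6))
  sites <- snp_list(rep(c("chr1", "chr2"), c(10, 5)),
                    c(seq(1e5, 1e6, length.out = 10),
                      seq(1e5, 5e5, length.out = 5)),
                    rep("A", 15), rep("T", 15))
  ds <- density_summary(sites, lens)
  expect_equal(ds$chromosomes$relative_density, c(1, 0.5))

  empty_chr <- density_summary(sites, rbind(lens,
    data.frame(chrom = "chr3", length = 1e6)))
  expect_equal(empty_chr$chromosomes$relative_density[3], 0)

  equal <- snp_list(c("chr1", "chr2"), c(100, 100), c("A", "A"),
                    c("T", "T"))
  expect_equal(density_summary(equal, lens)$chromosomes$relative_density,
               c(1, 1))
  expect_error(density_summary(sites,
                               data.frame(chrom = "chr1", length = 1e6)),
               "no length")
})

test_that("1-Mbp bins are half-open", {
  lens <- data.frame(chrom = "chr1", length = 3e6)
  sites <- snp_list(rep("chr1", 3), c(999999, 1000000, 1000001),
                    rep("A", 3), rep("T", 3))
  ds <- density_summary(sites, lens)
  expect_equal(ds$bins$bin_start, c(0L, 1000000L))
  expect_equal(ds$bins$count, c(1L, 2L))  # pos 1e6 starts the second bin
})

test_that("de novo comparison arithmetic and novel-site audit", {
  sites <- toy_sites(10)
  listb <- sites[1:4, ]
  denovo <- sites[c(1:3, 5:8), ]
  cmp <- denovo_audit(denovo, listb)
  expect_equal(cmp$n_denovo, 7)
  expect_equal(cmp$absolute_increase, 3)
  expect_equal(cmp$pct_list_reidentified, 75)

  same <- denovo_audit(listb, listb)
  expect_equal(same$fold_increase, 1.0)
  expect_equal(same$pct_list_reidentified, 100)
  expect_equal(same$absolute_increase, 0)

  flagged <- denovo_audit(listb, listb[0, ])
  expect_true(is.na(flagged$fold_increase))

  # novel sites audited against the deep truth
  deep <- toy_gm(matrix(0L, 10, 4))
  dn_gm <- subset_sites(deep, match(paste(denovo$chrom, denovo$pos,
                                          sep = ":"),
                                    rownames(deep$geno)))
  dn_gm$geno[4, ] <- 2L  # one novel site entirely mismatching
  cmp2 <- denovo_audit(denovo, listb, dn_gm, deep)
  expect_equal(cmp2$novel_audit$consistent, 3 / 4)
  expect_equal(cmp2$novel_audit$incorrect, 1 / 4)
  expect_equal(cmp2$novel_audit$missing, 0)
})

test_that("per-individual yields summarize non-missing counts", {
  empty <- yield_summary(toy_gm(matrix(NA_integer_, 5, 3)))
  expect_equal(c(empty$average, empty$minimum, empty$maximum), c(0, 0, 0))

  full <- yield_summary(toy_gm(matrix(0L, 100, 3)))
  expect_equal(c(full$average, full$minimum, full$maximum),
               c(100, 100, 100))

  g <- matrix(NA_integer_, 7, 3)
  g[1:3, 1] <- 0L; g[1:5, 2] <- 1L; g[1:7, 3] <- 2L
  y <- yield_summary(toy_gm(g))
  expect_equal(y$average, 5)
  expect_equal(y$minimum, 3)
  expect_equal(y$maximum, 7)
})

test_that("simulated DH mismatch rate does not rise with depth filtering", {
  spec <- population_spec("DOUBLED_HAPLOID", 40, 800, seed = 91)
  truth <- simulate_truth(spec)
  deep <- simulate_reads(truth, coverage_profile(2, cv = 0.17, n = 40,
                                                 seed = 92),
                         error_model(0.005), seed = 93)
  deep_gm <- genotype_matrix(deep, truth$sites, caller_params(0.005))
  skim <- thin_depths(deep, skim_fraction(1, 2), seed = 94)
  base_gm <- genotype_matrix(skim, truth$sites, caller_params(0.005))
  mm <- vapply(1:3, function(d) {
    gm <- mask_by_depth(base_gm, skim, d)
    concordance(gm, deep_gm, d, deep)$mismatch_pct
  }, numeric(1))
  expect_true(all(diff(mm) <= 0.5))  # non-increasing up to sampling noise
})

test_that("log-linear fit recovers an exact exponential trend", {
  cov <- c(0.25, 0.5, 1, 2, 3, 4, 5)
  set.seed(3)
  counts <- 100 * exp(1.3 * cov + rnorm(7, sd = 0.01))
  fit <- fit_exponential_growth(cov, counts)
  expect_equal(fit$rate, 1.3, tolerance = 0.02)
  expect_gt(fit$r_squared, 0.99)
  expect_error(fit_exponential_growth(1:2, c(5, 10)), "at least 3")
  expect_error(fit_exponential_growth(1:3, c(5, 0, 10)), "positive")
})
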