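test_that("depth masking hits exactly the shallow cells", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L), 3, 3))
  depths <- matrix(1:9, 3, 3)
  adm <- toy_adm(depths)
  expect_identical(mask_by_depth(gm, adm, 0)$geno, gm$geno)

  all1 <- toy_adm(matrix(1L, 3, 3))
  expect_true(all(is.na(mask_by_depth(gm, all1, 2)$geno)))

  masked <- mask_by_depth(gm, adm, 2)
  expect_identical(unname(is.na(masked$geno)), depths < 2)
  masked5 <- mask_by_depth(gm, adm, 5)
  expect_identical(unname(is.na(masked5$geno)), depths < 5)
})

test_that("missing-data filter boundary is inclusive on the retain side", {
  g <- matrix(0L, 3, 10)
  g[1, 1:5] <- NA  # exactly 0.5 missing
  g[2, 1:6] <- NA  # 0.6 missing
  gm <- toy_gm(g)
  kept <- filter_missing(gm, 0.5)
  expect_equal(nrow(kept$geno), 2L)
  expect_true(all(rowMeans(is.na(kept$geno)) <= 0.5))

  full <- toy_gm(matrix(1L, 4, 5))
  expect_identical(filter_missing(full, 0.5)$geno, full$geno)
})

test_that("MAF filter counts alleles and applies the any-group rule", {
  # 9 hom-ref + 1 het: p = 1/20 = 0.05, retained at threshold 0.05
  gm <- toy_gm(matrix(c(rep(0L, 9), 1L), 1, 10))
  expect_equal(nrow(filter_maf(gm, 0.05)$geno), 1L)

  mono <- toy_gm(matrix(0L, 2, 10))
  expect_equal(nrow(filter_maf(mono, 0.05)$geno), 0L)

  # group A monomorphic, group B at MAF 0.2: any-group retains,
  # all-group removes
  g <- matrix(0L, 1, 10)
  g[1, 6:7] <- 2L  # group B: p = 4/10 -> wait, 2 hom-alt of 5 -> p = 0.4
  gm2 <- toy_gm(g)
  groups <- rep(c("A", "B"), each = 5)
  expect_equal(nrow(filter_maf(gm2, 0.05, groups, "any")$geno), 1L)
  expect_equal(nrow(filter_maf(gm2, 0.05, groups, "all")$geno), 0L)

  allmiss <- toy_gm(matrix(NA_integer_, 1, 10))
  expect_equal(nrow(filter_maf(allmiss, 0.05)$geno), 0L)
  expect_error(filter_maf(gm, 0.05, groups = c("A", "B")), "length")
})

test_that("heterozygosity filter boundary is inclusive", {
  dh <- toy_gm(matrix(c(0L, 2L), 2, 10))
  expect_identical(filter_het(dh, 0.1)$geno, dh$geno)

  two_het <- toy_gm(matrix(c(1L, 1L, rep(0L, 8)), 1, 10))
  expect_equal(nrow(filter_het(two_het, 0.1)$geno), 0L)

  one_het <- toy_gm(matrix(c(1L, rep(0L, 9)), 1, 10))
  expect_equal(nrow(filter_het(one_het, 0.1)$geno), 1L)
})

test_that("triallelic policies drop, mask or keep flagged sites", {
  sites <- snp_list(rep("chr1", 3), c(10, 20, 30),
                    c("A", "C", "G"), c("T", "G,T", "A"))
  gm <- geno_matrix(matrix(0L, 3, 4), sites, toy_samples(4))
  expect_identical(handle_triallelic(gm, "KEEP")$geno, gm$geno)
  dropped <- handle_triallelic(gm, "DROP_SITE")
  expect_equal(dropped$sites$pos, c(10L, 30L))
  masked <- handle_triallelic(gm, "SET_MISSING")
  expect_equal(nrow(masked$geno), 3L)
  expect_true(all(is.na(masked$geno[2, ])))
  expect_false(anyNA(masked$geno[c(1, 3), ]))

  biall <- toy_gm(matrix(0L, 2, 2))
  for (pol in c("KEEP", "DROP_SITE", "SET_MISSING"))
    expect_identical(handle_triallelic(biall, pol)$geno, biall$geno)
})

test_that("pipeline report accounts for every site and data point", {
  disabled <- filter_params()
  gm <- toy_gm(matrix(c(0L, 1L, 2L, NA), 4, 5))
  adm <- flat_adm(4, 5, 3L)
  res <- apply_filter_pipeline(gm, adm, disabled)
  expect_identical(res$geno$geno, gm$geno)
  expect_equal(sum(res$report$sites_removed_per_rule), 0L)
  expect_equal(res$report$total_data_points, 4L * 5L)

  # hand-enumerated casualties on a crafted matrix
  g <- rbind(
    c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),  # het 0.2 -> het filter
    rep(0L, 10),                                  # monomorphic -> MAF
    c(2L, rep(0L, 9)),                            # MAF 0.1 -> survives
    c(rep(NA, 6), rep(0L, 4)),                    # 0.6 missing -> missing
    c(1L, rep(0L, 9)))                            # MAF 0.05, het 0.1 -> ok
  gm2 <- toy_gm(g)
  adm2 <- flat_adm(5, 10, 3L)
  params <- filter_params(min_depth = 2, max_missing = 0.5, min_maf = 0.05,
                          max_het = 0.1)
  res2 <- apply_filter_pipeline(gm2, adm2, params)
  expect_equal(unname(res2$report$sites_removed_per_rule),
               c(0L, 1L, 1L, 1L))  # triallelic, missing, maf, het
  expect_equal(res2$report$sites_out, 2L)
  expect_equal(res2$report$sites_in,
               res2$report$sites_out +
                 sum(res2$report$sites_removed_per_rule))
  expect_equal(res2$report$total_data_points, 2L * 10L)
})

test_that("the pipeline is idempotent", {
  set.seed(51)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE), 40, 5)
  gm <- toy_gm(g)
  adm <- toy_adm(matrix(rpois(200, 3), 40, 5))
  params <- filter_params(min_depth = 2, max_missing = 0.5, min_maf = 0.05,
                          max_het = 0.3)
  once <- apply_filter_pipeline(gm, adm, params)
  adm_once <- subset_sites(adm, rownames(adm$ref) %in%
                             rownames(once$geno$geno))
  twice <- apply_filter_pipeline(once$geno, adm_once, params)
  expect_identical(twice$geno$geno, once$geno$geno)
  expect_equal(sum(twice$report$sites_removed_per_rule), 0L)
})

test_that("surviving sites are monotone in the depth threshold", {
  set.seed(61)
  g <- matrix(sample(c(0L, 1L, 2L), 500, TRUE, prob = c(.6, .2, .2)),
              100, 5)
  gm <- toy_gm(g)
  adm <- toy_adm(matrix(rpois(500, 2), 100, 5))
  survivors <- vapply(0:5, function(d) {
    params <- filter_params(min_depth = d, max_missing = 0.5)
    apply_filter_pipeline(gm, adm, params)$report$sites_out
  }, numeric(1))
  expect_true(all(diff(survivors) <= 0))
})

test_that("site filters are invariant to sample permutation", {
  set.seed(71)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 300, TRUE), 30, 10)
  gm <- toy_gm(g)
  perm <- sample(10)
  gmp <- geno_matrix(g[, perm], gm$sites, gm$samples[perm, ])
  params <- filter_params(max_missing = 0.5, min_maf = 0.05, max_het = 0.3)
  a <- apply_filter_pipeline(gm, flat_adm(30, 10, 5L), params)
  b <- apply_filter_pipeline(gmp, flat_adm(30, 10, 5L), params)
  expect_equal(a$report$sites_out, b$report$sites_out)
  expect_equal(rownames(a$geno$geno), rownames(b$geno$geno))
})

test_that("relaxing max_missing never removes a retained site", {
  set.seed(81)
  g <- matrix(sample(c(0L, NA), 400, TRUE), 40, 10)
  gm <- toy_gm(g)
  tight <- rownames(filter_missing(gm, 0.3)$geno)
  loose <- rownames(filter_missing(gm, 0.5)$geno)
  expect_true(all(tight %in% loose))
})
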