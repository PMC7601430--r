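test_that("yearling-weight adjustment is the day-365 linear extrapolation", {
  expect_equal(adjust_yearling_weight(400, 400, 300, 200), 400)  # zero gain
  expect_equal(adjust_yearling_weight(350, 210, 365, 180), 350)  # t = 365
  expect_equal(adjust_yearling_weight(300, 200, 360, 180),
               100 / 180 * 185 + 200)
  # vectorised
  expect_equal(adjust_yearling_weight(c(400, 300), c(400, 200),
                                      c(300, 360), c(200, 180)),
               c(400, 100 / 180 * 185 + 200))
  expect_error(adjust_yearling_weight(300, 200, 180, 180), "t must exceed")
  expect_error(adjust_yearling_weight(300, -1, 360, 180), "positive")
})

test_that("phenotype rules drop the intended records and log counts", {
  tab <- data.frame(animal = c("a", "b", "c"), ms = c(4, 5, 6),
                    year = c(2004, 2005, 2010))
  out <- filter_phenotypes(tab, "ms", list(year = min_year_rule(2005)))
  expect_setequal(out$animal, c("b", "c"))
  expect_equal(attr(out, "removed")$year, 1L)
  expect_identical(filter_phenotypes(tab, "ms", list())[, 1:3], tab)
  expect_warning(filter_phenotypes(tab, "ms",
                                   list(y = min_year_rule(3000))),
                 "all phenotype records removed")
  expect_error(filter_phenotypes(tab, "cw"), "unknown trait")
})

make_snp_test_panel <- function() {
  # 8 animals x 7 SNPs with one SNP per failure mode plus two clean ones
  set.seed(1)
  g <- cbind(
    clean1 = c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 2L),
    unknown = c(1L, 1L, 0L, 2L, 1L, 0L, 1L, 1L),
    sexchr = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L),
    lowcall = c(NA, NA, 1L, 1L, 0L, 1L, 2L, 1L),     # call rate 6/8
    lowmaf = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),      # monomorphic
    hwe = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),         # all het at p = 0.5
    both = c(NA, NA, 0L, 0L, 0L, 0L, 0L, 0L))        # low call AND zero MAF
  rownames(g) <- sprintf("a%d", 1:8)
  toy_panel(g, chrom = c("1", "0", "X", "2", "2", "3", "3"),
            pos = c(100L, 0L, 50L, 200L, 300L, 400L, 500L))
}

test_that("SNP filters attribute failures in order and close the accounting", {
  panel <- make_snp_test_panel()
  res <- filter_snps(panel)
  rm <- res$report$removed_by_filter
  expect_equal(unlist(rm), c(unknown_position = 1, sex_chromosome = 1,
                             call_rate = 2, maf = 1, hwe = 1))
  # the SNP failing call rate and MAF went to the first filter it fails
  expect_false("both" %in% res$panel$map$snp)
  expect_setequal(res$panel$map$snp, "clean1")
  expect_equal(res$report$survivors +
                 sum(unlist(res$report$removed_by_filter)), 7)
  # idempotence: a filtered panel loses nothing more
  res2 <- filter_snps(res$panel)
  expect_equal(sum(unlist(res2$report$removed_by_filter)), 0)
  expect_identical(res2$panel$geno, res$panel$geno)
})

test_that("animal filters flag missingness, conflicts, deviation, no-phenotype", {
  spec <- qc_fixture_spec(n_total_snps = 600, n_total_animals = 80,
                          n_high_missing = 4, n_parent_conflict = 3,
                          n_pedigree_genomic_deviation = 5, n_no_phenotype = 2)
  fx <- make_qc_fixture(spec, seed = 23)
  res <- filter_animals(fx$panel, fx$ped, fx$phenotypes)
  rm <- res$report$removed_by_filter
  expect_equal(unlist(rm), c(high_missing = 4, parent_conflict = 3,
                             pedigree_genomic_deviation = 5, no_phenotype = 2))
  expect_equal(res$report$survivors, 80 - 14)
  expect_equal(nrow(res$panel$geno), 66)
  # survivors then pass a second time untouched
  res2 <- filter_animals(res$panel, fx$ped, fx$phenotypes)
  expect_equal(sum(unlist(res2$report$removed_by_filter)), 0)
})

test_that("SNP counting fixture hits each filter exactly", {
  spec <- qc_fixture_spec(n_total_snps = 500, n_unknown_position = 5,
                          n_sex_chromosome = 10, n_low_call_rate = 8,
                          n_low_maf = 12, n_hwe_fail = 3,
                          n_total_animals = 120)
  fx <- make_qc_fixture(spec, seed = 29)
  res <- filter_snps(fx$panel)
  expect_equal(unlist(res$report$removed_by_filter),
               c(unknown_position = 5, sex_chromosome = 10, call_rate = 8,
                 maf = 12, hwe = 3))
  expect_equal(res$report$survivors, 500 - 38)
  # all-zero failure spec: everything survives
  fx0 <- make_qc_fixture(qc_fixture_spec(n_total_snps = 200,
                                         n_total_animals = 50), seed = 31)
  expect_equal(filter_snps(fx0$panel)$report$survivors, 200)
  expect_equal(filter_animals(fx0$panel, fx0$ped,
                              fx0$phenotypes)$report$survivors, 50)
  expect_error(qc_fixture_spec(n_total_snps = 10, n_low_maf = 11,
                               n_total_animals = 5), "exceed")
})

test_that("surviving SNP set is unchanged by filter order (attribution only)", {
  panel <- make_snp_test_panel()
  survivors <- filter_snps(panel)$panel$map$snp
  # drop SNPs by each single rule in isolation and intersect memberships
  th <- qc_thresholds()
  keep_each <- list(
    !(panel$map$chrom %in% "0" | panel$map$pos_bp <= 0),
    !(panel$map$chrom %in% c("X", "Y")),
    (1 - colMeans(is.na(panel$geno))) >= th$min_call_rate,
    pmin(colMeans(panel$geno, na.rm = TRUE) / 2,
         1 - colMeans(panel$geno, na.rm = TRUE) / 2) >= th$min_maf,
    abs(colMeans(panel$geno == 1, na.rm = TRUE) -
          2 * (colMeans(panel$geno, na.rm = TRUE) / 2) *
          (1 - colMeans(panel$geno, na.rm = TRUE) / 2)) <=
      th$max_hwe_het_deviation)
  expect_setequal(panel$map$snp[Reduce(`&`, keep_each)], survivors)
})
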