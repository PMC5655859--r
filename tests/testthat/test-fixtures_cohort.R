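# fixtures_cohort: scenario construction and concordance scoring.

test_that("cohort truths carry the published sizes and carrier states", {
  co <- build_cohort(seed = 3)
  expect_length(co, 11)
  expect_equal(co[["CDMD1159"]]$truth$size, -45839)
  expect_equal(co[["CDMD1131"]]$truth$size, -250092)
  expect_equal(co[["CDMD1132"]]$truth$size, -249994)
  expect_equal(co[["CDMD1163"]]$truth$size, 12968)
  expect_equal(co[["CDMD1164"]]$truth$size, 12857)
  expect_equal(co[["CDMD1187"]]$truth$type, "inversion")
  expect_equal(co[["CDMD1187"]]$truth$span, 5.1e6)
  expect_equal(length(co[["CDMD1187"]]$channels), 2)
  # the non-carrier mother has no planted SV and two wild-type haplotypes
  expect_equal(nrow(co[["CDMD1158"]]$truth), 0)
  expect_identical(co[["CDMD1158"]]$haplotypes[[1]],
                   co[["CDMD1158"]]$haplotypes[[2]])
  # probands are haploid for the region, mothers diploid
  expect_equal(unname(co[["CDMD1003"]]$ploidy), 1L)
  expect_equal(unname(co[["CDMD1132"]]$ploidy), 2L)
  # family members share a reference region
  expect_identical(co[["CDMD1131"]]$ref, co[["CDMD1132"]]$ref)
})

test_that("cohort generation is seed-deterministic", {
  expect_identical(build_cohort(seed = 5), build_cohort(seed = 5))
  a <- build_cohort(seed = 5)[["CDMD1159"]]$truth$ref_start
  b <- build_cohort(seed = 6)[["CDMD1159"]]$truth$ref_start
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("concordance scoring applies type, size, zygosity and extras rules", {
  co <- build_cohort(seed = 3)
  perfect <- lapply(co, function(scn) {
    calls <- omsv:::empty_calls()
    if (nrow(scn$truth)) {
      tr <- scn$truth
      calls[1, ] <- list(1L, tr$type, "chrXr", "chrXr", tr$ref_start - 2e3,
                         tr$ref_start + 2e3, tr$ref_end - 2e3,
                         tr$ref_end + 2e3, tr$size,
                         if (tr$type == "inversion") tr$span else abs(tr$size),
                         tr$zygosity, log(1e-30), "m", "", 1L)
    }
    structure(list(calls = calls), class = "om_result")
  })
  rep <- score_concordance(co, perfect)
  expect_equal(rep$concordance, 1.0)

  # one missed sample -> 10/11
  miss <- perfect
  miss[["CDMD1159"]]$calls <- omsv:::empty_calls()
  expect_equal(score_concordance(co, miss)$concordance, 10 / 11)

  # a deletion called as insertion is discordant regardless of size
  wrong <- perfect
  wrong[["CDMD1159"]]$calls$type <- "insertion"
  expect_equal(score_concordance(co, wrong)$concordance, 10 / 11)

  # an extra call on the non-carrier is discordant
  extra <- perfect
  extra[["CDMD1158"]]$calls <- perfect[["CDMD1159"]]$calls
  expect_equal(score_concordance(co, extra)$concordance, 10 / 11)

  # size outside the tolerance fails the match
  off <- perfect
  off[["CDMD1159"]]$calls$size <- -45839 * 1.08
  expect_equal(score_concordance(co, off)$concordance, 10 / 11)
})

test_that("region too small for the planted SV is rejected", {
  expect_error(build_cohort(seed = 1, region_length = 4e5), "too small")
})
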