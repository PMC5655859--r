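# sv_caller: outlier test, classification rules, breakpoint intervals,
# dual-enzyme combination, zygosity, catalog filter, SMAP I/O.

# a "perfect consensus" shortcut: the edited reference's own label map
perfect_consensus <- function(edited_ref, id = "c1") {
  lab <- edited_ref$contigs[[1]]$channels[[1]]
  omsv:::new_consensus(id, lab, rep(20L, length(lab)),
                       length = edited_ref$contigs[[1]]$length)
}

test_that("a noiseless wild-type map yields zero SV calls", {
  cons <- perfect_consensus(fix_ref)
  res <- call_svs(list(cons), fix_ref, fix_scoring, fix_null)
  expect_equal(nrow(res$calls), 0)
})

test_that("a noiseless 45,839-bp deletion is recovered exactly", {
  ed <- apply_sv_to_map(fix_ref, list(list(type = "deletion",
                                           contig = "synth1",
                                           start = 4e5, end = 4e5 + 45839)))
  res <- call_svs(list(perfect_consensus(ed$ref)), fix_ref, fix_scoring,
                  fix_null)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$type, "deletion")
  expect_equal(res$calls$size, -45839, tolerance = 1e-6)
  expect_lte(res$calls$bp1_lo, 4e5)
  expect_gte(res$calls$bp1_hi, 4e5 - 1e-6)
  expect_lte(res$calls$bp2_lo, 4e5 + 45839 + 1e-6)
  expect_gte(res$calls$bp2_hi, 4e5 + 45839 - 1e-6)
})

test_that("a noiseless duplication-insertion is recovered exactly", {
  ed <- apply_sv_to_map(fix_ref, list(list(type = "insertion",
                                           contig = "synth1",
                                           start = 5e5, end = 5e5 + 12968)))
  res <- call_svs(list(perfect_consensus(ed$ref)), fix_ref, fix_scoring,
                  fix_null)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$type, "insertion")
  expect_equal(res$calls$size, 12968, tolerance = 1e-6)
})

test_that("deletion/insertion duality: editing the other side mirrors calls", {
  # deleting from the sample equals inserting into the reference
  ed <- apply_sv_to_map(fix_ref, list(list(type = "deletion",
                                           contig = "synth1",
                                           start = 4e5, end = 4.6e5)))
  del_call <- call_svs(list(perfect_consensus(ed$ref)), fix_ref,
                       fix_scoring, fix_null)$calls
  nu2 <- fit_null(ed$ref, fix_scoring, n_draws = 900, seed = 3)
  ins_call <- call_svs(list(perfect_consensus(fix_ref)), ed$ref,
                       fix_scoring, nu2)$calls
  expect_equal(del_call$type, "deletion")
  expect_equal(ins_call$type, "insertion")
  # mirrored up to the flanking-label geometry of the two references
  expect_equal(ins_call$size, -del_call$size, tolerance = 500 / 60000)
})

test_that("the outlier threshold is a strict inequality", {
  sp <- fix_scoring
  pars <- sv_params()
  # two matched pairs spanning one interval with discrepancy D tuned to sit
  # exactly at p = outlier_p
  refspan <- 10000
  sdv <- sqrt(sp$sd0^2 + sp$sd_scale * refspan)
  D_exact <- -qnorm(pars$outlier_p / 2) * sdv
  al <- omsv:::empty_alignment()
  al$pairs <- cbind(qidx = c(1L, 2L), tidx = c(1L, 2L))
  out <- indel_outlier_test(al, query = c(0, refspan + D_exact * (1 - 1e-6)),
                            target_labels = c(0, refspan), sp, pars)
  expect_null(out)  # at/above the cutoff: not reported (strict <)
  out2 <- indel_outlier_test(al, query = c(0, refspan + D_exact * (1 + 1e-4)),
                             target_labels = c(0, refspan), sp, pars)
  expect_false(is.null(out2))
})

test_that("segment geometry classifies inversion and translocations", {
  seg <- function(contig, sign, tidx, qidx, lp = log(1e-40)) {
    s <- omsv:::empty_alignment()
    s$contig <- contig; s$sign <- sign
    s$pairs <- cbind(qidx = qidx, tidx = tidx)
    s$log_p <- lp
    s$q_from <- min(qidx); s$q_to <- max(qidx)
    s
  }
  ref2 <- reference_map(list(
    list(id = "cA", length = 1e7,
         channels = list(seq(5e3, 1e7 - 5e3, by = 6e3))),
    list(id = "cB", length = 1e7,
         channels = list(seq(4e3, 1e7 - 4e3, by = 6e3)))))
  q <- seq(5e3, 3e6, by = 6e3)
  nq <- length(q)
  half <- floor(nq / 2)
  # opposite orientations, same contig -> inversion
  s1 <- seg("cA", 1, 1:half, 1:half)
  s2 <- seg("cA", -1, (half + 60):(half + 1), (half + 1):(half + 60))
  calls <- classify_variant(list(s1, s2), q, ref2, fix_scoring,
                            sv_params(), "m")
  expect_true("inversion" %in% calls$type)
  # different contigs -> inter-chromosomal translocation
  s3 <- seg("cB", 1, 1:60, (half + 1):(half + 60))
  calls2 <- classify_variant(list(s1, s3), q, ref2, fix_scoring,
                             sv_params(), "m")
  expect_true("inter_translocation" %in% calls2$type)
  # same contig, same orientation, 6-Mb reference gap -> intra-chromosomal
  far <- which(ref2$contigs[["cA"]]$channels[[1]] > 6.5e6)[1]
  s4 <- seg("cA", 1, far:(far + 59), (half + 1):(half + 60))
  calls3 <- classify_variant(list(s1, s4), q, ref2, fix_scoring,
                             sv_params(), "m")
  expect_true("intra_translocation" %in% calls3$type)
})

test_that("breakpoint intervals are bounded by flanking labels and query gap", {
  rl <- c(1e4, 2e4, 2.4e4, 5e4)
  iv <- omsv:::flank_interval(2e4, +1, q_gap = 1e4, rl, resolution_bp = 1500)
  expect_equal(unname(iv["lo"]), 2e4)
  expect_equal(unname(iv["hi"]), 2.4e4)  # next resolvable label 4 kb away
  # a narrower query gap tightens the interval below the label spacing
  iv2 <- omsv:::flank_interval(2e4, +1, q_gap = 2e3, rl, resolution_bp = 1500)
  expect_equal(unname(iv2["hi"]), 2.2e4)
  # denser labels -> narrower intervals
  dense <- omsv:::flank_interval(2e4, +1, q_gap = 1e4, c(rl, 2.2e4), 100)
  expect_lte(dense["hi"] - dense["lo"], iv["hi"] - iv["lo"])
})

test_that("dual-enzyme combination intersects intervals and merges sizes", {
  c1 <- omsv:::empty_calls()
  c1[1, ] <- list(1L, "deletion", "c", "c", 100, 600, 5100, 5600, -5000,
                  5000, "hemizygous", log(1e-10), "m1", "", 1L, NA_real_,
                  NA_real_)
  c2 <- c1
  c2$bp1_lo <- 300; c2$bp1_hi <- 900; c2$bp2_lo <- 5200; c2$bp2_hi <- 5900
  c2$size <- -5100
  m <- combine_dual_enzyme(c1, c2)
  expect_equal(nrow(m), 1)
  expect_equal(m$bp1_lo, 300); expect_equal(m$bp1_hi, 600)
  expect_equal(m$bp2_lo, 5200); expect_equal(m$bp2_hi, 5600)
  expect_equal(m$size, -5050)
  expect_lte(m$bp1_hi - m$bp1_lo, c1$bp1_hi - c1$bp1_lo)
  # unmatched calls pass through flagged
  c3 <- c1; c3$bp1_lo <- 9e5; c3$bp1_hi <- 9.1e5
  c3$bp2_lo <- 9.6e5; c3$bp2_hi <- 9.7e5
  m2 <- combine_dual_enzyme(c1, c3)
  expect_equal(nrow(m2), 2)
  expect_true(all(grepl("single_channel", m2$flags)))
})

test_that("zygosity follows ploidy and concordant allele coverage", {
  calls <- omsv:::empty_calls()
  calls[1, ] <- list(1L, "deletion", "chrXr", "chrXr", 1e5, 1.1e5, 2e5,
                     2.1e5, -9e4, 1e5, "unknown", log(1e-10), "var1", "", 1L,
                     NA_real_, NA_real_)
  cov_het <- data.frame(map = c("var1", "wt1"), hap = 0L, contig = "chrXr",
                        t_lo = c(0, 0), t_hi = c(9e5, 9e5),
                        n_segments = c(2L, 1L))
  expect_equal(call_zygosity(calls, cov_het, c(chrXr = 1))$zygosity,
               "hemizygous")
  expect_equal(call_zygosity(calls, cov_het, c(chrXr = 2))$zygosity,
               "heterozygous")
  cov_hom <- cov_het[1, , drop = FALSE]
  expect_equal(call_zygosity(calls, cov_hom, c(chrXr = 2))$zygosity,
               "homozygous")
  expect_equal(call_zygosity(calls, cov_het[0, ], c(chrXr = 2))$zygosity,
               "unknown")
})

test_that("known-SV filtering needs same type and 50% reciprocal overlap", {
  calls <- omsv:::empty_calls()
  calls[1, ] <- list(1L, "deletion", "c", "c", 1e5, 1.05e5, 2e5, 2.05e5,
                     -1e5, 1e5, "unknown", log(1e-10), "m", "", 1L, NA_real_,
                     NA_real_)
  expect_false(filter_known_sv(calls, NULL)$known)
  cat_exact <- data.frame(contig = "c", start = 1e5, end = 2.05e5,
                          type = "deletion")
  expect_true(filter_known_sv(calls, cat_exact)$known)
  cat_40 <- data.frame(contig = "c", start = 1.64e5, end = 3.7e5,
                       type = "deletion")
  expect_false(filter_known_sv(calls, cat_40)$known)
  cat_type <- data.frame(contig = "c", start = 1e5, end = 2.05e5,
                         type = "insertion")
  expect_false(filter_known_sv(calls, cat_type)$known)
})

test_that("SMAP round-trips calls and keeps the loss sign convention", {
  calls <- omsv:::empty_calls()
  calls[1, ] <- list(1L, "deletion", "chrXr", "chrXr", 1e5, 1.1e5, 3e5,
                     3.1e5, -182665, 2e5, "hemizygous", log(1e-20),
                     "map1", "", 1L, NA_real_, NA_real_)
  calls[2, ] <- list(2L, "insertion", "chrXr", "chrXr", 5e5, 5.1e5, 5e5,
                     5.1e5, 12968, 1e4, "heterozygous", log(1e-8),
                     "map2,map3", "single_channel", 1L, NA_real_, NA_real_)
  path <- withr::local_tempfile(fileext = ".smap")
  write_smap(calls, path)
  lines <- readLines(path)
  expect_true(any(grepl("-182665", lines)))  # loss emitted with "-"
  back <- read_smap(path)
  expect_equal(back$type, calls$type)
  expect_equal(back$size, calls$size, tolerance = 0.1)
  expect_equal(back$zygosity, calls$zygosity)
  expect_equal(back$maps, calls$maps)
  expect_equal(back$bp1_lo, calls$bp1_lo, tolerance = 0.1)
  # zero calls -> header-only file that reads back empty
  p2 <- withr::local_tempfile(fileext = ".smap")
  write_smap(omsv:::empty_calls(), p2)
  expect_equal(nrow(read_smap(p2)), 0)
})

test_that("catalog reader skips malformed rows with a warning", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c\t100\t200\tdeletion", "broken line", "c\t500\tXX\tinsertion",
               "c\t900\t1200\tinversion"), path)
  expect_warning(cat <- read_sv_catalog(path), "malformed")
  expect_equal(nrow(cat), 2)
})
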