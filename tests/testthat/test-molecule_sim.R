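# molecule_sim: observation noise chain, coverage accounting, BNX I/O.

test_that("noiseless observation is the identity up to the window shift", {
  pl <- list(molecule_id = 1L, contig = "synth1", start = 2e5, length = 2.5e5,
             strand = "+", hap = 1L)
  set.seed(1)
  m <- observe_molecule(fix_ref, pl, noiseless_model())
  truth <- fix_labels[fix_labels >= 2e5 & fix_labels < 4.5e5] - 2e5
  expect_equal(m$channels[[1]], truth)
  # reverse strand mirrors the label order
  pl$strand <- "-"
  set.seed(1)
  mr <- observe_molecule(fix_ref, pl, noiseless_model())
  expect_equal(mr$channels[[1]], sort(2.5e5 - truth))
})

test_that("label miss and false-label rates match their expectations", {
  model <- error_model(sizing_sd0 = 0, sizing_sd_scale = 0,
                       label_miss_rate = 0.2, false_label_rate = 0,
                       fragile_break_prob = 0, chimera_rate = 0,
                       resolution_limit = 0)
  pl <- list(molecule_id = 1L, contig = "synth1", start = 0, length = 9.9e5,
             strand = "+", hap = 1L)
  n_true <- sum(fix_labels < 9.9e5)
  set.seed(3)
  kept <- replicate(30, length(observe_molecule(fix_ref, pl, model)$channels[[1]]))
  n <- 30 * n_true
  expect_lt(abs(sum(kept) - 0.8 * n), 4 * sqrt(n * 0.8 * 0.2))

  model2 <- error_model(sizing_sd0 = 0, sizing_sd_scale = 0,
                        label_miss_rate = 0, false_label_rate = 2,
                        fragile_break_prob = 0, chimera_rate = 0,
                        resolution_limit = 0)
  set.seed(4)
  tot <- replicate(30, length(observe_molecule(fix_ref, pl, model2)$channels[[1]]))
  lam <- 30 * (n_true + 2 * 9.9e5 / 1e5)
  expect_lt(abs(sum(tot) - lam), 4 * sqrt(lam))
})

test_that("labels within the resolution limit merge into one", {
  ref <- reference_map(list(list(id = "c", length = 1e5,
                                 channels = list(c(1e4, 1.05e4, 5e4)))))
  pl <- list(molecule_id = 1L, contig = "c", start = 0, length = 1e5,
             strand = "+", hap = 1L)
  model <- error_model(sizing_sd0 = 0, sizing_sd_scale = 0,
                       label_miss_rate = 0, false_label_rate = 0,
                       fragile_break_prob = 0, chimera_rate = 0,
                       resolution_limit = 1500)
  set.seed(5)
  m <- observe_molecule(ref, pl, model)
  expect_equal(m$channels[[1]], c(1.025e4, 5e4))
})

test_that("fragile breakage truncates only at fragile sites", {
  ref <- reference_map(list(list(id = "c", length = 5e5,
                                 channels = list(seq(1e4, 4.9e5, by = 1e4)))))
  ref$contigs[[1]]$fragile <- 2.5e5
  model <- error_model(sizing_sd0 = 0, sizing_sd_scale = 0,
                       label_miss_rate = 0, false_label_rate = 0,
                       fragile_break_prob = 1, chimera_rate = 0,
                       resolution_limit = 0)
  pl <- list(molecule_id = 1L, contig = "c", start = 0, length = 5e5,
             strand = "+", hap = 1L)
  set.seed(6)
  m <- observe_molecule(ref, pl, model)
  expect_equal(m$length, 2.5e5)
  expect_true(all(m$channels[[1]] < 2.5e5))
  # no fragile sites in the window: no truncation
  pl2 <- list(molecule_id = 1L, contig = "c", start = 2.6e5, length = 2e5,
              strand = "+", hap = 1L)
  set.seed(7)
  expect_equal(observe_molecule(ref, pl2, model)$length, 2e5)
})

test_that("draw_molecule_lengths meets its stopping and truncation contracts", {
  pl <- draw_molecule_lengths(10, list(fix_ref), mean_length = 2e5,
                              min_length = 1.5e5, seed = 21)
  tot <- sum(pl$length)
  expect_gte(tot, 10 * 1e6)
  expect_lt(tot, 10 * 1e6 + max(pl$length) + 1)
  expect_true(all(pl$length >= pmin(1.5e5, 1e6)))
  big <- draw_molecule_lengths(400, list(fix_ref), mean_length = 2e5,
                               min_length = 1e5, seed = 22)
  expect_lt(abs(mean(big$length) - 2e5) / 2e5, 0.12)
})

test_that("per-molecule substreams make molecule k batch-size invariant", {
  r1 <- simulate_run(fix_ref, error_model(), coverage = 2, seed = 31)
  r2 <- simulate_run(fix_ref, error_model(), coverage = 4, seed = 31)
  for (k in seq_along(r1$molecules))
    expect_identical(r1$molecules[[k]], r2$molecules[[k]])
  expect_lt(abs(r2$summary$raw_coverage - 4), max(r2$molecules[[1]]$length,
                                                  4e5) / 1e6)
})

test_that("effective coverage follows its defining arithmetic", {
  expect_equal(effective_coverage(320e9, 3.2e9, 0.7), 70)
  expect_equal(effective_coverage(5e9, 3.2e9, 0), 0)
  expect_equal(effective_coverage(4.8e9, 3.2e9, 1), 1.5)
  expect_error(effective_coverage(-1, 3.2e9, 0.5), "non-negative")
  expect_error(effective_coverage(1e9, 0, 0.5), "positive")
  expect_error(effective_coverage(1e9, 3.2e9, 1.2), "0, 1")
})

test_that("BNX round-trips molecules with optional truth sidecar", {
  run <- simulate_run(fix_ref, error_model(), coverage = 1, seed = 41)
  path <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(run$molecules[1:3], path)
  back <- read_bnx(path)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$channels[[1]],
                 round(run$molecules[[k]]$channels[[1]], 1))
    expect_equal(back[[k]]$origin$start,
                 round(run$molecules[[k]]$origin$start, 1))
    expect_equal(back[[k]]$origin$hap, run$molecules[[k]]$origin$hap)
  }
  # without truth sidecar, molecules load with empty origin
  path2 <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(run$molecules[1:2], path2, truth = FALSE)
  back2 <- read_bnx(path2)
  expect_null(back2[[1]]$origin)
  # zero-label molecule is a valid record
  zl <- structure(list(id = "z", length = 1e5, channels = list(numeric(0)),
                       origin = NULL), class = "om_molecule")
  path3 <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(list(zl), path3)
  expect_equal(length(read_bnx(path3)[[1]]$channels[[1]]), 0)
  # malformed rows are rejected with a line number
  lines <- readLines(path)
  lines[3] <- "0\tbroken"
  bad <- withr::local_tempfile(fileext = ".bnx")
  writeLines(lines, bad)
  expect_error(read_bnx(bad), "line")
})
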