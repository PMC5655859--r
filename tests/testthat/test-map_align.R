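# map_align: DP kernel vs brute force, orientation symmetry, empirical
# null calibration, filtering semantics.

test_that("self-alignment matches all labels with zero residuals", {
  q <- fix_labels[1:30]
  al <- align_maps(q, q, fix_scoring)
  expect_equal(nrow(al$pairs), 30)
  expect_equal(al$orientation, "+")
  expect_true(all(abs(al$residuals) < 1e-9))
})

test_that("mirror alignment matches in - orientation with equal score", {
  q <- fix_labels[5:25] - fix_labels[5]
  L <- max(q)
  qm <- sort(L - q)
  fwd <- align_maps(q, q, fix_scoring, qlen = L)
  rev <- align_maps(qm, q, fix_scoring, qlen = L)
  expect_equal(rev$orientation, "-")
  expect_equal(rev$score, fwd$score, tolerance = 1e-9)
  expect_equal(nrow(rev$pairs), nrow(fwd$pairs))
  # matched pairs are decreasing in target for "-" orientation
  expect_true(all(diff(rev$pairs[, "tidx"]) < 0))
})

test_that("DP equals brute-force enumeration on small random instances", {
  set.seed(99)
  for (rep in 1:200) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    q <- cumsum(runif(m, 2000, 15000))
    t <- cumsum(runif(n, 2000, 15000))
    al <- align_maps(q, t, fix_scoring, orientation = "+")
    expect_equal(al$score, brute_align_score(q, t, fix_scoring),
                 tolerance = 1e-6, info = paste("instance", rep))
  }
})

test_that("fewer than two labels yields the empty-alignment sentinel", {
  al <- align_maps(numeric(0), fix_labels, fix_scoring)
  expect_equal(al$score, -Inf)
  expect_equal(nrow(al$pairs), 0)
})

test_that("null fit is seed-deterministic and its P-values are calibrated", {
  n1 <- fit_null(fix_ref, fix_scoring, n_draws = 900, seed = 2)
  expect_identical(n1$buckets, fix_null$buckets)
  # monotone: higher score, smaller p
  ps <- vapply(seq(10, 120, by = 5), alignment_pvalue, 1,
               n_labels = 25, null = fix_null)
  expect_true(all(diff(ps) < 0))
  # score at the null median gives p near 0.5
  mb <- omsv:::null_mu_beta(fix_null, 20)
  med_score <- mb["mu"] - mb["beta"] * log(log(2))
  expect_lt(abs(alignment_pvalue(med_score, 20, fix_null) - 0.5), 0.05)
  # held-out shuffled queries exceed the fitted 99th percentile ~1% of the
  # time, and essentially never reach p < 1e-12
  iv <- diff(fix_labels)
  set.seed(77)
  exceed <- 0L; tiny <- 0L; ndr <- 400L
  for (d in seq_len(ndr)) {
    s <- sample.int(length(iv) - 20, 1)
    qq <- cumsum(c(0, sample(iv[s:(s + 19)])))
    al <- align_maps(qq, fix_labels, fix_scoring, null = fix_null)
    if (!is.na(al$log_p) && al$log_p < log(0.01)) exceed <- exceed + 1L
    if (!is.na(al$log_p) && al$log_p < log(1e-12)) tiny <- tiny + 1L
  }
  expect_lt(abs(exceed - 0.01 * ndr), 4 * sqrt(ndr * 0.01 * 0.99) + 1)
  expect_equal(tiny, 0L)
  degenerate <- reference_map(list(list(id = "d", length = 5e4,
                                        channels = list(c(1e4, 2e4, 3e4)))))
  expect_error(fit_null(degenerate), "sparse")
  expect_error(alignment_pvalue(10, 20, list()), "not fitted")
})

test_that("a strong self-alignment is far beyond the 1e-12 cutoff", {
  q <- fix_labels[10:29] - fix_labels[10]
  al <- align_maps(q, fix_labels, fix_scoring, null = fix_null)
  expect_lt(al$log_p, log(1e-12))
})

test_that("noiseless molecules recover their placement exactly", {
  run <- simulate_run(fix_ref, noiseless_model(), coverage = 3, seed = 51)
  ok <- 0L; tot <- 0L
  for (m in run$molecules) {
    if (length(m$channels[[1]]) < 8) next
    tot <- tot + 1L
    al <- align_maps(m$channels[[1]], fix_labels, fix_scoring,
                     qlen = m$length, null = fix_null)
    est_start <- if (al$orientation == "+") al$offset else al$offset - m$length
    if (abs(est_start - m$origin$start) < 1) ok <- ok + 1L
  }
  expect_gt(tot, 10)
  expect_equal(ok, tot)
})

test_that("filter_best_alignments applies cutoff and overlap dominance", {
  mk <- function(lp, tstart, tend, tspan = tend - tstart) {
    a <- omsv:::empty_alignment("q", "t")
    a$log_p <- lp; a$tstart <- tstart; a$tend <- tend
    a$tspan <- tspan; a$score <- 1
    a
  }
  none <- filter_best_alignments(list(mk(log(1e-3), 0, 10)), cutoff = 1e-12)
  expect_length(none, 0)
  one <- filter_best_alignments(list(mk(log(1e-20), 0, 10)), cutoff = 1e-12)
  expect_length(one, 1)
  both <- filter_best_alignments(list(mk(log(1e-15), 0, 10),
                                      mk(log(1e-20), 5, 15)),
                                 cutoff = 1e-12)
  expect_length(both, 1)
  expect_equal(both[[1]]$log_p, log(1e-20))
})
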