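# reference_maps: in-silico digestion, Poisson references, SV editing,
# CMAP round trips.

test_that("digest_sequence agrees with a brute-force IUPAC scan", {
  expect_identical(digest_sequence("", enzyme_spec("e", "GCTCTTC")),
                   numeric(0))
  # single plus-strand occurrence at 1-based position 3 (0-based 2)
  ez <- enzyme_spec("bspq", "GCTCTTC", both_strands = FALSE)
  expect_equal(digest_sequence("AAGCTCTTCAA", ez), 2)
  set.seed(41)
  motifs <- c("GCTCTTC", "CACGAG", "GANTC", "RGATCY")
  for (mo in motifs) {
    seq <- random_dna(5000)
    for (bs in c(TRUE, FALSE)) {
      got <- digest_sequence(seq, enzyme_spec("x", mo, both_strands = bs))
      expect_equal(got, as.numeric(brute_digest(seq, mo, bs)),
                   info = paste(mo, bs))
    }
  }
})

test_that("both-strand digestion is symmetric on seq + revcomp(seq)", {
  set.seed(7)
  seq <- random_dna(3000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  ez <- enzyme_spec("x", "GCTCTTC", both_strands = TRUE)
  lab <- digest_sequence(paste0(seq, rc), ez)
  # motif occurrences mirror about the junction: site p pairs with
  # 2n - len(motif) - p
  n <- nchar(seq)
  mirrored <- sort(2 * n - nchar("GCTCTTC") - lab)
  expect_equal(sort(lab), mirrored)
})

test_that("digest rejects non-nucleotide input and bad motifs", {
  expect_error(digest_sequence("ACGTX", enzyme_spec("e", "GCTC")),
               "non-nucleotide")
  expect_error(enzyme_spec("e", ""), "non-empty")
  expect_error(enzyme_spec("e", "GC1T"), "non-IUPAC")
})

test_that("poisson_reference is seeded, calibrated, and exponential", {
  r1 <- poisson_reference(1e6, 6000, seed = 5)
  r2 <- poisson_reference(1e6, 6000, seed = 5)
  expect_identical(r1, r2)
  n <- length(r1$contigs[[1]]$channels[[1]])
  lambda <- 1e6 / 6000
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))
  big <- poisson_reference(1e7, 6000, seed = 6)
  sp <- diff(big$contigs[[1]]$channels[[1]])
  expect_lt(abs(mean(sp) - 6000) / 6000, 0.10)
  ks <- ks.test(sp, "pexp", rate = 1 / mean(sp))
  expect_gt(ks$p.value, 0.01)
  expect_error(poisson_reference(1e6, -5), "positive")
  expect_error(poisson_reference(10000, 6000), "twice")
})

test_that("apply_sv_to_map does exact coordinate arithmetic", {
  ref <- poisson_reference(1e6, 5000, seed = 9)
  lab <- ref$contigs[[1]]$channels[[1]]
  del <- apply_sv_to_map(ref, list(list(type = "deletion", contig = "synth1",
                                        start = 4e5, end = 45e4)))
  lab2 <- del$ref$contigs[[1]]$channels[[1]]
  downstream <- lab[lab >= 45e4]
  expect_equal(lab2[lab2 >= 4e5], downstream - 5e4)
  expect_equal(del$ref$contigs[[1]]$length, 1e6 - 5e4)
  expect_equal(del$truth$size, -5e4)

  inv <- apply_sv_to_map(ref, list(list(type = "inversion", contig = "synth1",
                                        start = 2e5, end = 7e5)))
  back <- apply_sv_to_map(inv$ref, list(list(type = "inversion",
                                             contig = "synth1",
                                             start = 2e5, end = 7e5)))
  expect_equal(back$ref$contigs[[1]]$channels[[1]], lab)
  expect_equal(length(inv$ref$contigs[[1]]$channels[[1]]), length(lab))

  dup <- apply_sv_to_map(ref, list(list(type = "insertion", contig = "synth1",
                                        start = 3e5, end = 3e5 + 12968)))
  expect_equal(dup$ref$contigs[[1]]$length, 1e6 + 12968)

  expect_error(apply_sv_to_map(ref, list(
    list(type = "deletion", contig = "synth1", start = 1e5, end = 3e5),
    list(type = "deletion", contig = "synth1", start = 2e5, end = 4e5))),
    "overlap")
  expect_error(apply_sv_to_map(ref, list(list(type = "deletion",
                                              contig = "synth1",
                                              start = 9e5, end = 2e6))),
               "outside")
})

test_that("CMAP round-trips exactly at emitted precision", {
  path <- withr::local_tempfile(fileext = ".cmap")
  ref <- poisson_reference(2e5, 6000, n_channels = 2, seed = 13)
  write_cmap(ref, path)
  back <- read_cmap(path)
  for (ch in 1:2)
    expect_equal(back$contigs[[1]]$channels[[ch]],
                 round(ref$contigs[[1]]$channels[[ch]], 1))
  # shuffled position column violates monotonicity and is rejected
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  lines[body[2:3]] <- lines[body[3:2]]
  bad <- withr::local_tempfile(fileext = ".cmap")
  writeLines(lines, bad)
  expect_error(read_cmap(bad), "increasing")
  # malformed column count names the line
  lines2 <- readLines(path)
  lines2[body[1]] <- "oops\t1"
  bad2 <- withr::local_tempfile(fileext = ".cmap")
  writeLines(lines2, bad2)
  expect_error(read_cmap(bad2), "line")
})

test_that("an empty channel writes a valid header-only map", {
  path <- withr::local_tempfile(fileext = ".cmap")
  ref <- reference_map(list(list(id = "c1", length = 5e4,
                                 channels = list(numeric(0)))))
  write_cmap(ref, path)
  back <- read_cmap(path)
  expect_equal(length(back$contigs[[1]]$channels[[1]]), 0)
  expect_equal(back$contigs[[1]]$length, 5e4)
})
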