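# assembler: OLC stages on constructed and simulated fixtures.

make_mol <- function(id, labels, length, hap = 1L, start = 0) {
  structure(list(id = id, length = length, channels = list(labels),
                 origin = list(contig = "synth1", start = start,
                               strand = "+", hap = hap, chimera = FALSE)),
            class = "om_molecule")
}

test_that("staggered noiseless molecules form a path graph with true offsets", {
  # three molecules tiling [0, 300k], [100k, 400k], [200k, 500k]
  lab <- thin_labels(fix_labels[fix_labels < 5e5])
  mols <- lapply(0:2, function(k) {
    a <- k * 1e5
    make_mol(k + 1, lab[lab >= a & lab < a + 3e5] - a, 3e5, start = a)
  })
  pa <- assembly_params(min_overlap_bp = 1e5)
  g <- pairwise_overlap_graph(mols, pa, fix_scoring, fix_null)
  expect_gte(nrow(g$edges), 2)  # adjacent pairs overlap 200 kb
  e12 <- g$edges[g$edges$i == 1 & g$edges$j == 2, ]
  expect_equal(e12$sign, 1)
  expect_lt(abs(e12$offset - (-1e5)), 1)  # x_2 = x_1 - 100k
  cons <- layout_and_initial_consensus(g, mols, pa, fix_scoring, fix_null)
  expect_length(cons, 1)
  expect_equal(diff(range(cons[[1]]$sites)), diff(range(lab)), tolerance = 1)
})

test_that("disjoint molecules get no edge", {
  lab <- thin_labels(fix_labels)
  m1 <- make_mol(1, lab[lab < 3e5], 3e5)
  m2 <- make_mol(2, lab[lab >= 6e5 & lab < 9e5] - 6e5, 3e5, start = 6e5)
  g <- pairwise_overlap_graph(list(m1, m2), assembly_params(), fix_scoring,
                              fix_null)
  expect_equal(nrow(g$edges), 0)
})

test_that("assembling exact copies of a map returns that map", {
  lab <- thin_labels(fix_labels[fix_labels < 4e5])
  mols <- lapply(1:6, function(k) make_mol(k, lab, 4e5))
  pa <- assembly_params(min_sites = 5)
  asm <- run_assembly(mols, pa, fix_scoring, fix_null)
  expect_length(asm$consensi, 1)
  sites <- asm$consensi[[1]]$sites
  expect_equal(length(sites), length(lab))
  expect_equal(diff(sites), diff(lab), tolerance = 0.5)
  expect_true(all(asm$consensi[[1]]$support >= 6 - 1L))
})

test_that("the driver logs exactly five extend-and-merge rounds by default", {
  lab <- thin_labels(fix_labels[fix_labels < 4e5])
  mols <- lapply(1:6, function(k) make_mol(k, lab, 4e5))
  asm <- run_assembly(mols, assembly_params(min_sites = 5), fix_scoring,
                      fix_null)
  expect_equal(sum(grepl("^extend_merge_", asm$stage_log$stage)), 5L)
})

test_that("extension grows a map to the span its molecules support", {
  lab <- thin_labels(fix_labels[fix_labels < 3e5])
  inner <- lab[lab >= 5e4 & lab < 2.5e5]
  cons <- omsv:::new_consensus("m1", inner, rep(5L, length(inner)),
                               mol_frames = data.frame(mol = 1:6, sign = 1,
                                                       offset = 0))
  mols <- lapply(1:6, function(k) make_mol(k, lab, 3e5))
  pa <- assembly_params(min_label_support = 3)
  ext <- omsv:::extend_one(cons, mols, pa, fix_scoring, fix_null)
  expect_gte(length(ext$sites), length(lab) - 2)
  expect_equal(diff(range(ext$sites)), diff(range(lab)), tolerance = 1)
})

test_that("same-locus maps merge; disjoint maps never merge", {
  lab1 <- fix_labels[fix_labels < 3e5]
  lab2 <- fix_labels[fix_labels >= 5e5 & fix_labels < 8e5] - 5e5
  c1 <- omsv:::new_consensus("a", lab1, rep(10L, length(lab1)))
  c2 <- omsv:::new_consensus("b", lab1 + 3, rep(4L, length(lab1)))
  c3 <- omsv:::new_consensus("c", lab2, rep(10L, length(lab2)))
  pa <- assembly_params()
  merged <- omsv:::merge_consensi(list(c1, c2, c3), pa, fix_scoring, fix_null)
  expect_length(merged, 2)
  spans <- sort(vapply(merged, function(k) diff(range(k$sites)), 1))
  expect_equal(spans, sort(c(diff(range(lab1)), diff(range(lab2)))),
               tolerance = 5)
})

test_that("a planted chimeric molecule is excluded from the consensus", {
  lab <- thin_labels(fix_labels)
  left <- lab[lab < 3e5]
  # chimera joins two unrelated loci
  chim_lab <- c(left[left < 1.5e5],
                1.5e5 + (lab[lab >= 7e5 & lab < 8.5e5] - 7e5))
  mols <- c(lapply(1:8, function(k) make_mol(k, left, 3e5)),
            list(make_mol(9L, chim_lab, 3e5)))
  pa <- assembly_params(min_sites = 5)
  asm <- run_assembly(mols, pa, fix_scoring, fix_null)
  main <- asm$consensi[[which.max(vapply(asm$consensi, function(k)
    length(k$sites), 1L))]]
  expect_equal(diff(range(main$sites)), diff(range(left)), tolerance = 5)
})

test_that("concordant molecules produce no extra maps via extend-and-split", {
  lab <- thin_labels(fix_labels[fix_labels < 4e5])
  mols <- lapply(1:8, function(k) make_mol(k, lab, 4e5))
  pa <- assembly_params(min_sites = 5)
  asm <- run_assembly(mols, pa, fix_scoring, fix_null)
  expect_length(asm$consensi, 1)
})

test_that("haplotype split fires on bimodal span residuals only", {
  pa <- assembly_params()
  sites <- seq(0, 3e5, by = 1e4)
  cons <- omsv:::new_consensus("h", sites, rep(20L, length(sites)))
  # homozygous: pure sizing noise never splits (20 seeded replicates)
  for (s in 1:20) {
    set.seed(s)
    resids <- lapply(seq_len(length(sites) - 1), function(k)
      cbind(mol = 1:16, r = rnorm(16, 0, 350)))
    expect_null(omsv:::detect_haplotype_locus(cons, resids, pa, fix_scoring),
                label = sprintf("seed %d", s))
  }
  # heterozygous 13-kb insertion signature at one interval: bimodal
  set.seed(101)
  resids <- lapply(seq_len(length(sites) - 1), function(k)
    cbind(mol = 1:16, r = rnorm(16, 0, 350)))
  resids[[15]] <- cbind(mol = 1:16,
                        r = c(rnorm(8, 0, 350), rnorm(8, 12968, 350)))
  loc <- omsv:::detect_haplotype_locus(cons, resids, pa, fix_scoring)
  expect_false(is.null(loc))
  expect_equal(loc$site, 15)
  expect_lt(abs(loc$sep - 12968), 600)
})

test_that("assembly is deterministic for identical inputs", {
  run <- simulate_run(fix_ref, error_model(), coverage = 12, seed = 61)
  a1 <- run_assembly(run$molecules, assembly_params(), fix_scoring, fix_null)
  a2 <- run_assembly(run$molecules, assembly_params(), fix_scoring, fix_null)
  expect_equal(a1$consensi, a2$consensi)
})

test_that("label support equals the number of clustering member molecules", {
  lab <- thin_labels(fix_labels[fix_labels < 3e5])
  mols <- lapply(1:5, function(k) make_mol(k, lab, 3e5))
  pa <- assembly_params(min_sites = 5)
  asm <- run_assembly(mols, pa, fix_scoring, fix_null)
  cons <- asm$consensi[[1]]
  expect_true(all(cons$support <= 5))
  expect_true(all(cons$support >= 4))
})
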