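# Shared fixtures, built once per suite. Kept small: a 1-Mb synthetic
# reference and a null model fitted on it cover most alignment tests.

fix_scoring <- scoring_params()

fix_ref <- poisson_reference(1e6, 6000, n_channels = 1, seed = 11)
fix_labels <- fix_ref$contigs[[1]]$channels[[1]]

fix_null <- fit_null(fix_ref, fix_scoring, n_draws = 900, seed = 2)

# brute-force motif scan oracle (IUPAC-aware), independent of Biostrings
iupac_tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

brute_digest <- function(seq, motif, both_strands = TRUE) {
  seq <- toupper(seq); motif <- toupper(motif)
  revcomp <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  scan1 <- function(pat) {
    sc <- strsplit(seq, "")[[1]]
    pc <- strsplit(pat, "")[[1]]
    m <- length(pc); n <- length(sc)
    if (n < m) return(integer(0))
    hits <- integer(0)
    for (off in 0:(n - m)) {
      ok <- TRUE
      for (k in seq_len(m)) {
        if (!sc[off + k] %in% iupac_tab[[pc[k]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, off)  # 0-based
    }
    hits
  }
  hits <- scan1(motif)
  if (both_strands) hits <- c(hits, scan1(revcomp(motif)))
  sort(unique(hits))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# brute-force alignment oracle: enumerate all monotone matchings of two
# small label maps (forward orientation) and return the best score under
# the same scoring scheme as the DP
brute_align_score <- function(q, t, sp) {
  m <- length(q); n <- length(t)
  best <- -Inf
  rec <- function(i, j, prev_i, prev_j, score, npairs) {
    if (npairs >= 1 && score > best) best <<- score
    if (i > m || j > n) return()
    for (ii in i:m) for (jj in j:n) {
      add <- sp$match_bonus
      if (npairs >= 1) {
        if (ii - prev_i - 1 > sp$max_skip - 1 ||
            jj - prev_j - 1 > sp$max_skip - 1) next
        dq <- q[ii] - q[prev_i]; dt <- t[jj] - t[prev_j]
        v <- max(sp$sd0^2 + sp$sd_scale * dt, 1)
        add <- add - (dq - dt)^2 / (2 * v) -
          (ii - prev_i - 1) * sp$false_penalty -
          (jj - prev_j - 1) * sp$miss_penalty
      }
      rec(ii + 1L, jj + 1L, ii, jj, score + add, npairs + 1L)
    }
  }
  rec(1L, 1L, 0L, 0L, 0, 0L)
  best
}

# drop labels closer than `gap` to their predecessor (greedy), so consensus
# formation cannot merge distinct fixture labels
thin_labels <- function(x, gap = 1600) {
  keep <- c(TRUE, diff(x) > gap)
  while (any(!keep)) {
    x <- x[keep]
    keep <- c(TRUE, diff(x) > gap)
  }
  x
}

# lazily computed full-cohort run shared by the acceptance blocks
acceptance_cache <- new.env()
cohort_run <- function() {
  if (is.null(acceptance_cache$res)) {
    acceptance_cache$co <- build_cohort(seed = 1)
    acceptance_cache$res <- run_cohort(acceptance_cache$co,
                                       pipeline_config(seed = 1),
                                       verbose = FALSE)
  }
  list(co = acceptance_cache$co, res = acceptance_cache$res)
}
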