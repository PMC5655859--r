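# molecule_sim module: generative model for nick-labeled long molecules.
#
# Noise chain per molecule: fragile-site truncation -> label miss ->
# interval sizing jitter -> false labels -> optical resolution merge ->
# (optionally) chimeric junction with an unrelated fragment.

#' Parametric molecule error model
#'
#' @param sizing_sd0 Baseline interval-noise SD (bp): an observed interval of
#'   true length L gets Gaussian noise with variance
#'   `sizing_sd0^2 + sizing_sd_scale * L`.
#' @param sizing_sd_scale Linear growth of interval variance with length
#'   (bp^2 per bp).
#' @param label_miss_rate Probability a true nick site is unlabeled.
#' @param false_label_rate Expected spurious labels per 100 kb.
#' @param fragile_break_prob Probability the molecule breaks at a fragile
#'   site (opposite-strand nick pair closer than the fragile window).
#' @param fragile_window Fragile-site window (bp); used at digestion time.
#' @param chimera_rate Probability a molecule is an artifactual junction of
#'   two unrelated fragments.
#' @param resolution_limit Labels closer than this (bp) merge into one
#'   observed label.
#' @return An object of class `om_error_model`.
#' @export
error_model <- function(sizing_sd0 = 100, sizing_sd_scale = 12,
                        label_miss_rate = 0.10, false_label_rate = 0.8,
                        fragile_break_prob = 0.5, fragile_window = 1000,
                        chimera_rate = 0.01, resolution_limit = 1500) {
  rates <- c(label_miss_rate, false_label_rate / 1e5, fragile_break_prob,
             chimera_rate)
  if (any(rates < 0) || label_miss_rate > 1 || fragile_break_prob > 1 ||
      chimera_rate > 1)
    stop_om("error-model rates must be probabilities / non-negative")
  if (sizing_sd0 < 0 || sizing_sd_scale < 0 || fragile_window < 0 ||
      resolution_limit < 0)
    stop_om("error-model SDs and windows must be non-negative")
  structure(list(sizing_sd0 = sizing_sd0, sizing_sd_scale = sizing_sd_scale,
                 label_miss_rate = label_miss_rate,
                 false_label_rate = false_label_rate,
                 fragile_break_prob = fragile_break_prob,
                 fragile_window = fragile_window, chimera_rate = chimera_rate,
                 resolution_limit = resolution_limit),
            class = "om_error_model")
}

#' A zero-noise error model (identity observation)
#' @return An `om_error_model` with all error rates zero.
#' @export
noiseless_model <- function() {
  error_model(sizing_sd0 = 0, sizing_sd_scale = 0, label_miss_rate = 0,
              false_label_rate = 0, fragile_break_prob = 0, chimera_rate = 0,
              resolution_limit = 0)
}

#' Draw molecule lengths and placements for a target raw coverage
#'
#' Lengths are log-normal (configured mean/spread) truncated below at
#' `min_length`; placements are uniform over haplotypes and contigs.
#' Molecules accumulate until total length reaches
#' `target_raw_coverage * genome_size`. Each molecule's draws come from its
#' own seed substream, so molecule k is identical regardless of batch size.
#'
#' @param target_raw_coverage Raw (pre-map-rate) fold coverage.
#' @param haplotypes List of `om_ref` objects (one per haplotype copy).
#' @param mean_length Mean molecule length (bp).
#' @param min_length Minimum-length filter (bp).
#' @param sdlog Log-scale SD of the length distribution.
#' @param seed Integer master seed.
#' @return data.frame with columns molecule_id, hap, contig, start, length,
#'   strand.
#' @export
draw_molecule_lengths <- function(target_raw_coverage, haplotypes,
                                  mean_length = 250e3, min_length = 150e3,
                                  sdlog = 0.45, seed = 1) {
  stopifnot(target_raw_coverage > 0)
  hap_sizes <- vapply(haplotypes, function(h)
    sum(vapply(h$contigs, function(ct) ct$length, 1)), 1)
  genome_size <- mean(hap_sizes)
  if (any(vapply(haplotypes, function(h)
    min(vapply(h$contigs, function(ct) ct$length, 1)), 1) < min_length))
    stop_om("a contig is shorter than the minimum molecule length")
  meanlog <- log(mean_length) - sdlog^2 / 2
  target <- target_raw_coverage * genome_size
  out <- vector("list", 2048L)
  total <- 0; k <- 0L
  while (total < target) {
    k <- k + 1L
    rec <- with_seed(derive_seed(seed, k, salt = 23L), {
      len <- rlnorm(1, meanlog, sdlog)
      tries <- 0L
      while (len < min_length && tries < 200L) {
        len <- rlnorm(1, meanlog, sdlog); tries <- tries + 1L
      }
      hap <- sample.int(length(haplotypes), 1L,
                        prob = hap_sizes / sum(hap_sizes))
      ctgs <- haplotypes[[hap]]$contigs
      clens <- vapply(ctgs, function(ct) ct$length, 1)
      ci <- sample.int(length(ctgs), 1L, prob = clens / sum(clens))
      len <- min(len, clens[ci])
      start <- runif(1, 0, clens[ci] - len)
      strand <- if (runif(1) < 0.5) "+" else "-"
      list(molecule_id = k, hap = hap, contig = ctgs[[ci]]$id,
           start = start, length = len, strand = strand)
    })
    total <- total + rec$length
    if (k > length(out)) out <- c(out, vector("list", length(out)))
    out[[k]] <- rec
  }
  do.call(rbind, lapply(out[seq_len(k)], as.data.frame))
}

#' Observe one molecule under the error model
#'
#' Extracts the true labels of the placement window, applies strand flip,
#' fragile-site truncation, label miss, interval sizing noise, false labels
#' and the optical resolution merge. RNG state is taken as-is; callers seed.
#'
#' @param ref `om_ref` (the haplotype the molecule comes from).
#' @param placement List/row with contig, start, length, strand.
#' @param model `om_error_model`.
#' @param channels Which reference channels to observe.
#' @return List of class `om_molecule`: id, length, channels (label position
#'   vectors, bp from molecule start), origin (hidden truth).
#' @export
observe_molecule <- function(ref, placement, model, channels = NULL) {
  ct <- ref$contigs[[as.character(placement$contig)]]
  if (is.null(ct)) stop_om("placement on unknown contig")
  channels <- channels %||% seq_along(ct$channels)
  a <- placement$start; len <- placement$length
  stopifnot(a >= 0, a + len <= ct$length + 1e-6)
  minus <- identical(placement$strand, "-")
  # fragile truncation (shared across channels: it breaks the backbone)
  obs_len <- len
  if (model$fragile_break_prob > 0 && length(ct$fragile)) {
    fr <- ct$fragile[ct$fragile > a & ct$fragile < a + len] - a
    if (minus) fr <- sort(len - fr)
    if (length(fr)) {
      hit <- which(runif(length(fr)) < model$fragile_break_prob)
      if (length(hit)) obs_len <- fr[hit[1]]
    }
  }
  out_ch <- lapply(channels, function(k) {
    lab <- ct$channels[[k]]
    rel <- lab[lab >= a & lab < a + len] - a
    if (minus) rel <- rev(len - rel)
    rel <- rel[rel < obs_len]
    # label miss
    if (model$label_miss_rate > 0 && length(rel))
      rel <- rel[runif(length(rel)) >= model$label_miss_rate]
    # sizing noise on inter-label intervals (first interval: start -> label)
    if (model$sizing_sd0 > 0 || model$sizing_sd_scale > 0) {
      if (length(rel)) {
        iv <- diff(c(0, rel))
        sdv <- sqrt(model$sizing_sd0^2 + model$sizing_sd_scale * iv)
        iv <- pmax(iv + rnorm(length(iv), 0, sdv), 1)
        rel <- cumsum(iv)
        rel <- rel[rel < obs_len]
      }
    }
    # false labels: Poisson along the backbone
    if (model$false_label_rate > 0) {
      nf <- rpois(1, model$false_label_rate * obs_len / 1e5)
      if (nf > 0) rel <- sort(c(rel, runif(nf, 0, obs_len)))
    }
    # optical resolution merge
    if (model$resolution_limit > 0 && length(rel) > 1) {
      cl <- cluster_1d(rel, model$resolution_limit)
      rel <- as.numeric(tapply(rel, cl, mean))
    }
    sort(rel[rel > 0 & rel < obs_len])
  })
  structure(list(id = placement$molecule_id %||% NA_integer_,
                 length = obs_len, channels = out_ch,
                 origin = list(contig = as.character(placement$contig),
                               start = a, strand = placement$strand %||% "+",
                               hap = placement$hap %||% 1L, chimera = FALSE)),
            class = "om_molecule")
}

#' Simulate a full labeling run
#'
#' Composes [draw_molecule_lengths()] and [observe_molecule()]; with
#' probability `chimera_rate` a molecule is replaced by a junction of two
#' unrelated fragments. Deterministic under `seed`.
#'
#' @param haplotypes `om_ref` or list of `om_ref` (haplotype copies).
#' @param model `om_error_model`.
#' @param coverage Target raw fold coverage (pre map-rate).
#' @param seed Integer master seed.
#' @param channels Reference channels to observe (default: all).
#' @param mean_length,min_length,sdlog Molecule length distribution.
#' @return List of class `om_run`: molecules (list of `om_molecule`) and
#'   summary (total_bases, molecule_count, raw_coverage, genome_size,
#'   map_rate = NA until alignment).
#' @export
simulate_run <- function(haplotypes, model = error_model(), coverage = 40,
                         seed = 1, channels = NULL, mean_length = 250e3,
                         min_length = 150e3, sdlog = 0.45) {
  if (inherits(haplotypes, "om_ref")) haplotypes <- list(haplotypes)
  pl <- draw_molecule_lengths(coverage, haplotypes, mean_length, min_length,
                              sdlog, seed)
  genome_size <- mean(vapply(haplotypes, function(h)
    sum(vapply(h$contigs, function(ct) ct$length, 1)), 1))
  mols <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    mols[[i]] <- with_seed(derive_seed(seed, p$molecule_id, salt = 31L), {
      m <- observe_molecule(haplotypes[[p$hap]], p, model, channels)
      if (model$chimera_rate > 0 && runif(1) < model$chimera_rate) {
        # junction of two unrelated fragments: re-place half the length
        hap2 <- sample.int(length(haplotypes), 1L)
        ctgs <- haplotypes[[hap2]]$contigs
        ci <- sample.int(length(ctgs), 1L)
        len2 <- min(p$length / 2, ctgs[[ci]]$length / 2)
        st2 <- runif(1, 0, ctgs[[ci]]$length - len2)
        p2 <- list(molecule_id = p$molecule_id, contig = ctgs[[ci]]$id,
                   start = st2, length = len2,
                   strand = if (runif(1) < 0.5) "+" else "-", hap = hap2)
        m2 <- observe_molecule(haplotypes[[hap2]], p2, model, channels)
        cut <- m$length / 2
        m$channels <- lapply(seq_along(m$channels), function(k)
          c(m$channels[[k]][m$channels[[k]] < cut], cut + m2$channels[[k]]))
        m$length <- cut + m2$length
        m$origin$chimera <- TRUE
      }
      m
    })
  }
  total <- sum(vapply(mols, function(m) m$length, 1))
  structure(list(
    molecules = mols,
    summary = list(total_bases = total, molecule_count = length(mols),
                   genome_size = genome_size,
                   raw_coverage = total / genome_size, map_rate = NA_real_,
                   effective_coverage = NA_real_),
    seed = seed), class = "om_run")
}

#' Effective coverage
#'
#' Total molecule bases divided by genome size, multiplied by the
#' molecule-to-reference map rate.
#'
#' @param total_bases Total molecule bases (bp).
#' @param genome_size Genome size (bp); 3.2e9 when emulating human.
#' @param map_rate Fraction of molecules aligning to the reference.
#' @return Fold coverage.
#' @examples
#' effective_coverage(320e9, 3.2e9, 0.7)  # 70
#' @export
effective_coverage <- function(total_bases, genome_size, map_rate) {
  if (genome_size <= 0) stop_om("genome size must be positive")
  if (total_bases < 0) stop_om("total bases must be non-negative")
  if (map_rate < 0 || map_rate > 1) stop_om("map rate must be in [0, 1]")
  total_bases / genome_size * map_rate
}
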