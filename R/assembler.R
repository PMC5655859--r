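# assembler module: Overlap-Layout-Consensus assembly of labeled molecules
# into haplotype-aware consensus maps, with the staged pipeline:
# pairwise -> layout/initial consensus -> Refine-B -> [extend + merge] x5 ->
# extend-and-split -> final refine with haplotype conversion.

#' Assembly parameters
#'
#' Stage P-value cutoffs follow the platform's published pipeline defaults:
#' Refine-B 1e-11, Extension 1e-11, Merge 1e-15, five extend-and-merge
#' rounds, Refine Final 1e-11; molecules with end alignment gaps > 30 kb are
#' re-assembled (extend-and-split) and internal alignment gaps < 50 kb
#' convert a map into two haplotype maps. They are bound here to this
#' package's empirical P scale; `p_scale` rescales all of them at once
#' (effective cutoff = cutoff^p_scale).
#'
#' @param pairwise_p,refine_b_p,extension_p,merge_p,refine_final_p Stage
#'   P-value cutoffs (strict `<`).
#' @param n_extend_merge_rounds Number of extend+merge rounds.
#' @param end_gap_split_bp Unaligned molecule end (bp) that routes a molecule
#'   to extend-and-split re-assembly.
#' @param internal_gap_haplotype_bp Maximum internal span difference (bp)
#'   treated as a haplotype difference (larger gaps are handled by
#'   extend-and-split).
#' @param min_mols Minimum molecules per consensus map.
#' @param min_labels Minimum labels for a molecule to enter assembly.
#' @param min_overlap_bp Minimum pairwise overlap span for a graph edge.
#' @param min_sites Minimum sites for a consensus map to be kept.
#' @param cluster_gap Label-clustering gap (bp) when forming consensus sites.
#' @param min_label_support Minimum molecule support per retained site.
#' @param chimera_cov_frac Coverage fraction (of the map median) below which
#'   a >=2-site window is treated as a chimeric join and split.
#' @param merge_min_frac Minimum fraction of the smaller map's sites that
#'   must match for a merge (keeps divergent allele maps separate).
#' @param hap_sep_sd Required cluster separation in within-cluster SDs for a
#'   haplotype split.
#' @param hap_min_sep_bp Absolute floor on haplotype cluster separation (bp).
#' @param p_scale Global exponent on all stage cutoffs.
#' @return Object of class `om_asm_params`.
#' @export
assembly_params <- function(pairwise_p = 1e-8, refine_b_p = 1e-11,
                            extension_p = 1e-11, merge_p = 1e-15,
                            refine_final_p = 1e-11,
                            n_extend_merge_rounds = 5,
                            end_gap_split_bp = 30000,
                            internal_gap_haplotype_bp = 50000,
                            min_mols = 3, min_labels = 8,
                            min_overlap_bp = 50000, min_sites = 10,
                            cluster_gap = 1200, min_label_support = 3,
                            chimera_cov_frac = 0.3, merge_min_frac = 0.75,
                            hap_sep_sd = 3, hap_min_sep_bp = 3000,
                            p_scale = 1) {
  out <- as.list(environment())
  ps <- c(pairwise_p, refine_b_p, extension_p, merge_p, refine_final_p)
  if (any(ps <= 0 | ps >= 1)) stop_om("stage P cutoffs must lie in (0,1)")
  if (n_extend_merge_rounds < 1) stop_om("need at least one extend-merge round")
  if (end_gap_split_bp <= 0 || internal_gap_haplotype_bp <= 0)
    stop_om("gap thresholds must be positive")
  structure(out, class = "om_asm_params")
}

log_cut <- function(p, params) params$p_scale * log(p)

new_consensus <- function(id, sites, support, length = NULL, hap = 0L,
                          mol_frames = NULL) {
  structure(list(id = as.character(id), sites = as.numeric(sites),
                 support = as.integer(support),
                 length = length %||% (if (length(sites)) max(sites) else 0),
                 hap = as.integer(hap),
                 mol_frames = mol_frames %||%
                   data.frame(mol = integer(0), sign = numeric(0),
                              offset = numeric(0))),
            class = "om_consensus")
}

#' @export
print.om_consensus <- function(x, ...) {
  cat(sprintf("<om_consensus> %s: %d sites, span %.0f bp, %d molecules%s\n",
              x$id, length(x$sites),
              if (length(x$sites)) diff(range(x$sites)) else 0,
              nrow(x$mol_frames),
              if (x$hap > 0) sprintf(", haplotype %d", x$hap) else ""))
  invisible(x)
}

mol_labels <- function(molecules, i, channel) molecules[[i]]$channels[[channel]]

# ---------------------------------------------------------------------------
# Pairwise overlap graph

# Cheap all-vs-all overlap screen (C++): adjacent-label chaining DP in both
# orientations; survivors are re-aligned with the full kernel. Purely a
# speedup over full all-vs-all DP.
screen_candidates <- function(labs, scoring, min_score = 12) {
  pair_screen_cpp(labs, scoring$match_bonus, scoring$sd0, scoring$sd_scale,
                  min_score)
}

#' Build the pairwise molecule overlap graph
#'
#' All-vs-all (q-gram prefiltered) DP alignment of molecules in both
#' orientations; an edge is kept when the alignment P-value passes the
#' pairwise cutoff and the overlap span reaches the configured minimum.
#'
#' @param molecules List of `om_molecule`.
#' @param params [assembly_params()].
#' @param scoring [scoring_params()].
#' @param null `om_null` from [fit_null()].
#' @param channel Label channel to assemble.
#' @return List with `edges` (data.frame i, j, sign, offset, score, log_p)
#'   and `nodes` (eligible molecule indices).
#' @export
pairwise_overlap_graph <- function(molecules, params, scoring, null,
                                   channel = 1L, min_agree = 0) {
  labs <- lapply(molecules, function(m) m$channels[[channel]])
  elig <- which(lengths(labs) >= params$min_labels &
                  !vapply(molecules, function(m) m$length <= 0, TRUE))
  cand <- screen_candidates(labs[elig], scoring)
  edges <- vector("list", nrow(cand))
  cut <- log_cut(params$pairwise_p, params)
  for (r in seq_len(nrow(cand))) {
    i <- elig[cand[r, 1]]; j <- elig[cand[r, 2]]
    al <- align_maps(labs[[i]], labs[[j]], scoring,
                     qlen = molecules[[i]]$length, null = null)
    if (!is.finite(al$score) || is.na(al$log_p)) next
    if (min_agree > 0 && nrow(al$pairs)) {
      # require the alignment to explain the molecules' full overlap:
      # molecule pairs from different alleles leave a divergent block
      # unmatched and must not be connected
      q <- labs[[i]]; t <- labs[[j]]
      q_of_t <- al$sign * (range(t) - al$offset)
      q_over <- c(max(min(q), min(q_of_t)), min(max(q), max(q_of_t)))
      t_of_q <- al$sign * range(q) + al$offset
      t_over <- c(max(min(t), min(t_of_q)), min(max(t), max(t_of_q)))
      nq_in <- sum(q >= q_over[1] - 1 & q <= q_over[2] + 1)
      nt_in <- sum(t >= t_over[1] - 1 & t <= t_over[2] + 1)
      if (nrow(al$pairs) < min_agree * max(nq_in, nt_in, 2)) next
    }
    if (al$log_p < cut && al$qspan >= params$min_overlap_bp) {
      edges[[r]] <- data.frame(i = i, j = j, sign = al$sign,
                               offset = al$offset, score = al$score,
                               log_p = al$log_p)
    }
  }
  edges <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
  list(edges = edges %||% data.frame(i = integer(0), j = integer(0),
                                     sign = numeric(0), offset = numeric(0),
                                     score = numeric(0), log_p = numeric(0)),
       nodes = elig)
}

# ---------------------------------------------------------------------------
# Layout + consensus formation

# Progressive consensus: molecules (pre-ordered and oriented by the spanning
# tree layout) are aligned one at a time to the growing consensus; matched
# sites take the support-weighted running mean, unmatched labels seed new
# sites. Local DP alignment absorbs the offset drift that accumulates along
# long spanning-tree paths.
progressive_consensus <- function(molecules, frames, params, scoring, null,
                                  channel = 1L) {
  starts <- vapply(seq_len(nrow(frames)), function(r) {
    q <- mol_labels(molecules, frames$mol[r], channel)
    min(frames$sign[r] * q + frames$offset[r])
  }, 1)
  frames <- frames[order(starts), ]
  cut <- log_cut(params$pairwise_p, params)
  first <- frames$mol[1]
  q0 <- mol_labels(molecules, first, channel)
  if (frames$sign[1] < 0) q0 <- sort(frames$offset[1] - q0)
  else q0 <- q0 + frames$offset[1]
  sites <- q0
  supp <- rep(1L, length(q0))
  born <- rep(0L, length(q0))
  cnt <- 0L
  used <- list(data.frame(mol = first, sign = frames$sign[1],
                          offset = frames$offset[1]))
  pending <- frames$mol[-1]
  repeat {
   failed <- integer(0)
   for (mi in pending) {
    # align against core sites only: support-1 sites that were seeded long
    # ago and never confirmed are junk (e.g. extrapolated chimera halves)
    # and would otherwise choke growth at the map ends
    core <- which(supp >= 2L | born >= cnt - 15L)
    if (length(core) < 2) { failed <- c(failed, mi); next }
    q <- mol_labels(molecules, mi, channel)
    al <- align_maps(q, sites[core], scoring, qlen = molecules[[mi]]$length,
                     null = null, query_id = mi, fast = TRUE)
    if (is.na(al$log_p) || al$log_p >= cut) { failed <- c(failed, mi); next }
    cnt <- cnt + 1L
    qq <- al$pairs[, "qidx"]; tq <- core[al$pairs[, "tidx"]]
    qa <- q[qq]; ta <- sites[tq]
    # piecewise projection through the matched anchors: matched labels land
    # exactly on their site (sites stay put; refit repositions later),
    # unmatched labels interpolate between local anchors
    proj <- approx(qa, ta, xout = q, rule = 2)$y
    nlo <- q < qa[1]; nhi <- q > qa[length(qa)]
    if (any(nlo)) proj[nlo] <- ta[1] + al$sign * (q[nlo] - qa[1])
    if (any(nhi)) proj[nhi] <- ta[length(ta)] + al$sign * (q[nhi] - qa[length(qa)])
    supp[tq] <- supp[tq] + 1L
    # growing the map beyond the anchored span (extrapolated labels) is only
    # trusted for strongly anchored alignments that also explain the full
    # overlap; weak or partial matches may be spurious joins whose
    # extrapolation would corrupt the map
    n_q_in <- sum(q >= qa[1] & q <= qa[length(qa)])
    core_sites <- sites[core]
    n_t_in <- sum(core_sites >= min(ta) & core_sites <= max(ta))
    agree <- nrow(al$pairs) / max(n_q_in, n_t_in, 2)
    strong <- nrow(al$pairs) >= 12 && al$qspan >= 6e4 && agree >= 0.7
    un <- setdiff(seq_along(q), qq)
    if (!strong) un <- un[q[un] >= qa[1] & q[un] <= qa[length(qa)]]
    if (length(un)) {
      # near-existing-site labels reinforce that site; the rest seed new ones
      pu <- proj[un]
      fi <- findInterval(pu, sites)
      lo <- pmax(fi, 1L); hi <- pmin(fi + 1L, length(sites))
      dlo <- abs(sites[lo] - pu); dhi <- abs(sites[hi] - pu)
      nearest <- ifelse(dlo <= dhi, lo, hi)
      ndist <- pmin(dlo, dhi)
      reinf <- ndist < params$cluster_gap
      if (any(reinf)) {
        for (sx in unique(nearest[reinf]))
          supp[sx] <- supp[sx] + sum(reinf & nearest == sx)
      }
      if (any(!reinf)) {
        sites <- c(sites, pu[!reinf])
        supp <- c(supp, rep(1L, sum(!reinf)))
        born <- c(born, rep(cnt, sum(!reinf)))
        o <- order(sites)
        sites <- sites[o]; supp <- supp[o]; born <- born[o]
      }
    }
    used[[length(used) + 1L]] <- data.frame(mol = mi, sign = al$sign,
                                            offset = al$offset)
   }
   # molecules skipped because their region was not yet assembled get
   # further passes once the consensus has grown past them
   if (length(failed) == length(pending)) break
   pending <- failed
   if (!length(pending)) break
  }
  if (length(used) < params$min_mols) return(NULL)
  keep <- supp >= min(params$min_label_support, length(used))
  new_consensus("tmp", sites[keep], supp[keep],
                mol_frames = do.call(rbind, used))
}

#' Lay out an overlap graph and form initial consensus maps
#'
#' Connected components are laid out by propagating pairwise offsets along a
#' maximum-weight (alignment score) spanning tree; molecule labels projected
#' into the component frame are clustered into consensus sites whose position
#' is the support mean.
#'
#' @inheritParams pairwise_overlap_graph
#' @param graph Result of [pairwise_overlap_graph()].
#' @return List of `om_consensus`.
#' @export
layout_and_initial_consensus <- function(graph, molecules, params,
                                         scoring = scoring_params(),
                                         null = NULL, channel = 1L) {
  ed <- graph$edges
  if (!nrow(ed)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$i), to = as.character(ed$j),
               weight = -ed$score), directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    verts <- names(comp$membership)[comp$membership == ci]
    if (length(verts) < params$min_mols) next
    sub <- igraph::induced_subgraph(g, verts)
    tree <- igraph::mst(sub)
    deg <- igraph::degree(sub)
    root <- names(deg)[which.max(deg)]
    ord <- igraph::bfs(tree, root = root, father = TRUE)
    vnames <- igraph::V(tree)$name
    sign_v <- setNames(rep(NA_real_, length(vnames)), vnames)
    off_v <- setNames(rep(NA_real_, length(vnames)), vnames)
    sign_v[root] <- 1; off_v[root] <- 0
    edge_lookup <- ed[, c("i", "j", "sign", "offset")]
    order_names <- vnames[as.integer(ord$order)]
    fathers <- setNames(vnames[as.integer(ord$father)], vnames)
    for (v in order_names[-1]) {
      f <- fathers[v]
      vi <- as.integer(v); fi <- as.integer(f)
      # edge transform maps i-frame -> j-frame: x_j = sign * x_i + offset
      hit <- which(edge_lookup$i == vi & edge_lookup$j == fi)
      if (length(hit)) {
        e <- edge_lookup[hit[1], ]
        sign_v[v] <- sign_v[f] * e$sign
        off_v[v] <- sign_v[f] * e$offset + off_v[f]
      } else {
        hit <- which(edge_lookup$i == fi & edge_lookup$j == vi)
        e <- edge_lookup[hit[1], ]
        sign_v[v] <- sign_v[f] * e$sign
        off_v[v] <- off_v[f] - sign_v[f] * e$sign * e$offset
      }
    }
    frames <- data.frame(mol = as.integer(vnames), sign = unname(sign_v),
                         offset = unname(off_v))
    # a progressive run can stall when junk blocks its growth frontier;
    # stranded molecules seed further consensus runs, and the overlapping
    # fragments are reunited by the merge rounds
    remaining <- frames
    tries <- 0L
    repeat {
      if (nrow(remaining) < params$min_mols || tries > 50L) break
      cons <- progressive_consensus(molecules, remaining, params, scoring,
                                    null, channel)
      if (is.null(cons) || nrow(cons$mol_frames) < params$min_mols) {
        # the seed molecule stranded this run; retry with the next seed
        starts <- vapply(seq_len(nrow(remaining)), function(r) {
          q <- mol_labels(molecules, remaining$mol[r], channel)
          min(remaining$sign[r] * q + remaining$offset[r])
        }, 1)
        remaining <- remaining[-which.min(starts), , drop = FALSE]
        tries <- tries + 1L
        next
      }
      used_mols <- cons$mol_frames$mol
      remaining <- remaining[!remaining$mol %in% used_mols, , drop = FALSE]
      if (length(cons$sites) >= params$min_sites) {
        cons$id <- sprintf("asm%03d", length(out) + 1L)
        out[[length(out) + 1L]] <- normalize_consensus(cons)
      }
    }
  }
  out
}

normalize_consensus <- function(cons, pad = 1000) {
  if (!length(cons$sites)) return(cons)
  shift <- min(cons$sites) - pad
  cons$sites <- cons$sites - shift
  cons$mol_frames$offset <- cons$mol_frames$offset - shift
  if (!is.null(cons$mol_ranges)) {
    cons$mol_ranges$lo <- cons$mol_ranges$lo - shift
    cons$mol_ranges$hi <- cons$mol_ranges$hi - shift
  }
  cons$length <- max(cons$sites) + pad
  cons
}

# ---------------------------------------------------------------------------
# Refinement core: realign assigned molecules, refit site positions,
# recompute support, add well-supported new sites.

refit_consensus <- function(cons, molecules, mol_ids, params, scoring, null,
                            log_cutoff, channel = 1L) {
  sites <- cons$sites
  ns <- length(sites)
  if (ns < 2) return(NULL)
  aligns <- list()
  frames <- list()
  for (mi in mol_ids) {
    q <- mol_labels(molecules, mi, channel)
    if (length(q) < 2) next
    al <- align_maps(q, sites, scoring, qlen = molecules[[mi]]$length,
                     null = null, query_id = mi, fast = TRUE)
    if (is.na(al$log_p) || al$log_p >= log_cutoff) next
    aligns[[length(aligns) + 1L]] <- al
    frames[[length(frames) + 1L]] <- data.frame(mol = mi, sign = al$sign,
                                                offset = al$offset)
  }
  if (!length(aligns)) return(NULL)
  iv <- diff(sites)
  iv_sum <- numeric(ns - 1); iv_n <- numeric(ns - 1)
  supp <- integer(ns)
  new_pos <- numeric(0); new_mol <- integer(0)
  for (al in aligns) {
    q <- mol_labels(molecules, al$query_id, channel)
    tq <- al$pairs[, "tidx"]; qq <- al$pairs[, "qidx"]
    supp[tq] <- supp[tq] + 1L
    if (length(tq) > 1) {
      # each measured span between matched sites refines the intervals it
      # covers (distributed proportionally across skipped sites, so
      # intervals flanked by junk sites still get re-estimated)
      for (k in seq_len(length(tq) - 1L)) {
        s1 <- min(tq[k], tq[k + 1]); s2 <- max(tq[k], tq[k + 1])
        if (s2 - s1 > 4L || s2 == s1) next
        dq <- abs(q[qq[k + 1]] - q[qq[k]])
        idx <- s1:(s2 - 1L)
        w <- iv[idx] / sum(iv[idx])
        iv_sum[idx] <- iv_sum[idx] + dq * w
        iv_n[idx] <- iv_n[idx] + 1
      }
    }
    un <- setdiff(seq_along(q), qq)
    if (length(un)) {
      proj <- approx(q[qq], sites[tq], xout = q[un], rule = 2)$y
      # extrapolate beyond the matched range with the end anchors
      lo <- q[un] < min(q[qq]); hi <- q[un] > max(q[qq])
      if (any(lo)) proj[lo] <- project_pos(al, q[un][lo])
      if (any(hi)) proj[hi] <- project_pos(al, q[un][hi])
      new_pos <- c(new_pos, proj)
      new_mol <- c(new_mol, rep(al$query_id, length(proj)))
    }
  }
  refined_iv <- ifelse(iv_n > 0, iv_sum / pmax(iv_n, 1e-9), iv)
  sites2 <- sites[1] + c(0, cumsum(refined_iv))
  # adaptive support: a real site is hit by ~(1 - miss) of the molecules
  # covering it, so junk (false-label clusters) falls well below a fraction
  # of the local molecule coverage
  mstart <- vapply(aligns, function(al)
    min(project_pos(al, c(0, 1))), 1)
  mend <- vapply(aligns, function(al)
    max(project_pos(al, c(0, molecules[[al$query_id]]$length))), 1)
  cov_at <- function(p) findInterval(p, sort(mstart)) -
    findInterval(p, sort(mend))
  locov <- cov_at(sites2)
  floor_supp <- min(params$min_label_support, length(aligns))
  keep <- supp >= pmax(floor_supp, 0.35 * locov)
  sites2 <- sites2[keep]; supp2 <- supp[keep]
  # well-supported unmatched label clusters become new sites
  if (length(new_pos)) {
    cl <- cluster_1d(new_pos, params$cluster_gap)
    cpos <- as.numeric(tapply(new_pos, cl, mean))
    csup <- as.integer(tapply(new_mol, cl, function(m) length(unique(m))))
    ok <- csup >= params$min_label_support
    if (any(ok)) {
      cpos <- cpos[ok]; csup <- csup[ok]
      near <- vapply(cpos, function(p)
        length(sites2) && min(abs(sites2 - p)) < params$cluster_gap, TRUE)
      if (any(!near)) {
        sites2 <- c(sites2, cpos[!near]); supp2 <- c(supp2, csup[!near])
        o <- order(sites2); sites2 <- sites2[o]; supp2 <- supp2[o]
      }
    }
  }
  mc <- merge_close_sites(sites2, supp2, 0.9 * params$cluster_gap)
  cons$sites <- mc$sites
  cons$support <- mc$support
  cons$mol_frames <- do.call(rbind, frames)
  cons$mol_ranges <- do.call(rbind, lapply(aligns, function(al) {
    ta <- sites[al$pairs[, "tidx"]]
    data.frame(mol = al$query_id, lo = min(ta), hi = max(ta))
  }))
  list(cons = normalize_consensus(cons), aligns = aligns)
}

# Split a consensus at chimeric joins. A mis-joined map has (almost) no
# molecules whose matched range spans the junction: each constituent
# molecule aligns on one side only. Site-support dips from
# resolution-limit artifacts keep full spanning coverage and do not split.
split_chimeric <- function(cons, params, molecules, channel = 1L) {
  rng <- cons$mol_ranges
  ns <- length(cons$sites)
  if (is.null(rng) || ns < 2 * params$min_sites) return(list(cons))
  mids <- (cons$sites[-ns] + cons$sites[-1]) / 2
  spanning <- vapply(mids, function(m)
    sum(rng$lo <= m - 2000 & rng$hi >= m + 2000), 1L)
  med <- median(spanning)
  cutpts <- which(spanning < pmax(params$chimera_cov_frac * med, 2))
  # ignore the coverage taper near map ends
  cutpts <- cutpts[cutpts > 5 & cutpts < ns - 5]
  if (!length(cutpts)) return(list(cons))
  bounds <- c(0L, cutpts, ns)
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[b] + 1L):bounds[b + 1L]
    if (length(idx) < params$min_sites) next
    span_lo <- min(cons$sites[idx]); span_hi <- max(cons$sites[idx])
    keep_m <- rng$mol[rng$lo < span_hi - 1e4 & rng$hi > span_lo + 1e4]
    fr <- cons$mol_frames[cons$mol_frames$mol %in% keep_m, , drop = FALSE]
    if (nrow(fr) < params$min_mols) next
    piece <- new_consensus(sprintf("%s.%d", cons$id, b), cons$sites[idx],
                           cons$support[idx], hap = cons$hap,
                           mol_frames = fr)
    piece$mol_ranges <- rng[rng$mol %in% keep_m, , drop = FALSE]
    out[[length(out) + 1L]] <- normalize_consensus(piece)
  }
  if (!length(out)) list(cons) else out
}

#' Refine-B: best-match molecule assignment, position refinement, chimera
#' removal
#'
#' Realigns every molecule to every consensus, assigns each to its single
#' best (lowest-P) map when it passes the Refine-B cutoff, refines site
#' positions from assigned molecules, and splits maps at coverage cliffs
#' (chimeric-join signature).
#'
#' @inheritParams pairwise_overlap_graph
#' @param consensi List of `om_consensus`.
#' @return List with `consensi` and `assignments` (map id per molecule, NA
#'   when unassigned).
#' @export
refine_b <- function(consensi, molecules, params, scoring, null,
                     channel = 1L) {
  asg <- assign_molecules(consensi, molecules, params, scoring, null,
                          log_cut(params$refine_b_p, params), channel)
  out <- list()
  for (k in seq_along(consensi)) {
    ids <- asg$mol[asg$map == consensi[[k]]$id]
    if (length(ids) < params$min_mols) next
    rf <- refit_consensus(consensi[[k]], molecules, ids, params, scoring,
                          null, log_cut(params$refine_b_p, params), channel)
    if (is.null(rf)) next
    # second pass: realigning against the refined sites self-corrects
    # positions near sites that were dropped or added in the first pass
    rf2 <- refit_consensus(rf$cons, molecules, ids, params, scoring, null,
                           log_cut(params$refine_b_p, params), channel)
    if (!is.null(rf2)) rf <- rf2
    out <- c(out, split_chimeric(rf$cons, params, molecules, channel))
  }
  list(consensi = dedup_ids(out), assignments = asg)
}

assign_molecules <- function(consensi, molecules, params, scoring, null,
                             log_cutoff, channel = 1L) {
  n <- length(molecules)
  best_map <- rep(NA_character_, n); best_lp <- rep(Inf, n)
  left_bp <- rep(NA_real_, n); right_bp <- rep(NA_real_, n)
  left_in <- rep(FALSE, n); right_in <- rep(FALSE, n)
  left_anchor <- rep(NA_real_, n); right_anchor <- rep(NA_real_, n)
  for (cons in consensi) {
    rng <- range(cons$sites)
    for (mi in seq_len(n)) {
      q <- mol_labels(molecules, mi, channel)
      if (length(q) < params$min_labels) next
      al <- align_maps(q, cons$sites, scoring, qlen = molecules[[mi]]$length,
                       null = null, fast = TRUE)
      if (is.na(al$log_p) || al$log_p >= log_cutoff) next
      if (al$log_p < best_lp[mi]) {
        best_lp[mi] <- al$log_p; best_map[mi] <- cons$id
        left_bp[mi] <- al$q_left_bp; right_bp[mi] <- al$q_right_bp
        tfirst <- cons$sites[al$pairs[1L, "tidx"]]
        tlast <- cons$sites[al$pairs[nrow(al$pairs), "tidx"]]
        # molecule-left maps to the high map side under "-" orientation
        if (al$sign > 0) {
          left_anchor[mi] <- tfirst; right_anchor[mi] <- tlast
        } else {
          left_anchor[mi] <- tlast; right_anchor[mi] <- tfirst
        }
        # does the unaligned molecule end project inside the map span?
        ends <- project_pos(al, c(0, molecules[[mi]]$length))
        mol_lo <- min(ends); mol_hi <- max(ends)
        slack <- 1.5e4
        left_in[mi] <- mol_lo > rng[1] + slack
        right_in[mi] <- mol_hi < rng[2] - slack
        if (al$sign < 0) {  # molecule left end projects to map high side
          tmp <- left_in[mi]; left_in[mi] <- right_in[mi]; right_in[mi] <- tmp
        }
      }
    }
  }
  data.frame(mol = seq_len(n), map = best_map, log_p = best_lp,
             left_bp = left_bp, right_bp = right_bp,
             left_inside = left_in, right_inside = right_in,
             left_anchor = left_anchor, right_anchor = right_anchor,
             stringsAsFactors = FALSE)
}

dedup_ids <- function(consensi) {
  seen <- character(0)
  for (k in seq_along(consensi)) {
    id <- consensi[[k]]$id
    while (id %in% seen) id <- paste0(id, "b")
    consensi[[k]]$id <- id
    seen <- c(seen, id)
  }
  consensi
}

# ---------------------------------------------------------------------------
# Extension and merging

#' One extend-and-merge round
#'
#' Molecules aligning past map ends (Extension cutoff) extend the map by a
#' consensus of their overhanging labels; overlapping maps are then merged
#' under the Merge cutoff. The driver runs this `n_extend_merge_rounds`
#' times.
#'
#' @inheritParams refine_b
#' @return Updated list of `om_consensus`.
#' @export
extend_and_merge_round <- function(consensi, molecules, params, scoring,
                                   null, channel = 1L) {
  consensi <- lapply(consensi, extend_one, molecules = molecules,
                     params = params, scoring = scoring, null = null,
                     channel = channel)
  merge_consensi(consensi, params, scoring, null)
}

extend_one <- function(cons, molecules, params, scoring, null, channel = 1L) {
  cut <- log_cut(params$extension_p, params)
  lo_pos <- numeric(0); lo_mol <- integer(0)
  hi_pos <- numeric(0); hi_mol <- integer(0)
  lo_end <- numeric(0); hi_end <- numeric(0)
  for (mi in unique(cons$mol_frames$mol)) {
    q <- mol_labels(molecules, mi, channel)
    al <- align_maps(q, cons$sites, scoring, qlen = molecules[[mi]]$length,
                     null = null, query_id = mi, fast = TRUE)
    if (is.na(al$log_p) || al$log_p >= cut) next
    proj <- project_pos(al, q)
    ends <- sort(project_pos(al, c(0, molecules[[mi]]$length)))
    over_lo <- proj < min(cons$sites) - params$cluster_gap
    over_hi <- proj > max(cons$sites) + params$cluster_gap
    if (any(over_lo)) {
      lo_pos <- c(lo_pos, proj[over_lo])
      lo_mol <- c(lo_mol, rep(mi, sum(over_lo)))
      lo_end <- c(lo_end, ends[1])
    }
    if (any(over_hi)) {
      hi_pos <- c(hi_pos, proj[over_hi])
      hi_mol <- c(hi_mol, rep(mi, sum(over_hi)))
      hi_end <- c(hi_end, ends[2])
    }
  }
  add_side <- function(pos, mol) {
    if (!length(pos)) return(NULL)
    cl <- cluster_1d(pos, params$cluster_gap)
    cpos <- as.numeric(tapply(pos, cl, mean))
    csup <- as.integer(tapply(mol, cl, function(m) length(unique(m))))
    ok <- csup >= params$min_label_support
    list(pos = cpos[ok], supp = csup[ok])
  }
  lo <- add_side(lo_pos, lo_mol); hi <- add_side(hi_pos, hi_mol)
  if (!is.null(lo) && length(lo$pos)) {
    cons$sites <- c(lo$pos, cons$sites)
    cons$support <- c(lo$supp, cons$support)
  }
  if (!is.null(hi) && length(hi$pos)) {
    cons$sites <- c(cons$sites, hi$pos)
    cons$support <- c(cons$support, hi$supp)
  }
  o <- order(cons$sites)
  mc <- merge_close_sites(cons$sites[o], cons$support[o],
                          0.9 * params$cluster_gap)
  cons$sites <- mc$sites; cons$support <- mc$support
  normalize_consensus(cons)
}

merge_consensi <- function(consensi, params, scoring, null) {
  cut <- log_cut(params$merge_p, params)
  repeat {
    merged <- FALSE
    nmaps <- length(consensi)
    if (nmaps < 2) break
    for (a in seq_len(nmaps - 1)) {
      for (b in (a + 1):nmaps) {
        # allele maps recovered by extend-and-split stay separate from the
        # primary maps they diverged from; they may merge with each other
        oa <- consensi[[a]]$origin %||% "primary"
        ob <- consensi[[b]]$origin %||% "primary"
        if (oa != ob) next
        small <- if (length(consensi[[a]]$sites) <=
                       length(consensi[[b]]$sites)) a else b
        big <- if (small == a) b else a
        q <- consensi[[small]]$sites; t <- consensi[[big]]$sites
        al <- align_maps(q, t, scoring, null = null)
        if (is.na(al$log_p) || al$log_p >= cut) next
        # the alignment must explain (almost) all query sites that fall in
        # the overlap of the two maps' spans; allele maps anchored on a
        # shared flank leave a block of unexplained sites and must not merge
        proj_q <- project_pos(al, q)
        ov_lo <- max(min(proj_q), min(t)) - params$cluster_gap
        ov_hi <- min(max(proj_q), max(t)) + params$cluster_gap
        inside <- sum(proj_q >= ov_lo & proj_q <= ov_hi)
        if (nrow(al$pairs) < params$merge_min_frac * max(inside, 2L)) next
        m <- do_merge(consensi[[big]], consensi[[small]], al, params)
        if (is.null(m)) next  # non-monotone result: merge rejected
        consensi[[big]] <- m
        consensi[[small]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  dedup_ids(consensi)
}

do_merge <- function(big, small, al, params) {
  q <- small$sites
  proj <- project_pos(al, q)
  sites <- big$sites; supp <- big$support
  matched_q <- al$pairs[, "qidx"]; matched_t <- al$pairs[, "tidx"]
  wq <- small$support[matched_q]; wt <- big$support[matched_t]
  sites[matched_t] <- (sites[matched_t] * wt + proj[matched_q] * wq) /
    pmax(wt + wq, 1L)
  supp[matched_t] <- supp[matched_t] + small$support[matched_q]
  un <- setdiff(seq_along(q), matched_q)
  ext <- un[proj[un] < min(big$sites) - params$cluster_gap |
              proj[un] > max(big$sites) + params$cluster_gap]
  sites <- c(sites, proj[ext]); supp <- c(supp, small$support[ext])
  o <- order(sites)
  if (any(duplicated(sites))) return(NULL)
  mc <- merge_close_sites(sites[o], supp[o], 0.9 * params$cluster_gap)
  sites <- mc$sites; supp <- mc$supp %||% mc$support
  if (any(diff(sites) <= 0)) return(NULL)
  sm_frames <- small$mol_frames
  if (nrow(sm_frames)) {
    # compose small-map frames with the small->big transform
    sm_frames$offset <- al$sign * sm_frames$offset + al$offset
    sm_frames$sign <- sm_frames$sign * al$sign
  }
  frames <- rbind(big$mol_frames,
                  sm_frames[!sm_frames$mol %in% big$mol_frames$mol, ])
  out <- new_consensus(big$id, sites, supp, hap = big$hap,
                       mol_frames = frames)
  out$origin <- big$origin %||% "primary"
  normalize_consensus(out)
}

# ---------------------------------------------------------------------------
# Extend-and-split: re-assemble molecules with large unaligned ends

#' Extend-and-split: recover divergent alleles from end-gap molecule
#' clusters
#'
#' Molecules whose best alignment leaves more than `end_gap_split_bp`
#' unaligned on one side are clustered by assigned map, gap side, and the
#' position where their alignment stops, and each cluster is re-assembled
#' into new candidate maps. A second round re-pools against the updated map
#' set, which isolates divergent-allele clusters that shared their first
#' cluster with unrelated end-gap molecules.
#'
#' @inheritParams refine_b
#' @param rounds Number of pool/re-assemble rounds.
#' @return Updated list of `om_consensus` (new allele maps appended).
#' @export
extend_and_split <- function(consensi, molecules, params, scoring, null,
                             channel = 1L, rounds = 2L) {
  for (round in seq_len(rounds)) {
    asg <- assign_molecules(consensi, molecules, params, scoring, null,
                            log_cut(params$extension_p, params), channel)
    gap <- params$end_gap_split_bp
    pool <- asg$mol[!is.na(asg$map) &
                      (asg$left_bp > gap | asg$right_bp > gap)]
    unasg <- asg$mol[is.na(asg$map) &
                       lengths(lapply(asg$mol, function(m)
                         mol_labels(molecules, m, channel))) >=
                       params$min_labels]
    allmol <- unique(c(pool, unasg))
    # molecules whose unaligned end projects INSIDE their map cluster at a
    # sub-50-kb allelic difference (they stop at the event instead of
    # aligning across): the internal-alignment-gap signature. These form
    # dedicated per-locus groups keyed by where the alignment stops.
    inside_gap <- 2e4  # above the few-label noise scale of unaligned ends
    ig_min <- max(params$min_mols, 4L)
    ig <- asg[!is.na(asg$map) &
                ((asg$left_bp > inside_gap & asg$left_inside) |
                   (asg$right_bp > inside_gap & asg$right_inside)), ,
              drop = FALSE]
    ig_groups <- list()
    if (round == 1L && nrow(ig) >= ig_min) {
      gap_side_left <- ig$left_bp > inside_gap & ig$left_inside
      anchor <- ifelse(gap_side_left, ig$left_anchor, ig$right_anchor)
      for (mp in unique(ig$map)) {
        idx <- which(ig$map == mp)
        cl <- cluster_1d(anchor[idx], 3e4)
        for (ci in unique(cl)) {
          mm <- ig$mol[idx[cl == ci]]
          if (length(mm) >= ig_min)
            ig_groups[[length(ig_groups) + 1L]] <- mm
        }
      }
    }
    if (length(allmol) < params$min_mols && !length(ig_groups))
      return(consensi)
    # one overlap graph over the whole end-gap pool, with edges required to
    # explain the molecules' full overlap: components then separate allele
    # clusters from unrelated end-gap and unassigned molecules
    pool_params <- params
    pool_params$pairwise_p <- max(params$pairwise_p, 1e-6)
    added <- 0L
    cand <- list()
    cand_mols <- list()
    if (length(allmol) >= params$min_mols) {
      sub <- molecules[allmol]
      g <- pairwise_overlap_graph(sub, params, scoring, null, channel,
                                  min_agree = 0.7)
      cnd <- layout_and_initial_consensus(g, sub, params, scoring,
                                          null, channel)
      for (k in seq_along(cnd)) {
        cand[[length(cand) + 1L]] <- cnd[[k]]
        cand_mols[[length(cand_mols) + 1L]] <- allmol
      }
    }
    # internal-gap clusters are small and co-anchored: build their allele
    # map directly by repeated progressive runs seeded from the longest
    # molecules, so a minority allele in a mixed cluster still surfaces
    for (grp in ig_groups) {
      remaining <- grp
      for (try in 1:3) {
        if (length(remaining) < params$min_mols) break
        lens <- vapply(molecules[remaining], function(m) m$length, 1)
        frames <- data.frame(mol = order(-lens), sign = 1, offset = 0)
        cons <- progressive_consensus(molecules[remaining], frames,
                                      pool_params, scoring, null, channel)
        if (is.null(cons)) break
        used <- remaining[cons$mol_frames$mol]
        cons$mol_frames$mol <- seq_along(used)
        remaining <- setdiff(remaining, used)
        cand[[length(cand) + 1L]] <- cons
        cand_mols[[length(cand_mols) + 1L]] <- used
      }
    }
    for (ci in seq_along(cand)) {
      cons <- cand[[ci]]
      cons$mol_frames$mol <- cand_mols[[ci]][cons$mol_frames$mol]
      # nascent allele maps are short; molecules overhanging their ends
      # realign at the graph-formation cutoff, not the Refine-B one
      rf <- refit_consensus(cons, molecules, cons$mol_frames$mol, params,
                            scoring, null,
                            log_cut(pool_params$pairwise_p, params), channel)
      if (is.null(rf)) next
      if (nrow(rf$cons$mol_frames) < params$min_mols) next
      if (length(rf$cons$sites) < params$min_sites) next
      rf$cons$id <- sprintf("split%02d", length(consensi) + added + 1L)
      rf$cons$origin <- "split"
      consensi <- c(consensi, list(rf$cons))
      added <- added + 1L
    }
    if (!added) break
    consensi <- dedup_ids(consensi)
  }
  consensi
}

# ---------------------------------------------------------------------------
# Final refinement + haplotype conversion

interval_residuals <- function(cons, molecules, aligns, channel = 1L) {
  ns <- length(cons$sites)
  res <- vector("list", max(ns - 1L, 0L))
  for (al in aligns) {
    q <- mol_labels(molecules, al$query_id, channel)
    tq <- al$pairs[, "tidx"]; qq <- al$pairs[, "qidx"]
    if (length(tq) < 2) next
    for (k in seq_len(length(tq) - 1L)) {
      s1 <- min(tq[k], tq[k + 1]); s2 <- max(tq[k], tq[k + 1])
      if (s2 - s1 > 6L) next  # keep residual variance bounded
      r <- abs(q[qq[k + 1]] - q[qq[k]]) - (cons$sites[s2] - cons$sites[s1])
      for (s in s1:(s2 - 1L))
        res[[s]] <- rbind(res[[s]], c(mol = al$query_id, r = r))
    }
  }
  res
}

sizing_sd <- function(span, scoring) {
  sqrt(scoring$sd0^2 + scoring$sd_scale * pmax(span, 0))
}

detect_haplotype_locus <- function(cons, resids, params, scoring) {
  best <- NULL
  for (s in seq_along(resids)) {
    m <- resids[[s]]
    if (is.null(m) || nrow(m) < 2 * params$min_mols) next
    r <- m[, "r"]
    tm <- two_means_1d(r)
    if (is.null(tm)) next
    sep <- diff(tm$centers)
    span <- cons$sites[s + 1L] - cons$sites[s]
    floor_bp <- max(params$hap_min_sep_bp, 5 * sizing_sd(span, scoring))
    if (sep < floor_bp) next
    if (sep >= params$internal_gap_haplotype_bp) next
    if (sep < params$hap_sep_sd * max(tm$within_sd, 1)) next
    if (min(tm$sizes) < params$min_mols) next
    if (tm$gap < 0.5 * sep) next  # genuine mode gap, not a stretched tail
    score <- sep / max(tm$within_sd, 1)
    if (is.null(best) || score > best$score)
      best <- list(site = s, score = score, threshold = tm$assign_threshold,
                   mols = m, sep = sep)
  }
  best
}

#' Final refinement with haplotype conversion
#'
#' Refines every map at the Refine Final cutoff, then looks for clusters of
#' molecules whose internal alignment spans disagree by less than
#' `internal_gap_haplotype_bp`; a bimodal cluster converts the map into two
#' haplotype maps, each refined from its own molecules.
#'
#' @inheritParams refine_b
#' @return Updated list of `om_consensus` (haplotype-tagged where split).
#' @export
final_refine_haplotype <- function(consensi, molecules, params, scoring,
                                   null, channel = 1L) {
  cut <- log_cut(params$refine_final_p, params)
  # global best-match assignment: molecules near an allelic difference move
  # to the allele map that fits them, de-mixing the primary consensus
  asg <- assign_molecules(consensi, molecules, params, scoring, null, cut,
                          channel)
  out <- list()
  for (cons in consensi) {
    ids <- asg$mol[!is.na(asg$map) & asg$map == cons$id]
    if (length(ids) < params$min_mols) next
    rf <- refit_consensus(cons, molecules, ids,
                          params, scoring, null, cut, channel)
    if (is.null(rf)) next
    cons <- rf$cons
    aligns <- list()
    for (mi in unique(cons$mol_frames$mol)) {
      al <- align_maps(mol_labels(molecules, mi, channel), cons$sites,
                       scoring, qlen = molecules[[mi]]$length, null = null,
                       query_id = mi, fast = TRUE)
      if (!is.na(al$log_p) && al$log_p < cut)
        aligns[[length(aligns) + 1L]] <- al
    }
    resids <- interval_residuals(cons, molecules, aligns, channel)
    locus <- detect_haplotype_locus(cons, resids, params, scoring)
    if (is.null(locus)) { out <- c(out, list(cons)); next }
    mols_at <- locus$mols
    grp1 <- unique(mols_at[mols_at[, "r"] <= locus$threshold, "mol"])
    grp2 <- unique(mols_at[mols_at[, "r"] > locus$threshold, "mol"])
    other <- setdiff(unique(cons$mol_frames$mol), c(grp1, grp2))
    haps <- list(c(grp1, other), c(grp2, other))
    for (h in 1:2) {
      hc <- cons
      hc$id <- sprintf("%s.h%d", cons$id, h)
      hc$hap <- h
      rfh <- refit_consensus(hc, molecules, haps[[h]], params, scoring,
                             null, cut, channel)
      if (!is.null(rfh) && nrow(rfh$cons$mol_frames) >= params$min_mols)
        out <- c(out, list(rfh$cons))
    }
  }
  dedup_ids(out)
}

# Merge consensus sites closer than the clustering gap: these are artifacts
# (the simulator cannot resolve labels below the optical resolution), and
# they split molecule support between near-coincident copies.
merge_close_sites <- function(sites, support, gap) {
  repeat {
    if (length(sites) < 2) break
    d <- diff(sites)
    k <- which.min(d)
    if (d[k] >= gap) break
    w <- support[k] + support[k + 1L]
    sites[k] <- (sites[k] * support[k] + sites[k + 1L] * support[k + 1L]) / w
    support[k] <- w
    sites <- sites[-(k + 1L)]; support <- support[-(k + 1L)]
  }
  list(sites = sites, support = as.integer(support))
}

consensus_fingerprint <- function(consensi) {
  lapply(consensi, function(k) c(length(k$sites), round(sum(k$sites), 3)))
}

# ---------------------------------------------------------------------------
# Driver

#' Run the full Overlap-Layout-Consensus assembly
#'
#' Pairwise overlap graph, layout and initial consensus, Refine-B,
#' `n_extend_merge_rounds` extend+merge rounds, extend-and-split, and final
#' refinement with haplotype conversion. Deterministic given molecules and
#' seed-bearing inputs (the pipeline itself draws no random numbers).
#'
#' @param molecules List of `om_molecule` (e.g. `om_run$molecules`).
#' @param params [assembly_params()].
#' @param scoring [scoring_params()].
#' @param null `om_null` from [fit_null()].
#' @param channel Label channel to assemble.
#' @return List of class `om_assembly`: `consensi` (list of `om_consensus`)
#'   and `stage_log` (data.frame stage, n_maps, detail).
#' @export
run_assembly <- function(molecules, params = assembly_params(),
                         scoring = scoring_params(), null, channel = 1L) {
  log_df <- data.frame(stage = character(0), n_maps = integer(0),
                       detail = character(0), stringsAsFactors = FALSE)
  note <- function(stage, maps, detail = "") {
    log_df <<- rbind(log_df, data.frame(stage = stage,
                                        n_maps = length(maps),
                                        detail = detail,
                                        stringsAsFactors = FALSE))
  }
  g <- pairwise_overlap_graph(molecules, params, scoring, null, channel)
  note("pairwise", list(), sprintf("%d edges / %d molecules",
                                   nrow(g$edges), length(g$nodes)))
  consensi <- layout_and_initial_consensus(g, molecules, params, scoring,
                                           null, channel)
  note("layout", consensi)
  rb <- refine_b(consensi, molecules, params, scoring, null, channel)
  consensi <- rb$consensi
  note("refine_b", consensi,
       sprintf("%d molecules assigned", sum(!is.na(rb$assignments$map))))
  changed <- TRUE
  for (round in seq_len(params$n_extend_merge_rounds)) {
    if (changed) {
      before <- consensus_fingerprint(consensi)
      consensi <- extend_and_merge_round(consensi, molecules, params,
                                         scoring, null, channel)
      changed <- !identical(before, consensus_fingerprint(consensi))
    }
    note(sprintf("extend_merge_%d", round), consensi,
         if (changed) "" else "converged")
  }
  consensi <- extend_and_split(consensi, molecules, params, scoring, null,
                               channel)
  note("extend_split", consensi)
  consensi <- merge_consensi(consensi, params, scoring, null)
  note("post_split_merge", consensi)
  consensi <- final_refine_haplotype(consensi, molecules, params, scoring,
                                     null, channel)
  note("refine_final", consensi)
  structure(list(consensi = consensi, stage_log = log_df,
                 params = params), class = "om_assembly")
}

#' @export
print.om_assembly <- function(x, ...) {
  cat(sprintf("<om_assembly> %d consensus map(s)\n", length(x$consensi)))
  print(x$stage_log, row.names = FALSE)
  invisible(x)
}
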