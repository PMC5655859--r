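# sv_caller module: call structural variants from consensus-to-reference
# alignments. Maps that do not align contiguously are split into segments;
# span discrepancies between adjacent matched labels are tested as indel
# outliers; segment geometry classifies inversions and translocations;
# breakpoint-uncertainty intervals are bounded by flanking matched labels
# and the unexplained query span.

#' SV-calling parameters
#'
#' @param align_p Alignment cutoff for accepting a consensus-to-reference
#'   segment (strict `<`).
#' @param outlier_p Two-sided outlier P cutoff for the indel span test
#'   (strict `<`).
#' @param skip_excess Number of consecutive unaligned labels on either side
#'   that flags a region even when the span test is not significant.
#' @param intra_trans_bp Reference gap beyond which same-chromosome,
#'   same-orientation segments indicate an intra-chromosomal translocation.
#' @param min_seg_labels Minimum query labels for a split-off segment.
#' @param dedupe_overlap Reciprocal overlap above which same-type calls from
#'   different maps are considered the same event.
#' @param zygosity_margin_bp A map must cover the event interval plus this
#'   margin on both sides to count as a reference-concordant allele.
#' @param drift_tol_bp Cumulative query-vs-reference drift within one
#'   alignment segment above which the segment is split and realigned
#'   (prevents large indels being absorbed as chains of small skips).
#' @param min_size_bp Smallest indel size reported; events below the
#'   label-density resolution floor (about 1.3 label intervals at the
#'   default 6-kb spacing) are suppressed.
#' @param secondary_p Cutoff for split-off remainder segments (shorter
#'   allele-map flanks after the primary anchoring passed `align_p`);
#'   junctions classified as inversion or translocation still require both
#'   segments to pass `align_p`.
#' @param min_junction_support Minimum number of the supporting map's
#'   molecules whose matched span crosses the event region.
#' @return Object of class `om_sv_params`.
#' @export
sv_params <- function(align_p = 1e-12, outlier_p = 3e-3, skip_excess = 3,
                      intra_trans_bp = 5e6, min_seg_labels = 6,
                      dedupe_overlap = 0.5, zygosity_margin_bp = 20000,
                      drift_tol_bp = 9000, min_size_bp = 8000,
                      secondary_p = 1e-6,
                      min_junction_support = 4L) {
  out <- as.list(environment())
  stopifnot(align_p > 0, align_p < 1, outlier_p > 0, outlier_p < 1,
            intra_trans_bp > 0)
  structure(out, class = "om_sv_params")
}

empty_calls <- function() {
  data.frame(call_id = integer(0), type = character(0), contig = character(0),
             contig2 = character(0), bp1_lo = numeric(0), bp1_hi = numeric(0),
             bp2_lo = numeric(0), bp2_hi = numeric(0), size = numeric(0),
             ref_span = numeric(0), zygosity = character(0),
             log_p = numeric(0), maps = character(0), flags = character(0),
             channel = integer(0), q_lo = numeric(0), q_hi = numeric(0),
             stringsAsFactors = FALSE)
}

#' Split a consensus map into reference alignment segments
#'
#' Finds the best contiguous alignment of the map to the reference; when a
#' query prefix/suffix of at least `min_seg_labels` labels remains unaligned,
#' the remainder is realigned genome-wide (recursively). Only segments with
#' `p < align_p` are returned.
#'
#' @param consensus `om_consensus` (or numeric site vector).
#' @param ref `om_ref`.
#' @param scoring [scoring_params()].
#' @param null `om_null` fitted on the reference channel.
#' @param params [sv_params()].
#' @param channel Reference channel.
#' @return List of segments: each an `om_alignment` plus `contig` and the
#'   global query index range (`q_from`, `q_to`).
#' @export
segment_alignment <- function(consensus, ref, scoring, null,
                              params = sv_params(), channel = 1L) {
  q <- as_labels(consensus)
  qlen <- if (inherits(consensus, "om_consensus")) consensus$length else NULL
  segs <- list()
  recurse <- function(idx, depth) {
    if (length(idx) < params$min_seg_labels || depth > 4) return()
    qq <- q[idx] - q[idx[1]]
    best <- NULL; best_ct <- NULL
    for (ct in ref$contigs) {
      t <- ct$channels[[channel]]
      al <- align_maps(qq, t, scoring, qlen = max(qq), null = null)
      if (is.finite(al$score) && (is.null(best) || al$score > best$score)) {
        best <- al; best_ct <- ct$id
      }
    }
    pcut <- if (depth == 1L) params$align_p
            else max(params$align_p, params$secondary_p)
    if (is.null(best) || is.na(best$log_p) ||
        best$log_p >= log(pcut)) return()
    # tension check: a local alignment can absorb a large indel as a chain
    # of small skips rather than breaking; when the cumulative query-vs-
    # reference drift across the alignment is large, split the query at the
    # largest drift step and realign both halves independently
    tp <- ref$contigs[[best_ct]]$channels[[channel]][best$pairs[, "tidx"]]
    qp <- qq[best$pairs[, "qidx"]]
    drift <- (qp - qp[1]) - best$sign * (tp - tp[1])
    if (depth < 6 && diff(range(drift)) > params$drift_tol_bp &&
        nrow(best$pairs) >= 2 * params$min_seg_labels) {
      step <- which.max(abs(diff(drift)))
      cutq <- best$pairs[step, "qidx"]
      recurse(idx[1:cutq], depth + 1L)
      if (length(idx) > cutq)
        recurse(idx[(cutq + 1L):length(idx)], depth + 1L)
      return()
    }
    lo <- min(best$pairs[, "qidx"]); hi <- max(best$pairs[, "qidx"])
    best$pairs[, "qidx"] <- best$pairs[, "qidx"] + idx[1] - 1L
    best$contig <- best_ct
    best$q_from <- idx[lo]; best$q_to <- idx[hi]
    segs[[length(segs) + 1L]] <<- best
    if (lo - 1L >= params$min_seg_labels) recurse(idx[1:(lo - 1L)], depth + 1L)
    if (length(idx) - hi >= params$min_seg_labels)
      recurse(idx[(hi + 1L):length(idx)], depth + 1L)
  }
  recurse(seq_along(q), 1L)
  if (!length(segs)) return(list())
  ord <- order(vapply(segs, function(s) s$q_from, 1L))
  segs[ord]
}

#' Indel outlier test over an alignment
#'
#' For each region between adjacent matched label pairs the discrepancy
#' `D = query span - reference span` is tested two-sided against the sizing
#' model `Normal(0, k * sd0^2 + sd_scale * ref_span)`; regions with
#' `p < outlier_p` (strict) or at least `skip_excess` consecutive unaligned
#' labels on one side are reported. `D > 0` indicates insertion, `D < 0`
#' deletion.
#'
#' @param alignment `om_alignment` (query = consensus sites).
#' @param query Query label positions the alignment refers to.
#' @param target_labels Target (reference) label positions.
#' @param scoring [scoring_params()] (sizing model).
#' @param params [sv_params()].
#' @return data.frame: q_lo, q_hi, t_lo, t_hi (flanking matched positions),
#'   tidx_lo, tidx_hi, D, p, nq_skip, nt_skip.
#' @export
indel_outlier_test <- function(alignment, query, target_labels, scoring,
                               params = sv_params()) {
  pr <- alignment$pairs
  out <- NULL
  if (nrow(pr) < 2) return(out)
  q <- query
  tpos <- target_labels[pr[, "tidx"]]
  for (k in seq_len(nrow(pr) - 1L)) {
    qs <- q[pr[k, "qidx"]]; qe <- q[pr[k + 1L, "qidx"]]
    ts <- tpos[k]; te <- tpos[k + 1L]
    refspan <- abs(te - ts)
    qspan <- qe - qs
    D <- qspan - refspan
    nt_skip <- abs(pr[k + 1L, "tidx"] - pr[k, "tidx"]) - 1L
    nq_skip <- pr[k + 1L, "qidx"] - pr[k, "qidx"] - 1L
    sdv <- sqrt((nt_skip + 1) * scoring$sd0^2 + scoring$sd_scale * refspan)
    p <- 2 * pnorm(-abs(D) / sdv)
    if (p < params$outlier_p || nt_skip >= params$skip_excess ||
        nq_skip >= params$skip_excess) {
      out <- rbind(out, data.frame(
        q_lo = qs, q_hi = qe, t_lo = min(ts, te), t_hi = max(ts, te),
        tidx_lo = min(pr[k, "tidx"], pr[k + 1L, "tidx"]),
        tidx_hi = max(pr[k, "tidx"], pr[k + 1L, "tidx"]),
        D = D, p = p, nq_skip = nq_skip, nt_skip = nt_skip))
    }
  }
  out
}

# Breakpoint-uncertainty interval on the flank side of a junction.
# The breakpoint lies after the last matched reference label `anchor`
# (toward the event); it can be no further than the next reference label and
# no further than the unexplained query span `q_gap`.
flank_interval <- function(anchor, direction, q_gap, ref_labels,
                           resolution_bp = 1500) {
  # an unmatched reference label within the optical resolution of the anchor
  # may be merged with it rather than absent, so it cannot bound the
  # breakpoint; the first label beyond the resolution limit can
  if (direction > 0) {
    nxt <- ref_labels[ref_labels > anchor + resolution_bp]
    lim <- if (length(nxt)) min(nxt) - anchor else Inf
    c(lo = anchor, hi = anchor + max(min(q_gap, lim), 0))
  } else {
    prv <- ref_labels[ref_labels < anchor - resolution_bp]
    lim <- if (length(prv)) anchor - max(prv) else Inf
    c(lo = anchor - max(min(q_gap, lim), 0), hi = anchor)
  }
}

#' Classify variants from alignment segments and outlier regions
#'
#' Outlier regions become insertion/deletion calls. Adjacent segments on the
#' same chromosome with opposite orientations indicate an inversion; segments
#' on different chromosomes an inter-chromosomal translocation; a reference
#' gap over the translocation distance on the same strand an
#' intra-chromosomal translocation; smaller same-strand gaps a large indel
#' via the span difference.
#'
#' @param segments From [segment_alignment()].
#' @param query Query (consensus) label positions.
#' @param ref `om_ref`.
#' @param scoring [scoring_params()].
#' @param params [sv_params()].
#' @param map_id Consensus map id for provenance.
#' @param channel Reference channel.
#' @param mol_ranges Optional per-molecule matched-span table of the map
#'   (`mol`, `lo`, `hi` in map coordinates) used to validate that events are
#'   crossed by at least `min_junction_support` molecules.
#' @return data.frame of calls (see [sv_params()] for interval semantics).
#' @export
classify_variant <- function(segments, query, ref, scoring,
                             params = sv_params(), map_id = "map",
                             channel = 1L, mol_ranges = NULL) {
  calls <- empty_calls()
  # molecule-span validation: an event is real only if enough of the map's
  # own molecules align across it; sparse junctions are assembly artifacts
  supported <- function(q_lo, q_hi) {
    if (is.null(mol_ranges) || is.na(q_lo)) return(TRUE)
    sum(mol_ranges$lo < q_lo - 5e3 & mol_ranges$hi > q_hi + 5e3) >=
      params$min_junction_support
  }
  add_call <- function(type, contig, bp1, bp2, size, log_p,
                       flags = "", contig2 = contig, ref_span = NA,
                       q_lo = NA_real_, q_hi = NA_real_) {
    if (identical(contig, contig2) && bp2[["lo"]] < bp1[["lo"]]) {
      tmp <- bp1; bp1 <- bp2; bp2 <- tmp
    }
    calls <<- rbind(calls, data.frame(
      call_id = nrow(calls) + 1L, type = type, contig = contig,
      contig2 = contig2, bp1_lo = bp1[["lo"]], bp1_hi = bp1[["hi"]],
      bp2_lo = bp2[["lo"]], bp2_hi = bp2[["hi"]], size = size,
      ref_span = ref_span, zygosity = "unknown", log_p = log_p,
      maps = map_id, flags = flags, channel = channel,
      q_lo = q_lo, q_hi = q_hi, stringsAsFactors = FALSE))
  }
  ref_labels_of <- function(ct) ref$contigs[[ct]]$channels[[channel]]

  # outlier indels within each segment
  for (seg in segments) {
    outl <- indel_outlier_test(seg, query,
                               ref_labels_of(seg$contig), scoring, params)
    if (is.null(outl)) next
    for (r in seq_len(nrow(outl))) {
      o <- outl[r, ]
      # unaligned-label clusters without a significant span discrepancy are
      # reported only when the discrepancy is still substantial
      if (o$p >= params$outlier_p && abs(o$D) < 5000) next
      if (abs(o$D) < params$min_size_bp) next
      if (!supported(o$q_lo, o$q_hi)) next
      rl <- ref_labels_of(seg$contig)
      q_gap <- max(o$q_hi - o$q_lo, 0)
      if (o$D > 0) {  # insertion: breakpoint between the flanking labels
        bp1 <- c(lo = o$t_lo, hi = o$t_hi)
        bp2 <- bp1
      } else {
        bp1 <- flank_interval(o$t_lo, +1, q_gap, rl)
        bp2 <- flank_interval(o$t_hi, -1, q_gap, rl)
      }
      add_call(if (o$D > 0) "insertion" else "deletion", seg$contig,
               bp1, bp2, o$D, log(max(o$p, 1e-320)),
               ref_span = o$t_hi - o$t_lo, q_lo = o$q_lo, q_hi = o$q_hi)
    }
  }

  # junctions between adjacent segments (ordered by query coordinate)
  if (length(segments) >= 2) {
    for (k in seq_len(length(segments) - 1L)) {
      rj <- refine_junction(segments[[k]], segments[[k + 1L]], query, ref,
                            channel)
      segments[[k]] <- rj$A; segments[[k + 1L]] <- rj$B
      A <- segments[[k]]; B <- segments[[k + 1L]]
      A$tpos <- segment_tpos(A, ref, channel)
      B$tpos <- segment_tpos(B, ref, channel)
      # a mispaired match at a segment edge (shifted by one label spacing)
      # shows as an offset step against its immediate neighbours; trim it so
      # it cannot anchor the junction
      trim_edge <- function(seg, head) {
        repeat {
          n <- nrow(seg$pairs)
          if (n < 6) return(seg)
          off <- seg$tpos - seg$sign * query[seg$pairs[, "qidx"]]
          if (head) {
            if (abs(off[1] - median(off[2:6])) <= 3500) return(seg)
            seg$pairs <- seg$pairs[-1, , drop = FALSE]
            seg$tpos <- seg$tpos[-1]
          } else {
            if (abs(off[n] - median(off[(n - 5):(n - 1)])) <= 3500)
              return(seg)
            seg$pairs <- seg$pairs[-n, , drop = FALSE]
            seg$tpos <- seg$tpos[-n]
          }
        }
      }
      A <- trim_edge(A, head = FALSE)
      B <- trim_edge(B, head = TRUE)
      nA <- nrow(A$pairs); qA <- query[A$pairs[nA, "qidx"]]
      qB <- query[B$pairs[1L, "qidx"]]
      tA <- A$tpos[nA]; tB <- B$tpos[1L]
      q_gap <- qB - qA
      # robust junction span discrepancy: median over anchor-pair
      # combinations from the segments' facing ends, so a single mis-paired
      # anchor label cannot bias the size estimate
      iA <- max(1L, nA - 4L):nA
      iB <- seq_len(min(5L, nrow(B$pairs)))
      combo <- expand.grid(a = iA, b = iB)
      D_med <- median((query[B$pairs[combo$b, "qidx"]] -
                         query[A$pairs[combo$a, "qidx"]]) -
                        A$sign * (B$tpos[combo$b] - A$tpos[combo$a]))
      lp <- max(A$log_p, B$log_p)
      strong <- lp < log(params$align_p)
      if (!identical(A$contig, B$contig)) {
        if (!strong || !supported(min(qA, qB), max(qA, qB))) next
        add_call("inter_translocation", A$contig,
                 flank_interval(tA, if (A$sign > 0) +1 else -1, q_gap,
                                ref_labels_of(A$contig)),
                 flank_interval(tB, if (B$sign > 0) -1 else +1, q_gap,
                                ref_labels_of(B$contig)),
                 0, lp, contig2 = B$contig)
      } else if (A$sign != B$sign) {
        if (!strong || !supported(min(qA, qB), max(qA, qB))) next
        add_call("inversion_junction", A$contig,
                 flank_interval(tA, if (A$sign > 0) +1 else -1, q_gap,
                                ref_labels_of(A$contig)),
                 flank_interval(tB, if (B$sign > 0) -1 else +1, q_gap,
                                ref_labels_of(B$contig)),
                 0, lp, ref_span = abs(tB - tA))
      } else {
        ref_gap <- (tB - tA) * A$sign
        if (ref_gap > params$intra_trans_bp) {
          if (!strong || !supported(min(qA, qB), max(qA, qB))) next
          add_call("intra_translocation", A$contig,
                   flank_interval(tA, if (A$sign > 0) +1 else -1, q_gap,
                                  ref_labels_of(A$contig)),
                   flank_interval(tB, if (A$sign > 0) -1 else +1, q_gap,
                                  ref_labels_of(A$contig)),
                   0, lp, ref_span = ref_gap)
        } else {
          # the nearest-anchor span difference is exact on clean junctions
          # (and at zero noise); the anchor-combination median is robust to
          # a single mis-paired anchor -- prefer the former unless they
          # disagree beyond measurement noise
          D_near <- q_gap - ref_gap
          D <- if (A$sign != B$sign) D_near
               else if (abs(D_near - D_med) < 300) D_near else D_med
          sdv <- sqrt(scoring$sd0^2 + scoring$sd_scale * abs(ref_gap))
          p <- 2 * pnorm(-abs(D) / sdv)
          if (p < params$outlier_p && abs(D) >= params$min_size_bp &&
              supported(min(qA, qB), max(qA, qB))) {
            rl <- ref_labels_of(A$contig)
            if (D < 0) {
              bp1 <- flank_interval(tA, if (A$sign > 0) +1 else -1, q_gap, rl)
              bp2 <- flank_interval(tB, if (A$sign > 0) -1 else +1, q_gap, rl)
            } else {
              bp1 <- c(lo = min(tA, tB), hi = max(tA, tB))
              bp2 <- bp1
            }
            add_call(if (D < 0) "deletion" else "insertion", A$contig,
                     bp1, bp2, D, log(max(p, 1e-320)),
                     ref_span = abs(ref_gap), q_lo = min(qA, qB),
                     q_hi = max(qA, qB))
          }
        }
      }
    }
    # two opposite-orientation junctions around one middle segment = one
    # inversion with both breakpoints
    inv <- which(calls$type == "inversion_junction")
    if (length(inv) == 2L && calls$contig[inv[1]] == calls$contig[inv[2]]) {
      j1 <- calls[inv[1], ]; j2 <- calls[inv[2], ]
      lo_first <- j1$bp1_lo <= j2$bp1_lo
      left <- if (lo_first) j1 else j2
      right <- if (lo_first) j2 else j1
      mid1 <- (left$bp1_lo + left$bp1_hi) / 2
      mid2 <- (right$bp2_lo + right$bp2_hi) / 2
      calls <- calls[-inv, ]
      add_call("inversion", j1$contig,
               c(lo = left$bp1_lo, hi = left$bp1_hi),
               c(lo = right$bp2_lo, hi = right$bp2_hi), 0,
               min(j1$log_p, j2$log_p), ref_span = mid2 - mid1)
    } else if (length(inv) >= 1L) {
      # a single orientation flip still localizes both breakpoints (the
      # interior side of the junction maps near the far inversion edge)
      calls$type[inv] <- "inversion"
      calls$flags[inv] <- paste0(calls$flags[inv], "open_end")
    }
  }
  calls
}


# Refine the query-label assignment at the junction between two adjacent
# segments. A local DP alignment can steal a flank label across the
# junction (an extra leading/trailing match with a tolerable one-interval
# residual), which biases both the junction gap and the size estimate.
# Each boundary label is reassigned to the segment whose local affine frame
# places it closest to a reference label, with the split kept monotone.
refine_junction <- function(A, B, query, ref, channel = 1L) {
  rlA <- ref$contigs[[A$contig]]$channels[[channel]]
  rlB <- ref$contigs[[B$contig]]$channels[[channel]]
  nA <- nrow(A$pairs); nB <- nrow(B$pairs)
  kA <- min(3L, nA - 2L); kB <- min(3L, nB - 2L)
  if (kA < 1L || kB < 1L) return(list(A = A, B = B))
  coreA <- seq_len(nA - kA)
  coreB <- seq_len(nB)[-seq_len(kB)]
  tposA <- rlA[A$pairs[, "tidx"]]; tposB <- rlB[B$pairs[, "tidx"]]
  offA <- median(tposA[coreA] - A$sign * query[A$pairs[coreA, "qidx"]])
  offB <- median(tposB[coreB] - B$sign * query[B$pairs[coreB, "qidx"]])
  zone <- (A$pairs[nA - kA, "qidx"] + 1L):(B$pairs[kB + 1L, "qidx"] - 1L)
  if (!length(zone)) return(list(A = A, B = B))
  fit <- function(x, sign, off, rl) {
    p <- sign * x + off
    i <- findInterval(p, rl)
    dmin <- pmin(abs(rl[pmax(i, 1L)] - p), abs(rl[pmin(i + 1L, length(rl))] - p))
    pmin(dmin, 3000)
  }
  dA <- fit(query[zone], A$sign, offA, rlA)
  dB <- fit(query[zone], B$sign, offB, rlB)
  nz <- length(zone)
  cost <- vapply(0:nz, function(k)
    sum(dA[seq_len(k)]) + sum(dB[seq_len(nz) > k]), 1)
  kbest <- which.min(cost) - 1L
  rebuild <- function(seg, core_idx, add_q, sign, off, rl, head) {
    pr <- seg$pairs[core_idx, , drop = FALSE]
    if (length(add_q)) {
      p <- sign * query[add_q] + off
      ti <- findInterval(p, rl)
      ti <- ifelse(abs(rl[pmax(ti, 1L)] - p) <=
                     abs(rl[pmin(ti + 1L, length(rl))] - p),
                   pmax(ti, 1L), pmin(ti + 1L, length(rl)))
      ok <- abs(rl[ti] - p) < 2000
      newp <- cbind(qidx = add_q[ok], tidx = ti[ok])
      pr <- if (head) rbind(newp, pr) else rbind(pr, newp)
    }
    o <- order(pr[, "qidx"])
    pr <- pr[o, , drop = FALSE]
    # enforce target monotonicity consistent with orientation
    keep <- rep(TRUE, nrow(pr))
    if (nrow(pr) > 1) {
      dt <- diff(pr[, "tidx"]) * seg$sign
      bad <- which(dt <= 0)
      for (b in bad) keep[if (head) b else b + 1L] <- FALSE
    }
    seg$pairs <- pr[keep, , drop = FALSE]
    seg
  }
  A2 <- rebuild(A, coreA, zone[seq_len(kbest)], A$sign, offA, rlA, head = FALSE)
  B2 <- rebuild(B, coreB, if (kbest < nz) zone[(kbest + 1L):nz] else integer(0),
                B$sign, offB, rlB, head = TRUE)
  if (nrow(A2$pairs) >= 2) A <- A2
  if (nrow(B2$pairs) >= 2) B <- B2
  list(A = A, B = B)
}

# reference positions of the matched target labels of a segment
segment_tpos <- function(seg, ref, channel = 1L) {
  ref$contigs[[seg$contig]]$channels[[channel]][seg$pairs[, "tidx"]]
}

#' Call SVs for a set of consensus maps against a reference (one channel)
#'
#' Runs [segment_alignment()] and [classify_variant()] per map, then merges
#' equivalent calls supported by several maps (same type, reciprocal overlap
#' above `dedupe_overlap`).
#'
#' @param consensi List of `om_consensus`.
#' @param ref `om_ref`.
#' @param scoring [scoring_params()].
#' @param null `om_null` for this channel.
#' @param params [sv_params()].
#' @param channel Reference channel.
#' @return List: `calls` (data.frame), `coverage` (per-map aligned spans:
#'   map, contig, t_lo, t_hi, n_segments), `map_rate_maps` (fraction of maps
#'   aligning).
#' @export
call_svs <- function(consensi, ref, scoring, null, params = sv_params(),
                     channel = 1L) {
  all_calls <- empty_calls()
  cov <- NULL
  for (cons in consensi) {
    segs <- segment_alignment(cons, ref, scoring, null, params, channel)
    if (!length(segs)) next
    q <- cons$sites
    cl <- classify_variant(segs, q, ref, scoring, params, cons$id, channel,
                           mol_ranges = cons$mol_ranges)
    if (nrow(cl)) all_calls <- rbind(all_calls, cl)
    for (seg in segs) {
      tp <- segment_tpos(seg, ref, channel)
      cov <- rbind(cov, data.frame(map = cons$id, hap = cons$hap,
                                   contig = seg$contig, t_lo = min(tp),
                                   t_hi = max(tp), n_segments = length(segs),
                                   stringsAsFactors = FALSE))
    }
  }
  list(calls = dedupe_calls(all_calls, params), coverage = cov)
}

call_interval <- function(calls) {
  cbind(lo = pmin(calls$bp1_lo, calls$bp2_lo),
        hi = pmax(calls$bp1_hi, calls$bp2_hi))
}

reciprocal_overlap <- function(a_lo, a_hi, b_lo, b_hi) {
  ov <- pmin(a_hi, b_hi) - pmax(a_lo, b_lo)
  wa <- pmax(a_hi - a_lo, 1); wb <- pmax(b_hi - b_lo, 1)
  pmax(ov, 0) / pmax(wa, wb)
}

dedupe_calls <- function(calls, params) {
  if (nrow(calls) < 2) return(calls)
  iv <- call_interval(calls)
  keep <- rep(TRUE, nrow(calls))
  o <- order(calls$log_p)
  for (a_i in seq_along(o)) {
    i <- o[a_i]
    if (!keep[i]) next
    for (b_i in seq_along(o)[-seq_len(a_i)]) {
      j <- o[b_i]
      if (!keep[j] || calls$type[i] != calls$type[j] ||
          calls$contig[i] != calls$contig[j]) next
      # same event when intervals overlap reciprocally and sizes agree
      rov <- reciprocal_overlap(iv[i, 1], iv[i, 2], iv[j, 1], iv[j, 2])
      size_ok <- if (abs(calls$size[i]) > 1000)
        abs(calls$size[j] - calls$size[i]) < 0.2 * abs(calls$size[i]) + 2000
      else TRUE
      if (rov >= params$dedupe_overlap && size_ok) {
        calls$maps[i] <- paste(unique(c(
          strsplit(calls$maps[i], ",")[[1]],
          strsplit(calls$maps[j], ",")[[1]])), collapse = ",")
        keep[j] <- FALSE
      }
    }
  }
  out <- calls[keep, , drop = FALSE]
  out$call_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign zygosity to calls from allele-map coverage
#'
#' A call supported by a variant map while another map covers the same locus
#' concordantly (no matching call, full span) is heterozygous; with no
#' concordant covering map it is homozygous on diploid contigs and
#' hemizygous on haploid ones; without enough covering maps it stays
#' unknown.
#'
#' @param calls Calls data.frame from [call_svs()].
#' @param coverage Coverage table from [call_svs()].
#' @param ploidy Named vector: contig -> copy number (e.g. `c(chrX = 1)`).
#' @param params [sv_params()].
#' @return Calls with the `zygosity` column filled.
#' @export
call_zygosity <- function(calls, coverage, ploidy, params = sv_params()) {
  if (!nrow(calls)) return(calls)
  iv <- call_interval(calls)
  m <- params$zygosity_margin_bp
  for (i in seq_len(nrow(calls))) {
    ct <- calls$contig[i]
    pl <- ploidy[[ct]] %||% NA_integer_
    if (is.na(pl)) { calls$zygosity[i] <- "unknown"; next }
    sup_maps <- strsplit(calls$maps[i], ",")[[1]]
    conc <- coverage[coverage$contig == ct & coverage$n_segments == 1L &
                       !coverage$map %in% sup_maps, , drop = FALSE]
    covering <- conc[conc$t_lo <= iv[i, 1] - m & conc$t_hi >= iv[i, 2] + m, ,
                     drop = FALSE]
    concordant <- nrow(covering) > 0
    if (!concordant && calls$type[i] == "deletion") {
      # the wild-type allele of a large heterozygous deletion is often
      # assembled as two maps cut near the junction; material retained
      # anywhere inside the deleted interval still indicates a second allele
      int_lo <- calls$bp1_hi[i]; int_hi <- calls$bp2_lo[i]
      if (int_hi > int_lo && nrow(conc)) {
        ov <- pmin(conc$t_hi, int_hi) - pmax(conc$t_lo, int_lo)
        cov_frac <- sum(pmax(ov, 0)) / (int_hi - int_lo)
        concordant <- cov_frac >= 0.5
      }
    }
    covering_any <- coverage[coverage$contig == ct, , drop = FALSE]
    covering_any <- nrow(covering_any) > 0 &&
      any(covering_any$t_hi >= iv[i, 1] & covering_any$t_lo <= iv[i, 2])
    calls$zygosity[i] <-
      if (pl == 1) "hemizygous"
      else if (concordant) "heterozygous"
      else if (pl >= 2 && covering_any) "homozygous"
      else "unknown"
  }
  calls
}

#' Merge call sets from two independent enzyme channels
#'
#' Calls are paired by type and reciprocal overlap; merged
#' breakpoint-uncertainty intervals are the intersections of the two
#' channels' intervals (falling back to the narrower interval when disjoint,
#' flagged), the size is the mean, and unpaired calls pass through flagged
#' `single_channel`.
#'
#' @param calls1,calls2 Call data.frames from [call_svs()].
#' @param params [sv_params()].
#' @return Merged calls data.frame.
#' @export
combine_dual_enzyme <- function(calls1, calls2, params = sv_params()) {
  if (!nrow(calls1) && !nrow(calls2)) return(empty_calls())
  iv1 <- call_interval(calls1); iv2 <- call_interval(calls2)
  used2 <- rep(FALSE, nrow(calls2))
  out <- NULL
  isect <- function(lo1, hi1, lo2, hi2, flag_env) {
    lo <- max(lo1, lo2); hi <- min(hi1, hi2)
    if (lo <= hi) return(c(lo = lo, hi = hi))
    flag_env$disjoint <- TRUE
    if (hi1 - lo1 <= hi2 - lo2) c(lo = lo1, hi = hi1) else c(lo = lo2, hi = hi2)
  }
  for (i in seq_len(nrow(calls1))) {
    j <- which(!used2 & calls2$type == calls1$type[i] &
                 calls2$contig == calls1$contig[i])
    if (length(j)) {
      rov <- reciprocal_overlap(iv1[i, 1], iv1[i, 2], iv2[j, 1], iv2[j, 2])
      j <- j[rov >= params$dedupe_overlap]
    }
    if (length(j)) {
      j <- j[1]
      used2[j] <- TRUE
      fe <- new.env(); fe$disjoint <- FALSE
      b1 <- isect(calls1$bp1_lo[i], calls1$bp1_hi[i],
                  calls2$bp1_lo[j], calls2$bp1_hi[j], fe)
      b2 <- isect(calls1$bp2_lo[i], calls1$bp2_hi[i],
                  calls2$bp2_lo[j], calls2$bp2_hi[j], fe)
      mc <- calls1[i, ]
      if (fe$disjoint) {
        # the channels disagree on a breakpoint, so one junction is
        # corrupted; mixing sides across channels would pair a good anchor
        # with a bad one. Keep the coherent call from the channel whose
        # total breakpoint uncertainty is smaller.
        w1 <- (calls1$bp1_hi[i] - calls1$bp1_lo[i]) +
          (calls1$bp2_hi[i] - calls1$bp2_lo[i])
        w2 <- (calls2$bp1_hi[j] - calls2$bp1_lo[j]) +
          (calls2$bp2_hi[j] - calls2$bp2_lo[j])
        src <- if (w1 <= w2) calls1[i, ] else calls2[j, ]
        b1 <- c(lo = src$bp1_lo, hi = src$bp1_hi)
        b2 <- c(lo = src$bp2_lo, hi = src$bp2_hi)
      }
      mc$bp1_lo <- b1[["lo"]]; mc$bp1_hi <- b1[["hi"]]
      mc$bp2_lo <- b2[["lo"]]; mc$bp2_hi <- b2[["hi"]]
      mc$size <- mean(c(calls1$size[i], calls2$size[j]))
      mc$ref_span <- mean(c(calls1$ref_span[i], calls2$ref_span[j]))
      mc$log_p <- min(calls1$log_p[i], calls2$log_p[j])
      mc$maps <- paste(calls1$maps[i], calls2$maps[j], sep = ";")
      mc$channel <- NA_integer_
      if (fe$disjoint) mc$flags <- paste0(mc$flags, "disjoint_intervals")
      if (mc$zygosity == "unknown") mc$zygosity <- calls2$zygosity[j]
      out <- rbind(out, mc)
    } else {
      mc <- calls1[i, ]
      mc$flags <- paste0(mc$flags, "single_channel")
      out <- rbind(out, mc)
    }
  }
  for (j in which(!used2)) {
    mc <- calls2[j, ]
    mc$flags <- paste0(mc$flags, "single_channel")
    out <- rbind(out, mc)
  }
  out <- out %||% empty_calls()
  out$call_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Partition calls into novel and known against an SV catalog
#'
#' Mechanical filter: a call matching a catalog interval of the same type
#' with reciprocal overlap of at least 50% is labeled known.
#'
#' @param calls Calls data.frame.
#' @param catalog data.frame with contig, start, end, type (e.g. from
#'   [read_sv_catalog()]).
#' @param min_overlap Reciprocal overlap threshold.
#' @return Calls with a logical `known` column.
#' @export
filter_known_sv <- function(calls, catalog, min_overlap = 0.5) {
  calls$known <- FALSE
  if (!nrow(calls) || is.null(catalog) || !nrow(catalog)) return(calls)
  iv <- call_interval(calls)
  for (i in seq_len(nrow(calls))) {
    hits <- catalog[catalog$type == calls$type[i] &
                      catalog$contig == calls$contig[i], , drop = FALSE]
    if (!nrow(hits)) next
    rov <- reciprocal_overlap(iv[i, 1], iv[i, 2], hits$start, hits$end)
    if (any(rov >= min_overlap)) calls$known[i] <- TRUE
  }
  calls
}

#' Read a BED-dialect SV catalog
#'
#' Tab-separated `contig start end type`; malformed rows are skipped with a
#' warning. Coordinates are taken as 0-based half-open (BED convention).
#'
#' @param path File path.
#' @return data.frame(contig, start, end, type).
#' @export
read_sv_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- NULL
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    st <- suppressWarnings(as.numeric(f[2]))
    en <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 4L || is.na(st) || is.na(en) || en <= st) {
      warning(sprintf("catalog row %d malformed; skipped", ln))
      next
    }
    out <- rbind(out, data.frame(contig = f[1], start = st, end = en,
                                 type = f[4], stringsAsFactors = FALSE))
  }
  out %||% data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), type = character(0))
}

#' Write calls in the SMAP dialect
#'
#' Tab-separated with a `# omsv-smap v1` header: call id, type, contigs,
#' breakpoint-uncertainty intervals (1-based), signed size (negative = loss
#' of material), zygosity, confidence (log10 P), flags, supporting maps.
#'
#' @param calls Calls data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smap <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# omsv-smap v1",
               paste0("#h SmapId\tType\tContig1\tContig2\tBp1Lo\tBp1Hi\t",
                      "Bp2Lo\tBp2Hi\tSize\tRefSpan\tZygosity\tLog10P\t",
                      "Flags\tMaps")), con)
  if (nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      writeLines(sprintf(
        "%d\t%s\t%s\t%s\t%.1f\t%.1f\t%.1f\t%.1f\t%.1f\t%.1f\t%s\t%.3f\t%s\t%s",
        calls$call_id[i], calls$type[i], calls$contig[i], calls$contig2[i],
        calls$bp1_lo[i] + 1, calls$bp1_hi[i] + 1, calls$bp2_lo[i] + 1,
        calls$bp2_hi[i] + 1, calls$size[i],
        if (is.na(calls$ref_span[i])) -1 else calls$ref_span[i],
        calls$zygosity[i], calls$log_p[i] / log(10),
        ifelse(nzchar(calls$flags[i]), calls$flags[i], "."),
        calls$maps[i]), con)
    }
  }
  invisible(path)
}

#' Read an SMAP-dialect file written by [write_smap()]
#' @param path File path.
#' @return Calls data.frame.
#' @export
read_smap <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# omsv-smap"))
    stop_om("%s: not an omsv SMAP file (missing header)", path)
  body <- lines[!startsWith(lines, "#")]
  out <- empty_calls()
  for (ln in seq_along(body)) {
    f <- strsplit(body[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 14L) stop_om("%s row %d: expected 14 columns", path, ln)
    rs <- as.numeric(f[10])
    out <- rbind(out, data.frame(
      call_id = as.integer(f[1]), type = f[2], contig = f[3], contig2 = f[4],
      bp1_lo = as.numeric(f[5]) - 1, bp1_hi = as.numeric(f[6]) - 1,
      bp2_lo = as.numeric(f[7]) - 1, bp2_hi = as.numeric(f[8]) - 1,
      size = as.numeric(f[9]), ref_span = if (rs < 0) NA_real_ else rs,
      zygosity = f[11], log_p = as.numeric(f[12]) * log(10),
      maps = f[14], flags = ifelse(f[13] == ".", "", f[13]),
      channel = NA_integer_, q_lo = NA_real_, q_hi = NA_real_,
      stringsAsFactors = FALSE))
  }
  out
}
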