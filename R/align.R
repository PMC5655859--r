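# map_align module: DP alignment of label maps with orientation search,
# sizing-error scoring, and empirical (Gumbel-tail) P-values.

#' Alignment scoring parameters
#'
#' Score = sum over matched pairs of
#' `match_bonus - residual^2 / (2 * (sd0^2 + sd_scale * ref_interval))`
#' minus `miss_penalty` per skipped target label and `false_penalty` per
#' skipped query label. `sd0`/`sd_scale` should mirror the simulator's sizing
#' model.
#'
#' @param match_bonus Bonus per matched label pair.
#' @param miss_penalty Penalty per skipped target label.
#' @param false_penalty Penalty per skipped query label.
#' @param max_skip Maximum consecutive skipped labels per side (lookback).
#' @param sd0,sd_scale Sizing-error model (bp; bp^2 per bp).
#' @return An object of class `om_scoring`.
#' @export
scoring_params <- function(match_bonus = 3, miss_penalty = 1,
                           false_penalty = 1, max_skip = 5, sd0 = 100,
                           sd_scale = 12) {
  stopifnot(miss_penalty >= 0, false_penalty >= 0, max_skip >= 1)
  structure(list(match_bonus = match_bonus, miss_penalty = miss_penalty,
                 false_penalty = false_penalty, max_skip = as.integer(max_skip),
                 sd0 = sd0, sd_scale = sd_scale), class = "om_scoring")
}

empty_alignment <- function(query_id = NA, target_id = NA) {
  structure(list(query_id = query_id, target_id = target_id,
                 orientation = "+", pairs = cbind(qidx = integer(0),
                                                  tidx = integer(0)),
                 residuals = numeric(0), score = -Inf, p_value = NA_real_,
                 log_p = NA_real_, offset = NA_real_, qspan = 0, tspan = 0,
                 q_left_bp = NA_real_, q_right_bp = NA_real_, n_query = 0L),
            class = "om_alignment")
}

#' Align two label maps
#'
#' Finds the maximum-score monotone matching of query to target labels by
#' dynamic programming (local on both ends, lookback bounded by `max_skip`),
#' searching both orientations. Deterministic tie-breaking: more matched
#' pairs, then smaller total |residual|, then `+` orientation.
#'
#' @param query,target Sorted numeric label positions (bp), or objects with
#'   labels (`om_molecule` channel 1 / `om_consensus` sites).
#' @param params [scoring_params()].
#' @param qlen Query backbone length (for unaligned-end bookkeeping);
#'   defaults to the last label position.
#' @param null Optional null model from [fit_null()]; when given, the
#'   alignment carries a P-value.
#' @param orientation `"both"`, `"+"` or `"-"`.
#' @param query_id,target_id Carried through into the result.
#' @param fast Use a lookback-1 screen to pick orientation and a target
#'   window before the full DP (exactness traded for speed on long targets;
#'   used by the assembler's inner loops).
#' @return An `om_alignment`: orientation, matched pairs (query/target label
#'   indices), per-pair interval residuals, score, P-value, offset
#'   (`target ~ orientation * query + offset`), spans, unaligned query ends.
#' @export
align_maps <- function(query, target, params = scoring_params(), qlen = NULL,
                       null = NULL, orientation = "both", query_id = NA,
                       target_id = NA, fast = FALSE) {
  q <- as_labels(query); t <- as_labels(target)
  if (length(q) < 2 || length(t) < 2) return(empty_alignment(query_id, target_id))
  qlen <- qlen %||% (max(q) + min(q))
  qm <- sort(qlen - q)  # mirrored query
  run <- function(qq, tv = t, base = 0L) {
    r <- dp_align_cpp(qq, tv, params$match_bonus, params$miss_penalty,
                      params$false_penalty, params$sd0, params$sd_scale,
                      params$max_skip)
    if (base > 0L && length(r$tidx)) r$tidx <- r$tidx + base
    r
  }
  best <- NULL
  if (fast && length(t) > 80 && orientation == "both") {
    # lookback-1 screen picks orientation and a target window for the full DP
    sf <- dp_screen1_cpp(q, t, params$match_bonus, params$sd0,
                         params$sd_scale, qlen)
    sr <- dp_screen1_cpp(qm, t, params$match_bonus, params$sd0,
                         params$sd_scale, qlen)
    top <- max(sf$score, sr$score)
    if (top >= 8) {
      wins <- list()
      for (o in c("+", "-")) {
        scr <- if (o == "+") sf else sr
        if (scr$score >= top - 8)
          wins[[length(wins) + 1L]] <- list(o = o, tc = t[scr$tend])
        if (is.finite(scr$score2) && scr$score2 >= top - 8)
          wins[[length(wins) + 1L]] <- list(o = o, tc = t[scr$tend2])
      }
      for (w in wins) {
        idx <- which(t >= w$tc - qlen - 8e4 & t <= w$tc + qlen + 8e4)
        if (length(idx) < 2) next
        r <- run(if (w$o == "+") q else qm, t[idx], idx[1] - 1L)
        r$orientation <- w$o
        if (is.null(best) || r$score > best$score + 1e-9) best <- r
      }
    }
    if (is.null(best)) return(empty_alignment(query_id, target_id))
  } else {
  if (orientation %in% c("both", "+")) {
    r <- run(q); r$orientation <- "+"; best <- r
  }
  if (orientation %in% c("both", "-")) {
    r <- run(qm); r$orientation <- "-"
    if (is.null(best) || r$score > best$score + 1e-9) best <- r
  }
  }
  if (!length(best$qidx)) return(empty_alignment(query_id, target_id))
  m <- length(q)
  if (best$orientation == "-") {
    qidx <- m + 1L - best$qidx  # back to original label indices
    o <- order(qidx)
    pairs <- cbind(qidx = qidx[o], tidx = best$tidx[o])
    resid <- rev(best$residuals)
    offset <- median(t[pairs[, "tidx"]] + q[pairs[, "qidx"]])
    sgn <- -1
  } else {
    pairs <- cbind(qidx = best$qidx, tidx = best$tidx)
    resid <- best$residuals
    offset <- median(t[pairs[, "tidx"]] - q[pairs[, "qidx"]])
    sgn <- 1
  }
  qpos <- q[pairs[, "qidx"]]; tpos <- t[pairs[, "tidx"]]
  al <- structure(list(
    query_id = query_id, target_id = target_id,
    orientation = best$orientation, pairs = pairs, residuals = resid,
    score = best$score, p_value = NA_real_, log_p = NA_real_,
    offset = offset, sign = sgn,
    qspan = max(qpos) - min(qpos), tspan = max(tpos) - min(tpos),
    tstart = min(tpos), tend = max(tpos),
    q_left_bp = min(qpos), q_right_bp = qlen - max(qpos),
    n_query = length(q)), class = "om_alignment")
  if (!is.null(null)) {
    al$log_p <- null_log_p(al$score, length(q), null)
    al$p_value <- exp(max(al$log_p, -745))
  }
  al
}

as_labels <- function(x, channel = 1L) {
  if (is.numeric(x)) return(x)
  if (inherits(x, "om_molecule")) return(x$channels[[channel]])
  if (inherits(x, "om_consensus")) return(x$sites)
  if (inherits(x, "om_ref")) return(x$contigs[[1]]$channels[[channel]])
  stop_om("cannot interpret object of class '%s' as a label map", class(x)[1])
}

#' Project a query position into target coordinates under an alignment
#' @noRd
project_pos <- function(al, x) al$sign * x + al$offset

#' Fit an empirical alignment null model
#'
#' Aligns interval-shuffled synthetic queries of varying label counts against
#' the reference and fits a Gumbel (extreme-value) location/scale per
#' label-count bucket; location and scale are then smoothed linearly in label
#' count so P-values extrapolate stably into the far tail.
#'
#' @param ref `om_ref` (or numeric label vector) to draw intervals from.
#' @param params [scoring_params()].
#' @param n_draws Total null draws (>= 1000 recommended).
#' @param seed Integer seed.
#' @param channel Reference channel.
#' @return Object of class `om_null` (bucket table + linear coefficients).
#' @export
fit_null <- function(ref, params = scoring_params(), n_draws = 2000,
                     seed = 1, channel = 1L) {
  t <- as_labels(ref, channel)
  if (length(t) < 10) stop_om("reference too sparse to fit a null (<10 labels)")
  iv <- diff(t)
  buckets <- c(6L, 9L, 12L, 16L, 20L, 26L, 33L, 42L, 52L)
  per <- max(ceiling(n_draws / length(buckets)), 25L)
  stats_df <- NULL
  draws <- list()
  for (bi in seq_along(buckets)) {
    n <- buckets[bi]
    qs <- with_seed(derive_seed(seed, bi, salt = 47L), {
      lapply(seq_len(per), function(d) {
        s <- sample.int(max(length(iv) - n, 1L), 1L)
        w <- iv[s:min(s + n - 1L, length(iv))]
        cumsum(c(0, sample(w)))
      })
    })
    sc_f <- dp_batch_scores_cpp(qs, t, params$match_bonus,
                                params$miss_penalty, params$false_penalty,
                                params$sd0, params$sd_scale, params$max_skip)
    qs_m <- lapply(qs, function(qq) sort(max(qq) - qq))
    sc_r <- dp_batch_scores_cpp(qs_m, t, params$match_bonus,
                                params$miss_penalty, params$false_penalty,
                                params$sd0, params$sd_scale, params$max_skip)
    sc <- pmax(sc_f, sc_r)
    beta <- sd(sc) * sqrt(6) / pi
    mu <- mean(sc) - 0.57721566 * beta
    stats_df <- rbind(stats_df, data.frame(n = n, mu = mu,
                                           beta = max(beta, 0.25),
                                           ndraws = per))
    draws[[bi]] <- sc
  }
  mu_fit <- lm(mu ~ n, data = stats_df, weights = stats_df$ndraws)
  beta_fit <- lm(beta ~ n, data = stats_df, weights = stats_df$ndraws)
  structure(list(buckets = stats_df, mu_coef = coef(mu_fit),
                 beta_coef = coef(beta_fit), n_draws = per * length(buckets),
                 seed = seed), class = "om_null")
}

null_mu_beta <- function(null, n) {
  n <- pmin(pmax(n, min(null$buckets$n)), max(null$buckets$n) * 2)
  mu <- null$mu_coef[1] + null$mu_coef[2] * n
  beta <- max(null$beta_coef[1] + null$beta_coef[2] * n, 0.25)
  c(mu = unname(mu), beta = unname(beta))
}

null_log_p <- function(score, n_labels, null) {
  mb <- null_mu_beta(null, n_labels)
  z <- (score - mb["mu"]) / mb["beta"]
  # right tail of Gumbel: p = 1 - exp(-exp(-z)); log-stable for large z
  if (z > 30) return(unname(-z))
  log(max(-expm1(-exp(-z)), 1e-320))
}

#' Empirical alignment P-value
#'
#' Right-tail probability of an alignment score under the fitted null,
#' conditioned on the query label count. Strictly decreasing in score.
#'
#' @param score Alignment score.
#' @param n_labels Query label count.
#' @param null `om_null` from [fit_null()].
#' @return P-value (may underflow to 0 in the far tail; see `log = TRUE`).
#' @param log Return the natural-log P-value instead.
#' @export
alignment_pvalue <- function(score, n_labels, null, log = FALSE) {
  if (!inherits(null, "om_null")) stop_om("null model not fitted (fit_null)")
  lp <- null_log_p(score, n_labels, null)
  if (log) lp else exp(max(lp, -745))
}

#' Filter alignments by P-value cutoff and target-overlap dominance
#'
#' Keeps alignments with `p < cutoff` (strict); among alignments whose target
#' intervals overlap, keeps the lower-P one (ties: longer aligned span, then
#' lower target coordinate).
#'
#' @param alignments List of `om_alignment` with P-values computed.
#' @param cutoff P-value cutoff (strict `<`).
#' @return Filtered list.
#' @export
filter_best_alignments <- function(alignments, cutoff = 1e-12) {
  alignments <- Filter(function(a) is.finite(a$score) &&
                         !is.na(a$log_p) && a$log_p < log(cutoff), alignments)
  if (length(alignments) <= 1) return(alignments)
  o <- order(vapply(alignments, function(a) a$log_p, 1),
             -vapply(alignments, function(a) a$tspan, 1),
             vapply(alignments, function(a) a$tstart, 1))
  alignments <- alignments[o]
  kept <- list()
  for (a in alignments) {
    clash <- any(vapply(kept, function(k)
      identical(k$target_id, a$target_id) &&
        a$tstart < k$tend && k$tstart < a$tend, TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept
}
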