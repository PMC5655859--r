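# Internal helpers: scoped RNG, seed substreams, 1-D clustering.

#' Evaluate code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic substream seed from a master seed (kept below 2^31)
#' @noRd
derive_seed <- function(master, k, salt = 0L) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 2654435761 +
                as.numeric(salt) * 40503) %% 2147483587 + 1)
}

#' Greedy single-linkage 1-D clustering: break at gaps > `gap`.
#' Returns integer cluster ids for sorted or unsorted input.
#' @noRd
cluster_1d <- function(x, gap) {
  if (length(x) == 0L) return(integer(0))
  o <- order(x)
  xs <- x[o]
  brk <- c(FALSE, diff(xs) > gap)
  id_sorted <- cumsum(brk) + 1L
  id <- integer(length(x))
  id[o] <- id_sorted
  id
}

#' Best 1-D two-means split of a numeric vector (sorted split point search).
#' Returns list(centers, sizes, within_sd, gap) or NULL when n < 4.
#' @noRd
two_means_1d <- function(x) {
  n <- length(x)
  if (n < 4L) return(NULL)
  xs <- sort(x)
  csum <- cumsum(xs)
  tot <- csum[n]
  best <- NULL
  best_ss <- Inf
  for (k in 2:(n - 2L)) {
    m1 <- csum[k] / k
    m2 <- (tot - csum[k]) / (n - k)
    ss <- sum((xs[1:k] - m1)^2) + sum((xs[(k + 1):n] - m2)^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- list(k = k, centers = c(m1, m2))
    }
  }
  k <- best$k
  wsd <- sqrt(best_ss / max(n - 2L, 1L))
  list(centers = best$centers, sizes = c(k, n - k), within_sd = wsd,
       gap = xs[k + 1L] - xs[k],
       assign_threshold = (xs[k] + xs[k + 1L]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_om <- function(...) stop(sprintf(...), call. = FALSE)
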