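# CMAP-dialect I/O: tab-separated consensus/reference map files.
# Emitted positions are 1-based with one decimal; internal storage is
# 0-based, so the shift happens only here.

#' Write maps in the CMAP dialect
#'
#' Tab-separated with a `# omsv-cmap v1` header; columns: map id, contig
#' length, number of sites, site id, channel, position (1-based bp, one
#' decimal) and an optional haplotype tag column for assembled consensi.
#'
#' @param maps An `om_ref`, or a list of consensus maps (`om_consensus`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# omsv-cmap v1",
               "#h CMapId\tContigLength\tNumSites\tSiteID\tChannel\tPosition\tHap"),
             con)
  emit <- function(id, len, channels, hap) {
    nsites <- sum(vapply(channels, length, 1L))
    site <- 0L
    for (k in seq_along(channels)) {
      for (p in channels[[k]]) {
        site <- site + 1L
        writeLines(sprintf("%s\t%.1f\t%d\t%d\t%d\t%.1f\t%d",
                           id, len, nsites, site, k, p + 1, hap), con)
      }
    }
    if (nsites == 0L)  # degenerate map: keep it discoverable on read
      writeLines(sprintf("%s\t%.1f\t0\t0\t1\tNA\t%d", id, len, hap), con)
  }
  if (inherits(maps, "om_ref")) {
    for (ct in maps$contigs) emit(ct$id, ct$length, ct$channels, 0L)
  } else {
    for (m in maps) {
      stopifnot(inherits(m, "om_consensus"))
      emit(m$id, m$length, list(m$sites), m$hap %||% 0L)
    }
  }
  invisible(path)
}

#' Read a CMAP-dialect file
#'
#' @param path File written by [write_cmap()].
#' @param as Return an `om_ref` (`"ref"`) or list of consensus maps
#'   (`"consensus"`).
#' @return `om_ref` or list of `om_consensus`.
#' @export
read_cmap <- function(path, as = c("ref", "consensus")) {
  as <- match.arg(as)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# omsv-cmap"))
    stop_om("%s: not an omsv CMAP file (missing header)", path)
  body <- which(!startsWith(lines, "#"))
  recs <- list()
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(6L, 7L))
      stop_om("%s line %d: expected 6 or 7 columns, found %d", path, ln, length(f))
    suppressWarnings({
      len <- as.numeric(f[2]); ch <- as.integer(f[5]); pos <- as.numeric(f[6])
    })
    if (is.na(len) || is.na(ch))
      stop_om("%s line %d: malformed numeric field", path, ln)
    id <- f[1]
    r <- recs[[id]] %||% list(id = id, length = len, channels = list(),
                              hap = if (length(f) == 7L) as.integer(f[7]) else 0L)
    if (!is.na(pos)) {
      while (length(r$channels) < ch) r$channels <- c(r$channels, list(numeric(0)))
      r$channels[[ch]] <- c(r$channels[[ch]], pos - 1)
    }
    recs[[id]] <- r
  }
  for (id in names(recs)) {
    nch <- max(1L, length(recs[[id]]$channels))
    while (length(recs[[id]]$channels) < nch)
      recs[[id]]$channels <- c(recs[[id]]$channels, list(numeric(0)))
    for (ch in recs[[id]]$channels)
      if (is.unsorted(ch, strictly = TRUE))
        stop_om("%s: map %s positions not strictly increasing", path, id)
  }
  nch <- max(vapply(recs, function(r) length(r$channels), 1L))
  for (id in names(recs))
    while (length(recs[[id]]$channels) < nch)
      recs[[id]]$channels <- c(recs[[id]]$channels, list(numeric(0)))
  if (as == "ref") {
    reference_map(lapply(unname(recs), function(r)
      list(id = r$id, length = r$length, channels = r$channels,
           fragile = numeric(0))))
  } else {
    lapply(unname(recs), function(r)
      new_consensus(id = r$id, sites = r$channels[[1]],
                    support = rep(NA_integer_, length(r$channels[[1]])),
                    length = r$length, hap = r$hap))
  }
}
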