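# BNX-dialect I/O: per-molecule text records.
# Record layout: `0 <id> <length>` header row, then one `<channel> <pos...>`
# row per channel and a constant-placeholder `Q<channel>` quality row.
# Hidden simulation truth travels in `#T` comment lines that standard
# consumers can ignore.

#' Write molecules in the BNX dialect
#'
#' @param molecules List of `om_molecule` (or an `om_run`).
#' @param path Output path.
#' @param truth Also write `#T` origin sidecar lines?
#' @return `path`, invisibly.
#' @export
write_bnx <- function(molecules, path, truth = TRUE) {
  if (inherits(molecules, "om_run")) molecules <- molecules$molecules
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# omsv-bnx v1", con)
  writeLines("#h 0:MoleculeId,Length 1..k:LabelChannel Q:Quality", con)
  for (m in molecules) {
    if (truth && !is.null(m$origin)) {
      o <- m$origin
      writeLines(sprintf("#T\t%s\t%s\t%.1f\t%s\t%d\t%d", m$id, o$contig,
                         o$start, o$strand, as.integer(o$hap),
                         as.integer(isTRUE(o$chimera))), con)
    }
    writeLines(sprintf("0\t%s\t%.1f", m$id, m$length), con)
    for (k in seq_along(m$channels)) {
      writeLines(paste(c(k, sprintf("%.1f", m$channels[[k]])),
                       collapse = "\t"), con)
      writeLines(paste(c(sprintf("Q%d", k),
                         rep("9.0", length(m$channels[[k]]))),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a BNX-dialect file
#'
#' @param path File written by [write_bnx()].
#' @return List of `om_molecule`; origins are populated when the truth
#'   sidecar is present, otherwise empty.
#' @export
read_bnx <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# omsv-bnx"))
    stop_om("%s: not an omsv BNX file (missing header)", path)
  mols <- list()
  cur <- NULL
  pending_truth <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      if (!length(cur$channels)) cur$channels <- list(numeric(0))
      mols[[length(mols) + 1L]] <<- structure(cur, class = "om_molecule")
    }
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) next
    if (startsWith(line, "#T")) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) != 7L)
        stop_om("%s line %d: malformed truth sidecar", path, ln)
      pending_truth <- list(contig = f[3], start = as.numeric(f[4]),
                            strand = f[5], hap = as.integer(f[6]),
                            chimera = as.integer(f[7]) == 1L)
      next
    }
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    tag <- f[1]
    if (tag == "0") {
      if (length(f) != 3L) stop_om("%s line %d: malformed molecule row", path, ln)
      flush()
      len <- suppressWarnings(as.numeric(f[3]))
      if (is.na(len)) stop_om("%s line %d: malformed length", path, ln)
      cur <- list(id = f[2], length = len, channels = list(),
                  origin = pending_truth)
      pending_truth <- NULL
    } else if (grepl("^[0-9]+$", tag)) {
      if (is.null(cur)) stop_om("%s line %d: label row before molecule row", path, ln)
      pos <- suppressWarnings(as.numeric(f[-1]))
      if (anyNA(pos)) stop_om("%s line %d: malformed label position", path, ln)
      cur$channels[[as.integer(tag)]] <- pos
    } else if (startsWith(tag, "Q")) {
      next
    } else {
      stop_om("%s line %d: unrecognized row tag '%s'", path, ln, tag)
    }
  }
  flush()
  mols
}
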