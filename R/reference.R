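# reference_maps module: nicking-enzyme specs, in-silico digestion,
# stochastic (Poisson) reference maps, and SV editing with planted truth.
#
# Internal coordinate convention: 0-based bp offsets from the contig start,
# intervals half-open [start, end). File I/O (CMAP dialect) is 1-based.

#' Nicking endonuclease specification
#'
#' @param name Short identifier (e.g. `"Nt.BspQI"`).
#' @param recognition_motif IUPAC nucleotide motif whose occurrences are
#'   nick-labeled. Defaults for the two stock enzymes are available through
#'   [default_enzymes()].
#' @param both_strands If `TRUE`, occurrences of the reverse-complement motif
#'   (minus-strand nicks) also produce labels.
#' @return An object of class `om_enzyme`.
#' @examples
#' enzyme_spec("Nt.BspQI", "GCTCTTC")
#' @export
enzyme_spec <- function(name, recognition_motif, both_strands = TRUE) {
  if (!nzchar(recognition_motif)) stop_om("recognition motif must be non-empty")
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", toupper(recognition_motif))
  if (!ok) stop_om("motif '%s' contains non-IUPAC characters", recognition_motif)
  structure(list(name = name, motif = toupper(recognition_motif),
                 both_strands = isTRUE(both_strands)),
            class = "om_enzyme")
}

#' Stock nicking enzymes
#'
#' Recognition motifs for the two commonly used single-strand nicking
#' endonucleases (standard enzyme-catalog sequences); both are overridable by
#' constructing an [enzyme_spec()] directly.
#' @return Named list of `om_enzyme` objects.
#' @export
default_enzymes <- function() {
  list(Nt.BspQI = enzyme_spec("Nt.BspQI", "GCTCTTC"),
       Nb.BssSI = enzyme_spec("Nb.BssSI", "CACGAG"))
}

#' In-silico digestion: label positions of a motif in a sequence
#'
#' Finds every start coordinate of the recognition motif on the plus strand
#' and, when the enzyme labels both strands, of its reverse complement.
#' Positions are returned 0-based, sorted, deduplicated. When
#' `return_strand = TRUE` the per-position strand is attached so that
#' fragile sites (opposite-strand nicks closer than a window) can be derived.
#'
#' @param seq A nucleotide string (IUPAC alphabet) or `Biostrings::DNAString`.
#' @param enzyme An [enzyme_spec()].
#' @param return_strand Attach a `strand` attribute (`"+"`/`"-"`)?
#' @return Numeric vector of 0-based label positions.
#' @export
digest_sequence <- function(seq, enzyme, return_strand = FALSE) {
  stopifnot(inherits(enzyme, "om_enzyme"))
  if (is.character(seq)) {
    if (!nzchar(seq)) return(numeric(0))
    if (!grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$", seq))
      stop_om("sequence contains non-nucleotide characters")
    seq <- Biostrings::DNAString(seq)
  }
  if (length(seq) < nchar(enzyme$motif)) return(numeric(0))
  pat <- Biostrings::DNAString(enzyme$motif)
  plus <- Biostrings::start(Biostrings::matchPattern(pat, seq, fixed = FALSE))
  minus <- integer(0)
  if (enzyme$both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    minus <- Biostrings::start(Biostrings::matchPattern(rc, seq, fixed = FALSE))
  }
  pos <- c(plus, minus) - 1L  # to 0-based
  strand <- rep(c("+", "-"), c(length(plus), length(minus)))
  o <- order(pos)
  pos <- pos[o]; strand <- strand[o]
  dup <- duplicated(pos)
  pos <- pos[!dup]; strand <- strand[!dup]
  out <- as.numeric(pos)
  if (return_strand) attr(out, "strand") <- strand
  out
}

#' Construct a reference map
#'
#' @param contigs List of contig descriptions: each a list with `id`,
#'   `length` (bp) and `channels` (list of sorted numeric label-position
#'   vectors, one per channel; 0-based bp). An optional `fragile` numeric
#'   vector marks positions where opposite-strand nicks fall within a
#'   double-strand-break window.
#' @param enzymes List of [enzyme_spec()] per channel (optional).
#' @return An object of class `om_ref`.
#' @export
reference_map <- function(contigs, enzymes = NULL) {
  for (ct in contigs) {
    stopifnot(!is.null(ct$id), is.numeric(ct$length), length(ct$channels) >= 1)
    for (ch in ct$channels) {
      if (is.unsorted(ch, strictly = TRUE))
        stop_om("contig %s: label positions must be strictly increasing", ct$id)
      if (length(ch) && (min(ch) < 0 || max(ch) >= ct$length))
        stop_om("contig %s: label positions outside [0, length)", ct$id)
    }
  }
  nch <- unique(vapply(contigs, function(ct) length(ct$channels), 1L))
  if (length(nch) != 1L)
    stop_om("every contig must carry the same number of channels")
  names(contigs) <- vapply(contigs, function(ct) as.character(ct$id), "")
  structure(list(contigs = contigs, enzymes = enzymes, n_channels = nch),
            class = "om_ref")
}

#' @export
print.om_ref <- function(x, ...) {
  cat(sprintf("<om_ref> %d contig(s), %d channel(s)\n",
              length(x$contigs), x$n_channels))
  for (ct in x$contigs) {
    cat(sprintf("  %s: %.0f bp, labels per channel: %s\n", ct$id, ct$length,
                paste(vapply(ct$channels, length, 1L), collapse = "/")))
  }
  invisible(x)
}

#' Build a reference map from sequences by in-silico digestion
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet`
#'   (e.g. from `Biostrings::readDNAStringSet` on a FASTA file).
#' @param enzymes List of [enzyme_spec()], one per label channel.
#' @param fragile_window Opposite-strand nick pairs closer than this many bp
#'   are recorded as fragile (double-strand break prone) sites.
#' @return An `om_ref`.
#' @export
digest_reference <- function(seqs, enzymes, fragile_window = 1000) {
  if (inherits(enzymes, "om_enzyme")) enzymes <- list(enzymes)
  if (is.character(seqs)) {
    nm <- names(seqs) %||% paste0("contig", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
    names(seqs) <- nm
  }
  contigs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    channels <- list()
    fragile <- numeric(0)
    for (k in seq_along(enzymes)) {
      lab <- digest_sequence(s, enzymes[[k]], return_strand = TRUE)
      strand <- attr(lab, "strand")
      if (length(lab) > 1) {
        close_opp <- which(diff(lab) < fragile_window &
                             strand[-length(strand)] != strand[-1])
        if (length(close_opp))
          fragile <- c(fragile, (lab[close_opp] + lab[close_opp + 1]) / 2)
      }
      channels[[k]] <- as.numeric(lab)
    }
    list(id = names(seqs)[i] %||% paste0("contig", i), length = length(s),
         channels = channels, fragile = sort(unique(fragile)))
  })
  reference_map(contigs, enzymes)
}

#' Synthetic reference map by homogeneous Poisson label placement
#'
#' Places labels along a single contig with exponential inter-label spacings,
#' one independent process per channel. Reproducible under the same seed.
#'
#' @param length_bp Contig length (bp); must exceed twice the mean spacing.
#' @param mean_spacing_bp Mean inter-label distance (bp), default 6000.
#' @param n_channels Number of label channels.
#' @param seed Integer seed.
#' @param contig_id Contig name.
#' @return An `om_ref` with one contig.
#' @export
poisson_reference <- function(length_bp, mean_spacing_bp = 6000,
                              n_channels = 1, seed = 1,
                              contig_id = "synth1") {
  if (mean_spacing_bp <= 0) stop_om("mean spacing must be positive")
  if (length_bp <= 2 * mean_spacing_bp)
    stop_om("contig length must exceed twice the mean spacing")
  channels <- lapply(seq_len(n_channels), function(k) {
    with_seed(derive_seed(seed, k, salt = 11L), {
      n_guess <- ceiling(length_bp / mean_spacing_bp * 1.35 + 50)
      pos <- cumsum(rexp(n_guess, rate = 1 / mean_spacing_bp))
      while (pos[length(pos)] < length_bp)
        pos <- c(pos, pos[length(pos)] +
                   cumsum(rexp(n_guess, rate = 1 / mean_spacing_bp)))
      pos[pos < length_bp]
    })
  })
  reference_map(list(list(id = contig_id, length = length_bp,
                          channels = channels, fragile = numeric(0))))
}

#' Plant structural variants into a reference map
#'
#' Applies a list of non-overlapping edits to the label maps of one contig
#' and returns the edited map together with an exact truth record.
#' `deletion` removes `[start, end)` and shifts downstream labels left;
#' `insertion` duplicates the labels of `[start, end)` in place (tandem
#' duplication) and shifts downstream labels right; `inversion` mirrors label
#' positions within `[start, end)`.
#'
#' @param ref An `om_ref`.
#' @param edits List of edits: each `list(type, contig, start, end)` with
#'   `type` one of `"deletion"`, `"insertion"`, `"inversion"`; 0-based
#'   half-open coordinates.
#' @return List with elements `ref` (edited `om_ref`) and `truth`
#'   (data.frame: type, contig, ref_start, ref_end, size, sample_pos).
#' @export
apply_sv_to_map <- function(ref, edits) {
  stopifnot(inherits(ref, "om_ref"))
  if (!length(edits))
    return(list(ref = ref, truth = empty_truth()))
  ed <- do.call(rbind, lapply(edits, function(e)
    data.frame(type = e$type, contig = as.character(e$contig),
               start = e$start, end = e$end, stringsAsFactors = FALSE)))
  if (any(!ed$type %in% c("deletion", "insertion", "inversion")))
    stop_om("unknown edit type")
  if (any(ed$end <= ed$start)) stop_om("edit end must exceed start")
  truth <- NULL
  for (cid in unique(ed$contig)) {
    ct <- ref$contigs[[cid]]
    if (is.null(ct)) stop_om("edit references unknown contig '%s'", cid)
    sub <- ed[ed$contig == cid, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop_om("edits overlap on contig '%s'", cid)
    if (any(sub$end > ct$length)) stop_om("edit outside contig '%s'", cid)
    # apply right-to-left so earlier coordinates stay valid
    for (r in rev(seq_len(nrow(sub)))) {
      a <- sub$start[r]; b <- sub$end[r]; sz <- b - a
      for (k in seq_along(ct$channels)) {
        x <- ct$channels[[k]]
        ct$channels[[k]] <- switch(sub$type[r],
          deletion = {
            keep <- x < a | x >= b
            y <- x[keep]
            y[y >= b] <- y[y >= b] - sz
            y
          },
          insertion = {
            inside <- x[x >= a & x < b]
            y <- x
            y[y >= b] <- y[y >= b] + sz
            sort(c(y, inside + sz))
          },
          inversion = {
            y <- x
            inside <- y >= a & y < b
            y[inside] <- a + b - y[inside]
            sort(y)
          })
      }
      if (length(ct$fragile)) {
        f <- ct$fragile
        f <- switch(sub$type[r],
          deletion = { f <- f[f < a | f >= b]; f[f >= b] <- f[f >= b] - sz; f },
          insertion = { f[f >= b] <- f[f >= b] + sz; f },
          inversion = { ins <- f >= a & f < b; f[ins] <- a + b - f[ins]; sort(f) })
        ct$fragile <- sort(f)
      }
      ct$length <- ct$length + switch(sub$type[r], deletion = -sz,
                                      insertion = sz, inversion = 0)
    }
    ref$contigs[[cid]] <- ct
    sub$size <- ifelse(sub$type == "deletion", -(sub$end - sub$start),
                ifelse(sub$type == "insertion", sub$end - sub$start, 0))
    sub$span <- sub$end - sub$start
    # position of the (left) junction in edited-sample coordinates, accounting
    # for length changes of earlier edits on the same contig
    shift <- cumsum(c(0, head(ifelse(sub$type == "deletion",
                                     -(sub$end - sub$start),
                              ifelse(sub$type == "insertion",
                                     sub$end - sub$start, 0)), -1)))
    sub$sample_pos <- sub$start + shift
    truth <- rbind(truth, data.frame(
      type = sub$type, contig = cid, ref_start = sub$start,
      ref_end = sub$end, size = sub$size, span = sub$span,
      sample_pos = sub$sample_pos, stringsAsFactors = FALSE))
  }
  list(ref = ref, truth = truth)
}

empty_truth <- function() {
  data.frame(type = character(0), contig = character(0),
             ref_start = numeric(0), ref_end = numeric(0), size = numeric(0),
             span = numeric(0), sample_pos = numeric(0),
             stringsAsFactors = FALSE)
}
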