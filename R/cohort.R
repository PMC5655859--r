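# fixtures_cohort module: synthetic analog of an X-linked dystrophinopathy
# case series (8 probands, 3 mothers) with the published SV sizes planted in
# region-restricted synthetic references, and concordance scoring of
# pipeline output against the planted truth.

#' Cohort scenario table
#'
#' The eleven samples: six hemizygous deletion probands (182,665; 224,364;
#' 59,771; 45,839; 250,092; 184,882 bp), a heterozygous 249,994-bp deletion
#' carrier mother, a non-carrier mother, a hemizygous 12,968-bp
#' duplication-insertion proband with his 12,857-bp carrier mother, and a
#' hemizygous 5.1-Mbp inversion proband run with two enzyme channels.
#' Probands are modeled on a haploid (male X) region, mothers on a diploid
#' one.
#'
#' @return data.frame: sample_id, family, relation, sv_type, sv_size,
#'   zygosity, ploidy, channels, region_length, coverage (the published runs
#'   put substantially deeper coverage on the diploid mothers, whose allelic
#'   evidence is split between haplotypes; the defaults mirror that within
#'   the 40-70x band).
#' @export
cohort_scenarios <- function() {
  data.frame(
    sample_id = c("CDMD1003", "CDMD1155", "CDMD1156", "CDMD1159",
                  "CDMD1131", "CDMD1132", "CDMD1157", "CDMD1158",
                  "CDMD1163", "CDMD1164", "CDMD1187"),
    family = c("F1", "F2", "F3", "F4", "F5", "F5", "F6", "F6", "F7", "F7",
               "F8"),
    relation = c("proband", "proband", "proband", "proband", "proband",
                 "mother", "proband", "mother", "proband", "mother",
                 "proband"),
    sv_type = c("deletion", "deletion", "deletion", "deletion", "deletion",
                "deletion", "deletion", "none", "insertion", "insertion",
                "inversion"),
    sv_size = c(182665, 224364, 59771, 45839, 250092, 249994, 184882, NA,
                12968, 12857, 5100000),
    zygosity = c("hemizygous", "hemizygous", "hemizygous", "hemizygous",
                 "hemizygous", "heterozygous", "hemizygous", NA,
                 "hemizygous", "heterozygous", "hemizygous"),
    ploidy = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L),
    channels = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L),
    region_length = c(3e6, 3e6, 3e6, 3e6, 3e6, 3e6, 3e6, 3e6, 3e6, 3e6,
                      8e6),
    coverage = c(40, 40, 40, 40, 40, 60, 40, 60, 40, 60, 40),
    stringsAsFactors = FALSE)
}

#' Build the synthetic cohort
#'
#' One synthetic reference region per family (Poisson nick-label placement),
#' shared between proband and mother so their maps are comparable; SVs are
#' planted at seeded random positions with the exact published sizes.
#' Mothers carry one edited and one wild-type haplotype (two wild-type for
#' the non-carrier); probands are haploid for the region.
#'
#' @param seed Integer master seed.
#' @param spacing Mean label spacing (bp per channel).
#' @param region_length,inv_region_length Region sizes (deletion/insertion
#'   families; inversion family).
#' @param margin Minimum distance of planted breakpoints from region ends.
#' @return List of scenarios: each with sample_id, ref (wild-type
#'   `om_ref`), haplotypes (list of `om_ref`), truth (data.frame), ploidy,
#'   channels, plus the scenario row.
#' @export
build_cohort <- function(seed = 1, spacing = 6000, region_length = 3e6,
                         inv_region_length = 8e6, margin = 3e5) {
  sc <- cohort_scenarios()
  sc$region_length[sc$region_length == 3e6] <- region_length
  sc$region_length[sc$channels == 2L] <- inv_region_length
  refs <- list()
  positions <- list()
  out <- vector("list", nrow(sc))
  for (i in seq_len(nrow(sc))) {
    row <- sc[i, ]
    fam <- row$family
    if (is.null(refs[[fam]])) {
      refs[[fam]] <- poisson_reference(
        row$region_length, spacing, n_channels = max(row$channels),
        seed = derive_seed(seed, match(fam, unique(sc$family)), salt = 71L),
        contig_id = "chrXr")
      if (!is.na(row$sv_size)) {
        span <- if (row$sv_type == "inversion") row$sv_size
                else max(row$sv_size, 1)
        if (row$region_length < span + 2 * margin)
          stop_om("region too small for the planted SV in family %s", fam)
        positions[[fam]] <- with_seed(
          derive_seed(seed, i, salt = 83L),
          runif(1, margin, row$region_length - span - margin))
      }
    }
    base <- refs[[fam]]
    if (row$sv_type == "none") {
      haps <- list(base, base)
      truth <- empty_truth()
    } else {
      a <- positions[[fam]]
      edit <- list(type = row$sv_type, contig = "chrXr", start = a,
                   end = a + row$sv_size)
      ed <- apply_sv_to_map(base, list(edit))
      truth <- ed$truth
      truth$zygosity <- row$zygosity
      haps <- if (row$ploidy == 1L) list(ed$ref) else list(ed$ref, base)
    }
    out[[i]] <- list(sample_id = row$sample_id, scenario = row, ref = base,
                     haplotypes = haps, truth = truth,
                     ploidy = c(chrXr = row$ploidy),
                     channels = seq_len(row$channels),
                     coverage = row$coverage)
  }
  names(out) <- sc$sample_id
  out
}

#' Run the pipeline over a cohort
#'
#' @param cohort From [build_cohort()].
#' @param config [pipeline_config()]; its seed is combined with each
#'   sample's index so samples are independent but reproducible.
#' @param verbose Print one progress line per sample.
#' @return Named list of `om_result` per sample.
#' @export
run_cohort <- function(cohort, config = pipeline_config(), verbose = TRUE) {
  out <- list()
  for (i in seq_along(cohort)) {
    scn <- cohort[[i]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i, salt = 97L)
    cfg$coverage <- scn$coverage %||% config$coverage
    t0 <- Sys.time()
    out[[scn$sample_id]] <- run_sample(scn$haplotypes, scn$ref, cfg,
                                       channels = scn$channels,
                                       ploidy = scn$ploidy)
    if (verbose)
      message(sprintf("%s: %d call(s) [%.0f s]", scn$sample_id,
                      nrow(out[[scn$sample_id]]$calls),
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  out
}

#' Score pipeline calls against planted truth
#'
#' A sample is concordant when every planted SV is called with the correct
#' type and zygosity and a size within tolerance, and no extra calls are
#' emitted; the non-carrier matches if and only if it has zero calls.
#' Inversions are size-matched on the span between breakpoint midpoints.
#'
#' @param cohort From [build_cohort()].
#' @param results From [run_cohort()].
#' @param size_tol Relative size tolerance (default 5%).
#' @return List of class `om_concordance`: `per_sample` data.frame
#'   (sample, n_expected, n_called, matched, extra, concordant) and
#'   `concordance` (fraction of concordant samples).
#' @export
score_concordance <- function(cohort, results, size_tol = 0.05) {
  rows <- NULL
  for (scn in cohort) {
    id <- scn$sample_id
    res <- results[[id]]
    calls <- if (is.null(res)) empty_calls() else res$calls
    truth <- scn$truth
    matched <- 0L
    used <- rep(FALSE, nrow(calls))
    notes <- character(0)
    if (nrow(truth)) {
      for (tr in seq_len(nrow(truth))) {
        tsize <- abs(truth$size[tr])
        if (truth$type[tr] == "inversion") tsize <- truth$span[tr]
        hit <- which(!used & calls$type == truth$type[tr])
        if (length(hit)) {
          csize <- ifelse(calls$type[hit] == "inversion",
                          calls$ref_span[hit], abs(calls$size[hit]))
          ok_size <- abs(csize - tsize) <= size_tol * tsize
          ok_zyg <- calls$zygosity[hit] == truth$zygosity[tr]
          hit <- hit[ok_size & ok_zyg]
        }
        if (length(hit)) {
          used[hit[1]] <- TRUE
          matched <- matched + 1L
        } else {
          notes <- c(notes, sprintf("missed %s %.0f", truth$type[tr],
                                    truth$size[tr]))
        }
      }
    }
    extra <- sum(!used)
    if (extra) notes <- c(notes, sprintf("%d extra call(s)", extra))
    ok <- matched == nrow(truth) && extra == 0L && !is.null(res)
    rows <- rbind(rows, data.frame(
      sample = id, n_expected = nrow(truth), n_called = nrow(calls),
      matched = matched, extra = extra, concordant = ok,
      note = paste(notes, collapse = "; "), stringsAsFactors = FALSE))
  }
  structure(list(per_sample = rows,
                 concordance = mean(rows$concordant)),
            class = "om_concordance")
}

#' @export
print.om_concordance <- function(x, ...) {
  print(x$per_sample, row.names = FALSE)
  cat(sprintf("concordance: %.1f%% (%d/%d samples)\n",
              100 * x$concordance, sum(x$per_sample$concordant),
              nrow(x$per_sample)))
  invisible(x)
}
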