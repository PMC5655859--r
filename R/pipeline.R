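# cli_config module: configuration container and the end-to-end driver
# (simulate -> assemble per channel -> call -> combine -> zygosity).

#' Pipeline configuration
#'
#' Bundles all stage parameter sets with simulation settings. Serializable
#' to/from YAML ([write_config()], [read_config()]).
#'
#' @param scoring [scoring_params()].
#' @param assembly [assembly_params()].
#' @param sv [sv_params()].
#' @param model [error_model()].
#' @param coverage Raw fold coverage to simulate.
#' @param genome_size Genome size for effective-coverage accounting
#'   (3.2e9 when emulating human; defaults to the simulated region size).
#' @param null_draws Draws for the alignment null fit.
#' @param seed Master seed.
#' @return Object of class `om_config`.
#' @export
pipeline_config <- function(scoring = scoring_params(),
                            assembly = assembly_params(), sv = sv_params(),
                            model = error_model(), coverage = 40,
                            genome_size = NULL, null_draws = 1500,
                            seed = 1) {
  stopifnot(inherits(scoring, "om_scoring"),
            inherits(assembly, "om_asm_params"),
            inherits(sv, "om_sv_params"), inherits(model, "om_error_model"))
  structure(list(scoring = scoring, assembly = assembly, sv = sv,
                 model = model, coverage = coverage,
                 genome_size = genome_size, null_draws = null_draws,
                 seed = seed), class = "om_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config `om_config`.
#' @param path File path.
#' @return `path` invisibly; `read_config` returns the `om_config`.
#' @export
write_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("scoring", "assembly", "sv", "model")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop_om("config is missing section(s): %s", paste(miss, collapse = ", "))
  pipeline_config(
    scoring = do.call(scoring_params, y$scoring),
    assembly = do.call(assembly_params, y$assembly),
    sv = do.call(sv_params, y$sv),
    model = do.call(error_model, y$model),
    coverage = y$coverage %||% 40,
    genome_size = y$genome_size,
    null_draws = y$null_draws %||% 1500,
    seed = y$seed %||% 1)
}

#' Run the full pipeline on one sample
#'
#' Simulates a labeling run from the sample's haplotypes, then per channel:
#' fits the alignment null on the reference, assembles the molecules de
#' novo, and calls SVs against the reference; dual-channel call sets are
#' merged by breakpoint-interval intersection. Deterministic under
#' `config$seed`.
#'
#' @param haplotypes `om_ref` or list of `om_ref` (the sample's haplotype
#'   copies, possibly SV-edited).
#' @param ref The (wild-type) reference `om_ref` to call against.
#' @param config [pipeline_config()].
#' @param channels Integer vector of enzyme channels to run (1 or 1:2).
#' @param ploidy Named vector contig -> copy number for zygosity.
#' @param compute_map_rate Also compute the molecule-to-reference map rate
#'   and effective coverage (adds one alignment pass).
#' @return List of class `om_result`: calls, per-channel assemblies and
#'   call sets, run summary, stage logs.
#' @export
run_sample <- function(haplotypes, ref, config = pipeline_config(),
                       channels = 1L, ploidy = c(synth1 = 1L),
                       compute_map_rate = FALSE) {
  if (inherits(haplotypes, "om_ref")) haplotypes <- list(haplotypes)
  run <- simulate_run(haplotypes, config$model, config$coverage,
                      seed = config$seed)
  per_channel <- list()
  for (ch in channels) {
    nu <- fit_null(ref, config$scoring, n_draws = config$null_draws,
                   seed = derive_seed(config$seed, ch, salt = 61L),
                   channel = ch)
    asm <- run_assembly(run$molecules, config$assembly, config$scoring, nu,
                        channel = ch)
    res <- call_svs(asm$consensi, ref, config$scoring, nu, config$sv,
                    channel = ch)
    res$calls <- call_zygosity(res$calls, res$coverage, ploidy, config$sv)
    res$calls$channel <- rep(ch, nrow(res$calls))
    per_channel[[as.character(ch)]] <- list(assembly = asm, calls = res$calls,
                                            coverage = res$coverage,
                                            null = nu)
    if (compute_map_rate && ch == channels[1]) {
      cut <- log(config$sv$align_p)
      n_map <- 0L
      for (m in run$molecules) {
        al <- align_maps(m$channels[[ch]], as_labels(ref, ch),
                         config$scoring, qlen = m$length, null = nu,
                         fast = TRUE)
        if (!is.na(al$log_p) && al$log_p < cut) n_map <- n_map + 1L
      }
      run$summary$map_rate <- n_map / length(run$molecules)
      run$summary$effective_coverage <- effective_coverage(
        run$summary$total_bases,
        config$genome_size %||% run$summary$genome_size,
        run$summary$map_rate)
    }
  }
  calls <- if (length(channels) >= 2) {
    combine_dual_enzyme(per_channel[[1]]$calls, per_channel[[2]]$calls,
                        config$sv)
  } else per_channel[[1]]$calls
  structure(list(calls = calls, channels = per_channel,
                 summary = run$summary, seed = config$seed),
            class = "om_result")
}

#' @export
print.om_result <- function(x, ...) {
  cat(sprintf("<om_result> %d call(s); %d molecules, raw coverage %.1fx\n",
              nrow(x$calls), x$summary$molecule_count,
              x$summary$raw_coverage))
  if (nrow(x$calls))
    print(x$calls[, c("type", "contig", "bp1_lo", "bp2_hi", "size",
                      "zygosity")], row.names = FALSE)
  invisible(x)
}
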