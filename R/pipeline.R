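#' Run the full consensus-reference analysis
#'
#' One call from cohort to report: simulate (or read) a cohort, build the
#' global and per-population consensus references, call variants for every
#' sample against the original reference, the global consensus and the
#' population-matched consensuses, and write all tabular artifacts plus a
#' manifest into `out_dir`. Re-running with the same config reproduces
#' byte-identical tables.
#'
#' Artifacts written: `cohort.vcf`, `reference.fa`, `populations.tsv`,
#' one `consensus_<scope>.fa` + `switch_<scope>.tsv` per scope,
#' `sample_summary.tsv` (per sample x scope hom/het counts),
#' `hom_distribution.tsv` (per-scope mean/median/sd/mode),
#' `zygosity_fractions.tsv`, and `manifest.json` (config echo, seeds,
#' package version, input checksums, per-stage counters).
#'
#' @param spec A [cohort_spec()] (synthetic run), or an `snv_cohort` you
#'   already read with [read_sites()].
#' @param out_dir Output directory.
#' @param pop_mode How population consensuses are summarised per sample:
#'   `"matched"` or `"mean"` (see [matched_population_calls()]).
#' @param n_report_genomes How many genomes feed the per-call AF tables
#'   (the cumulative-distribution inputs); counts in `sample_summary.tsv`
#'   always cover every sample.
#' @return Invisibly, a list with the key result tibbles and artifact paths.
#' @export
run_pipeline <- function(spec, out_dir, pop_mode = c("matched", "mean"),
                         n_report_genomes = 100L) {
  pop_mode <- match.arg(pop_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (inherits(spec, "cohort_spec")) simulate_cohort(spec) else spec
  stopifnot(inherits(cohort, "snv_cohort"))
  paths <- write_cohort(cohort, out_dir)

  pops <- unique(cohort$samples$population)
  pops <- pops[!is.na(pops)]
  scopes <- c("ALL", pops)
  consensuses <- purrr::map(scopes, function(sc) build_consensus(cohort, sc))
  names(consensuses) <- scopes
  for (sc in scopes) {
    if (!is.null(consensuses[[sc]]$sequence)) {
      write_fasta(consensuses[[sc]]$sequence,
                  paste0(cohort$chrom, "_consensus_", sc),
                  file.path(out_dir, sprintf("consensus_%s.fa", sc)))
    }
    write_switch_table(consensuses[[sc]],
                       file.path(out_dir, sprintf("switch_%s.tsv", sc)))
  }

  report_samples <- sample_genomes(
    cohort, n_report_genomes,
    seed = child_seed(if (!is.null(cohort$spec)) cohort$spec$seed else 0L, 50L))

  vc_ref <- call_variants(cohort, reference_scope(cohort),
                          samples = report_samples, keep_calls = TRUE)
  vc_ref_all <- call_variants(cohort, reference_scope(cohort),
                              keep_calls = FALSE)
  vc_cons <- call_variants(cohort, consensuses[["ALL"]],
                           samples = report_samples, keep_calls = TRUE)
  vc_cons_all <- call_variants(cohort, consensuses[["ALL"]],
                               keep_calls = FALSE)
  summaries <- list(vc_ref_all, vc_cons_all)
  if (length(pops) > 1) {
    summaries <- c(summaries,
                   list(matched_population_calls(cohort, consensuses[pops],
                                                 mode = pop_mode)))
  }
  summary_tbl <- purrr::list_rbind(purrr::map(summaries, "summary"))
  readr::write_tsv(summary_tbl, file.path(out_dir, "sample_summary.tsv"))

  hom_tbl <- summarize_hom_distribution(summary_tbl)
  readr::write_tsv(hom_tbl, file.path(out_dir, "hom_distribution.tsv"))

  zyg_tbl <- dplyr::bind_rows(
    zygosity_af_fractions(vc_ref$calls) |> mutate(scope = "reference"),
    zygosity_af_fractions(vc_cons$calls) |> mutate(scope = "ALL")
  )
  readr::write_tsv(zyg_tbl, file.path(out_dir, "zygosity_fractions.tsv"))

  calls_tbl <- dplyr::bind_rows(vc_ref$calls, vc_cons$calls)
  readr::write_tsv(calls_tbl, file.path(out_dir, "per_call_af.tsv"))

  manifest <- list(
    package = "consensusref",
    version = as.character(utils::packageVersion("consensusref")),
    config = if (inherits(spec, "cohort_spec")) unclass(spec) else "external cohort",
    pop_mode = pop_mode,
    n_report_genomes = length(report_samples),
    counters = list(
      n_sites = nrow(cohort$sites),
      n_samples = ncol(cohort$genotypes),
      n_swapped = purrr::map_int(consensuses, function(x) sum(x$switch_table$swapped)),
      n_calls_reported = nrow(calls_tbl)
    ),
    input_checksums = as.list(tools::md5sum(unlist(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    cohort = cohort, consensuses = consensuses,
    summary = summary_tbl, hom_distribution = hom_tbl,
    zygosity_fractions = zyg_tbl, paths = paths, out_dir = out_dir
  ))
}
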