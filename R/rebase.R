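#' Re-project an ALT dosage through a REF/ALT swap
#'
#' When consensus construction swaps REF and ALT at a site, a dosage d
#' counted against the old labels becomes 2 - d against the new ones
#' (missing stays missing); heterozygotes are unchanged. Applying the
#' operation twice with the same flag is the identity.
#'
#' @param dosage Integer dosage vector in `{0, 1, 2, NA}`.
#' @param swapped Logical vector (recycled) of per-site swap flags.
#' @return Re-projected dosage vector.
#' @examples
#' reproject_dosage(c(0L, 1L, 2L, NA), swapped = TRUE)
#' @export
reproject_dosage <- function(dosage, swapped) {
  stopifnot(all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)))
  swapped <- rep_len(as.logical(swapped), length(dosage))
  out <- dosage
  out[swapped] <- 2L - out[swapped]
  out
}

#' Call variants for personal genomes against a (possibly consensus) reference
#'
#' After re-projecting each sample's dosages through the switch table,
#' dosage 2 is a homozygous variant call, dosage 1 a heterozygous call, and
#' dosage 0 or missing no call. The allele frequency recorded per call is
#' the population frequency of the carried non-reference allele -- the
#' complement of `af_used` at swapped sites.
#'
#' @param cohort An `snv_cohort`.
#' @param reference A `consensus_ref` over the same site list (use
#'   [reference_scope()] for the original reference).
#' @param samples Sample labels to call (default: all).
#' @param keep_calls Also return the per-call table? For large cohorts the
#'   per-sample summary alone is much lighter.
#' @return An object of class `variant_calls`: list with `summary` (tibble:
#'   `sample`, `scope`, `n_hom`, `n_het`) and, when `keep_calls = TRUE`,
#'   `calls` (tibble: `sample`, `chrom`, `pos`, `zygosity`, `called_af`).
#' @examples
#' co <- simulate_cohort(cohort_spec(100, 10, seed = 5))
#' vc <- call_variants(co, build_consensus(co))
#' tidy(vc)
#' @export
call_variants <- function(cohort, reference, samples = NULL,
                          keep_calls = TRUE) {
  stopifnot(inherits(cohort, "snv_cohort"), inherits(reference, "consensus_ref"))
  st <- reference$switch_table
  if (nrow(st) != nrow(cohort$sites) ||
      !identical(st$pos, cohort$sites$pos) ||
      !identical(st$ref, cohort$sites$ref_allele)) {
    abort(sprintf(
      "Switch table (scope '%s') does not match the cohort's site list; rebuild it from this cohort.",
      reference$scope))
  }
  samples <- samples %||% colnames(cohort$genotypes)
  missing_samp <- setdiff(samples, colnames(cohort$genotypes))
  if (length(missing_samp) > 0) {
    abort(sprintf("Samples not in the cohort: %s",
                  paste(utils::head(missing_samp, 5), collapse = ", ")))
  }
  D <- cohort$genotypes[, samples, drop = FALSE]
  flip <- st$swapped
  if (any(flip)) D[flip, ] <- 2L - D[flip, , drop = FALSE]
  called_af_site <- ifelse(flip, 1 - st$af_used, st$af_used)

  summary <- tibble(
    sample = samples,
    scope = reference$scope,
    n_hom = unname(colSums(D == 2L, na.rm = TRUE)),
    n_het = unname(colSums(D == 1L, na.rm = TRUE))
  )
  calls <- NULL
  if (keep_calls) {
    idx <- which(!is.na(D) & D >= 1L, arr.ind = TRUE)
    calls <- tibble(
      sample = samples[idx[, 2]],
      chrom = st$chrom[idx[, 1]],
      pos = st$pos[idx[, 1]],
      zygosity = ifelse(D[idx] == 2L, "hom", "het"),
      called_af = called_af_site[idx[, 1]],
      scope = reference$scope
    ) |>
      arrange(.data$sample, .data$pos)
  }
  structure(list(summary = summary, calls = calls, scope = reference$scope),
            class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("<variant_calls> scope %s: %d samples, mean %.1f hom + %.1f het per genome\n",
              x$scope, nrow(x$summary), mean(x$summary$n_hom),
              mean(x$summary$n_het)))
  invisible(x)
}

#' Per-sample calls against population-specific consensuses
#'
#' `mode = "matched"` (default): each sample is called against the consensus
#' of its own population. `mode = "mean"`: each sample is called against
#' every population consensus and its counts are averaged across them. The
#' `scope` column records which mode produced the numbers.
#'
#' @param cohort An `snv_cohort` with population assignments.
#' @param consensuses Named list of `consensus_ref`, one per population
#'   (names = population labels), e.g. from [build_consensus()] per scope.
#' @param mode `"matched"` or `"mean"`.
#' @param keep_calls Keep per-call tables (matched mode only)?
#' @return A `variant_calls`; in `"mean"` mode `n_hom`/`n_het` are averages
#'   over consensuses (possibly non-integer).
#' @export
matched_population_calls <- function(cohort, consensuses,
                                     mode = c("matched", "mean"),
                                     keep_calls = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "snv_cohort"))
  pops <- unique(cohort$samples$population)
  missing_pop <- setdiff(pops, names(consensuses))
  if (length(missing_pop) > 0) {
    abort(sprintf("No consensus supplied for population(s): %s",
                  paste(missing_pop, collapse = ", ")))
  }
  if (mode == "matched") {
    parts <- purrr::map(pops, function(pp) {
      idx <- cohort$samples$sample[cohort$samples$population == pp]
      call_variants(cohort, consensuses[[pp]], samples = idx,
                    keep_calls = keep_calls)
    })
    summary <- purrr::list_rbind(purrr::map(parts, "summary")) |>
      mutate(scope = "population-matched") |>
      arrange(.data$sample)
    calls <- if (keep_calls) {
      purrr::list_rbind(purrr::map(parts, "calls"))
    } else {
      NULL
    }
    structure(list(summary = summary, calls = calls,
                   scope = "population-matched"),
              class = "variant_calls")
  } else {
    per_cons <- purrr::map(consensuses[pops], function(cons) {
      call_variants(cohort, cons, keep_calls = FALSE)$summary
    })
    summary <- purrr::list_rbind(per_cons) |>
      group_by(.data$sample) |>
      summarise(n_hom = mean(.data$n_hom), n_het = mean(.data$n_het),
                .groups = "drop") |>
      mutate(scope = "population-mean") |>
      select("sample", "scope", "n_hom", "n_het")
    structure(list(summary = summary, calls = NULL, scope = "population-mean"),
              class = "variant_calls")
  }
}

#' Expected per-site homozygous-variant probability under HWE
#'
#' Closed forms for the probability that a diploid genome is a homozygous
#' variant at a site with ALT frequency p, under Hardy-Weinberg genotypes:
#' against a fixed reference carrying REF, p^2; against a random-haplotype
#' ("type specimen") reference, p(1-p) (the reference carries ALT with
#' probability p); against the major-allele consensus, min(p, 1-p)^2.
#' Averaged over a uniform site-frequency spectrum these give 1/3, 1/6 and
#' 1/12 respectively -- the analytic anchors for the simulation checks.
#'
#' @param af ALT allele frequency (vectorised).
#' @param reference_model `"fixed-ref"`, `"random-haplotype"`, or
#'   `"consensus"`.
#' @return Expected homozygous-variant probability per site.
#' @examples
#' expected_hom_rate(0.9, "fixed-ref")   # 0.81
#' expected_hom_rate(0.9, "consensus")   # 0.01
#' @export
expected_hom_rate <- function(af,
                              reference_model = c("fixed-ref",
                                                  "random-haplotype",
                                                  "consensus")) {
  reference_model <- match.arg(reference_model)
  stopifnot(all(af >= 0 & af <= 1))
  switch(reference_model,
    "fixed-ref" = af^2,
    "random-haplotype" = af * (1 - af),
    "consensus" = pmin(af, 1 - af)^2
  )
}
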