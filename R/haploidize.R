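#' Collapse a diploid personal genome onto the reference
#'
#' Produces a haploid personal "reference": at homozygous-ALT sites the
#' personal allele is ALT, at homozygous-REF sites it is REF, and at
#' heterozygous sites one of the two alleles is chosen by an independent
#' fair coin from a seeded stream. Missing genotypes collapse to REF. The
#' returned sequence equals the reference with exactly those substitutions
#' applied.
#'
#' @param cohort An `snv_cohort` (must include the sample).
#' @param sample Sample label to collapse.
#' @param seed Seed for the heterozygous coin; defaults to a per-sample
#'   child seed of the cohort spec's root seed, so different samples are
#'   independent but each is reproducible.
#' @return An object of class `haploid_genome`: list with `sample`,
#'   `carried` (integer 0/1 per site; 1 = carries ALT), `sequence`
#'   (collapsed chromosome, `NULL` when the cohort has no reference
#'   sequence), and `sites` (the cohort's site tibble).
#' @examples
#' co <- simulate_cohort(cohort_spec(20, 5, seed = 3))
#' collapse_diploid(co, "S0001")
#' @export
collapse_diploid <- function(cohort, sample, seed = NULL) {
  stopifnot(inherits(cohort, "snv_cohort"))
  if (!sample %in% colnames(cohort$genotypes)) {
    abort(sprintf("Sample '%s' not present in the cohort.", sample))
  }
  if (is.null(seed)) {
    root <- if (!is.null(cohort$spec)) cohort$spec$seed else 0L
    seed <- child_seed(root, 100L + match(sample, colnames(cohort$genotypes)))
  }
  d <- cohort$genotypes[, sample]
  carried <- integer(length(d))
  carried[!is.na(d) & d == 2L] <- 1L
  het <- !is.na(d) & d == 1L
  if (any(het)) {
    carried[het] <- with_seed(seed, stats::rbinom(sum(het), 1L, 0.5))
  }
  sequence <- NULL
  if (!is.null(cohort$sequence)) {
    check_sites_vs_sequence(cohort$sites, cohort$sequence)
    alt_idx <- carried == 1L
    sequence <- seq_replace(cohort$sequence,
                            cohort$sites$pos[alt_idx],
                            cohort$sites$alt_allele[alt_idx])
  }
  structure(
    list(sample = sample, carried = carried, sequence = sequence,
         sites = cohort$sites),
    class = "haploid_genome"
  )
}

check_sites_vs_sequence <- function(sites, sequence) {
  got <- substring(sequence, sites$pos, sites$pos)
  bad <- got != sites$ref_allele
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Site REF disagrees with the sequence at %s:%d (site %s, sequence %s).",
                  sites$chrom[i], sites$pos[i], sites$ref_allele[i], got[i]))
  }
  invisible(TRUE)
}

#' Population frequency of the allele a haploid genome carries
#'
#' For each site, reports the cohort frequency of the allele the haploid
#' genome carries: `af_alt` where it carries ALT, `1 - af_alt` where it
#' carries REF. The reference genome itself is the all-REF vector
#' (`carried = 0` everywhere). These values feed the cumulative
#' allele-frequency distributions that compare the reference with personal
#' genomes.
#'
#' @param carried Integer/logical vector (1 = carries ALT) or a
#'   `haploid_genome`.
#' @param af_alt ALT allele frequencies per site (ignored when `carried` is
#'   a `haploid_genome`).
#' @return Numeric vector of carried-allele frequencies.
#' @examples
#' reference_allele_spectrum(c(0, 1), af_alt = c(0.7, 0.7)) # 0.3, 0.7
#' @export
reference_allele_spectrum <- function(carried, af_alt = NULL) {
  if (inherits(carried, "haploid_genome")) {
    af_alt <- carried$sites$af_alt
    carried <- carried$carried
  }
  stopifnot(length(carried) == length(af_alt))
  ifelse(carried == 1L, af_alt, 1 - af_alt)
}
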