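#' Specify a synthetic cohort
#'
#' A `cohort_spec` collects every parameter of the synthetic-cohort
#' generator: how many bi-allelic SNV sites and diploid samples to simulate,
#' the site-frequency spectrum (SFS) the global ALT frequencies are drawn
#' from, the number of subpopulations and their divergence (Fst under the
#' Balding-Nichols model), and how the synthetic reference chromosome is
#' constructed.
#'
#' Frequencies are truncated to `(eps, 1 - eps)`; the default
#' `eps = 1 / (2 * n_samples)` makes every simulated site expected to be
#' polymorphic in a cohort of that size, mirroring analyses that operate on
#' called polymorphic sites only.
#'
#' @param n_sites Number of bi-allelic SNV sites (positive integer).
#' @param n_samples Number of diploid samples (positive integer).
#' @param sfs_model Site-frequency spectrum for the global ALT frequency:
#'   `"uniform"` (flat on the truncated interval), `"beta"` (Beta(a, b)
#'   truncated), or `"neutral"` (density proportional to 1/p, truncated --
#'   the classic neutral SFS shape).
#' @param sfs_params Named numeric vector of SFS parameters; for
#'   `"beta"` supply `c(a = ..., b = ...)`.
#' @param n_subpops Number of subpopulations (>= 1).
#' @param fst Divergence of subpopulation frequencies around the global
#'   frequency, in `[0, 1)`. `fst = 0` forces every subpopulation frequency
#'   equal to the global one.
#' @param subpop_sizes Integer vector of per-subpopulation sample counts
#'   summing to `n_samples`; defaults to an (almost) even split.
#' @param seed Root RNG seed; every stage derives a child seed from it, so a
#'   spec is fully reproducible.
#' @param ref_mode `"random-haplotype"`: the reference base at each site is
#'   the model ALT allele with probability p, so the reference behaves like
#'   one sampled haploid genome (the "type specimen" property);
#'   `"all-ancestral"`: the reference always carries the designated ancestral
#'   base.
#' @param chrom Name of the synthetic chromosome (default `"1"`, so the
#'   emitted VCF passes the default autosome whitelist).
#' @param chrom_length Length of the synthetic chromosome; must admit
#'   `n_sites` distinct positions. Default `max(2 * n_sites, 1000)`.
#' @param eps Truncation constant for frequencies; default
#'   `1 / (2 * n_samples)`.
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_sites = 100, n_samples = 20, seed = 1)
#' spec
#' @export
cohort_spec <- function(n_sites,
                        n_samples,
                        sfs_model = c("uniform", "beta", "neutral"),
                        sfs_params = c(a = 1, b = 1),
                        n_subpops = 1L,
                        fst = 0,
                        subpop_sizes = NULL,
                        seed = 1L,
                        ref_mode = c("random-haplotype", "all-ancestral"),
                        chrom = "1",
                        chrom_length = NULL,
                        eps = NULL) {
  sfs_model <- match.arg(sfs_model)
  ref_mode <- match.arg(ref_mode)

  check_count <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
      abort(sprintf("`%s` must be a single positive integer.", name))
    }
  }
  check_count(n_sites, "n_sites")
  check_count(n_samples, "n_samples")
  check_count(n_subpops, "n_subpops")

  if (length(fst) != 1L || is.na(fst) || fst < 0 || fst >= 1) {
    abort("`fst` must be a single value in [0, 1).")
  }
  if (sfs_model == "beta") {
    if (!all(c("a", "b") %in% names(sfs_params)) ||
        any(sfs_params[c("a", "b")] <= 0)) {
      abort("`sfs_params` must contain positive `a` and `b` for sfs_model = \"beta\".")
    }
  }

  if (is.null(subpop_sizes)) {
    base <- n_samples %/% n_subpops
    subpop_sizes <- rep(base, n_subpops)
    extra <- n_samples - sum(subpop_sizes)
    if (extra > 0) subpop_sizes[seq_len(extra)] <- subpop_sizes[seq_len(extra)] + 1L
  }
  if (length(subpop_sizes) != n_subpops || sum(subpop_sizes) != n_samples ||
      any(subpop_sizes < 1)) {
    abort("`subpop_sizes` must be positive counts of length `n_subpops` summing to `n_samples`.")
  }

  chrom_length <- chrom_length %||% max(2L * n_sites, 1000L)
  if (chrom_length < n_sites) {
    abort("`chrom_length` must be at least `n_sites` (sites occupy distinct positions).")
  }
  eps <- eps %||% (1 / (2 * n_samples))
  if (eps <= 0 || eps >= 0.5) {
    abort("`eps` must be in (0, 0.5).")
  }

  structure(
    list(
      n_sites = as.integer(n_sites),
      n_samples = as.integer(n_samples),
      sfs_model = sfs_model,
      sfs_params = sfs_params,
      n_subpops = as.integer(n_subpops),
      fst = fst,
      subpop_sizes = as.integer(subpop_sizes),
      seed = as.integer(seed),
      ref_mode = ref_mode,
      chrom = chrom,
      chrom_length = as.integer(chrom_length),
      eps = eps
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  sites: %d  samples: %d  subpops: %d (Fst = %g)\n",
              x$n_sites, x$n_samples, x$n_subpops, x$fst))
  cat(sprintf("  SFS: %s  ref_mode: %s  seed: %d\n",
              x$sfs_model, x$ref_mode, x$seed))
  invisible(x)
}

pop_labels <- function(spec) sprintf("POP%d", seq_len(spec$n_subpops))

#' Sample-to-population assignment table
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `sample` and `population`.
#' @export
sample_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tibble(
    sample = sprintf("S%04d", seq_len(spec$n_samples)),
    population = rep(pop_labels(spec), times = spec$subpop_sizes)
  )
}
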