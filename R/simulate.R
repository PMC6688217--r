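#' Draw per-site allele frequencies
#'
#' Draws `n_sites` global ALT frequencies i.i.d. from the spec's
#' site-frequency spectrum, truncated to `(eps, 1 - eps)` so no simulated
#' site is monomorphic in expectation, then draws one frequency per
#' subpopulation from the Balding-Nichols distribution: a Beta with mean `p`
#' and variance `fst * p * (1 - p)`. With `fst = 0` the subpopulation
#' frequencies equal the global frequency exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per site: `site`, global frequency `p`, and
#'   one column `p_<POP>` per subpopulation.
#' @examples
#' draw_site_frequencies(cohort_spec(5, 10, n_subpops = 2, fst = 0.1, seed = 1))
#' @export
draw_site_frequencies <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_sites
  eps <- spec$eps
  p <- with_seed(child_seed(spec$seed, 1L), {
    switch(spec$sfs_model,
      uniform = stats::runif(n, eps, 1 - eps),
      beta = {
        a <- spec$sfs_params[["a"]]
        b <- spec$sfs_params[["b"]]
        # inverse-CDF sampling restricted to the truncated interval
        lo <- stats::pbeta(eps, a, b)
        hi <- stats::pbeta(1 - eps, a, b)
        stats::qbeta(stats::runif(n, lo, hi), a, b)
      },
      neutral = {
        # density proportional to 1/p on (eps, 1 - eps)
        eps * ((1 - eps) / eps)^stats::runif(n)
      }
    )
  })
  p <- pmin(pmax(p, eps), 1 - eps)

  labs <- pop_labels(spec)
  out <- tibble(site = seq_len(n), p = p)
  if (spec$fst == 0) {
    for (lab in labs) out[[paste0("p_", lab)]] <- p
  } else {
    shape_scale <- (1 - spec$fst) / spec$fst
    pk <- with_seed(child_seed(spec$seed, 2L), {
      vapply(labs, function(lab) {
        stats::rbeta(n, p * shape_scale, (1 - p) * shape_scale)
      }, numeric(n))
    })
    pk <- matrix(pk, nrow = n)
    colnames(pk) <- paste0("p_", labs)
    out <- dplyr::bind_cols(out, as_tibble(pk))
  }
  out
}

#' Draw diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Each sample's ALT dosage at each site is Binomial(2, p_k) where p_k is the
#' frequency in that sample's subpopulation -- i.e. genotype frequencies
#' p^2 : 2p(1-p) : (1-p)^2 within each subpopulation.
#'
#' @param freqs A site-frequency tibble from [draw_site_frequencies()] (or a
#'   hand-built one with the same columns).
#' @param spec The [cohort_spec()].
#' @return An integer matrix of ALT dosages (0/1/2), sites in rows, samples
#'   in columns (named as in [sample_table()]).
#' @export
draw_genotypes <- function(freqs, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  samples <- sample_table(spec)
  n <- nrow(freqs)
  G <- matrix(0L, nrow = n, ncol = spec$n_samples,
              dimnames = list(NULL, samples$sample))
  with_seed(child_seed(spec$seed, 3L), {
    for (lab in pop_labels(spec)) {
      idx <- which(samples$population == lab)
      pk <- freqs[[paste0("p_", lab)]]
      G[, idx] <- stats::rbinom(n * length(idx), 2L, pk)
    }
  })
  G
}

#' Build the synthetic reference chromosome and site list
#'
#' Emits a synthetic chromosome sequence and the site list with REF/ALT
#' labels defined *relative to that sequence*. In
#' `ref_mode = "random-haplotype"` the reference base at each site is the
#' model's derived allele with probability p, so the reference behaves like
#' one sampled haploid genome -- at sites where it carries the derived
#' allele, REF/ALT labels are swapped and all frequencies re-expressed as
#' `1 - p`. In `ref_mode = "all-ancestral"` the reference carries the
#' designated ancestral base everywhere and `af_alt = p` at every site.
#'
#' @param freqs Site-frequency tibble from [draw_site_frequencies()].
#' @param spec The [cohort_spec()].
#' @return A list with `sequence` (single string), `sites` (tibble with
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `af_alt`, one `af_<POP>`
#'   column per subpopulation, and `ref_is_derived`), and `chrom`.
#' @export
make_reference <- function(freqs, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(freqs)
  labs <- pop_labels(spec)
  res <- with_seed(child_seed(spec$seed, 4L), {
    sequence <- random_dna(spec$chrom_length)
    pos <- sort(sample.int(spec$chrom_length, n))
    anc <- sample(DNA_BASES, n, replace = TRUE)
    # derived allele differs from the ancestral base
    der <- vapply(anc, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    ref_is_derived <- if (spec$ref_mode == "random-haplotype") {
      stats::runif(n) < freqs$p
    } else {
      rep(FALSE, n)
    }
    list(sequence = sequence, pos = pos, anc = anc, der = unname(der),
         ref_is_derived = ref_is_derived)
  })

  ref_allele <- ifelse(res$ref_is_derived, res$der, res$anc)
  alt_allele <- ifelse(res$ref_is_derived, res$anc, res$der)
  af_alt <- ifelse(res$ref_is_derived, 1 - freqs$p, freqs$p)

  sites <- tibble(
    chrom = spec$chrom,
    pos = res$pos,
    ref_allele = ref_allele,
    alt_allele = alt_allele,
    af_alt = af_alt,
    ref_is_derived = res$ref_is_derived
  )
  for (lab in labs) {
    pk <- freqs[[paste0("p_", lab)]]
    sites[[paste0("af_", lab)]] <- ifelse(res$ref_is_derived, 1 - pk, pk)
  }
  sequence <- seq_replace(res$sequence, res$pos, ref_allele)
  list(sequence = sequence, sites = sites, chrom = spec$chrom)
}

#' Simulate a full synthetic cohort
#'
#' Orchestrates [draw_site_frequencies()], [draw_genotypes()] and
#' [make_reference()] and re-expresses the genotype dosages against the
#' emitted reference: at sites where the reference carries the derived
#' allele, dosage d becomes 2 - d so that dosage always counts copies of the
#' VCF ALT allele.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `snv_cohort`: a list with `spec`, `sites`
#'   (tibble; REF/ALT and frequencies relative to the reference sequence),
#'   `genotypes` (integer ALT-dosage matrix, sites x samples), `samples`
#'   (tibble), `sequence` (reference chromosome string) and `chrom`.
#' @examples
#' co <- simulate_cohort(cohort_spec(50, 10, seed = 7))
#' co
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  freqs <- draw_site_frequencies(spec)
  G <- draw_genotypes(freqs, spec)
  ref <- make_reference(freqs, spec)
  flip <- ref$sites$ref_is_derived
  if (any(flip)) {
    G[flip, ] <- 2L - G[flip, , drop = FALSE]
  }
  new_snv_cohort(
    spec = spec,
    sites = ref$sites,
    genotypes = G,
    samples = sample_table(spec),
    sequence = ref$sequence,
    chrom = spec$chrom
  )
}

new_snv_cohort <- function(spec = NULL, sites, genotypes, samples, sequence = NULL,
                           chrom) {
  stopifnot(nrow(sites) == nrow(genotypes))
  structure(
    list(spec = spec, sites = sites, genotypes = genotypes, samples = samples,
         sequence = sequence, chrom = chrom),
    class = "snv_cohort"
  )
}

#' @export
print.snv_cohort <- function(x, ...) {
  cat("<snv_cohort>\n")
  cat(sprintf("  %d bi-allelic SNV sites x %d samples", nrow(x$sites),
              ncol(x$genotypes)))
  if (!is.null(x$samples)) {
    cat(sprintf("  (%d population%s)", dplyr::n_distinct(x$samples$population),
                ifelse(dplyr::n_distinct(x$samples$population) > 1, "s", "")))
  }
  cat("\n")
  if (!is.null(x$sequence)) {
    cat(sprintf("  reference: %s (%d bp)\n", x$chrom, nchar(x$sequence)))
  }
  invisible(x)
}

#' Sample a subset of personal genomes from a cohort
#'
#' Mirrors the "randomly chosen personal genomes" used to compare allele
#' spectra: draws `n` sample labels without replacement, optionally
#' stratified by population (proportional allocation).
#'
#' @param cohort An `snv_cohort`.
#' @param n Number of genomes to draw.
#' @param stratify Stratify the draw by population?
#' @param seed RNG seed for the draw.
#' @return Character vector of sample labels.
#' @export
sample_genomes <- function(cohort, n, stratify = FALSE, seed = 1L) {
  stopifnot(inherits(cohort, "snv_cohort"))
  labels <- cohort$samples$sample
  n <- min(n, length(labels))
  with_seed(seed, {
    if (!stratify) {
      sample(labels, n)
    } else {
      pops <- split(labels, cohort$samples$population)
      alloc <- round(n * lengths(pops) / length(labels))
      alloc[1] <- n - sum(alloc[-1])
      unlist(purrr::map2(pops, alloc, function(x, k) sample(x, min(k, length(x)))),
             use.names = FALSE)
    }
  })
}
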