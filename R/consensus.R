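#' Major-allele choice at one site
#'
#' The consensus rule: the consensus carries the ALT allele exactly when its
#' frequency is strictly above 0.5; at a tie (AF = 0.5) the reference allele
#' is kept, so the rule is reproducible at ties.
#'
#' @param ref_allele,alt_allele Single-base alleles (vectorised).
#' @param af ALT allele frequency in `[0, 1]` (vectorised).
#' @return A tibble with `base` (the consensus base) and `swapped`
#'   (`TRUE` when the ALT replaced the REF).
#' @examples
#' consensus_allele("A", "G", c(0.7, 0.5, 0.2))
#' @export
consensus_allele <- function(ref_allele, alt_allele, af) {
  stopifnot(all(af >= 0 & af <= 1, na.rm = TRUE))
  swapped <- !is.na(af) & af > 0.5
  tibble(base = ifelse(swapped, alt_allele, ref_allele), swapped = swapped)
}

#' Build a consensus reference by major-allele replacement
#'
#' Replaces, at every listed site where the ALT frequency exceeds 0.5, the
#' reference base with the ALT base; all other positions are untouched. The
#' per-site decisions are returned as a switch table -- the contract every
#' downstream stage (genotype re-projection, variant calling) consumes.
#'
#' `scope = "ALL"` uses the cohort-wide frequency. A population label uses
#' that population's frequency: recomputed from that population's genotypes
#' when the cohort has genotypes and population assignments, otherwise taken
#' from the site table's `af_<pop>` column. Every site in the global site
#' list is considered, whatever its within-population frequency.
#'
#' @param cohort An `snv_cohort`.
#' @param scope `"ALL"` or a population label.
#' @param af_source `"genotypes"` (recompute within scope from the dosage
#'   matrix; default when genotypes are present) or `"sites"` (use the site
#'   table's frequency columns).
#' @return An object of class `consensus_ref`: list with `sequence` (the
#'   consensus chromosome; `NULL` if the cohort has no reference sequence),
#'   `switch_table` (tibble: `chrom`, `pos`, `ref`, `alt`, `af_used`,
#'   `swapped`, `effective_ref`, `effective_alt`, `scope`), and `scope`.
#' @examples
#' co <- simulate_cohort(cohort_spec(50, 20, seed = 2))
#' cons <- build_consensus(co)
#' glance(cons)
#' @export
build_consensus <- function(cohort, scope = "ALL",
                            af_source = c("genotypes", "sites")) {
  stopifnot(inherits(cohort, "snv_cohort"))
  af_source <- match.arg(af_source)
  s <- cohort$sites
  if (anyDuplicated(s[c("chrom", "pos")]) > 0) {
    abort("Overlapping sites: more than one record at a single position.")
  }
  has_gt <- ncol(cohort$genotypes) > 0

  af_used <- if (scope == "ALL") {
    if (af_source == "genotypes" && has_gt) {
      compute_af(cohort$genotypes)$af
    } else {
      s$af_alt
    }
  } else {
    pops <- unique(cohort$samples$population)
    if (af_source == "genotypes" && has_gt && scope %in% pops) {
      idx <- cohort$samples$population == scope
      compute_af(cohort$genotypes[, idx, drop = FALSE])$af
    } else if (paste0("af_", scope) %in% names(s)) {
      s[[paste0("af_", scope)]]
    } else {
      avail <- unique(c(pops, sub("^af_", "", grep("^af_(?!alt$)", names(s),
                                                   value = TRUE, perl = TRUE))))
      abort(sprintf("Unknown population scope '%s'; available: %s.",
                    scope, paste(stats::na.omit(avail), collapse = ", ")))
    }
  }

  choice <- consensus_allele(s$ref_allele, s$alt_allele, af_used)
  switch_table <- tibble(
    chrom = s$chrom,
    pos = s$pos,
    ref = s$ref_allele,
    alt = s$alt_allele,
    af_used = af_used,
    swapped = choice$swapped,
    effective_ref = choice$base,
    effective_alt = ifelse(choice$swapped, s$ref_allele, s$alt_allele),
    scope = scope
  )

  sequence <- NULL
  if (!is.null(cohort$sequence)) {
    check_sites_vs_sequence(s, cohort$sequence)
    sw <- which(switch_table$swapped)
    sequence <- seq_replace(cohort$sequence, s$pos[sw], s$alt_allele[sw])
  }
  structure(list(sequence = sequence, switch_table = switch_table,
                 scope = scope),
            class = "consensus_ref")
}

#' @export
print.consensus_ref <- function(x, ...) {
  st <- x$switch_table
  cat(sprintf("<consensus_ref> scope %s: %d/%d sites swapped to the major allele\n",
              x$scope, sum(st$swapped), nrow(st)))
  invisible(x)
}

#' A no-swap switch table for the original reference
#'
#' Calling variants "against the reference" is the degenerate case of the
#' switch-table machinery: no site is swapped. This helper builds that
#' table so the same calling code serves both references.
#'
#' @param cohort An `snv_cohort`.
#' @return A `consensus_ref` with `swapped = FALSE` everywhere and scope
#'   `"reference"`.
#' @export
reference_scope <- function(cohort) {
  stopifnot(inherits(cohort, "snv_cohort"))
  s <- cohort$sites
  structure(
    list(
      sequence = cohort$sequence,
      switch_table = tibble(
        chrom = s$chrom, pos = s$pos, ref = s$ref_allele, alt = s$alt_allele,
        af_used = s$af_alt, swapped = FALSE,
        effective_ref = s$ref_allele, effective_alt = s$alt_allele,
        scope = "reference"
      ),
      scope = "reference"
    ),
    class = "consensus_ref"
  )
}

#' Write a switch table as TSV
#' @param consensus A `consensus_ref`.
#' @param path Output path.
#' @export
write_switch_table <- function(consensus, path) {
  readr::write_tsv(consensus$switch_table, path)
  invisible(path)
}

#' Re-express a cohort against a consensus reference
#'
#' Returns a new `snv_cohort` whose REF/ALT labels, allele frequencies,
#' genotype dosages and reference sequence are all relative to the given
#' consensus: at swapped sites REF and ALT exchange roles, every frequency
#' column becomes its complement, and each dosage d becomes 2 - d (missing
#' stays missing). Rebuilding a consensus from the result (same scope, same
#' cohort) swaps nothing -- the construction is a fixed point.
#'
#' @param cohort An `snv_cohort`.
#' @param consensus A `consensus_ref` built from it.
#' @return An `snv_cohort` relative to the consensus.
#' @export
rebase_cohort <- function(cohort, consensus) {
  stopifnot(inherits(cohort, "snv_cohort"), inherits(consensus, "consensus_ref"))
  st <- consensus$switch_table
  if (!identical(st$pos, cohort$sites$pos)) {
    abort("Switch table and cohort cover different site lists.")
  }
  s <- cohort$sites
  flip <- st$swapped
  s$ref_allele <- st$effective_ref
  s$alt_allele <- st$effective_alt
  for (cc in grep("^af_", names(s), value = TRUE)) {
    s[[cc]] <- ifelse(flip, 1 - s[[cc]], s[[cc]])
  }
  if ("ref_is_derived" %in% names(s)) s$ref_is_derived <- NULL
  G <- cohort$genotypes
  if (ncol(G) > 0 && any(flip)) {
    G[flip, ] <- 2L - G[flip, , drop = FALSE]
  }
  new_snv_cohort(spec = cohort$spec, sites = s, genotypes = G,
                 samples = cohort$samples,
                 sequence = consensus$sequence %||% cohort$sequence,
                 chrom = cohort$chrom)
}
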