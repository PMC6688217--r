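#' Allele frequencies from a genotype matrix
#'
#' Computes the ALT allele frequency at each site as ALT-allele count over
#' called-allele count; missing genotypes are excluded from the denominator,
#' never imputed. With a grouping vector, per-group frequencies are computed
#' on the group's samples the same way.
#'
#' @param genotypes Integer ALT-dosage matrix (sites x samples; `NA` =
#'   missing).
#' @param groups Optional character/factor vector of length `ncol(genotypes)`
#'   assigning each sample to a group (e.g. a population).
#' @return A tibble with one row per site: `site`, `af`, `n_called`
#'   (called-allele denominator), and one `af_<group>` column per group.
#'   Sites where every genotype is missing get `af = NA`.
#' @examples
#' G <- rbind(c(0L, 1L, 2L), c(2L, 2L, NA))
#' compute_af(G)
#' @export
compute_af <- function(genotypes, groups = NULL) {
  stopifnot(is.matrix(genotypes))
  one <- function(M) {
    called <- 2L * rowSums(!is.na(M))
    alt <- rowSums(M, na.rm = TRUE)
    ifelse(called > 0, alt / called, NA_real_)
  }
  out <- tibble(
    site = seq_len(nrow(genotypes)),
    af = one(genotypes),
    n_called = 2L * rowSums(!is.na(genotypes))
  )
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(genotypes))
    for (g in unique(as.character(groups))) {
      out[[paste0("af_", g)]] <- one(genotypes[, groups == g, drop = FALSE])
    }
  }
  out
}

default_autosomes <- function() {
  a <- as.character(1:22)
  c(a, paste0("chr", a))
}

strip_chr <- function(x) sub("^chr", "", x)

gt_to_dosage <- function(gt) {
  # phase is ignored; "." anywhere in the call means missing
  gt <- gsub("|", "/", gt, fixed = TRUE)
  d <- rep(NA_integer_, length(gt))
  d[gt %in% c("0/0", "0")] <- 0L
  d[gt %in% c("0/1", "1/0")] <- 1L
  d[gt %in% c("1/1", "1")] <- 2L
  d
}

dosage_to_gt <- function(d) {
  gt <- rep("./.", length(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  gt
}

#' Read bi-allelic SNV sites (and genotypes) from a VCF
#'
#' Parses a VCF and applies the site filter chain used throughout the
#' analysis: keep only records with a single-base REF, exactly one
#' single-base ALT (bi-allelic SNVs), on a whitelisted autosome. Record
#' order is preserved; counts of excluded records by reason are attached as
#' the `filter_log` attribute and reported via `message()`.
#'
#' ALT allele frequencies are recomputed from GT when genotypes are present
#' (`af_source = "gt"`, the default); otherwise the INFO `AF` field is used.
#' When both are available they are cross-checked and disagreements beyond
#' `af_tol` raise a warning (or an error with `strict = TRUE`).
#'
#' @param vcf Path to a VCF file (plain or bgzipped).
#' @param fasta Optional path to the reference FASTA; when given, each
#'   retained record's REF base is checked against the sequence and a
#'   mismatch is a hard error naming the first offending site.
#' @param populations Optional path to a sample-to-population TSV (columns
#'   `sample`, `population`) or a data frame of the same shape; enables
#'   per-population allele frequencies.
#' @param autosomes Character whitelist of contig names (default "1".."22",
#'   tolerant of a "chr" prefix).
#' @param af_source `"gt"` (recompute from genotypes, fall back to INFO) or
#'   `"info"` (use INFO AF).
#' @param af_tol Tolerance for the GT-vs-INFO AF cross-check.
#' @param strict Error (rather than warn) on AF cross-check failures.
#' @return An `snv_cohort` (see [simulate_cohort()]); `sequence` is filled
#'   only when `fasta` is supplied. The exclusion log is in
#'   `attr(x, "filter_log")`.
#' @export
read_sites <- function(vcf, fasta = NULL, populations = NULL,
                       autosomes = default_autosomes(),
                       af_source = c("gt", "info"),
                       af_tol = 0.01, strict = FALSE) {
  af_source <- match.arg(af_source)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n0 <- nrow(fix)
  if (n0 == 0L) abort(sprintf("No records in VCF '%s'.", vcf))

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  not_snv <- !multi & !(fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES)
  off_chrom <- !multi & !not_snv & !(fix$CHROM %in% autosomes)
  keep <- !(multi | not_snv | off_chrom)

  filter_log <- tibble(
    reason = c("multi-allelic", "not SNV", "non-autosome"),
    n_excluded = c(sum(multi), sum(not_snv), sum(off_chrom))
  )
  if (any(!keep)) {
    message(sprintf(
      "read_sites: excluded %d/%d records (%s)", sum(!keep), n0,
      paste(sprintf("%s: %d", filter_log$reason, filter_log$n_excluded),
            collapse = ", ")
    ))
  }
  if (!any(keep)) abort("No records pass the bi-allelic SNV filter.")

  sites <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref_allele = fix$REF[keep],
    alt_allele = fix$ALT[keep]
  )

  # genotypes
  G <- NULL
  samples <- NULL
  if (ncol(v@gt) > 1L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    G <- matrix(gt_to_dosage(gt), nrow = nrow(gt),
                dimnames = list(NULL, colnames(gt)))
    samples <- tibble(sample = colnames(G), population = NA_character_)
  }
  if (is.null(G) && af_source == "gt") af_source <- "info"
  if (is.null(G) && !is.null(populations)) {
    warn("`populations` supplied but the VCF carries no genotypes; ignored.")
    populations <- NULL
  }

  if (!is.null(populations)) {
    pops <- if (is.data.frame(populations)) {
      as_tibble(populations)
    } else {
      read_populations(populations)
    }
    missing_samp <- setdiff(samples$sample, pops$sample)
    if (length(missing_samp) > 0) {
      abort(sprintf("Samples missing from population table: %s",
                    paste(utils::head(missing_samp, 5), collapse = ", ")))
    }
    samples <- dplyr::left_join(samples["sample"], pops, by = "sample")
  }

  # INFO AF (cohort-wide)
  info_af <- suppressWarnings(vcfR::extract.info(v, element = "AF",
                                                 as.numeric = TRUE))[keep]

  if (af_source == "gt") {
    groups <- if (!is.null(populations)) samples$population else NULL
    aft <- compute_af(G, groups = groups)
    all_missing <- is.na(aft$af)
    if (any(all_missing)) {
      message(sprintf("read_sites: excluded %d site(s) with all genotypes missing", sum(all_missing)))
      sites <- sites[!all_missing, , drop = FALSE]
      G <- G[!all_missing, , drop = FALSE]
      aft <- aft[!all_missing, , drop = FALSE]
      info_af <- info_af[!all_missing]
      filter_log <- dplyr::bind_rows(
        filter_log, tibble(reason = "all genotypes missing",
                           n_excluded = sum(all_missing)))
    }
    sites$af_alt <- aft$af
    if (!is.null(populations)) {
      for (nm in setdiff(names(aft), c("site", "af", "n_called"))) {
        sites[[nm]] <- aft[[nm]]
      }
    }
    bad <- !is.na(info_af) & abs(info_af - sites$af_alt) > af_tol
    if (any(bad)) {
      msg <- sprintf("GT-derived AF disagrees with INFO AF beyond %g at %d site(s); first at %s:%d.",
                     af_tol, sum(bad), sites$chrom[which(bad)[1]], sites$pos[which(bad)[1]])
      if (strict) abort(msg) else message("read_sites: ", msg)
    }
  } else {
    if (all(is.na(info_af))) abort("af_source = \"info\" but the VCF has no INFO AF field.")
    sites$af_alt <- info_af
    # per-population INFO keys, if present (AF_<pop>)
    first_info <- strsplit(v@fix[which(keep)[1], "INFO"], ";", fixed = TRUE)[[1]]
    pop_keys <- sub("=.*$", "", grep("^AF_", first_info, value = TRUE))
    for (key in pop_keys) {
      vals <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))[keep]
      if (!all(is.na(vals))) sites[[sub("^AF_", "af_", key)]] <- vals
    }
  }

  sequence <- NULL
  chrom <- unique(sites$chrom)
  if (!is.null(fasta)) {
    dna <- Biostrings::readDNAStringSet(fasta)
    names(dna) <- sub("\\s.*$", "", names(dna))
    for (ch in chrom) {
      nm <- if (ch %in% names(dna)) ch else strip_chr(ch)
      if (!nm %in% names(dna)) {
        abort(sprintf("Contig '%s' not found in FASTA '%s'.", ch, fasta))
      }
      idx <- sites$chrom == ch
      chseq <- as.character(dna[[nm]])
      got <- substring(chseq, sites$pos[idx], sites$pos[idx])
      bad <- got != sites$ref_allele[idx]
      if (any(bad)) {
        first <- which(idx)[which(bad)[1]]
        abort(sprintf("REF mismatch vs FASTA at %s:%d (VCF %s, FASTA %s).",
                      sites$chrom[first], sites$pos[first],
                      sites$ref_allele[first], got[which(bad)[1]]))
      }
    }
    if (length(chrom) == 1L) {
      nm <- if (chrom %in% names(dna)) chrom else strip_chr(chrom)
      sequence <- as.character(dna[[nm]])
    }
  }

  out <- new_snv_cohort(
    spec = NULL, sites = sites,
    genotypes = if (is.null(G)) {
      matrix(integer(0), nrow = nrow(sites), ncol = 0)
    } else G,
    samples = samples, sequence = sequence,
    chrom = if (length(chrom) == 1L) chrom else chrom
  )
  attr(out, "filter_log") <- filter_log
  out
}

#' Read a sample-to-population TSV
#'
#' @param path TSV with header `sample<TAB>population`.
#' @return A tibble with columns `sample`, `population`.
#' @export
read_populations <- function(path) {
  pops <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample", "population") %in% names(pops))) {
    abort(sprintf("Population table '%s' must have columns 'sample' and 'population'.", path))
  }
  pops[c("sample", "population")]
}

#' Write a sample-to-population TSV
#' @param samples Tibble with columns `sample`, `population`.
#' @param path Output path.
#' @export
write_populations <- function(samples, path) {
  readr::write_tsv(samples[c("sample", "population")], path)
  invisible(path)
}

#' Write a cohort's sites and genotypes as VCFv4.2
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT plus one GT column per
#' sample (unphased, "/" separator, "./." for missing). INFO carries the
#' cohort `AF` and one `AF_<POP>` key per population-frequency column of the
#' site table.
#'
#' @param cohort An `snv_cohort`.
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "snv_cohort"))
  s <- cohort$sites
  pop_cols <- grep("^af_(?!alt$)", names(s), value = TRUE, perl = TRUE)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=consensusref",
    sprintf("##contig=<ID=%s%s>", unique(s$chrom),
            if (!is.null(cohort$sequence)) sprintf(",length=%d", nchar(cohort$sequence)) else ""),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"ALT allele frequency\">",
    vapply(pop_cols, function(cc) {
      sprintf("##INFO=<ID=AF_%s,Number=A,Type=Float,Description=\"ALT allele frequency in population %s\">",
              sub("^af_", "", cc), sub("^af_", "", cc))
    }, ""),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  info <- sprintf("AF=%s", formatC(s$af_alt, format = "g", digits = 8))
  for (cc in pop_cols) {
    info <- paste0(info, ";AF_", sub("^af_", "", cc), "=",
                   formatC(s[[cc]], format = "g", digits = 8))
  }
  has_gt <- ncol(cohort$genotypes) > 0
  body <- paste(s$chrom, s$pos, ".", s$ref_allele, s$alt_allele, ".", "PASS",
                info, sep = "\t")
  if (has_gt) {
    gt <- apply(cohort$genotypes, 2, dosage_to_gt)
    gt_lines <- do.call(paste, c(split(gt, col(gt)), sep = "\t"))
    body <- paste(body, "GT", gt_lines, sep = "\t")
    colhdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(cohort$genotypes)),
                    collapse = "\t")
  } else {
    colhdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO"), collapse = "\t")
  }
  writeLines(c(hdr, colhdr, body), path)
  invisible(path)
}

#' Write a sequence as FASTA (60-column wrap)
#'
#' @param sequence Single sequence string.
#' @param name Sequence name for the header.
#' @param path Output path.
#' @export
write_fasta <- function(sequence, name, path) {
  dna <- Biostrings::DNAStringSet(sequence)
  names(dna) <- name
  Biostrings::writeXStringSet(dna, path, width = 60L)
  invisible(path)
}

#' Write every cohort artifact (VCF, FASTA, population TSV) to a directory
#'
#' @param cohort An `snv_cohort` with a reference sequence.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "snv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    fasta = file.path(dir, "reference.fa"),
    populations = file.path(dir, "populations.tsv")
  )
  write_vcf(cohort, paths$vcf)
  if (!is.null(cohort$sequence)) {
    write_fasta(cohort$sequence, cohort$chrom, paths$fasta)
  }
  write_populations(cohort$samples, paths$populations)
  paths
}
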