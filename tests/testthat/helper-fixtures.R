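# Shared fixtures: tiny hand-enumerable cohorts and an independent
# sequence-comparison oracle for variant counts.

# A 5-site, 3-sample cohort small enough to enumerate by hand. Dosages and
# frequencies are fixed, not drawn.
toy_cohort <- function() {
  co <- simulate_cohort(cohort_spec(n_sites = 5, n_samples = 3, seed = 99))
  co$sites$af_alt <- c(0.2, 0.3, 0.9, 0.4, 0.8)
  co$sites$af_POP1 <- co$sites$af_alt
  co$genotypes[] <- c(
    0L, 1L, 2L, 2L, 1L,  # S0001
    0L, 0L, 0L, 0L, 0L,  # S0002
    2L, 2L, 1L, 0L, 1L   # S0003
  )
  co
}

# Plain-text VCF writer for hand-built records (filter-chain tests).
write_toy_vcf <- function(records, path, samples = character(),
                          gt = NULL, extra_header = character()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  body <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    line <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
                  r$info %||% ".", sep = "\t")
    if (length(samples)) line <- paste(c(line, "GT", gt[[i]]), collapse = "\t")
    line
  }, "")
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent oracle: per-sample hom/het counts by brute-force base-by-base
# comparison of the personal diploid sequence pair against a target
# reference sequence. Personal haplotypes are built on the ORIGINAL
# reference labels: hap1 carries ALT where dosage >= 1, hap2 where
# dosage == 2.
brute_force_counts <- function(cohort, target_sequence, sample) {
  d <- cohort$genotypes[, sample]
  s <- cohort$sites
  hap_seq <- function(carries_alt) {
    v <- strsplit(cohort$sequence, "")[[1]]
    v[s$pos[carries_alt]] <- s$alt_allele[carries_alt]
    v
  }
  h1 <- hap_seq(!is.na(d) & d >= 1L)
  h2 <- hap_seq(!is.na(d) & d == 2L)
  tg <- strsplit(target_sequence, "")[[1]]
  diff1 <- h1 != tg
  diff2 <- h2 != tg
  c(n_hom = sum(diff1 & diff2), n_het = sum(xor(diff1, diff2)))
}
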