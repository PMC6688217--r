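test_that("the filter chain keeps only autosomal bi-allelic SNVs, in order", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(list(
    list(chrom = "1", pos = 100, ref = "A", alt = "G", info = "AF=0.4"),
    list(chrom = "1", pos = 200, ref = "C", alt = "G,T", info = "AF=0.2"), # multi-allelic
    list(chrom = "2", pos = 300, ref = "AT", alt = "A", info = "AF=0.1"),  # not SNV
    list(chrom = "X", pos = 400, ref = "G", alt = "A", info = "AF=0.3"),   # non-autosome
    list(chrom = "chr2", pos = 500, ref = "T", alt = "C", info = "AF=0.6"),
    list(chrom = "2", pos = 600, ref = "G", alt = "T", info = "AF=0.9")
  ), path)
  co <- suppressMessages(read_sites(path, af_source = "info"))
  expect_equal(nrow(co$sites), 3)
  expect_equal(co$sites$pos, c(100L, 500L, 600L))
  expect_equal(co$sites$af_alt, c(0.4, 0.6, 0.9))
  log <- attr(co, "filter_log")
  expect_equal(log$n_excluded[log$reason == "multi-allelic"], 1)
  expect_equal(log$n_excluded[log$reason == "not SNV"], 1)
  expect_equal(log$n_excluded[log$reason == "non-autosome"], 1)
})

test_that("genotype dosages come from GT with phase ignored, missing never imputed", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(list(
    list(chrom = "1", pos = 10, ref = "A", alt = "G"),
    list(chrom = "1", pos = 20, ref = "C", alt = "T")
  ), path, samples = c("sA", "sB", "sC"),
  gt = list(c("0/0", "1|0", "1/1"), c("./.", "0|1", "1/1")))
  co <- suppressMessages(read_sites(path))
  expect_identical(unname(co$genotypes),
                   rbind(c(0L, 1L, 2L), c(NA, 1L, 2L)))
  # AF recomputed from GT, missing excluded from the denominator
  expect_equal(co$sites$af_alt, c(3 / 6, 3 / 4))
})

test_that("compute_af counts called alleles, globally and per group", {
  G <- rbind(c(0L, 1L, 2L), c(2L, 2L, NA))
  af <- compute_af(G)
  expect_equal(af$af, c(0.5, 1.0))
  expect_equal(af$n_called, c(6L, 4L))

  # 10-sample stratified toy: hand-computed group frequencies
  G2 <- matrix(c(rep(1L, 4), rep(0L, 6)), nrow = 1)
  af2 <- compute_af(G2, groups = rep(c("a", "b"), each = 5))
  expect_equal(af2$af_a, (4 + 0) / 10 * (10 / 10)) # 4 ALT alleles of 10
  expect_equal(af2$af_a, 0.4)
  expect_equal(af2$af_b, 0)
})

test_that("REF mismatch against the FASTA is a hard error naming the site", {
  spec <- cohort_spec(20, 6, seed = 3)
  co <- simulate_cohort(spec)
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  # corrupt the stored reference at the first site
  bad <- co$sites$ref_allele[1]
  swap <- setdiff(c("A", "C", "G", "T"), bad)[1]
  seq2 <- co$sequence
  substr(seq2, co$sites$pos[1], co$sites$pos[1]) <- swap
  write_fasta(seq2, co$chrom, paths$fasta)
  expect_error(suppressMessages(read_sites(paths$vcf, fasta = paths$fasta)),
               sprintf("REF mismatch.*%s:%d", co$sites$chrom[1], co$sites$pos[1]))
})

test_that("write/read round trip preserves CHROM/POS/REF/ALT/GT", {
  spec <- cohort_spec(150, 20, n_subpops = 2, fst = 0.05, seed = 12)
  co <- simulate_cohort(spec)
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  co2 <- suppressMessages(
    read_sites(paths$vcf, fasta = paths$fasta, populations = paths$populations))
  expect_identical(co2$sites[c("chrom", "pos", "ref_allele", "alt_allele")],
                   co$sites[c("chrom", "pos", "ref_allele", "alt_allele")])
  expect_identical(unname(co2$genotypes), unname(co$genotypes))
  expect_identical(co2$samples, co$samples)
  expect_identical(co2$sequence, co$sequence)
  # AF recomputed from GT on read equals the cohort's empirical AF exactly
  expect_equal(co2$sites$af_alt, compute_af(co$genotypes)$af)
})

test_that("INFO-AF fallback and the strict GT/INFO cross-check work", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(list(
    list(chrom = "1", pos = 10, ref = "A", alt = "G", info = "AF=0.9")
  ), path, samples = c("sA", "sB"), gt = list(c("0/0", "0/1")))
  # gt source wins by default; INFO disagrees (0.25 vs 0.9) -> logged
  expect_message(read_sites(path), "disagrees with INFO AF")
  expect_error(suppressMessages(read_sites(path, strict = TRUE)),
               "disagrees with INFO AF")
  co <- suppressMessages(read_sites(path, af_source = "info"))
  expect_equal(co$sites$af_alt, 0.9)
})

test_that("sites with every genotype missing are excluded with a logged reason", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(list(
    list(chrom = "1", pos = 10, ref = "A", alt = "G"),
    list(chrom = "1", pos = 20, ref = "C", alt = "T")
  ), path, samples = c("sA", "sB"), gt = list(c("0/1", "1/1"), c("./.", "./.")))
  co <- suppressMessages(read_sites(path))
  expect_equal(nrow(co$sites), 1)
  log <- attr(co, "filter_log")
  expect_equal(log$n_excluded[log$reason == "all genotypes missing"], 1)
})
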