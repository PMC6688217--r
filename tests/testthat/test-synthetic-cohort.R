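test_that("cohort_spec validates its fields", {
  expect_s3_class(cohort_spec(10, 4, seed = 1), "cohort_spec")
  expect_error(cohort_spec(0, 4), "n_sites")
  expect_error(cohort_spec(10, 4, fst = 1), "fst")
  expect_error(cohort_spec(10, 4, sfs_model = "beta", sfs_params = c(a = -1, b = 2)),
               "sfs_params")
  expect_error(cohort_spec(10, 4, n_subpops = 2, subpop_sizes = c(3, 3)),
               "subpop_sizes")
})

test_that("zero Fst forces subpopulation frequencies equal to the global one", {
  freqs <- draw_site_frequencies(
    cohort_spec(200, 30, n_subpops = 3, fst = 0, seed = 4))
  expect_identical(freqs$p_POP1, freqs$p)
  expect_identical(freqs$p_POP2, freqs$p)
  expect_identical(freqs$p_POP3, freqs$p)
})

test_that("frequencies stay strictly polymorphic and match the SFS mean", {
  spec <- cohort_spec(20000, 50, seed = 8)
  freqs <- draw_site_frequencies(spec)
  expect_true(all(freqs$p > 0 & freqs$p < 1))
  # uniform SFS is symmetric: mean 0.5 within 3 standard errors
  se <- sqrt(1 / 12 / nrow(freqs))
  expect_lt(abs(mean(freqs$p) - 0.5), 3 * se)
})

test_that("subpopulation divergence follows the Balding-Nichols variance", {
  spec <- cohort_spec(5000, 50, n_subpops = 3, fst = 0.1, seed = 21)
  freqs <- draw_site_frequencies(spec)
  # standardised deviations should have variance ~= Fst across all sites/pops
  z2 <- unlist(lapply(paste0("p_POP", 1:3), function(cc) {
    (freqs[[cc]] - freqs$p)^2 / (freqs$p * (1 - freqs$p))
  }))
  expect_lt(abs(mean(z2) - 0.1), 0.005)
  # concrete anchor: p = 0.5, Fst = 0.1 -> variance Fst*p*(1-p) = 0.025
  # (~500 sites near 0.5 -> sd of the variance estimate ~ 0.0016)
  near_half <- abs(freqs$p - 0.5) < 0.05
  v <- var(freqs$p_POP1[near_half] - freqs$p[near_half])
  expect_lt(abs(v - 0.025), 0.005)
})

test_that("genotypes are Hardy-Weinberg within each subpopulation", {
  spec <- cohort_spec(300, 2000, seed = 13)
  freqs <- draw_site_frequencies(spec)
  freqs$p[] <- 0.5
  freqs$p_POP1[] <- 0.5
  G <- draw_genotypes(freqs, spec)
  fr <- table(G) / length(G)
  expect_equal(unname(fr[["0"]]), 0.25, tolerance = 0.01)
  expect_equal(unname(fr[["1"]]), 0.50, tolerance = 0.01)
  expect_equal(unname(fr[["2"]]), 0.25, tolerance = 0.01)

  # degenerate frequencies pin the genotype
  freqs$p_POP1[] <- 0
  expect_true(all(draw_genotypes(freqs, spec) == 0L))
  freqs$p_POP1[] <- 1
  expect_true(all(draw_genotypes(freqs, spec) == 2L))
})

test_that("cohort allele frequencies converge to the generating values", {
  spec <- cohort_spec(2000, 400, seed = 31)
  co <- simulate_cohort(spec)
  af <- compute_af(co$genotypes)$af
  se <- sqrt(co$sites$af_alt * (1 - co$sites$af_alt) / (2 * 400))
  expect_true(mean(abs(af - co$sites$af_alt) <= 4 * se + 1e-9) > 0.99)
})

test_that("random-haplotype reference carries the derived allele at rate p", {
  spec <- cohort_spec(5000, 20, seed = 17)
  freqs <- draw_site_frequencies(spec)
  freqs$p[] <- 0.999
  ref <- make_reference(freqs, spec)
  expect_equal(mean(ref$sites$ref_is_derived), 0.999, tolerance = 0.003)
  # REF/ALT labels are relative to the emitted sequence
  expect_identical(substring(ref$sequence, ref$sites$pos, ref$sites$pos),
                   ref$sites$ref_allele)
  # frequencies re-expressed: where the reference carries the derived
  # allele, af_alt is the complement of p
  expect_equal(ref$sites$af_alt,
               ifelse(ref$sites$ref_is_derived, 1 - freqs$p, freqs$p))
})

test_that("all-ancestral mode never puts the derived allele in the reference", {
  spec <- cohort_spec(500, 20, seed = 17, ref_mode = "all-ancestral")
  ref <- make_reference(draw_site_frequencies(spec), spec)
  expect_false(any(ref$sites$ref_is_derived))
})

test_that("identical specs give bit-identical VCF and FASTA artifacts", {
  spec <- cohort_spec(200, 25, n_subpops = 2, fst = 0.05, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(spec), d1)
  write_cohort(simulate_cohort(spec), d2)
  for (f in c("cohort.vcf", "reference.fa", "populations.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("per-individual homozygous-variant rate matches E[p(1-p)] = 1/6", {
  # uniform SFS + random-haplotype reference: a diploid disagrees
  # homozygously with the reference with per-site probability p(1-p)
  spec <- cohort_spec(20000, 40, seed = 55)
  co <- simulate_cohort(spec)
  rate <- mean(co$genotypes == 2L)
  # dominant noise: Var(p(1-p)) = 1/180 over 20000 sites -> sd ~ 5e-4
  expect_lt(abs(rate - 1 / 6), 0.01)
})
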