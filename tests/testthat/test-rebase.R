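test_that("dosage re-projection relabels alleles and is an involution", {
  expect_equal(reproject_dosage(c(0L, 1L, 2L, NA), TRUE), c(2L, 1L, 0L, NA))
  expect_equal(reproject_dosage(c(0L, 1L, 2L), FALSE), c(0L, 1L, 2L))
  d <- c(0L, 1L, 2L, NA, 2L)
  sw <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(reproject_dosage(reproject_dosage(d, sw), sw), d)
})

test_that("calls enumerate correctly on the 5-site toy", {
  co <- toy_cohort() # S0001: dosages 0,1,2,2,1; swaps F,F,T,F,T
  cons <- build_consensus(co, af_source = "sites")
  vc <- call_variants(co, cons, samples = "S0001")
  expect_equal(vc$summary$n_hom, 1) # site 4 only (site 3 re-projects 2 -> 0)
  expect_equal(vc$summary$n_het, 2) # sites 2 and 5
  expect_setequal(vc$calls$pos, co$sites$pos[c(2, 4, 5)])
  # the recorded AF is the frequency of the carried non-reference allele
  expect_equal(sort(vc$calls$called_af), sort(c(0.3, 0.4, 0.2)))

  # a reference-identical genome calls nothing
  vc2 <- call_variants(co, reference_scope(co), samples = "S0002")
  expect_equal(vc2$summary$n_hom + vc2$summary$n_het, 0)
})

test_that("missing dosages never become calls", {
  co <- toy_cohort()
  co$genotypes[3, "S0001"] <- NA # swapped site: would otherwise re-project
  cons <- build_consensus(co, af_source = "sites")
  vc <- call_variants(co, cons, samples = "S0001")
  expect_equal(vc$summary$n_hom, 1)
  expect_false(any(vc$calls$pos == co$sites$pos[3]))
})

test_that("every call against a consensus has called-allele AF <= 0.5", {
  co <- simulate_cohort(cohort_spec(1500, 80, seed = 19))
  vc <- call_variants(co, build_consensus(co))
  expect_lte(max(vc$calls$called_af), 0.5)
  zf <- zygosity_af_fractions(vc)
  expect_equal(zf$frac_af_above_half, c(0, 0))
})

test_that("scope/site-list mismatches are hard errors", {
  co <- simulate_cohort(cohort_spec(50, 10, seed = 2))
  other <- simulate_cohort(cohort_spec(50, 10, seed = 3))
  expect_error(call_variants(co, build_consensus(other)), "site list")
  expect_error(call_variants(co, build_consensus(co), samples = "nope"),
               "not in the cohort")
})

test_that("expected_hom_rate matches its closed forms", {
  expect_equal(expected_hom_rate(0.5, "consensus"), 0.25)
  expect_equal(expected_hom_rate(0.9, "fixed-ref"), 0.81)
  expect_equal(expected_hom_rate(0.9, "consensus"), 0.01)
  expect_equal(expected_hom_rate(0.9, "random-haplotype"), 0.09)
  # uniform-SFS averages: 1/6 vs random haplotype, 1/12 vs consensus
  int <- function(model) {
    stats::integrate(function(p) expected_hom_rate(p, model), 0, 1)$value
  }
  expect_equal(int("random-haplotype"), 1 / 6, tolerance = 1e-6)
  expect_equal(int("consensus"), 1 / 12, tolerance = 1e-6)
})

test_that("genotype bookkeeping equals brute-force sequence comparison", {
  for (s in 1:10) {
    spec <- cohort_spec(n_sites = 30, n_samples = 4,
                        n_subpops = sample(1:2, 1), fst = 0.1,
                        chrom_length = 120, seed = 500 + s)
    co <- simulate_cohort(spec)
    cons <- build_consensus(co)
    for (smp in co$samples$sample) {
      book <- call_variants(co, cons, samples = smp, keep_calls = FALSE)$summary
      brute <- brute_force_counts(co, cons$sequence, smp)
      expect_equal(book$n_hom, unname(brute["n_hom"]))
      expect_equal(book$n_het, unname(brute["n_het"]))
    }
  }
})

test_that("population-matched and mean modes both summarise per sample", {
  co <- simulate_cohort(cohort_spec(600, 60, n_subpops = 3, fst = 0.15, seed = 33))
  consensuses <- lapply(setNames(nm = c("POP1", "POP2", "POP3")),
                        function(pp) build_consensus(co, pp))
  matched <- matched_population_calls(co, consensuses, mode = "matched")
  expect_equal(sort(matched$summary$sample), sort(co$samples$sample))
  expect_equal(unique(matched$summary$scope), "population-matched")
  avg <- matched_population_calls(co, consensuses, mode = "mean")
  expect_equal(nrow(avg$summary), 60)
  # averaging over mismatched consensuses can only do worse on average
  expect_lte(mean(matched$summary$n_hom), mean(avg$summary$n_hom))
  expect_error(matched_population_calls(co, consensuses["POP1"]),
               "No consensus supplied")
})
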