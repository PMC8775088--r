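quiet_opts()

test_that("cohort_spec validates its inputs", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(centers = "ONLY"), "2 distinct")
  expect_error(cohort_spec(center_error_rates = c(BCM = 2, BGI = 0, BI = 0, WUGSC = 0)),
               "\\[0,1\\]")
  expect_error(cohort_spec(center_error_rates = c(BCM = 0.9, BGI = 0, BI = 0, WUGSC = 0)),
               "error_recurrence")
  w <- matrix(1, 4, 4)
  expect_error(cohort_spec(center_assignment_weights = w), "sum to 1")
  expect_error(cohort_spec(n_variants = 0), "positive integer")
})

test_that("generation is deterministic and error-free when e_c = 0", {
  spec <- cohort_spec(n_populations = 2, samples_per_pop = 30,
                      n_variants = 400, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$genotypes$variants, b$genotypes$variants)
  expect_identical(a$metadata, b$metadata)
  expect_identical(sum(a$truth$n_flips), 0)
  expect_identical(nrow(a$truth$flips), 0L)
  expect_identical(length(a$truth$error_created), 0L)
})

test_that("AC equals the sum of ALT copies for every variant", {
  spec <- cohort_spec(n_populations = 2, samples_per_pop = 25, n_variants = 500,
                      center_error_rates = c(BCM = 0.01, BGI = 0.003, BI = 0,
                                             WUGSC = 0.005), seed = 5)
  co <- generate_cohort(spec)
  expect_identical(co$genotypes$variants$ac,
                   as.integer(colSums(co$genotypes$geno)))
  expect_true(all(co$genotypes$variants$ac >= 1L))
  expect_true(all(co$genotypes$variants$ac < 2L * nrow(co$genotypes$geno)))
})

test_that("independent-mode flip rate matches its binomial expectation", {
  # one noisy center at e_c = 0.01, independent per-genotype flips
  spec <- cohort_spec(n_populations = 1, n_continents = 1, samples_per_pop = 200,
                      n_variants = 5000, error_recurrence = 0,
                      center_error_rates = c(BCM = 0.01, BGI = 0, BI = 0,
                                             WUGSC = 0), seed = 21)
  co <- generate_cohort(spec)
  flips <- co$truth$n_flips[["BCM"]]
  eligible <- co$truth$n_eligible[["BCM"]]
  rate <- flips / eligible
  tol <- 3 * sqrt(0.01 * 0.99 / eligible)
  expect_lt(abs(rate - 0.01), tol)
  expect_identical(unname(co$truth$n_flips[c("BGI", "BI", "WUGSC")]), rep(0, 3))
})

test_that("recurrent mode preserves the marginal flip rate", {
  spec <- cohort_spec(n_populations = 1, n_continents = 1, samples_per_pop = 200,
                      n_variants = 5000, error_recurrence = 0.5,
                      center_error_rates = c(BCM = 0.01, BGI = 0, BI = 0,
                                             WUGSC = 0), seed = 22)
  co <- generate_cohort(spec)
  rate <- co$truth$n_flips[["BCM"]] / co$truth$n_eligible[["BCM"]]
  # site-level recurrence overdisperses the flip count; allow a loose band
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("per-center singleton counts are exchangeable without errors", {
  # Kruskal-Wallis across centers should reject at alpha = 0.01 in <= 5% of
  # seeded replicates when no center-specific error process exists
  n_rej <- 0L
  for (s in 1:100) {
    spec <- cohort_spec(n_populations = 1, n_continents = 1,
                        samples_per_pop = 60, n_variants = 300, seed = s)
    co <- generate_cohort(spec)
    counts <- count_singletons(co$genotypes)
    kw <- stats::kruskal.test(counts, factor(co$metadata$center))
    if (is.finite(kw$p.value) && kw$p.value < 0.01) n_rej <- n_rej + 1L
  }
  expect_lte(n_rej, 5L)
})

test_that("per-center singleton totals are monotone in the error rate", {
  rates <- c(0, 0.001, 0.005, 0.01)
  means <- sapply(rates, function(e) {
    mean(sapply(1:10, function(s) {
      spec <- cohort_spec(n_populations = 1, n_continents = 1,
                          samples_per_pop = 60, n_variants = 1000,
                          error_recurrence = 0,
                          center_error_rates = c(BCM = e, BGI = 0, BI = 0,
                                                 WUGSC = 0),
                          seed = 100 + s)
      co <- generate_cohort(spec)
      sum(count_singletons(co$genotypes)[co$metadata$center == "BCM"])
    }))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("the Sprime generator honours its fraction and determinism", {
  spec <- cohort_spec(n_populations = 2, samples_per_pop = 20,
                      n_variants = 200, seed = 3)
  co <- generate_cohort(spec)
  expect_identical(nrow(generate_sprime_table(co, 0, seed = 1)), 0L)
  full <- generate_sprime_table(co, 1, seed = 1)
  npop <- length(unique(co$metadata$pop))
  expect_identical(nrow(full), nrow(co$genotypes$variants) * npop)
  expect_identical(anyDuplicated(paste(full$POS, full$POP)), 0L)
  expect_identical(generate_sprime_table(co, 0.3, seed = 9),
                   generate_sprime_table(co, 0.3, seed = 9))
  expect_error(generate_sprime_table(co, 1.5), "\\[0,1\\]")
})

test_that("count simulator recovers its nesting structure and determinism", {
  ct <- simulate_count_table(n_samples = 120, seed = 8)
  expect_s3_class(ct, "count_table")
  expect_identical(ct, simulate_count_table(n_samples = 120, seed = 8))
  expect_true(all(ct$n_singletons > 0))
  nest <- unique(ct[, c("pop", "super_pop")])
  expect_identical(anyDuplicated(nest$pop), 0L)
})
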