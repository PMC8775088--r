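quiet_opts()

test_that("chi-square and inertia identities hold on random tables", {
  set.seed(11)
  for (i in 1:20) {
    tab <- matrix(rpois(26 * 7, lambda = 20) + 1, 26, 7,
                  dimnames = list(paste0("P", 1:26), paste0("C", 1:7)))
    ca <- correspondence_analysis(tab)
    expect_equal(ca$chisq, chisq_oracle(tab), tolerance = 1e-9)
    expect_equal(ca$total_inertia, ca$chisq / sum(tab), tolerance = 1e-9)
  }
})

test_that("independence tables give zero chi-square and zero inertia", {
  tab <- outer(c(10, 20, 30), c(5, 10, 15, 20))
  ca <- correspondence_analysis(tab)
  expect_equal(ca$chisq, 0, tolerance = 1e-9)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
})

test_that("a 2x2 table has one CA dimension carrying all the inertia", {
  tab <- matrix(c(30, 10, 5, 25), 2, dimnames = list(c("a", "b"), c("x", "y")))
  ca <- correspondence_analysis(tab)
  expect_identical(ca$df, 1L)
  expect_length(ca$inertia, 1L)
  expect_equal(ca$inertia[1], ca$chisq / sum(tab), tolerance = 1e-12)
  expect_identical(ncol(ca$row_coords), 1L)
})

test_that("CA principal coordinates agree with vegan's decomposition", {
  skip_if_not_installed("vegan")
  set.seed(21)
  tab <- matrix(rpois(8 * 4, 30) + 1, 8, 4,
                dimnames = list(paste0("P", 1:8), paste0("C", 1:4)))
  ca <- correspondence_analysis(tab, n_dims = 3)
  cca <- vegan::cca(as.data.frame(tab))
  expect_equal(unname(ca$inertia[1:3]), unname(cca$CA$eig[1:3]),
               tolerance = 1e-8)
  # coordinates match up to per-dimension sign
  sc <- vegan::scores(cca, display = "sites", choices = 1:3, scaling = 1)
  for (d in 1:3) {
    expect_equal(abs(unname(ca$row_coords[, d])), abs(unname(sc[, d])),
                 tolerance = 1e-6)
  }
})

test_that("zero margins are dropped with a warning", {
  tab <- matrix(c(5, 0, 3, 0, 0, 0, 2, 0, 4), 3)
  expect_warning(ca <- correspondence_analysis(tab), "empty")
  expect_identical(dim(ca$table), c(2L, 2L))
})

test_that("mixed model recovers a known center effect", {
  ct <- simulate_count_table(n_samples = 500,
                             center_effects = c(BI = 0.13), seed = 31)
  m <- fit_center_mixed_model(ct, "n_singletons")
  expect_s3_class(m, "center_lmm")
  expect_identical(m$reference, "BCM")
  est <- coef(m)[["BI"]]
  expect_lt(abs(est - 0.13), 0.3 * 0.13)
  expect_lt(m$lrt_p, 0.01)
  expect_gte(m$lrt, 0)
  expect_gt(m$logLik_full, m$logLik_null - 1e-8)
  expect_true(all(m$varcomp >= 0))
})

test_that("centers absent from some population are excluded from the contrast", {
  ct <- simulate_count_table(n_samples = 300, seed = 33)
  ct$center[ct$center == "WUGSC" & ct$pop != "POP01"] <- "BCM"
  # WUGSC now only sequences POP01 and must be dropped
  m <- fit_center_mixed_model(ct, "n_singletons")
  expect_false("WUGSC" %in% m$centers)
})

test_that("constant response yields zero variance and zero center effects", {
  ct <- simulate_count_table(n_samples = 200, seed = 35)
  ct$n_singletons <- 1000L
  m <- fit_center_mixed_model(ct, "n_singletons")
  expect_true(all(abs(coef(m)[-1]) < 1e-10))
  expect_true(all(m$varcomp < 1e-10))
  expect_equal(m$lrt, 0, tolerance = 1e-6)
})

test_that("zero counts follow the configured policy", {
  ct <- simulate_count_table(n_samples = 100, seed = 37)
  ct$n_singletons[1:3] <- 0L
  m_drop <- fit_center_mixed_model(ct, "n_singletons")
  expect_identical(m_drop$n, 97L)
  m_add <- fit_center_mixed_model(ct, "n_singletons", zero_policy = "add_one")
  expect_identical(m_add$n, 100L)
})

test_that("pairwise Wilcoxon matches the exact tail for separated groups", {
  ct <- data.frame(sample = sprintf("S%02d", 1:30),
                   pop = "POPA", super_pop = "EUR",
                   center = rep(c("A", "B", "C"), each = 10),
                   n_lof = c(1:10, 101:110, 1:10), stringsAsFactors = FALSE)
  m <- pairwise_wilcoxon(ct, "POPA", "n_lof")
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(sum(!is.na(m)), 3L)        # upper triangle only
  # A vs B completely separated, n = 10 each: exact two-sided tail
  expect_equal(m["A", "B"], separated_wilcox_p(10, 10), tolerance = 1e-12)
  # A vs C identical value multisets: no evidence of difference
  expect_gt(m["A", "C"], 0.9)
})

test_that("centers with fewer than two samples give undefined contrasts", {
  ct <- data.frame(sample = paste0("S", 1:11), pop = "POPA", super_pop = "EUR",
                   center = rep(c("A", "B", "C"), c(5, 5, 1)),
                   n_lof = rpois(11, 5), stringsAsFactors = FALSE)
  m <- pairwise_wilcoxon(ct, "POPA", "n_lof")
  expect_true(is.na(m["A", "C"]) && is.na(m["B", "C"]))
  expect_false(is.na(m["A", "B"]))
})
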