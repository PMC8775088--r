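quiet_opts()

test_that("LoF consensus requires all three predictors and no homozygote", {
  gm <- toy_gm()
  lof <- classify_lof(gm)
  # variant 7: (D,D,D), hets only -> LoF
  # variant 8: (D,D,D) but one hom-alt carrier -> excluded
  # variant 9: (D,D,B) -> excluded; non-coding variants never LoF
  expect_identical(lof, 7L)
  ben <- classify_benign(gm)
  expect_identical(ben, 10L)
  expect_length(intersect(lof, ben), 0L)
})

test_that("per-sample carrier counts match hand enumeration", {
  gm <- toy_gm()
  expect_identical(count_carriers_per_sample(gm, classify_lof(gm)),
                   c(S1 = 1L, S2 = 0L, S3 = 0L, S4 = 1L, S5 = 0L, S6 = 0L))
  expect_identical(count_carriers_per_sample(gm, integer(0)),
                   c(S1 = 0L, S2 = 0L, S3 = 0L, S4 = 0L, S5 = 0L, S6 = 0L))
})

test_that("singleton and derived-singleton rules follow AC and AA", {
  gm <- toy_gm()
  s <- count_singletons(gm)
  expect_identical(s, c(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 1L, S5 = 1L, S6 = 1L))
  # conservation: total singleton count equals number of AC = 1 variants
  expect_identical(sum(s), sum(gm$variants$ac == 1L))

  d <- count_derived_singletons(gm)
  # only variant 1 (AA = REF) is derived; AA in {., -, N} excluded;
  # AA = ALT means the ALT copy is ancestral; AA matching neither is dropped
  expect_identical(d, c(S1 = 1L, S2 = 0L, S3 = 0L, S4 = 0L, S5 = 0L, S6 = 0L))
  expect_true(all(d <= s))
})

test_that("introgressed-allele counts are population-specific and dosage-aware", {
  gm <- toy_gm()
  md <- toy_metadata()
  sprime <- data.frame(CHROM = "1", POS = c(700L, 1000L, 100L),
                       ALLELE = c("C", "T", "A"),
                       POP = c("POPA", "POPB", "POPA"),
                       stringsAsFactors = FALSE)
  n <- count_introgressed(gm, sprime, md)
  # v7 ALT in POPA: S1 het (+1); S4 het but POPB (0)
  # v10 ALT in POPB: S5 het (+1), S6 hom (+2)
  # v1 REF in POPA: S1 carries 1 REF copy, S2 and S3 carry 2 each
  expect_identical(n, c(S1 = 2L, S2 = 2L, S3 = 2L, S4 = 0L, S5 = 1L, S6 = 2L))
  expect_identical(count_introgressed(gm, NULL, md),
                   c(S1 = 0L, S2 = 0L, S3 = 0L, S4 = 0L, S5 = 0L, S6 = 0L))
})

test_that("the assembled count table carries metadata and all counters", {
  gm <- toy_gm()
  md <- toy_metadata()
  ct <- rare_event_counts(gm, md)
  expect_s3_class(ct, "count_table")
  expect_identical(ct$sample, paste0("S", 1:6))
  expect_identical(ct$center, md$center)
  expect_identical(ct$n_lof, c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_identical(ct$n_benign, c(1L, 0L, 0L, 0L, 1L, 1L))
  expect_true(all(ct$n_derived_singletons <= ct$n_singletons))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  back <- utils::read.delim(f)
  expect_identical(back$n_singletons, ct$n_singletons)
})

test_that("missing genotypes contribute nothing to any counter", {
  gm <- toy_gm()
  g <- gm$geno
  g[2, 2] <- NA  # S2's singleton becomes missing
  gm2 <- genotype_matrix(g, rownames(g), gm$variants, recompute_ac = TRUE)
  expect_identical(gm2$variants$ac[2], 0L)
  s <- count_singletons(gm2)
  expect_identical(unname(s[2]), 0L)
})

test_that("mean singleton counts per center rise with that center's error rate", {
  means <- sapply(c(0, 0.01), function(e) {
    mean(sapply(1:10, function(s) {
      co <- generate_cohort(cohort_spec(
        n_populations = 1, n_continents = 1, samples_per_pop = 50,
        n_variants = 800, error_recurrence = 0,
        center_error_rates = c(BCM = e, BGI = 0, BI = 0, WUGSC = 0),
        seed = 200 + s))
      mean(count_singletons(co$genotypes)[co$metadata$center == "BCM"])
    }))
  })
  expect_gt(means[2], means[1])
})
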