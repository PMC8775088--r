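quiet_opts()

test_that("theta matches the variance-components oracle on random tables", {
  set.seed(42)
  for (i in 1:200) {
    K <- sample(2:6, 1)
    n <- sample(2:10, 1)
    tb <- random_table(K, n)
    got <- weir_cockerham_fst(tb)
    want <- wc_oracle(tb)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("theta is 1 under complete fixation contrast and <= 0 without
           among-center variance", {
  fixed <- rbind(c(0, 0, 5), matrix(rep(c(5, 0, 0), 3), 3, byrow = TRUE))
  colnames(fixed) <- c("n_hom_ref", "n_het", "n_hom_alt")
  expect_equal(weir_cockerham_fst(fixed), 1)

  same <- matrix(rep(c(2, 2, 1), 4), 4, byrow = TRUE,
                 dimnames = list(NULL, c("n_hom_ref", "n_het", "n_hom_alt")))
  expect_lte(weir_cockerham_fst(same), 0)

  mono <- matrix(rep(c(5, 0, 0), 3), 3, byrow = TRUE,
                 dimnames = list(NULL, c("n_hom_ref", "n_het", "n_hom_alt")))
  expect_true(is.na(weir_cockerham_fst(mono)))
})

test_that("theta is invariant under center reordering", {
  set.seed(7)
  for (i in 1:50) {
    tb <- random_table(4, 6)
    th <- weir_cockerham_fst(tb)
    perm <- tb[sample(4), ]
    if (is.na(th)) expect_true(is.na(weir_cockerham_fst(perm)))
    else expect_equal(weir_cockerham_fst(perm), th, tolerance = 1e-12)
  }
})

test_that("design MAF follows the allele-copies formula", {
  tb <- function(a) {
    # K = 4 centers, n = 5: convert per-center ALT-copy counts to genotypes
    t(sapply(a, function(ac) c(n_hom_ref = 5 - ceiling(ac / 2),
                               n_het = ac %% 2, n_hom_alt = ac %/% 2)))
  }
  m <- compute_maf_p(tb(c(1, 0, 0, 0)))
  expect_equal(m$p_ap, 1 / 40)
  expect_equal(m$maf_p, 0.025)
  m2 <- compute_maf_p(tb(c(10, 10, 10, 10)))
  expect_equal(m2$p_ap, 1)
  expect_equal(m2$maf_p, 0)
  m3 <- compute_maf_p(tb(c(5, 5, 5, 5)))
  expect_equal(m3$maf_p, 0.5)
})

test_that("packed configuration fills centers sequentially", {
  # maf 0.25 at K = 4, n = 5: 10 minor copies exactly fix center 1
  cfg <- max_fst_config(0.25, 4, 5)
  expect_identical(unname(cfg[1, ]), c(0L, 0L, 5L))
  expect_identical(unname(cfg[2, ]), c(5L, 0L, 0L))
  # odd remainder becomes one het in the next center
  cfg2 <- max_fst_config(11 / 40, 4, 5)
  expect_identical(unname(cfg2[2, ]), c(4L, 1L, 0L))
  # maf 0.5 at K = 2: two centers fixed for opposite alleles
  expect_equal(max_fst_given_maf(0.5, 2, 5), 1)
  expect_true(is.na(max_fst_given_maf(0.001, 2, 2)))  # rounds to zero copies
})

test_that("the packed configuration maximizes theta at every achievable MAF", {
  # exhaustive enumeration of all genotype allocations for K = 2, n = 2
  comps <- expand.grid(h0 = 0:2, h1 = 0:2, h2 = 0:2)
  comps <- comps[rowSums(comps) == 2, ]
  best <- list()
  for (i in seq_len(nrow(comps))) for (j in seq_len(nrow(comps))) {
    tb <- rbind(as.numeric(comps[i, ]), as.numeric(comps[j, ]))
    colnames(tb) <- c("n_hom_ref", "n_het", "n_hom_alt")
    m <- sum(tb[, 2] + 2 * tb[, 3])
    maf <- min(m, 8 - m) / 8
    if (maf == 0) next
    th <- weir_cockerham_fst(tb)
    if (is.na(th)) next
    key <- as.character(maf)
    best[[key]] <- max(best[[key]] %||% -Inf, th)
  }
  for (key in names(best)) {
    expect_equal(max_fst_given_maf(as.numeric(key), 2, 2), best[[key]],
                 tolerance = 1e-12)
  }
})

test_that("the packed configuration self-normalizes to scaled Fst 1", {
  for (K in c(2, 4, 6)) for (n in c(2, 5)) {
    grid <- seq_len(K * n) / (2 * K * n)  # achievable MAFs
    for (maf in grid) {
      fmax <- max_fst_given_maf(maf, K, n)
      # at the rarest MAFs of tiny designs the maximum itself can be <= 0,
      # where scaled Fst is undefined by construction
      if (!is.na(fmax) && fmax > 0) expect_equal(scale_fst(fmax, fmax), 1)
    }
  }
  # the pipeline's own design (K = 4 centers, n = 5) is non-degenerate at
  # every achievable MAF
  grid <- seq_len(20) / 40
  expect_true(all(sapply(grid, max_fst_given_maf, K = 4, n = 5) > 0))
})

test_that("scaling floors negatives and clamps at one", {
  expect_equal(scale_fst(-0.2, 0.5), 0)
  expect_equal(scale_fst(0.25, 0.5), 0.5)
  expect_equal(scale_fst(0.7, 0.5), 1)
  expect_true(is.na(scale_fst(0.3, NA)))
})

test_that("subsampling enforces the equal-n threshold and is seeded", {
  md <- data.frame(
    sample = sprintf("S%03d", 1:62),
    pop = "POPA", super_pop = "EUR",
    center = rep(c("A", "B", "C", "D"), c(30, 25, 5, 2)),
    stringsAsFactors = FALSE)
  sub <- subsample_centers(md, "POPA", n = 5, seed = 3)
  expect_identical(sort(unique(sub$center)), c("A", "B", "C"))
  expect_identical(attr(sub, "excluded_centers"), "D")
  expect_true(all(table(sub$center) == 5))
  expect_identical(sub, subsample_centers(md, "POPA", n = 5, seed = 3))
  md2 <- md[md$center %in% c("A", "D"), ]
  expect_error(subsample_centers(md2, "POPA", n = 5), "< 2 centers")
})

test_that("fst_scan drops monomorphic subsample sites and scales into [0,1]", {
  co <- generate_cohort(cohort_spec(
    n_populations = 1, n_continents = 1, samples_per_pop = 80,
    n_variants = 1500,
    center_error_rates = c(BCM = 0.01, BGI = 0, BI = 0, WUGSC = 0),
    seed = 17))
  sc <- fst_scan(co$genotypes, co$metadata, "POP01", n = 5, seed = 2)
  expect_s3_class(sc, "fst_scan")
  expect_gt(nrow(sc$records), 0)
  expect_true(all(sc$records$fst_scaled >= 0 & sc$records$fst_scaled <= 1))
  expect_true(all(sc$records$maf_p > 0 & sc$records$maf_p <= 0.5))
  expect_true(all(sc$records$fst_max > 0))
  # MAF grid of a 4-center, n = 5 design: multiples of 1/40
  expect_true(all(abs(sc$records$maf_p * 40 -
                        round(sc$records$maf_p * 40)) < 1e-12))
  sc2 <- fst_scan(co$genotypes, co$metadata, "POP01", n = 5, seed = 2)
  expect_identical(sc$records, sc2$records)
})

test_that("MAF summary computes per-MAF means, bins and Spearman rho", {
  rec <- data.frame(variant = paste0("1:", 1:6),
                    maf_p = c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3),
                    fst_raw = 0, fst_max = 1,
                    fst_scaled = c(0.9, 0.8, 0.5, 0.4, 0.2, 0.1),
                    maf_bin = c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3))
  s <- summarize_by_maf(rec, bin_width = 0.05)
  expect_equal(s$per_maf$mean_fst_scaled, c(0.85, 0.45, 0.15))
  expect_equal(s$rho, -1)

  rec$fst_scaled <- 0.5
  s2 <- summarize_by_maf(rec, bin_width = 0.05)
  expect_equal(s2$rho, 0)
  expect_true(is.na(s2$rho_p))
})

test_that("center-specific errors at rare sites drive rho negative", {
  co <- generate_cohort(cohort_spec(
    n_populations = 1, n_continents = 1, samples_per_pop = 150,
    n_variants = 4000,
    center_error_rates = c(BCM = 0.01, BGI = 0, BI = 0, WUGSC = 0),
    seed = 19))
  sc <- fst_scan(co$genotypes, co$metadata, "POP01", n = 5, seed = 4)
  s <- summarize_by_maf(sc)
  expect_lt(s$rho, 0)
})
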