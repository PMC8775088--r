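# Independent oracles and small builders used across the suite.
# The oracles deliberately take a different computational route from the
# package implementation they check.

# Weir & Cockerham (1984) theta via the ANOVA mean-squares route: treat every
# allele copy as an observation nested in individual nested in center, form
# the observed sums of squares directly, convert mean squares to variance
# components. Independent of the package's closed-form a/b/c implementation.
wc_oracle <- function(tb) {
  tb <- as.matrix(as.data.frame(tb)[, c("n_hom_ref", "n_het", "n_hom_alt")])
  r <- nrow(tb)
  n_i <- rowSums(tb)
  p_i <- (tb[, "n_het"] + 2 * tb[, "n_hom_alt"]) / (2 * n_i)
  ntot <- sum(n_i)
  pbar <- sum(n_i * p_i) / ntot

  # SS within individuals: a het contributes (0.5^2 + 0.5^2) = 0.5
  ssg <- sum(tb[, "n_het"]) * 0.5
  msg <- ssg / ntot
  # SS among individuals within centers: 2 * sum_i sum_j (xbar_ij - p_i)^2
  ssi <- 0
  for (i in seq_len(r)) {
    xbar <- rep(c(0, 0.5, 1), tb[i, ])
    ssi <- ssi + 2 * sum((xbar - p_i[i])^2)
  }
  msi <- ssi / (ntot - r)
  # SS among centers
  ssp <- 2 * sum(n_i * (p_i - pbar)^2)
  msp <- ssp / (r - 1)

  nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  s2_g <- msg
  s2_i <- (msi - msg) / 2
  s2_p <- (msp - msi) / (2 * nc)
  denom <- s2_p + s2_i + s2_g
  if (denom == 0) return(NA_real_)
  s2_p / denom
}

# random center-allele table: K centers, n diploid individuals each
random_table <- function(K, n) {
  t(vapply(seq_len(K), function(i) {
    counts <- as.vector(stats::rmultinom(1, n, prob = stats::runif(3)))
    counts
  }, numeric(3))) |>
    (\(m) {colnames(m) <- c("n_hom_ref", "n_het", "n_hom_alt"); m})()
}

# Pearson chi-square computed straight from the textbook formula
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exact two-sided rank-sum tail probability for completely separated groups
separated_wilcox_p <- function(n1, n2) 2 / choose(n1 + n2, n1)

# small genotype_matrix built in code
toy_gm <- function() {
  geno <- rbind(
    S1 = c(1, 0, 0, 0, 0, 0, 1, 0, 0, 1),
    S2 = c(0, 1, 0, 0, 0, 0, 0, 2, 0, 0),
    S3 = c(0, 0, 1, 0, 0, 0, 0, 1, 1, 0),
    S4 = c(0, 0, 0, 1, 0, 0, 1, 0, 0, 0),
    S5 = c(0, 0, 0, 0, 1, 0, 0, 0, 1, 1),
    S6 = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 2))
  variants <- data.frame(
    chrom = "1", pos = (1:10) * 100,
    ref = c("A", "C", "G", "T", "A", "A", "G", "C", "T", "A"),
    alt = c("G", "T", "A", "C", "G", "C", "C", "G", "A", "T"),
    aa  = c("A", ".", "-", "N", "G", "T", "G", "C", "T", "A"),
    p1 = c(rep("absent", 6), "D", "D", "D", "B"),
    p2 = c(rep("absent", 6), "D", "D", "D", "B"),
    p3 = c(rep("absent", 6), "D", "D", "B", "B"),
    stringsAsFactors = FALSE)
  genotype_matrix(geno, rownames(geno), variants, recompute_ac = TRUE)
}

toy_metadata <- function() {
  data.frame(sample = paste0("S", 1:6),
             pop = rep(c("POPA", "POPB"), each = 3),
             super_pop = "EUR",
             center = c("CTRX", "CTRX", "CTRY", "CTRX", "CTRY", "CTRY"),
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "batchfst")

quiet_opts <- function() options(batchfst.quiet = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
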