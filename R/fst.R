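# Per-SNV between-center Weir & Cockerham (1984) Fst with equal-n
# subsampling, MAF computation over the subsampled design, normalization by
# the maximum Fst attainable at that MAF, MAF binning and Spearman summary.

# Vectorized single-locus Weir & Cockerham theta over many SNVs.
# p, h: V x K matrices of per-center ALT-allele frequency and observed
# heterozygote proportion; nmat: V x K matrix of genotyped individuals per
# center. Returns the V-vector theta = a / (a + b + c), NA where undefined.
wc_theta_core <- function(p, h, nmat) {
  r <- ncol(p)
  nbar <- rowSums(nmat) / r
  nc <- (r * nbar - rowSums(nmat^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(nmat * p) / (r * nbar)
  s2 <- rowSums(nmat * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- a / denom
  theta[!is.finite(theta) | denom == 0 | nbar <= 1 |
          rowSums(nmat == 0) > 0] <- NA_real_
  theta
}

#' Weir & Cockerham Fst for one SNV from per-center genotype counts
#'
#' Computes the Weir & Cockerham (1984) single-locus estimator
#' `theta = a / (a + b + c)` from the among-center (a), among-individual (b)
#' and within-individual (c) variance components, using per-center allele
#' frequencies and observed heterozygote proportions. The estimate can be
#' negative; sites monomorphic in the table (no variance in any component)
#' return `NA` and are excluded downstream.
#'
#' @param table matrix or data frame with one row per center and columns
#'   `n_hom_ref`, `n_het`, `n_hom_alt` (a center-allele table); centers may
#'   have unequal sizes.
#' @return the theta estimate (scalar; `NA` when undefined).
#' @export
weir_cockerham_fst <- function(table) {
  tb <- as.matrix(as.data.frame(table)[, c("n_hom_ref", "n_het", "n_hom_alt")])
  abort_if(nrow(tb) < 2L, "need >= 2 centers")
  abort_if(any(tb < 0) || any(tb != floor(tb)), "genotype counts must be non-negative integers")
  n <- rowSums(tb)
  abort_if(any(n == 0), "every center needs >= 1 genotyped individual")
  p <- (tb[, "n_het"] + 2 * tb[, "n_hom_alt"]) / (2 * n)
  h <- tb[, "n_het"] / n
  wc_theta_core(matrix(p, 1L), matrix(h, 1L), matrix(n, 1L))
}

#' Design-wide allele frequency and MAF of a center-allele table
#'
#' `p_ap = sum_c a_c / (K * 2n)`: the ALT-allele frequency over the
#' equal-n subsampled design, where `a_c` is the ALT-copy count at center `c`
#' and `2n` the allele copies sampled per center; `maf_p = min(p_ap, 1 -
#' p_ap)`. With unequal center sizes the denominator is the total number of
#' sampled allele copies, to which `K * 2n` reduces under the equal-n design.
#'
#' @param table a center-allele table as in [weir_cockerham_fst()].
#' @return list with `p_ap` and `maf_p`.
#' @export
compute_maf_p <- function(table) {
  tb <- as.matrix(as.data.frame(table)[, c("n_hom_ref", "n_het", "n_hom_alt")])
  a_c <- tb[, "n_het"] + 2 * tb[, "n_hom_alt"]
  copies <- 2 * rowSums(tb)
  p_ap <- sum(a_c) / sum(copies)
  list(p_ap = p_ap, maf_p = min(p_ap, 1 - p_ap))
}

#' Maximally differentiated genotype configuration at a given MAF
#'
#' The largest between-center differentiation attainable at minor allele
#' frequency `maf_p` under the equal-n design is reached when the
#' `m = round(K * 2n * maf_p)` minor-allele copies are packed into as few
#' centers as possible, each active center carrying its copies in as many
#' heterozygotes as its `n` individuals allow (`t` copies become `t` hets
#' when `t <= n`, else `2n - t` hets plus `t - n` homozygotes), with all
#' remaining centers fixed for the major allele. Spreading the copies as
#' heterozygotes maximizes the estimator: clustering them into homozygotes
#' inflates the among-individual (within-center) variance component the way
#' inbreeding would, which the Weir-Cockerham estimator distinguishes from
#' among-center differentiation — exhaustive enumeration over all genotype
#' allocations at small designs confirms the heterozygote-packed
#' configuration attains the maximum at every achievable MAF.
#' `max_fst_config()` returns that genotype table; `max_fst_given_maf()`
#' evaluates [weir_cockerham_fst()] on it. At the very rarest MAFs of tiny
#' designs the maximum itself can be zero or negative; the scaled Fst is
#' undefined there and such sites are dropped downstream.
#'
#' @param maf_p minor allele frequency in (0, 0.5].
#' @param K number of centers.
#' @param n diploid individuals per center.
#' @return `max_fst_config()`: a K x 3 center-allele table;
#'   `max_fst_given_maf()`: the maximum theta (`NA` when `maf_p` rounds to
#'   zero copies).
#' @export
max_fst_config <- function(maf_p, K, n) {
  abort_if(!is.numeric(maf_p) || maf_p < 0 || maf_p > 0.5,
           "maf_p must lie in [0, 0.5]")
  n <- as.integer(n); K <- as.integer(K)
  m <- as.integer(round(K * 2L * n * maf_p))
  tb <- matrix(0L, K, 3L, dimnames = list(NULL, c("n_hom_ref", "n_het", "n_hom_alt")))
  tb[, "n_hom_ref"] <- n
  for (c_i in seq_len(K)) {
    if (m <= 0L) break
    take <- min(m, 2L * n)
    het <- if (take <= n) take else 2L * n - take
    homs <- (take - het) %/% 2L
    tb[c_i, ] <- c(n - homs - het, het, homs)
    m <- m - take
  }
  tb
}

#' @rdname max_fst_config
#' @export
max_fst_given_maf <- function(maf_p, K, n) {
  if (round(K * 2 * n * maf_p) < 1) return(NA_real_)
  weir_cockerham_fst(max_fst_config(maf_p, K, n))
}

#' Scale an Fst estimate by its MAF-conditional maximum
#'
#' Negative Weir-Cockerham estimates are floored at 0 and the ratio is
#' clamped to at most 1, so scaled values are comparable in `[0, 1]` across
#' minor allele frequencies.
#'
#' @param fst_raw raw theta estimate(s).
#' @param fst_max maximum theta at the site's MAF ([max_fst_given_maf()]).
#' @return scaled Fst in `[0, 1]`; `NA` where `fst_max` is undefined or
#'   non-positive.
#' @export
scale_fst <- function(fst_raw, fst_max) {
  out <- pmin(pmax(fst_raw, 0) / fst_max, 1)
  out[!is.finite(fst_max) | fst_max <= 0] <- NA_real_
  out
}

#' Draw an equal-n per-center subsample within one population
#'
#' Selects, uniformly without replacement, exactly `n` individuals per
#' sequencing center among the population's centers having at least `n`
#' individuals; smaller centers are excluded and reported. The equal-n design
#' removes center sample-size as a confounder of the between-center Fst.
#'
#' @param metadata sample metadata (`sample`, `pop`, `center`).
#' @param population population label to subsample within.
#' @param n individuals per center (default 5).
#' @param seed RNG seed.
#' @return data frame of the subsampled rows of `metadata` (class keeps an
#'   `excluded_centers` attribute).
#' @export
subsample_centers <- function(metadata, population, n = 5L, seed = 1L) {
  md <- metadata[metadata$pop == population, , drop = FALSE]
  abort_if(nrow(md) == 0L, paste0("no samples in population ", population))
  sizes <- table(md$center)
  eligible <- names(sizes)[sizes >= n]
  excluded <- names(sizes)[sizes < n]
  if (length(excluded))
    bf_msg("population ", population, ": excluding center(s) with < ", n,
           " samples: ", paste(excluded, collapse = ", "))
  if (length(eligible) < 2L)
    stop("population ", population,
         " has < 2 centers with >= ", n, " samples; skipped", call. = FALSE)
  with_seed(seed, {
    take <- unlist(lapply(eligible, function(cc) {
      ids <- md$sample[md$center == cc]
      sample(ids, n)
    }))
    out <- md[match(take, md$sample), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "excluded_centers") <- excluded
    out
  })
}

# Per-center genotype-class counts for a pool of samples.
# G: pool x V genotype codes; A: pool x K 0/1 center-assignment matrix.
# Returns V x K matrices of het counts, ALT-copy counts and genotyped n.
center_counts <- function(G, A) {
  na <- is.na(G)
  G0 <- G; G0[na] <- 0L
  het <- t(crossprod(A, (G0 == 1L) & !na))
  alt <- t(crossprod(A, G0))
  nmat <- t(crossprod(A, !na))
  list(het = het, alt = alt, nmat = nmat)
}

# theta for every SNV given a pool genotype matrix and a center assignment
theta_for_assignment <- function(G, A) {
  cc <- center_counts(G, A)
  p <- cc$alt / (2 * cc$nmat)
  h <- cc$het / cc$nmat
  p[cc$nmat == 0] <- 0; h[cc$nmat == 0] <- 0
  wc_theta_core(p, h, cc$nmat)
}

#' Per-SNV between-center scaled-Fst scan within a population
#'
#' The package's core statistic. Within the given population, `n` individuals
#' are drawn per eligible sequencing center ([subsample_centers()]); for
#' every SNV polymorphic in the subsample the Weir-Cockerham theta among
#' centers, the design MAF (`maf_p`), the maximum theta attainable at that
#' MAF and the scaled Fst (`fst_scaled = max(theta, 0) / fst_max`, clamped to
#' `[0, 1]`) are computed, together with a 0.05-wide MAF-bin index. Sites
#' monomorphic in the subsample are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param metadata sample metadata.
#' @param population population label.
#' @param n individuals subsampled per center.
#' @param bin_width MAF bin width for summaries (default 0.05).
#' @param seed RNG seed for the subsample.
#' @return an object of class `fst_scan`: list with `records` (one row per
#'   retained SNV: `variant`, `maf_p`, `fst_raw`, `fst_max`, `fst_scaled`,
#'   `maf_bin`), the subsample (`pool`), `population`, `centers`, `n`,
#'   `bin_width`, `seed`.
#' @seealso [summarize_by_maf()], [fst_null()]
#' @export
fst_scan <- function(gm, metadata, population, n = 5L, bin_width = 0.05,
                     seed = 1L) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  pool <- subsample_centers(metadata, population, n = n, seed = seed)
  abort_if(!all(pool$sample %in% rownames(gm$geno)),
           "subsampled individuals missing from the genotype matrix")
  centers <- sort(unique(pool$center))
  K <- length(centers)
  G <- gm$geno[pool$sample, , drop = FALSE]
  A <- outer(pool$center, centers, "==") * 1L

  theta <- theta_for_assignment(G, A)
  cc <- center_counts(G, A)
  copies <- rowSums(2 * cc$nmat)
  alt_total <- rowSums(cc$alt)
  # minor-copy count first, then divide: keeps mirrored frequencies on the
  # same exact MAF grid value (1 - x is not exact in floating point)
  maf <- pmin(alt_total, copies - alt_total) / copies

  keep <- !is.na(theta) & maf > 0
  umaf <- sort(unique(maf[keep]))
  fmax_lookup <- vapply(umaf, max_fst_given_maf, numeric(1L), K = K, n = n)
  fst_max <- fmax_lookup[match(maf, umaf)]
  scaled <- scale_fst(theta, fst_max)
  keep <- keep & !is.na(scaled)

  nb <- ceiling(0.5 / bin_width)
  bin <- pmin(floor(maf / bin_width), nb - 1L)

  records <- data.frame(
    variant = variant_keys(gm)[keep],
    maf_p = maf[keep], fst_raw = theta[keep], fst_max = fst_max[keep],
    fst_scaled = scaled[keep],
    maf_bin = bin_width * bin[keep],
    stringsAsFactors = FALSE)
  rownames(records) <- NULL

  structure(list(records = records, pool = pool, population = population,
                 centers = centers, n = as.integer(n),
                 bin_width = bin_width, seed = seed,
                 n_dropped = sum(!keep)),
            class = "fst_scan")
}

#' Summarize a scaled-Fst scan over minor allele frequency
#'
#' Averages the scaled Fst over all SNVs sharing the same `maf_p` (the MAF
#' values of an equal-n design are discrete), computes the Spearman rank
#' correlation between the distinct MAF values and their mean scaled Fst
#' (mid-rank ties convention; a batch effect concentrated in rare variants
#' shows as a strongly negative rho), and additionally averages per MAF bin
#' for plotting. If the per-MAF means have zero variance the correlation is
#' reported as 0 with an undefined p-value.
#'
#' @param x an `fst_scan` or its `records` data frame.
#' @param bin_width MAF bin width; defaults to the scan's.
#' @return list of class `fst_maf_summary`: `per_maf`, `per_bin` data frames,
#'   `rho`, `rho_p`.
#' @export
summarize_by_maf <- function(x, bin_width = NULL) {
  records <- if (inherits(x, "fst_scan")) x$records else x
  if (is.null(bin_width))
    bin_width <- if (inherits(x, "fst_scan")) x$bin_width else 0.05
  abort_if(nrow(records) == 0L, "no Fst records to summarize")
  per_maf <- stats::aggregate(fst_scaled ~ maf_p, records, mean)
  per_maf$n_snvs <- as.vector(table(records$maf_p))
  names(per_maf)[2L] <- "mean_fst_scaled"

  nb <- ceiling(0.5 / bin_width)
  bin <- bin_width * pmin(floor(records$maf_p / bin_width), nb - 1L)
  per_bin <- stats::aggregate(records$fst_scaled, list(maf_bin = bin), mean)
  names(per_bin)[2L] <- "mean_fst_scaled"
  per_bin$n_snvs <- as.vector(table(bin))

  if (nrow(per_maf) < 2L) {
    rho <- NA_real_; rho_p <- NA_real_
  } else if (stats::sd(per_maf$mean_fst_scaled) == 0) {
    rho <- 0; rho_p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(per_maf$maf_p, per_maf$mean_fst_scaled,
                      method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  structure(list(per_maf = per_maf, per_bin = per_bin,
                 rho = rho, rho_p = rho_p),
            class = "fst_maf_summary")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf("Between-center scaled-Fst scan: population %s\n", x$population))
  cat(sprintf("  %d centers (%s), n = %d per center\n",
              length(x$centers), paste(x$centers, collapse = ", "), x$n))
  cat(sprintf("  %d SNVs retained (%d dropped as monomorphic in the subsample)\n",
              nrow(x$records), x$n_dropped))
  invisible(x)
}

#' @export
summary.fst_scan <- function(object, ...) summarize_by_maf(object)

#' @export
print.fst_maf_summary <- function(x, ...) {
  cat("Scaled Fst by minor allele frequency\n")
  print(x$per_bin, row.names = FALSE)
  cat(sprintf("Spearman rho(MAF, mean scaled Fst) = %.3f (p = %.3g)\n",
              x$rho, x$rho_p))
  invisible(x)
}

#' @export
plot.fst_scan <- function(x, log = TRUE, ...) {
  s <- summarize_by_maf(x)
  y <- s$per_bin$mean_fst_scaled
  if (log) y <- log10(pmax(y, 1e-6))
  graphics::plot(s$per_bin$maf_bin + x$bin_width / 2, y, type = "b", pch = 19,
                 xlab = "MAF bin",
                 ylab = if (log) "log10 mean scaled Fst" else "mean scaled Fst",
                 main = paste0("Population ", x$population), ...)
  invisible(x)
}

#' @rdname fst_scan
#' @param scan an `fst_scan`.
#' @param path output TSV path for the per-SNV records.
#' @export
write_fst_records <- function(scan, path) {
  utils::write.table(scan$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
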