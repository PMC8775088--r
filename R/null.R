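# Monte Carlo permutation null for the scaled-Fst MAF profile, and the
# observed-versus-null slope quantifying the sequencing-center batch effect.

#' Permute center labels within an equal-n subsample
#'
#' Randomly reassigns the center labels of a subsampled pool to the same
#' individuals, preserving exactly `n` labels per center. Population and
#' continent assignments are untouched. This is the exchangeability null:
#' any systematic between-center differentiation disappears under relabeling
#' while the allele frequencies (and hence each SNV's MAF category) stay
#' fixed.
#'
#' @param pool data frame from [subsample_centers()].
#' @param seed RNG seed.
#' @return the pool with its `center` column permuted.
#' @export
permute_centers <- function(pool, seed = 1L) {
  with_seed(seed, {
    pool$center <- pool$center[sample.int(nrow(pool))]
    pool
  })
}

#' Monte Carlo null profile and observed-vs-null slope for a scaled-Fst scan
#'
#' For each of `n_permutations` random reassignments of the subsampled
#' individuals to centers, recomputes the per-SNV scaled Fst and averages it
#' within MAF category; the null value of a category is the mean over
#' permutations (per-permutation values are retained for dispersion). The
#' batch effect is quantified by the ordinary least-squares fit (intercept
#' retained) of the observed category means on the null category means: a
#' slope of 1 indicates agreement with randomness, a slope substantially
#' above 1 an excess of between-center differentiation concentrated where
#' the null is smallest. Categories whose scaled Fst is constant under any
#' labeling (zero variance across permutations, e.g. the single-minor-copy
#' category) are excluded from the slope fit: they are pinned to the
#' identity line by construction and would only add leverage, not
#' information.
#'
#' Because a permutation only relabels individuals, each SNV's `maf_p`,
#' maximum Fst and MAF category are identical across permutations; only
#' theta changes.
#'
#' @param scan an [fst_scan()] object.
#' @param gm the [genotype_matrix()] the scan was computed from.
#' @param n_permutations number of Monte Carlo permutations (default 100).
#' @param categories `"maf"` (distinct `maf_p` values, default) or `"bin"`
#'   (the scan's MAF bins); the slope uses the same choice as the observed
#'   profile.
#' @param seed RNG seed.
#' @return object of class `fst_null`: list with `categories`, `observed`,
#'   `null_mean`, `per_permutation` (matrix permutations x categories),
#'   `slope`, `slope_se`, `slope_p`, `intercept`, `n_permutations`, `seed`.
#' @export
fst_null <- function(scan, gm, n_permutations = 100L,
                     categories = c("maf", "bin"), seed = 1L) {
  abort_if(!inherits(scan, "fst_scan"), "scan must be an fst_scan")
  abort_if(!is_count(n_permutations), "n_permutations must be >= 1")
  categories <- match.arg(categories)
  rec <- scan$records
  if (nrow(rec) == 0L) {
    bf_msg("scan has no records; null profile is empty")
    return(structure(list(categories = numeric(0), observed = numeric(0),
                          null_mean = numeric(0),
                          per_permutation = matrix(0, 0, 0),
                          informative = logical(0),
                          slope = NA_real_, slope_se = NA_real_,
                          slope_p = NA_real_, intercept = NA_real_,
                          n_permutations = n_permutations, seed = seed),
                     class = "fst_null"))
  }
  cat_val <- if (categories == "maf") rec$maf_p else rec$maf_bin
  cats <- sort(unique(cat_val))
  grp <- match(cat_val, cats)
  ncat <- length(cats)
  gsize <- tabulate(grp, ncat)

  observed <- as.vector(rowsum(rec$fst_scaled, grp)) / gsize

  pool <- scan$pool
  G <- gm$geno[pool$sample, , drop = FALSE]
  vidx <- match(rec$variant, variant_keys(gm))
  G <- G[, vidx, drop = FALSE]
  centers <- scan$centers
  fmax <- rec$fst_max

  per_perm <- matrix(NA_real_, n_permutations, ncat)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      lab <- pool$center[sample.int(nrow(pool))]
      A <- outer(lab, centers, "==") * 1L
      theta <- theta_for_assignment(G, A)
      sc <- scale_fst(theta, fmax)
      sc[is.na(sc)] <- 0  # monomorphic-in-relabeling cannot occur; guard only
      per_perm[b, ] <- as.vector(rowsum(sc, grp)) / gsize
    }
  })
  null_mean <- colMeans(per_perm)

  # Categories with zero variance across permutations are degenerate: every
  # site in them scores the same scaled Fst under any labeling (e.g. the
  # one-minor-copy category, where theta is label-invariant), so observed
  # and null are pinned to the same constant by construction. Such points
  # sit exactly on the identity line with high leverage and carry no
  # information about the departure; the slope is fitted without them.
  perm_sd <- apply(per_perm, 2L, stats::sd)
  informative <- perm_sd > 0
  fit <- observed_vs_null_slope(observed[informative], null_mean[informative])
  structure(c(list(categories = cats, observed = observed,
                   null_mean = null_mean, per_permutation = per_perm,
                   informative = informative,
                   category_type = categories,
                   n_permutations = as.integer(n_permutations), seed = seed),
              fit),
            class = "fst_null")
}

#' Slope of the observed scaled-Fst profile on its Monte Carlo null
#'
#' Ordinary least squares of the observed per-category means on the null
#' per-category means, intercept retained (it is reported but not
#' interpreted). Under no batch effect the observed profile is one more draw
#' from the null, so the slope is close to 1; center-specific error processes
#' inflate the observed means where the null is smallest, driving the slope
#' above 1. The p-value is the standard two-sided test of slope = 0.
#'
#' @param observed,null numeric vectors of per-category means (>= 3 shared
#'   categories).
#' @return list with `slope`, `slope_se`, `slope_p`, `intercept`.
#' @export
observed_vs_null_slope <- function(observed, null) {
  abort_if(length(observed) != length(null),
           "observed and null must share categories")
  if (length(observed) < 3L || stats::sd(null) == 0) {
    bf_msg("observed-vs-null slope undefined (",
           length(observed), " categories, null variance ",
           if (length(null) > 1L) stats::var(null) else NA, ")")
    return(list(slope = NA_real_, slope_se = NA_real_, slope_p = NA_real_,
                intercept = NA_real_))
  }
  fit <- stats::lm(observed ~ null)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["null", "Estimate"]),
       slope_se = unname(sm["null", "Std. Error"]),
       slope_p = unname(sm["null", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]))
}

#' @export
print.fst_null <- function(x, ...) {
  cat(sprintf("Monte Carlo null for scaled-Fst profile (%d permutations, %d %s categories)\n",
              x$n_permutations, length(x$categories),
              if (identical(x$category_type, "bin")) "MAF-bin" else "MAF"))
  if (length(x$categories))
    cat(sprintf("  observed vs null slope = %.3f (se %.3f, p = %.3g), intercept = %.4f\n  fitted on %d informative categories (%d pinned/degenerate excluded)\n",
                x$slope, x$slope_se, x$slope_p, x$intercept,
                sum(x$informative), sum(!x$informative)))
  invisible(x)
}

#' @export
summary.fst_null <- function(object, ...) {
  lo <- apply(object$per_permutation, 2L, stats::quantile, 0.025)
  hi <- apply(object$per_permutation, 2L, stats::quantile, 0.975)
  data.frame(category = object$categories, observed = object$observed,
             null_mean = object$null_mean, null_q025 = lo, null_q975 = hi)
}

#' @export
plot.fst_null <- function(x, ...) {
  graphics::plot(x$null_mean, x$observed, pch = 19,
                 xlab = "null mean scaled Fst", ylab = "observed mean scaled Fst",
                 main = sprintf("slope = %.2f", x$slope), ...)
  graphics::abline(0, 1, lty = 2)
  if (is.finite(x$slope)) graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}

#' Serialize a null summary to JSON
#'
#' @param x an `fst_null`.
#' @param path output path.
#' @export
write_null_summary <- function(x, path) {
  jsonlite::write_json(list(
    categories = x$categories, observed = x$observed,
    null_mean = x$null_mean, slope = x$slope, slope_se = x$slope_se,
    slope_p = x$slope_p, intercept = x$intercept,
    n_permutations = x$n_permutations, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
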