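# Statistical contrasts on the per-individual count table: hierarchical
# mixed models with nested random effects and a likelihood-ratio test for
# the center term, correspondence analysis of the population-by-center
# sampling design, and pairwise Wilcoxon contrasts within a population.

#' Hierarchical mixed model for a center effect on rare-event counts
#'
#' Fits `log(response) ~ center + (1 | super_pop / pop)` by maximum
#' likelihood (\pkg{lme4}): a fixed sequencing-center effect with nested
#' random intercepts for continental group and population within continental
#' group, compared against the center-free null model via a likelihood-ratio
#' test with `#centers - 1` degrees of freedom. ML rather than REML is used
#' because the two models differ in fixed effects. Only centers that
#' sequenced samples in every population are retained, so the center
#' contrast is not confounded with population membership. The reference
#' center (absorbed in the intercept) is the alphabetically first retained
#' center. Coefficient p-values are Satterthwaite-based Wald tests
#' (\pkg{lmerTest}).
#'
#' @param counts a `count_table` (from [rare_event_counts()] or
#'   [simulate_count_table()]).
#' @param response name of the count column to model (e.g. `"n_singletons"`).
#' @param zero_policy what to do with zero counts before taking logs:
#'   `"drop"` (default) excludes those samples with a message, `"add_one"`
#'   models `log(count + 1)`.
#' @return object of class `center_lmm`: coefficient table, variance
#'   components, log-likelihoods of the full and null fits, LRT statistic,
#'   df and p-value, and the underlying fits.
#' @export
fit_center_mixed_model <- function(counts, response = "n_singletons",
                                   zero_policy = c("drop", "add_one")) {
  zero_policy <- match.arg(zero_policy)
  abort_if(!response %in% names(counts),
           paste0("no column ", response, " in counts"))
  d <- as.data.frame(counts)
  d$.y <- d[[response]]
  abort_if(any(d$.y < 0), "counts must be non-negative")

  # centers present across all populations
  pops <- unique(d$pop)
  by_center <- tapply(d$pop, d$center, function(p) length(unique(p)))
  keep_centers <- names(by_center)[by_center == length(pops)]
  dropped <- setdiff(names(by_center), keep_centers)
  if (length(dropped))
    bf_msg("dropping center(s) not present in every population: ",
           paste(dropped, collapse = ", "))
  abort_if(length(keep_centers) < 2L,
           "fewer than 2 centers sequenced samples in every population")
  d <- d[d$center %in% keep_centers, , drop = FALSE]

  if (any(d$.y == 0)) {
    if (zero_policy == "drop") {
      bf_msg("excluding ", sum(d$.y == 0), " sample(s) with zero ", response,
             " (use zero_policy = \"add_one\" to keep them as log(count + 1))")
      d <- d[d$.y > 0, , drop = FALSE]
      abort_if(nrow(d) == 0L, "no samples left after dropping zero counts")
    } else {
      d$.y <- d$.y + 1
    }
  }
  d$logS <- log(d$.y)
  d$center <- factor(d$center, levels = sort(keep_centers))
  d$pop <- factor(d$pop); d$super_pop <- factor(d$super_pop)

  ctrl <- lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4))
  full <- suppressWarnings(suppressMessages(
    lmerTest::lmer(logS ~ center + (1 | super_pop / pop), data = d,
                   REML = FALSE, control = ctrl)))
  null <- suppressWarnings(suppressMessages(
    lme4::lmer(logS ~ (1 | super_pop / pop), data = d,
               REML = FALSE, control = ctrl)))

  co <- as.data.frame(summary(full)$coefficients)
  names(co) <- c("coefficient", "std_error", "df", "t", "p")[seq_len(ncol(co))]
  rownames(co) <- sub("^center", "", rownames(co))

  vc <- as.data.frame(lme4::VarCorr(full))
  vcomp <- stats::setNames(vc$vcov, vc$grp)

  ll_full <- as.numeric(stats::logLik(full))
  ll_null <- as.numeric(stats::logLik(null))
  lrt <- max(0, 2 * (ll_full - ll_null))
  df <- length(keep_centers) - 1L
  p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)

  structure(list(response = response, coefficients = co,
                 varcomp = vcomp, logLik_full = ll_full, logLik_null = ll_null,
                 lrt = lrt, lrt_df = df, lrt_p = p,
                 centers = keep_centers, reference = sort(keep_centers)[1L],
                 n = nrow(d), singular = lme4::isSingular(full, tol = 1e-4),
                 fit = full, fit_null = null),
            class = "center_lmm")
}

#' @export
print.center_lmm <- function(x, ...) {
  cat(sprintf("Hierarchical mixed model: log(%s) ~ center + (1 | continent/pop)\n",
              x$response))
  cat(sprintf("  %d samples; centers: %s (reference %s)%s\n", x$n,
              paste(x$centers, collapse = ", "), x$reference,
              if (x$singular) "; singular random-effect fit" else ""))
  print(round(x$coefficients, 5))
  cat(sprintf("  LRT vs center-free null: chi2 = %.3f, df = %d, p = %.3g\n",
              x$lrt, x$lrt_df, x$lrt_p))
  invisible(x)
}

#' @export
coef.center_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$coefficient,
                  rownames(object$coefficients))
}

#' @export
summary.center_lmm <- function(object, ...) {
  list(coefficients = object$coefficients,
       varcomp = object$varcomp,
       lrt = c(statistic = object$lrt, df = object$lrt_df, p = object$lrt_p))
}

#' Correspondence analysis of the population-by-center sampling design
#'
#' Builds (or accepts) the populations x centers contingency table of sample
#' counts, tests independence with the Pearson chi-square, and decomposes
#' the departure from independence by SVD of the standardized-residual
#' matrix. Principal coordinates are the singular vectors scaled by the
#' singular values over the square-root masses; the inertia of dimension
#' `k` is its squared singular value, and total inertia equals `chi2 / N`.
#' An uneven design (populations clustering near particular centers) is the
#' precondition for center batch effects to masquerade as population
#' structure.
#'
#' @param x a contingency table/matrix, or a metadata / `count_table` data
#'   frame with `pop` and `center` columns (the table is then tabulated).
#' @param n_dims number of leading dimensions to return coordinates for.
#' @return object of class `ca_batch`: the table, `chisq`, `df`, `p_value`,
#'   `row_coords`, `col_coords`, `inertia`, `total_inertia`.
#' @export
correspondence_analysis <- function(x, n_dims = 2L) {
  tab <- if (is.data.frame(x) && all(c("pop", "center") %in% names(x)))
    table(x$pop, x$center) else as.table(as.matrix(x))
  N <- sum(tab)
  abort_if(N == 0, "empty contingency table")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " empty row(s) and ", sum(zc),
            " empty column(s)", call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  abort_if(nrow(tab) < 2L || ncol(tab) < 2L,
           "contingency table must be at least 2 x 2")

  P <- tab / N
  r <- rowSums(P); c_ <- colSums(P)
  E <- outer(r, c_)
  S <- (P - E) / sqrt(E)           # standardized residuals / sqrt(N)
  chisq <- N * sum(S^2)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p_value <- stats::pchisq(chisq, df, lower.tail = FALSE)

  sv <- svd(S)
  ndim <- min(n_dims, length(sv$d), df)
  keep <- seq_len(min(nrow(tab), ncol(tab)) - 1L)
  inertia <- sv$d[keep]^2
  row_coords <- sweep(sv$u[, seq_len(ndim), drop = FALSE] / sqrt(r), 2L,
                      sv$d[seq_len(ndim)], `*`)
  col_coords <- sweep(sv$v[, seq_len(ndim), drop = FALSE] / sqrt(c_), 2L,
                      sv$d[seq_len(ndim)], `*`)
  dimnames(row_coords) <- list(rownames(tab), paste0("Dim", seq_len(ndim)))
  dimnames(col_coords) <- list(colnames(tab), paste0("Dim", seq_len(ndim)))

  structure(list(table = tab, chisq = chisq, df = df, p_value = p_value,
                 row_coords = row_coords, col_coords = col_coords,
                 inertia = inertia, total_inertia = sum(inertia)),
            class = "ca_batch")
}

#' @export
print.ca_batch <- function(x, ...) {
  cat(sprintf("Correspondence analysis of a %d x %d contingency table\n",
              nrow(x$table), ncol(x$table)))
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.3g; total inertia = %.5f\n",
              x$chisq, x$df, x$p_value, x$total_inertia))
  if (length(x$inertia))
    cat("  inertia by dimension:",
        paste(sprintf("%.4f", x$inertia), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ca_batch <- function(x, ...) {
  rc <- x$row_coords; cc <- x$col_coords
  if (ncol(rc) < 2L) stop("need >= 2 CA dimensions to plot", call. = FALSE)
  lim1 <- range(c(rc[, 1L], cc[, 1L])); lim2 <- range(c(rc[, 2L], cc[, 2L]))
  graphics::plot(rc[, 1L], rc[, 2L], col = "blue", pch = 19,
                 xlim = lim1, ylim = lim2, xlab = "Dim 1", ylab = "Dim 2",
                 main = "Correspondence analysis", ...)
  graphics::text(rc[, 1L], rc[, 2L], rownames(rc), col = "blue", pos = 3, cex = 0.7)
  graphics::points(cc[, 1L], cc[, 2L], col = "red", pch = 17)
  graphics::text(cc[, 1L], cc[, 2L], rownames(cc), col = "red", pos = 3, cex = 0.7)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Pairwise Wilcoxon contrasts between centers within a population
#'
#' Two-sided rank-sum tests of a count response for every unordered pair of
#' sequencing centers within one population, reported as an upper-triangular
#' p-value matrix. No multiple-testing correction is applied. Centers with
#' fewer than two samples are reported as `NA`. Exact p-values are used for
#' small tie-free samples, the tie-corrected normal approximation otherwise
#' (the \code{\link[stats]{wilcox.test}} default).
#'
#' @param counts a `count_table`.
#' @param population population label to restrict to.
#' @param response count column to compare.
#' @return matrix of p-values (rows/columns = centers, upper triangle
#'   filled), with attribute `n_samples` giving per-center sample sizes.
#' @export
pairwise_wilcoxon <- function(counts, population, response = "n_lof") {
  d <- as.data.frame(counts)
  d <- d[d$pop == population, , drop = FALSE]
  abort_if(nrow(d) == 0L, paste0("no samples in population ", population))
  abort_if(!response %in% names(d), paste0("no column ", response))
  centers <- sort(unique(d$center))
  abort_if(length(centers) < 2L, "need >= 2 centers in the population")
  y <- split(d[[response]], factor(d$center, levels = centers))
  m <- matrix(NA_real_, length(centers), length(centers),
              dimnames = list(centers, centers))
  for (i in seq_along(centers)[-length(centers)]) {
    for (j in seq((i + 1L), length(centers))) {
      if (length(y[[i]]) < 2L || length(y[[j]]) < 2L) next
      m[i, j] <- suppressWarnings(
        stats::wilcox.test(y[[i]], y[[j]], alternative = "two.sided")$p.value)
    }
  }
  attr(m, "n_samples") <- vapply(y, length, 0L)
  m
}
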