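#' Generate a synthetic multi-center genotype cohort
#'
#' Draws a cohort according to a [cohort_spec()]: per-variant cohort allele
#' frequencies from the configured site frequency spectrum, Hardy-Weinberg
#' genotypes within populations, uneven assignment of individuals to
#' sequencing centers, and a center-specific error process that flips
#' homozygous-reference genotypes to heterozygous with per-center probability
#' `e_c`, thereby creating spurious rare alleles. The alternative-allele count
#' `AC` is recomputed over the whole cohort after error injection and variants
#' monomorphic after the error process are removed, so the returned matrix is
#' biallelic and polymorphic across the whole dataset. Ancestral-allele codes
#' (`AA`) are assigned REF/ALT/degenerate per the spec probabilities, and
#' coding variants receive three functional-predictor labels with a
#' concordance structure that enriches error-created coding variants for
#' all-deleterious consensus.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{genotypes}{a `genotype_matrix` (see [genotype_matrix()])}
#'     \item{metadata}{a data frame with columns `sample`, `pop`,
#'       `super_pop`, `center`}
#'     \item{truth}{bookkeeping of the injected error process: per-center flip
#'       and eligible-site counts, the (variant, sample) coordinates of every
#'       flip, the keys of error-created variants (variants whose alternative
#'       allele exists only because of flips), and the per-center error rates}
#'   }
#' @export
generate_cohort <- function(spec) {
  abort_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")

  with_seed(spec$seed, {
    n_pop <- spec$n_populations
    pops <- sprintf("POP%02d", seq_len(n_pop))
    conts <- sprintf("CONT%d", seq_len(spec$n_continents))
    pop_cont <- conts[((seq_len(n_pop) - 1L) %% spec$n_continents) + 1L]

    N <- n_pop * spec$samples_per_pop
    sample_ids <- sprintf("S%04d", seq_len(N))
    sample_pop <- rep(pops, each = spec$samples_per_pop)
    sample_cont <- rep(pop_cont, each = spec$samples_per_pop)

    # center assignment, per-population multinomial with the spec weights
    center_idx <- integer(N)
    for (i in seq_len(n_pop)) {
      rows <- which(sample_pop == pops[i])
      center_idx[rows] <- sample.int(length(spec$centers), length(rows),
                                     replace = TRUE,
                                     prob = spec$center_assignment_weights[i, ])
    }
    sample_center <- spec$centers[center_idx]
    if (!all(spec$centers %in% sample_center))
      stop("center(s) with zero assigned samples: ",
           paste(setdiff(spec$centers, sample_center), collapse = ", "),
           "; increase samples_per_pop or adjust weights", call. = FALSE)

    metadata <- data.frame(sample = sample_ids, pop = sample_pop,
                           super_pop = sample_cont, center = sample_center,
                           stringsAsFactors = FALSE)

    V <- spec$n_variants
    # SFS on cohort ALT-allele counts 1..2N-1, weight 1/i^exponent
    counts <- seq_len(2L * N - 1L)
    q <- sample(counts, V, replace = TRUE,
                prob = counts^(-spec$sfs_exponent)) / (2 * N)

    # Hardy-Weinberg genotypes: code = ALT copies, Binomial(2, q) per sample
    geno <- matrix(stats::rbinom(N * V, 2L, rep(q, each = N)), nrow = N, ncol = V)
    ac_before <- colSums(geno)

    # Center-specific error injection: hom-ref -> het flips. With
    # error_recurrence f > 0 each center has its own error-prone sites
    # (probability e_c / f per site) at which each of its hom-ref genotypes
    # is flipped with probability f; with f = 0 flips are independent per
    # genotype. Marginal per-genotype flip probability is e_c either way.
    err <- spec$center_error_rates
    rec <- spec$error_recurrence
    eligible <- geno == 0L
    n_eligible <- stats::setNames(rep(0, length(spec$centers)), spec$centers)
    for (cc in spec$centers)
      n_eligible[cc] <- sum(eligible[sample_center == cc, ])
    flips <- NULL
    prone_sites <- list()
    if (any(err > 0)) {
      do_flip <- matrix(FALSE, N, V)
      for (cc in spec$centers) {
        e_c <- err[[cc]]
        if (e_c <= 0) next
        rows <- which(sample_center == cc)
        if (rec > 0) {
          prone <- which(stats::runif(V) < e_c / rec)
          prone_sites[[cc]] <- prone
          if (!length(prone)) next
          u <- matrix(stats::runif(length(rows) * length(prone)), length(rows))
          do_flip[rows, prone] <- eligible[rows, prone, drop = FALSE] & (u < rec)
        } else {
          u <- matrix(stats::runif(length(rows) * V), length(rows))
          do_flip[rows, ] <- eligible[rows, , drop = FALSE] & (u < e_c)
        }
      }
      geno[do_flip] <- 1L
      flips <- which(do_flip, arr.ind = TRUE)
    }
    n_flips <- stats::setNames(rep(0, length(spec$centers)), spec$centers)
    if (!is.null(flips) && nrow(flips)) {
      tb <- table(sample_center[flips[, 1L]])
      n_flips[names(tb)] <- as.numeric(tb)
    }

    ac_after <- colSums(geno)
    error_created <- ac_before == 0L & ac_after > 0L

    # variant metadata
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, V, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    pos <- seq_len(V) * 100L

    # ancestral allele: REF-heavy, some ALT, some degenerate codes
    p_deg <- sum(spec$aa_missing_rates)
    p_ref <- (1 - p_deg) * 0.8 / 0.9
    p_alt <- (1 - p_deg) * 0.1 / 0.9
    aa_draw <- sample(c("REF", "ALT", ".", "-", "N"), V, replace = TRUE,
                      prob = c(p_ref, p_alt, spec$aa_missing_rates))
    aa <- ifelse(aa_draw == "REF", ref, ifelse(aa_draw == "ALT", alt, aa_draw))

    coding <- stats::runif(V) < spec$frac_coding
    p_cons <- ifelse(error_created, spec$predictor_concordance,
                     spec$predictor_baseline)
    consensus_del <- coding & (stats::runif(V) < p_cons)
    lab <- matrix("absent", V, 3L)
    for (j in 1:3) {
      indep <- ifelse(stats::runif(V) < spec$predictor_marginal, "D", "B")
      lab[, j] <- ifelse(consensus_del, "D", indep)
    }
    lab[!coding, ] <- "absent"

    variants <- data.frame(
      chrom = "1", pos = pos, ref = ref, alt = alt,
      ac = ac_after, aa = aa, coding = coding,
      p1 = lab[, 1L], p2 = lab[, 2L], p3 = lab[, 3L],
      stringsAsFactors = FALSE
    )

    # keep biallelic sites polymorphic across the whole cohort
    keep <- ac_after > 0L & ac_after < 2L * N
    if (!any(keep))
      stop("all variants monomorphic after error injection; ",
           "check n_variants and sfs_exponent", call. = FALSE)
    dropped_mono <- sum(!keep)
    variants <- variants[keep, , drop = FALSE]
    geno <- geno[, keep, drop = FALSE]
    rownames(variants) <- NULL

    key <- function(v) paste0(v$chrom, ":", v$pos)
    flip_df <- if (is.null(flips) || !nrow(flips)) {
      data.frame(variant = character(0), sample = character(0))
    } else {
      kept_flips <- flips[keep[flips[, 2L]], , drop = FALSE]
      data.frame(variant = paste0("1:", pos[kept_flips[, 2L]]),
                 sample = sample_ids[kept_flips[, 1L]],
                 stringsAsFactors = FALSE)
    }

    gm <- genotype_matrix(geno = geno, sample_ids = sample_ids,
                          variants = variants)

    structure(list(
      genotypes = gm,
      metadata = metadata,
      truth = list(
        center_error_rates = spec$center_error_rates,
        n_flips = n_flips,
        n_eligible = n_eligible,
        flips = flip_df,
        prone_sites = lapply(prone_sites, function(i) paste0("1:", pos[i[keep[i]]])),
        error_created = key(variants)[error_created[keep]],
        dropped_monomorphic = dropped_mono
      ),
      spec = spec
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multi-center cohort\n")
  cat(sprintf("  %d samples x %d variants; centers: %s\n",
              nrow(x$genotypes$geno), nrow(x$genotypes$variants),
              paste(sort(unique(x$metadata$center)), collapse = ", ")))
  cat(sprintf("  error flips injected: %d (%d error-created variants)\n",
              sum(x$truth$n_flips), length(x$truth$error_created)))
  invisible(x)
}

#' Generate an Sprime-style introgressed-allele table for a synthetic cohort
#'
#' Marks, independently per population, a random subset of the cohort's
#' variants as carrying an archaic introgressed allele (REF or ALT with equal
#' probability). The returned table mimics the per-population output format of
#' archaic-introgression scans: one row per (variant, population), with the
#' introgressed allele spelled as a base.
#'
#' @param cohort a `synthetic_cohort`.
#' @param frac_introgressed fraction of variants marked per population.
#' @param seed RNG seed.
#' @return data frame with columns `CHROM`, `POS`, `ALLELE`, `POP`.
#' @export
generate_sprime_table <- function(cohort, frac_introgressed = 0.05, seed = 1L) {
  abort_if(!inherits(cohort, "synthetic_cohort"), "cohort must be a synthetic_cohort")
  abort_if(!is_prob(frac_introgressed) || length(frac_introgressed) != 1L,
           "frac_introgressed must lie in [0,1]")
  v <- cohort$genotypes$variants
  pops <- sort(unique(cohort$metadata$pop))
  with_seed(seed, {
    out <- lapply(pops, function(p) {
      take <- stats::runif(nrow(v)) < frac_introgressed
      if (!any(take)) return(NULL)
      use_alt <- stats::runif(sum(take)) < 0.5
      data.frame(CHROM = v$chrom[take], POS = v$pos[take],
                 ALLELE = ifelse(use_alt, v$alt[take], v$ref[take]),
                 POP = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(CHROM = character(0), POS = integer(0),
                        ALLELE = character(0), POP = character(0))
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-individual rare-event counts with a known center effect
#'
#' Direct simulator for count tables used to validate the hierarchical mixed
#' model: log-counts are drawn as an intercept plus a fixed center effect,
#' nested Gaussian random intercepts for continent and population within
#' continent, and Gaussian residual noise, then exponentiated and rounded.
#' Defaults put the intercept and dispersion on the scale of per-individual
#' singleton counts in large resequencing cohorts (thousands per genome).
#'
#' @param n_samples number of individuals.
#' @param centers center labels; individuals are assigned uniformly.
#' @param n_continents,pops_per_continent nesting structure.
#' @param mu intercept on the log scale.
#' @param center_effects named numeric vector of log-scale fixed effects per
#'   center (unnamed centers get 0); a value `b` multiplies expected counts by
#'   `exp(b)` for samples sequenced at that center.
#' @param sd_continent,sd_pop,sd_resid standard deviations of the continent
#'   and population-in-continent random intercepts and the residual.
#' @param response name of the count column to produce.
#' @param seed RNG seed.
#' @return a `count_table` data frame (sample, pop, super_pop, center, count).
#' @export
simulate_count_table <- function(n_samples = 500L,
                                 centers = c("BCM", "BGI", "BI", "WUGSC"),
                                 n_continents = 3L, pops_per_continent = 2L,
                                 mu = 9.4, center_effects = NULL,
                                 sd_continent = 0.10, sd_pop = 0.05,
                                 sd_resid = 0.12,
                                 response = "n_singletons", seed = 1L) {
  abort_if(!is_count(n_samples), "n_samples must be a positive integer")
  b <- stats::setNames(rep(0, length(centers)), centers)
  if (!is.null(center_effects)) {
    abort_if(is.null(names(center_effects)) ||
               !all(names(center_effects) %in% centers),
             "center_effects must be named by center")
    b[names(center_effects)] <- center_effects
  }
  with_seed(seed, {
    n_pop <- n_continents * pops_per_continent
    pops <- sprintf("POP%02d", seq_len(n_pop))
    conts <- rep(sprintf("CONT%d", seq_len(n_continents)),
                 each = pops_per_continent)
    pop_of <- sort(rep_len(seq_len(n_pop), n_samples))
    center <- sample(centers, n_samples, replace = TRUE)
    u_cont <- stats::rnorm(n_continents, 0, sd_continent)
    u_pop <- stats::rnorm(n_pop, 0, sd_pop)
    eta <- mu + b[center] + u_cont[((pop_of - 1L) %/% pops_per_continent) + 1L] +
      u_pop[pop_of] + stats::rnorm(n_samples, 0, sd_resid)
    out <- data.frame(sample = sprintf("S%04d", seq_len(n_samples)),
                      pop = pops[pop_of], super_pop = conts[pop_of],
                      center = center, stringsAsFactors = FALSE)
    out[[response]] <- as.integer(round(exp(eta)))
    class(out) <- c("count_table", "data.frame")
    out
  })
}
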