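#' Specify a synthetic multi-center cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' generator emulates the structure of a multi-center resequencing cohort:
#' populations nested in continental groups, individuals assigned unevenly to
#' sequencing centers, Hardy-Weinberg genotypes at frequencies drawn from a
#' neutral-like site frequency spectrum rich in singletons, and a
#' center-specific genotype-error process that preferentially creates spurious
#' rare heterozygotes.
#'
#' @param n_populations number of populations.
#' @param n_continents number of continental groups; populations are assigned
#'   to continents round-robin, so populations nest within continents.
#' @param centers character vector of sequencing-center labels (>= 2).
#' @param samples_per_pop diploid individuals per population.
#' @param center_assignment_weights numeric matrix (`n_populations` x
#'   `length(centers)`) of per-population assignment probabilities over
#'   centers; rows must sum to 1. Default: moderately uneven weights that
#'   emulate the sampling bias of real multi-center projects.
#' @param n_variants number of biallelic SNVs to simulate (before the
#'   polymorphism filter).
#' @param sfs_exponent shape of the site frequency spectrum: cohort
#'   alternative-allele counts i in 1..2N-1 are drawn with probability
#'   proportional to 1/i^`sfs_exponent`. The default 1 is the neutral
#'   expectation and yields abundant singletons.
#' @param center_error_rates named numeric vector, one per center: per-site
#'   probability that a homozygous-reference genotype of a sample sequenced at
#'   that center is misread as heterozygous. Defaults to 0 for every center.
#'   Sequencing error rates of real platforms are on the order of 0.1-1% per
#'   nucleotide, so values in `[0.001, 0.01]` are realistic for studies of the
#'   error process.
#' @param error_recurrence site-recurrence of center artifacts, in `[0, 1]`.
#'   Systematic center artifacts (context-dependent miscalls, center-specific
#'   alignment and calling pipelines) recur at the same site across many of a
#'   center's samples rather than striking genotypes independently. With
#'   `error_recurrence = f > 0`, each center draws its own set of error-prone
#'   sites with probability `e_c / f` per site, and at a prone site each of
#'   the center's homozygous-reference genotypes is flipped with probability
#'   `f`; the marginal per-genotype flip probability is exactly `e_c` either
#'   way. `error_recurrence = 0` selects fully independent per-genotype
#'   flips. The default 0.5 means about half of a center's samples are
#'   miscalled at one of its error-prone sites. Requires `e_c <=
#'   error_recurrence` when positive.
#' @param frac_coding fraction of variants falling inside simulated genes;
#'   only these receive functional-predictor labels.
#' @param predictor_concordance probability that an error-created coding
#'   variant is labeled deleterious by all three predictors (sequencing errors
#'   inside genes tend to look like loss-of-function to all predictors).
#' @param predictor_baseline probability that any other coding variant is
#'   labeled deleterious by all three predictors.
#' @param predictor_marginal marginal probability that a single predictor
#'   calls a non-consensus coding variant deleterious (labels independent).
#' @param aa_missing_rates named numeric vector with names `"."`, `"-"`, `"N"`:
#'   probabilities of the three degenerate ancestral-allele codes (no
#'   alignment, lineage-specific insertion, allele not present). The
#'   remaining mass is split 8:1 between REF and ALT as the ancestral state.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_populations = 4L,
                        n_continents = 2L,
                        centers = c("BCM", "BGI", "BI", "WUGSC"),
                        samples_per_pop = 50L,
                        center_assignment_weights = NULL,
                        n_variants = 5000L,
                        sfs_exponent = 1,
                        center_error_rates = NULL,
                        error_recurrence = 0.5,
                        frac_coding = 0.2,
                        predictor_concordance = 0.9,
                        predictor_baseline = 0.02,
                        predictor_marginal = 0.25,
                        aa_missing_rates = c("." = 0.05, "-" = 0.02, "N" = 0.03),
                        seed = 1L) {
  abort_if(!is_count(n_populations), "n_populations must be a positive integer")
  abort_if(!is_count(n_continents) || n_continents > n_populations,
           "n_continents must be a positive integer <= n_populations")
  centers <- as.character(centers)
  abort_if(length(centers) < 2L || anyDuplicated(centers) > 0L,
           "centers must be >= 2 distinct labels")
  abort_if(!is_count(samples_per_pop), "samples_per_pop must be a positive integer")
  abort_if(!is_count(n_variants), "n_variants must be a positive integer")
  abort_if(!is.numeric(sfs_exponent) || sfs_exponent < 0,
           "sfs_exponent must be >= 0")

  K <- length(centers)
  if (is.null(center_assignment_weights)) {
    # uneven but non-degenerate: each population favors a different center
    w <- matrix(1, n_populations, K)
    for (i in seq_len(n_populations)) w[i, ((i - 1L) %% K) + 1L] <- 2
    center_assignment_weights <- w / rowSums(w)
  }
  center_assignment_weights <- as.matrix(center_assignment_weights)
  abort_if(!all(dim(center_assignment_weights) == c(n_populations, K)),
           "center_assignment_weights must be n_populations x length(centers)")
  abort_if(!is_prob(center_assignment_weights),
           "center_assignment_weights must lie in [0,1]")
  abort_if(max(abs(rowSums(center_assignment_weights) - 1)) > 1e-8,
           "center_assignment_weights rows must sum to 1")

  if (is.null(center_error_rates)) {
    center_error_rates <- stats::setNames(rep(0, K), centers)
  }
  abort_if(is.null(names(center_error_rates)) ||
             !setequal(names(center_error_rates), centers),
           "center_error_rates must be named by center")
  center_error_rates <- center_error_rates[centers]
  abort_if(!is_prob(center_error_rates), "center_error_rates must lie in [0,1]")
  abort_if(!is_prob(error_recurrence) || length(error_recurrence) != 1L,
           "error_recurrence must lie in [0,1]")
  abort_if(error_recurrence > 0 && any(center_error_rates > error_recurrence),
           "center_error_rates must be <= error_recurrence (or set error_recurrence = 0)")

  abort_if(!is_prob(frac_coding) || length(frac_coding) != 1L,
           "frac_coding must be a probability")
  abort_if(!is_prob(predictor_concordance) || !is_prob(predictor_baseline) ||
             !is_prob(predictor_marginal),
           "predictor probabilities must lie in [0,1]")
  abort_if(is.null(names(aa_missing_rates)) ||
             !setequal(names(aa_missing_rates), c(".", "-", "N")),
           "aa_missing_rates must be named '.', '-', 'N'")
  aa_missing_rates <- aa_missing_rates[c(".", "-", "N")]
  abort_if(!is_prob(aa_missing_rates) || sum(aa_missing_rates) > 1,
           "aa_missing_rates must be probabilities summing to <= 1")

  structure(list(
    n_populations = as.integer(n_populations),
    n_continents = as.integer(n_continents),
    centers = centers,
    samples_per_pop = as.integer(samples_per_pop),
    center_assignment_weights = center_assignment_weights,
    n_variants = as.integer(n_variants),
    sfs_exponent = sfs_exponent,
    center_error_rates = center_error_rates,
    error_recurrence = error_recurrence,
    frac_coding = frac_coding,
    predictor_concordance = predictor_concordance,
    predictor_baseline = predictor_baseline,
    predictor_marginal = predictor_marginal,
    aa_missing_rates = aa_missing_rates,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d populations in %d continental groups, %d samples each\n",
              x$n_populations, x$n_continents, x$samples_per_pop))
  cat(sprintf("  centers: %s\n", paste(x$centers, collapse = ", ")))
  cat(sprintf("  error rates: %s\n",
              paste(sprintf("%s=%.4g", x$centers, x$center_error_rates),
                    collapse = ", ")))
  cat(sprintf("  %d variants, SFS exponent %.3g, %.0f%% coding, seed %d\n",
              x$n_variants, x$sfs_exponent, 100 * x$frac_coding, x$seed))
  invisible(x)
}
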