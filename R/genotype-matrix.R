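#' Construct a genotype matrix
#'
#' The package's central container: diploid genotype codes (0 = hom-ref,
#' 1 = het, 2 = hom-alt, NA = missing) for samples x biallelic SNVs, together
#' with per-variant metadata. `AC`, the alternative-allele count over the
#' whole cohort, is validated (or recomputed) against the genotype codes:
#' `AC = sum of codes over non-missing samples`.
#'
#' @param geno integer matrix, samples in rows, variants in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of row identifiers.
#' @param variants data frame with one row per variant and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt` (single bases), `ac`, `aa`, and optionally
#'   `coding`, `p1`, `p2`, `p3` (predictor labels in \{"D","B","absent"\}).
#' @param recompute_ac if TRUE, `ac` is recomputed from the codes rather than
#'   validated.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sample_ids, variants, recompute_ac = FALSE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  abort_if(length(sample_ids) != nrow(geno),
           "sample_ids length must match nrow(geno)")
  abort_if(nrow(variants) != ncol(geno),
           "variants rows must match ncol(geno)")
  abort_if(!all(geno %in% c(0L, 1L, 2L, NA)),
           "genotype codes must be 0, 1, 2 or NA")
  abort_if(!all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
           "variants needs chrom, pos, ref, alt")
  for (col in c("aa", "p1", "p2", "p3"))
    if (is.null(variants[[col]])) variants[[col]] <- "absent"
  if (is.null(variants$coding))
    variants$coding <- variants$p1 != "absent"
  ac <- colSums(geno, na.rm = TRUE)
  if (recompute_ac || is.null(variants$ac)) {
    variants$ac <- as.integer(ac)
  } else {
    abort_if(!all(variants$ac == ac),
             "AC does not equal the sum of ALT copies over samples")
    variants$ac <- as.integer(variants$ac)
  }
  rownames(geno) <- sample_ids
  colnames(geno) <- paste0(variants$chrom, ":", variants$pos)
  rownames(variants) <- NULL
  structure(list(geno = geno, variants = variants), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic SNVs\n",
              nrow(x$geno), ncol(x$geno)))
  cat(sprintf("  singletons (AC = 1): %d; coding: %d; missing genotypes: %d\n",
              sum(x$variants$ac == 1L), sum(x$variants$coding),
              sum(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

variant_keys <- function(gm) colnames(gm$geno)
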