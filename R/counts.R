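# Per-individual counters of the rare genomic events used to probe
# center-associated batch effects: consensus LoF and benign variants,
# singletons, derived singletons, and archaic introgressed alleles.

#' Classify consensus loss-of-function variants
#'
#' A variant is called LoF only under a conservative consensus: all three
#' functional predictors label it deleterious AND no sample anywhere in the
#' cohort carries it in homozygosis (healthy cohorts are expected to carry
#' severe LoF only in heterozygosis; homozygous carriers point to dispensable
#' genes or to genotyping error). Variants with absent predictor labels
#' (non-coding) are never LoF.
#'
#' @param gm a [genotype_matrix()].
#' @return integer vector of variant indices (columns of `gm$geno`).
#' @export
classify_lof <- function(gm) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  v <- gm$variants
  consensus <- v$p1 == "D" & v$p2 == "D" & v$p3 == "D"
  has_hom <- colSums(gm$geno == 2L, na.rm = TRUE) > 0L
  unname(which(consensus & !has_hom))
}

#' Classify consensus benign variants
#'
#' The complementary consensus set: coding variants labeled benign by all
#' three predictors. Variants with mixed labels belong to neither set.
#'
#' @param gm a [genotype_matrix()].
#' @return integer vector of variant indices.
#' @export
classify_benign <- function(gm) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  v <- gm$variants
  unname(which(v$p1 == "B" & v$p2 == "B" & v$p3 == "B"))
}

#' Per-sample count of LoF (or benign) variants carried
#'
#' For LoF sites a carrier is necessarily heterozygous (homozygous-alt sites
#' are excluded from the set), so the count is the number of set variants at
#' which the sample's genotype code is 1; for generality any code >= 1 counts
#' as carrying. Missing genotypes contribute 0.
#'
#' @param gm a [genotype_matrix()].
#' @param variant_set integer vector of variant indices.
#' @return named integer vector, one count per sample.
#' @export
count_carriers_per_sample <- function(gm, variant_set) {
  if (length(variant_set) == 0L)
    return(stats::setNames(integer(nrow(gm$geno)), rownames(gm$geno)))
  sub <- gm$geno[, variant_set, drop = FALSE]
  out <- rowSums(sub >= 1L, na.rm = TRUE)
  stats::setNames(as.integer(out), rownames(gm$geno))
}

#' Per-sample singleton counts
#'
#' A singleton is a variant whose alternative allele appears exactly once in
#' the whole cohort (`AC = 1`); the count for a sample is the number of
#' singletons whose single ALT copy that sample carries.
#'
#' @param gm a [genotype_matrix()].
#' @return named integer vector of per-sample counts.
#' @export
count_singletons <- function(gm) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  sing <- which(gm$variants$ac == 1L)
  count_carriers_per_sample(gm, sing)
}

#' Per-sample derived-singleton counts
#'
#' Among singleton variants, sites whose ancestral allele is a degenerate
#' code are excluded: `"."` (no alignment in the primate EPO), `"-"`
#' (lineage-specific insertion) and `"N"` (allele not present). A remaining
#' singleton is derived iff the reference allele equals the ancestral allele,
#' so the single ALT copy is the derived (new) allele; the count goes to its
#' carrier. Sites whose ancestral allele matches neither REF nor ALT are
#' excluded and reported.
#'
#' @param gm a [genotype_matrix()].
#' @return named integer vector of per-sample counts.
#' @export
count_derived_singletons <- function(gm) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  v <- gm$variants
  sing <- v$ac == 1L
  degen <- v$aa %in% c(".", "-", "N", "absent")
  usable <- sing & !degen
  mismatch <- usable & v$aa != v$ref & v$aa != v$alt
  if (any(mismatch))
    bf_msg("excluding ", sum(mismatch),
           " singleton(s) whose ancestral allele matches neither REF nor ALT")
  derived <- usable & !mismatch & v$aa == v$ref
  count_carriers_per_sample(gm, which(derived))
}

#' Per-sample introgressed-allele counts
#'
#' For each sample, sums over the variants marked introgressed in the
#' sample's own population the number of copies of the introgressed allele it
#' carries (0, 1 or 2). Entries for other populations contribute nothing.
#'
#' @param gm a [genotype_matrix()].
#' @param sprime a table from [read_sprime_table()] /
#'   [generate_sprime_table()].
#' @param metadata sample metadata with `sample` and `pop`.
#' @return named integer vector of per-sample counts.
#' @export
count_introgressed <- function(gm, sprime, metadata) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  out <- stats::setNames(integer(nrow(gm$geno)), rownames(gm$geno))
  if (is.null(sprime) || nrow(sprime) == 0L) return(out)
  pop_of <- stats::setNames(metadata$pop, metadata$sample)
  vidx <- match(paste0(sprime$CHROM, ":", sprime$POS), variant_keys(gm))
  ok <- !is.na(vidx)
  sprime <- sprime[ok, , drop = FALSE]; vidx <- vidx[ok]
  is_alt <- sprime$ALLELE == gm$variants$alt[vidx]
  for (p in unique(sprime$POP)) {
    rows <- which(sprime$POP == p)
    samp <- which(pop_of[rownames(gm$geno)] == p)
    if (!length(samp)) next
    sub <- gm$geno[samp, vidx[rows], drop = FALSE]
    copies <- ifelse(rep(is_alt[rows], each = length(samp)), sub, 2L - sub)
    out[samp] <- out[samp] + as.integer(rowSums(matrix(copies, nrow = length(samp)),
                                                na.rm = TRUE))
  }
  out
}

#' Assemble the per-individual rare-event count table
#'
#' Runs every counter and joins the results to the sample metadata. This is
#' the table the association models consume (one row per individual;
#' grouping columns plus `n_lof`, `n_benign`, `n_singletons`,
#' `n_derived_singletons`, `n_introgressed`).
#'
#' @param gm a [genotype_matrix()].
#' @param metadata sample metadata (`sample`, `pop`, `super_pop`, `center`).
#' @param sprime optional introgressed-allele table; without it the
#'   `n_introgressed` column is 0.
#' @return a `count_table` data frame.
#' @export
rare_event_counts <- function(gm, metadata, sprime = NULL) {
  abort_if(!all(rownames(gm$geno) %in% metadata$sample),
           "every genotyped sample needs metadata")
  md <- metadata[match(rownames(gm$geno), metadata$sample), , drop = FALSE]
  out <- data.frame(
    sample = rownames(gm$geno),
    pop = md$pop, super_pop = md$super_pop, center = md$center,
    n_lof = count_carriers_per_sample(gm, classify_lof(gm)),
    n_benign = count_carriers_per_sample(gm, classify_benign(gm)),
    n_singletons = count_singletons(gm),
    n_derived_singletons = count_derived_singletons(gm),
    n_introgressed = count_introgressed(gm, sprime, md),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("count_table", "data.frame")
  out
}

#' @rdname rare_event_counts
#' @param counts a `count_table` to write.
#' @param path output TSV path.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
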