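# Readers and writers for the formats the pipeline consumes and emits:
# VCF 4.2 (GT genotypes; INFO keys AC, AA and predictor labels), the sample
# metadata TSV mirroring the sample spreadsheets of large multi-center
# projects, Sprime-style
# introgressed-allele TSVs, and per-individual count tables.

#' Predictor-label mappings for annotated VCFs
#'
#' Describe where the three functional-predictor labels live in the VCF INFO
#' field and which raw codes count as deleterious. `predictor_mapping()` is
#' the default used by the synthetic writer (labels already in \{"D","B"\}).
#' `dbnsfp_mapping()` maps dbNSFP-style prediction codes: SIFT "D"
#' (deleterious), Polyphen2 HDIV "D" (probably damaging) and MutationAssessor
#' "H" (high) are deleterious; every other observed code is benign. The exact
#' category cut is a declared convention, configurable via the
#' `deleterious` codes.
#'
#' @param keys INFO keys of the three predictors, in order.
#' @param deleterious list of three character vectors: raw codes mapped to
#'   "D" for each predictor.
#' @return a list understood by [read_vcf()].
#' @export
predictor_mapping <- function(keys = c("P1", "P2", "P3"),
                              deleterious = list("D", "D", "D")) {
  abort_if(length(keys) != 3L || length(deleterious) != 3L,
           "exactly three predictors are expected")
  list(keys = keys, deleterious = deleterious)
}

#' @rdname predictor_mapping
#' @export
dbnsfp_mapping <- function() {
  predictor_mapping(
    keys = c("SIFT_pred", "Polyphen2_HDIV_pred", "MutationAssessor_pred"),
    deleterious = list("D", "D", "H"))
}

info_field <- function(info, key) {
  m <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
  out <- rep(NA_character_, length(info))
  hit <- m > 0L
  out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
  out
}

#' Read a VCF into a genotype matrix, applying the variant-selection rules
#'
#' Loads a VCF (via \pkg{vcfR}), keeps only biallelic SNVs that are
#' polymorphic across the whole dataset, and reports how many records each
#' filter removed. Genotypes are read from the GT field, unphased; `./.`
#' becomes a missing code. `AC` is recomputed from the genotype codes so the
#' container invariant `AC = sum of ALT copies` always holds (a message is
#' emitted if the INFO value disagreed). The ancestral allele is taken from
#' the `AA` INFO key: the first `|`-separated token, uppercased unless
#' `strict_case`, with the degenerate codes `"."`, `"-"`, `"N"` preserved and
#' anything malformed or absent mapped to `"."` (no alignment).
#'
#' @param path VCF file (plain text or gzipped).
#' @param predictor_map a [predictor_mapping()]; INFO values matching the
#'   configured deleterious codes become "D", other observed values "B",
#'   absent keys "absent".
#' @param strict_case if TRUE, the ancestral allele keeps its case (lowercase
#'   EPO calls then fail the REF/ALT match and are excluded downstream);
#'   default FALSE compares case-insensitively.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, predictor_map = predictor_mapping(),
                     strict_case = FALSE) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  abort_if(nrow(v@fix) == 0L, "VCF contains no variant records")
  abort_if(ncol(v@gt) < 2L, "VCF has no sample genotype columns")
  fmt <- v@gt[, 1L]
  abort_if(!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, TRUE)),
           "VCF records lack the GT FORMAT field")

  chrom <- v@fix[, "CHROM"]
  pos <- as.integer(v@fix[, "POS"])
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  info <- v@fix[, "INFO"]

  snv <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  keep1 <- snv & !multi
  n_multi <- sum(multi)
  n_nonsnv <- sum(!snv & !multi)

  gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
  gt <- gt[keep1, , drop = FALSE]
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  code[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]

  ac <- rowSums(code, na.rm = TRUE)
  n_nonmiss <- rowSums(!is.na(code))
  poly <- ac > 0L & ac < 2L * n_nonmiss
  n_mono <- sum(!poly)

  info_k <- info[keep1]
  ac_info <- suppressWarnings(as.integer(info_field(info_k, "AC")))
  if (any(!is.na(ac_info) & ac_info != ac))
    bf_msg(sum(!is.na(ac_info) & ac_info != ac),
           " variant(s) had INFO/AC disagreeing with the genotypes; recomputed")

  aa_raw <- info_field(info_k, "AA")
  aa <- vapply(strsplit(ifelse(is.na(aa_raw), ".", aa_raw), "|", fixed = TRUE),
               function(x) if (length(x)) x[[1L]] else ".", "")
  if (!strict_case) aa <- toupper(aa)
  bad_aa <- !(aa %in% c("A", "C", "G", "T", ".", "-", "N")) &
    !(strict_case & aa %in% c("a", "c", "g", "t"))
  aa[bad_aa] <- "."

  labels <- matrix("absent", sum(keep1), 3L)
  for (j in 1:3) {
    raw <- info_field(info_k, predictor_map$keys[[j]])
    labels[, j] <- ifelse(is.na(raw), "absent",
                          ifelse(raw %in% predictor_map$deleterious[[j]], "D", "B"))
  }

  bf_msg(sprintf(
    "read_vcf: %d records; dropped %d multi-allelic, %d non-SNV, %d monomorphic; kept %d",
    length(chrom), n_multi, n_nonsnv, n_mono, sum(poly)))

  variants <- data.frame(
    chrom = chrom[keep1][poly], pos = pos[keep1][poly],
    ref = ref[keep1][poly], alt = alt[keep1][poly],
    aa = aa[poly], p1 = labels[poly, 1L], p2 = labels[poly, 2L],
    p3 = labels[poly, 3L], stringsAsFactors = FALSE)

  genotype_matrix(t(code[poly, , drop = FALSE]),
                  sample_ids = colnames(gt), variants = variants,
                  recompute_ac = TRUE)
}

#' Write a genotype matrix as plain-text VCF 4.2
#'
#' Emits GT genotypes and the INFO keys `AC`, `AA` plus the three predictor
#' labels for coding variants. Output is deterministic text, suitable for
#' byte-level comparison of pipeline runs.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param predictor_map a [predictor_mapping()] giving the INFO keys to write.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, predictor_map = predictor_mapping()) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  v <- gm$variants
  gt <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = nrow(gm$geno))
  gt[is.na(gm$geno)] <- "./."
  info <- sprintf("AC=%d;AA=%s", v$ac, v$aa)
  for (j in 1:3) {
    lab <- v[[paste0("p", j)]]
    has <- lab != "absent"
    info[has] <- paste0(info[has], ";", predictor_map$keys[[j]], "=", lab[has])
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=batchfst",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate allele count across samples\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Predictor %d label\">",
            unlist(predictor_map$keys), 1:3),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$geno)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read the sample-metadata table
#'
#' Expects a TSV with columns `sample`, `pop`, `super_pop`, `center` (the
#' layout of a multi-center project's sample spreadsheet). Samples with a
#' missing sequencing center are excluded and reported, mirroring the
#' exclusion of samples whose center cannot be established. Duplicate sample
#' identifiers are an error.
#'
#' @param path TSV file.
#' @return data frame with the four columns, class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  abort_if(nrow(md) == 0L, "metadata table is empty")
  need <- c("sample", "pop", "super_pop", "center")
  abort_if(!all(need %in% names(md)),
           paste0("metadata needs columns: ", paste(need, collapse = ", ")))
  md <- md[, need]
  abort_if(anyDuplicated(md$sample) > 0L, "duplicate sample IDs in metadata")
  miss <- is.na(md$center) | md$center == "" | md$center == "NA"
  if (any(miss))
    bf_msg("excluding ", sum(miss), " sample(s) with missing center: ",
           paste(md$sample[miss], collapse = ", "))
  md <- md[!miss, , drop = FALSE]
  rownames(md) <- NULL
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' @rdname read_metadata
#' @param metadata a metadata data frame to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check that genotypes and metadata describe the same samples
#'
#' @param gm a [genotype_matrix()].
#' @param metadata a metadata table.
#' @return (invisibly) a list with `missing_in_metadata` and
#'   `missing_in_genotypes`; a warning is raised if either is non-empty.
#' @export
check_cohort_consistency <- function(gm, metadata) {
  g <- rownames(gm$geno)
  m <- metadata$sample
  out <- list(missing_in_metadata = setdiff(g, m),
              missing_in_genotypes = setdiff(m, g))
  if (length(out$missing_in_metadata))
    warning(length(out$missing_in_metadata),
            " genotyped sample(s) absent from metadata: ",
            paste(out$missing_in_metadata, collapse = ", "), call. = FALSE)
  invisible(out)
}

#' Read an Sprime-style introgressed-allele table
#'
#' Expects a TSV with columns `CHROM`, `POS`, `ALLELE`, `POP`: one row per
#' variant and population in which the allele was called introgressed.
#' Duplicate (variant, population) entries are an error. When a genotype
#' matrix is supplied, rows at positions absent from it are skipped (and
#' counted) and rows whose allele matches neither REF nor ALT of the matched
#' variant are skipped with a warning.
#'
#' @param path TSV file.
#' @param genotypes optional [genotype_matrix()] to validate against.
#' @return data frame with columns `CHROM`, `POS`, `ALLELE`, `POP`.
#' @export
read_sprime_table <- function(path, genotypes = NULL) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tb) == 0L)
    return(data.frame(CHROM = character(0), POS = integer(0),
                      ALLELE = character(0), POP = character(0)))
  need <- c("CHROM", "POS", "ALLELE", "POP")
  abort_if(!all(need %in% names(tb)),
           paste0("Sprime table needs columns: ", paste(need, collapse = ", ")))
  tb <- tb[, need]
  tb$CHROM <- as.character(tb$CHROM)
  tb$POS <- as.integer(tb$POS)
  key <- paste(tb$CHROM, tb$POS, tb$POP)
  abort_if(anyDuplicated(key) > 0L,
           "duplicate (variant, population) entries in Sprime table")
  if (!is.null(genotypes)) {
    vkey <- paste0(tb$CHROM, ":", tb$POS)
    hit <- match(vkey, variant_keys(genotypes))
    if (any(is.na(hit)))
      bf_msg("skipping ", sum(is.na(hit)),
             " Sprime row(s) at positions absent from the genotypes")
    tb <- tb[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
    v <- genotypes$variants
    okallele <- tb$ALLELE == v$ref[hit] | tb$ALLELE == v$alt[hit]
    if (any(!okallele))
      warning("skipping ", sum(!okallele),
              " Sprime row(s) whose allele matches neither REF nor ALT",
              call. = FALSE)
    tb <- tb[okallele, , drop = FALSE]
  }
  rownames(tb) <- NULL
  tb
}

#' @rdname read_sprime_table
#' @param table an Sprime-style table to write.
#' @export
write_sprime_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
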