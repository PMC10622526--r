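#' Genotype codes
#'
#' Integer codes used throughout the package for per-cell genotype calls:
#' `GT_REF = 0` (homozygous reference), `GT_HET = 1` (heterozygous),
#' `GT_HOM = 2` (homozygous alternate). Missing genotypes are stored as `NA`.
#'
#' @name genotype-codes
#' @aliases GT_REF GT_HET GT_HOM
#' @export GT_REF GT_HET GT_HOM
NULL

GT_REF <- 0L
GT_HET <- 1L
GT_HOM <- 2L

#' Construct a single-nucleus genotype matrix
#'
#' The central container of the package: a set of variants genotyped across a
#' set of nuclei (cells), holding per-(variant, cell) genotype codes, total
#' read depth, alternate-allele read counts and genotype qualities, together
#' with per-variant metadata.
#'
#' @param variants data.frame with one row per variant and columns `chrom`
#'   (character), `pos` (1-based integer), `ref`, `alt` (non-empty allele
#'   strings). Optional columns `var_id` (dbSNP rsID or `NA`), `in_dbsnp`,
#'   `is_anchor`, `multi_alt` (logical) are added with defaults when absent;
#'   `is_indel` is always recomputed as `nchar(ref) != nchar(alt)`.
#' @param cell_ids character vector of unique cell (nucleus) identifiers.
#' @param GT integer matrix of genotype codes (`GT_REF`/`GT_HET`/`GT_HOM`/`NA`),
#'   variants in rows, cells in columns.
#' @param DP,AD,GQ integer matrices of the same dimension: total depth,
#'   alternate-allele read count, genotype quality. Any may be `NULL`, in which
#'   case a zero (DP/AD) or `NA` (GQ) matrix is used.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `variants`, `cell_ids`, `GT`, `DP`, `AD`, `GQ`. Variants are sorted by
#'   `(chrom, pos)`.
#' @export
genotype_matrix <- function(variants, cell_ids, GT, DP = NULL, AD = NULL,
                            GQ = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)))
    stop("ref and alt alleles must be non-empty")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  if (is.null(variants$var_id)) variants$var_id <- NA_character_
  if (is.null(variants$in_dbsnp)) variants$in_dbsnp <- FALSE
  if (is.null(variants$is_anchor)) variants$is_anchor <- FALSE
  if (is.null(variants$multi_alt)) variants$multi_alt <- FALSE
  variants$is_indel <- nchar(variants$ref) != nchar(variants$alt)

  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")

  nv <- nrow(variants)
  nc <- length(cell_ids)
  as_mat <- function(m, fill) {
    if (is.null(m)) m <- matrix(fill, nv, nc)
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (!all(dim(m) == c(nv, nc)))
      stop("all matrices must be |variants| x |cells| (", nv, " x ", nc, ")")
    dimnames(m) <- list(NULL, cell_ids)
    m
  }
  GT <- as_mat(GT, NA_integer_)
  DP <- as_mat(DP, 0L)
  AD <- as_mat(AD, 0L)
  GQ <- as_mat(GQ, NA_integer_)
  if (!all(GT %in% c(GT_REF, GT_HET, GT_HOM, NA)))
    stop("GT entries must be 0 (REF), 1 (HET), 2 (HOM) or NA (missing)")
  if (any(DP < 0L, na.rm = TRUE) || any(AD < 0L, na.rm = TRUE))
    stop("DP and AD must be non-negative")
  if (any(AD > DP, na.rm = TRUE))
    stop("AD (alternate reads) cannot exceed DP (total depth)")

  ord <- order(variants$chrom, variants$pos)
  obj <- structure(list(variants = variants[ord, , drop = FALSE],
                        cell_ids = cell_ids,
                        GT = GT[ord, , drop = FALSE],
                        DP = DP[ord, , drop = FALSE],
                        AD = AD[ord, , drop = FALSE],
                        GQ = GQ[ord, , drop = FALSE]),
                   class = "genotype_matrix")
  rownames(obj$variants) <- NULL
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$variants), "variants x",
      length(x$cell_ids), "cells\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  anchors:", sum(x$variants$is_anchor),
      "| dbSNP-annotated:", sum(x$variants$in_dbsnp),
      "| indels:", sum(x$variants$is_indel), "\n")
  gt <- x$GT
  cat(sprintf("  genotype calls: %.1f%% missing, %.1f%% het of called\n",
              100 * mean(is.na(gt)),
              if (all(is.na(gt))) NA_real_ else
                100 * mean(gt[!is.na(gt)] == GT_HET)))
  invisible(x)
}

#' Canonical variant keys
#'
#' @param x a `genotype_matrix` or a variants data.frame.
#' @return character vector `"chrom:pos:ref:alt"`, one entry per variant.
#' @export
variant_keys <- function(x) {
  v <- if (inherits(x, "genotype_matrix")) x$variants else x
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param variants integer/logical index into variants, or `NULL` for all.
#' @param cells integer/logical index or character cell ids, or `NULL` for all.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_matrix <- function(x, variants = NULL, cells = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else cells
  if (is.character(ci)) ci <- match(ci, x$cell_ids)
  genotype_matrix(x$variants[vi, , drop = FALSE],
                  x$cell_ids[ci],
                  x$GT[vi, ci, drop = FALSE],
                  x$DP[vi, ci, drop = FALSE],
                  x$AD[vi, ci, drop = FALSE],
                  x$GQ[vi, ci, drop = FALSE])
}

#' Flag variants present in a dbSNP membership list
#'
#' Germline-SNP selection requires membership in dbSNP; variants absent from
#' the catalogue are candidates for exclusion (whitelisted somatic anchors are
#' always retained downstream regardless). The membership list may mix rsIDs
#' and `"chrom:pos:ref:alt"` keys.
#'
#' @param x a `genotype_matrix`.
#' @param id_set character vector of rsIDs and/or variant keys (may be empty).
#' @return `x` with `variants$in_dbsnp` set; matrices untouched.
#' @export
annotate_dbsnp <- function(x, id_set) {
  stopifnot(inherits(x, "genotype_matrix"))
  id_set <- as.character(id_set)
  hit_id <- !is.na(x$variants$var_id) & x$variants$var_id %in% id_set
  hit_key <- variant_keys(x) %in% id_set
  x$variants$in_dbsnp <- hit_id | hit_key
  x
}
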