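#' Write a genotype matrix as a TSV quartet
#'
#' Canonical plain-text interchange format: four tab-separated files
#' (`gt.tsv`, `dp.tsv`, `ad.tsv`, `gq.tsv`) with a `variant` key column
#' (`"chrom:pos:ref:alt"`) and one column per cell, plus a `variants.tsv`
#' carrying per-variant metadata (rsID, dbSNP/anchor/multi-alt flags). Missing
#' genotypes and qualities are written as the literal token `NA`. Output is
#' byte-stable for a fixed input.
#'
#' @param x a `genotype_matrix`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the five file paths, invisibly.
#' @export
write_matrix_tsv <- function(x, out_dir) {
  stopifnot(inherits(x, "genotype_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  keys <- variant_keys(x)
  paths <- c(gt = file.path(out_dir, "gt.tsv"),
             dp = file.path(out_dir, "dp.tsv"),
             ad = file.path(out_dir, "ad.tsv"),
             gq = file.path(out_dir, "gq.tsv"),
             variants = file.path(out_dir, "variants.tsv"))
  write_one <- function(m, path) {
    df <- data.frame(variant = keys, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  write_one(x$GT, paths["gt"])
  write_one(x$DP, paths["dp"])
  write_one(x$AD, paths["ad"])
  write_one(x$GQ, paths["gq"])
  meta <- cbind(variant = keys,
                x$variants[, c("var_id", "in_dbsnp", "is_anchor", "multi_alt")])
  utils::write.table(meta, paths["variants"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(paths)
}

#' Read a genotype matrix from a TSV quartet
#'
#' Inverse of [write_matrix_tsv()]. All four files must carry identical
#' variant keys and cell columns in identical order; any mismatch is an error
#' naming the offending keys, never silently reconciled.
#'
#' @param gt_path either the directory written by [write_matrix_tsv()] or the
#'   path to the GT file.
#' @param dp_path,ad_path,gq_path paths to the DP/AD/GQ files (ignored when
#'   `gt_path` is a directory).
#' @param variants_path optional path to the metadata file; when present,
#'   rsIDs and dbSNP/anchor/multi-alt flags are restored.
#' @return a `genotype_matrix`.
#' @export
read_matrix_tsv <- function(gt_path, dp_path = NULL, ad_path = NULL,
                            gq_path = NULL, variants_path = NULL) {
  if (dir.exists(gt_path)) {
    dir <- gt_path
    gt_path <- file.path(dir, "gt.tsv")
    dp_path <- file.path(dir, "dp.tsv")
    ad_path <- file.path(dir, "ad.tsv")
    gq_path <- file.path(dir, "gq.tsv")
    vp <- file.path(dir, "variants.tsv")
    if (is.null(variants_path) && file.exists(vp)) variants_path <- vp
  }
  read_one <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = NA,
                            stringsAsFactors = FALSE)
    if (names(df)[1] != "variant")
      stop("first column of ", path, " must be 'variant'")
    df
  }
  gt <- read_one(gt_path); dp <- read_one(dp_path)
  ad <- read_one(ad_path); gq <- read_one(gq_path)

  ref_keys <- gt$variant
  ref_cells <- names(gt)[-1]
  check <- function(df, what) {
    if (!identical(df$variant, ref_keys)) {
      bad <- union(setdiff(df$variant, ref_keys), setdiff(ref_keys, df$variant))
      if (length(bad) == 0L) bad <- "(same keys, different order)"
      stop(what, " variant keys disagree with GT file: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (!identical(names(df)[-1], ref_cells))
      stop(what, " cell columns disagree with GT file (order matters): ",
           paste(utils::head(setdiff(names(df)[-1], ref_cells), 5),
                 collapse = ", "))
  }
  check(dp, "DP"); check(ad, "AD"); check(gq, "GQ")

  parts <- strsplit(ref_keys, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("malformed variant key(s): ",
         paste(utils::head(ref_keys[lengths(parts) != 4L], 5), collapse = ", "))
  variants <- data.frame(chrom = vapply(parts, `[`, "", 1),
                         pos = as.integer(vapply(parts, `[`, "", 2)),
                         ref = vapply(parts, `[`, "", 3),
                         alt = vapply(parts, `[`, "", 4),
                         stringsAsFactors = FALSE)
  if (!is.null(variants_path)) {
    meta <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
    m <- match(ref_keys, meta$variant)
    if (anyNA(m)) stop("variants metadata file missing keys: ",
                       paste(utils::head(ref_keys[is.na(m)], 5), collapse = ", "))
    variants$var_id <- as.character(meta$var_id[m])
    variants$in_dbsnp <- as.logical(meta$in_dbsnp[m])
    variants$is_anchor <- as.logical(meta$is_anchor[m])
    variants$multi_alt <- as.logical(meta$multi_alt[m])
  }
  to_mat <- function(df) as.matrix(df[, -1, drop = FALSE])
  genotype_matrix(variants, ref_cells, to_mat(gt), to_mat(dp), to_mat(ad),
                  to_mat(gq))
}

#' Read a dbSNP membership list
#'
#' One identifier per line (rsIDs or `"chrom:pos:ref:alt"` keys); blank lines
#' and `#` comments ignored.
#'
#' @param path text file path.
#' @return character vector of identifiers.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
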