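#' Read per-nucleus genotypes from a multi-sample VCF
#'
#' Ingests a VCF 4.2 file with one sample column per nucleus, as exported from
#' single-cell genotyping pipelines. FORMAT must contain `GT`; `AD`, `DP` and
#' `GQ` are used when present. Diploid genotypes map to codes as `0/0` -> REF,
#' `0/1`/`1/0` -> HET, `1/1` -> HOM and `./.` -> missing; phased separators
#' (`|`) are treated like `/`.
#'
#' Multi-allelic records are split into one biallelic row per alternate
#' allele. A cell heterozygous for two different alternate alleles (e.g.
#' `1/2`) is recorded as HET on both rows and the affected rows are flagged
#' `multi_alt = TRUE` (consumed by [flag_confounded_snps()]).
#'
#' Missing per-cell fields degrade gracefully: absent AD -> 0 alternate reads,
#' absent DP -> sum of AD (0 if both absent), absent GQ -> `NA`; one summary
#' warning reports how many fields were missing.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return a `genotype_matrix`. rsIDs from the ID column populate `var_id`.
#' @export
read_cell_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF '", path, "' has zero sample columns")
  fix <- v@fix
  cells <- colnames(gt_raw)[-1]
  n_rec <- nrow(fix)
  n_missing_fields <- 0L

  rows <- list()
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    keys <- strsplit(gt_raw[i, 1], ":", fixed = TRUE)[[1]]
    if (!"GT" %in% keys)
      stop("VCF record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " lacks GT in FORMAT")
    fields <- strsplit(gt_raw[i, -1], ":", fixed = TRUE)
    get_field <- function(f, key) {
      j <- match(key, keys)
      if (is.na(j) || j > length(f)) NA_character_ else f[[j]]
    }
    gts <- vapply(fields, get_field, "", key = "GT")
    ads <- vapply(fields, get_field, "", key = "AD")
    dps <- vapply(fields, get_field, "", key = "DP")
    gqs <- vapply(fields, get_field, "", key = "GQ")
    n_missing_fields <- n_missing_fields +
      sum(is.na(ads) | ads == ".") + sum(is.na(dps) | dps == ".") +
      sum(is.na(gqs) | gqs == ".")

    alleles <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
    ad_list <- lapply(ads, function(a) {
      if (is.na(a) || a == ".") return(integer(0))
      suppressWarnings(as.integer(strsplit(a, ",", fixed = TRUE)[[1]]))
    })
    dp_num <- suppressWarnings(as.integer(dps))
    gq_num <- suppressWarnings(as.integer(gqs))

    for (a in seq_along(alts)) {
      gt_code <- integer(length(cells))
      multi <- FALSE
      for (s in seq_along(cells)) {
        al <- alleles[[s]]
        if (length(al) == 0L || any(al == ".") || any(is.na(al))) {
          gt_code[s] <- NA_integer_
          next
        }
        al <- as.integer(al)
        n_this <- sum(al == a)
        gt_code[s] <- if (n_this == 0L) GT_REF
                      else if (n_this == length(al)) GT_HOM
                      else GT_HET
        if (length(unique(al[al > 0L])) > 1L && n_this >= 1L) multi <- TRUE
      }
      ad_alt <- vapply(ad_list, function(z) {
        if (length(z) >= a + 1L && !is.na(z[a + 1L])) z[a + 1L] else 0L
      }, 0L)
      dp_row <- ifelse(is.na(dp_num),
                       vapply(ad_list, function(z) {
                         if (length(z)) sum(z, na.rm = TRUE) else 0L
                       }, 0L),
                       dp_num)
      dp_row <- pmax(dp_row, ad_alt)
      rows[[length(rows) + 1L]] <- list(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a],
        var_id = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".")
          NA_character_ else fix[i, "ID"],
        multi_alt = multi,
        gt = gt_code, dp = as.integer(dp_row), ad = ad_alt, gq = gq_num)
    }
  }
  if (n_missing_fields > 0L)
    warning(n_missing_fields,
            " missing AD/DP/GQ sample fields treated as 0/NA", call. = FALSE)

  variants <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 0L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    var_id = vapply(rows, `[[`, "", "var_id"),
    multi_alt = vapply(rows, `[[`, FALSE, "multi_alt"),
    stringsAsFactors = FALSE)
  pull <- function(name) t(vapply(rows, `[[`, integer(length(cells)), name))
  genotype_matrix(variants, cells, pull("gt"), pull("dp"), pull("ad"),
                  pull("gq"))
}
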