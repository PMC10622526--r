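#' Genotype-filter thresholds
#'
#' Per-cell genotype refinement thresholds in the style of targeted
#' single-cell DNA pipelines. Defaults are the standard mosaic-style values:
#' minimum depth 10 reads, minimum genotype quality 30, VAF bands of at most
#' 5% for a reference call, at least 95% for a homozygous-alternate call and
#' at least 15% for a heterozygous call, with variant-level retention
#' requiring genotypes in at least 75% of cells and mutant (het or hom) calls
#' in at least 50% of genotyped cells.
#'
#' @param min_depth minimum total reads for a call (below -> missing).
#' @param min_gq minimum genotype quality (below -> missing).
#' @param vaf_ref_max maximum VAF (percent) for a REF call.
#' @param vaf_hom_min minimum VAF (percent) for a HOM call.
#' @param vaf_het_min minimum VAF (percent) for a HET call; VAFs in the
#'   ambiguous band between `vaf_ref_max` and `vaf_het_min` become missing.
#' @param min_pct_cells_genotyped variant retention: percent of cells with a
#'   non-missing genotype.
#' @param min_pct_cells_mutant variant retention: percent of *genotyped* cells
#'   called HET or HOM.
#' @return a `filter_thresholds` object.
#' @export
filter_thresholds <- function(min_depth = 10, min_gq = 30, vaf_ref_max = 5,
                              vaf_hom_min = 95, vaf_het_min = 15,
                              min_pct_cells_genotyped = 75,
                              min_pct_cells_mutant = 50) {
  t <- list(min_depth = min_depth, min_gq = min_gq, vaf_ref_max = vaf_ref_max,
            vaf_hom_min = vaf_hom_min, vaf_het_min = vaf_het_min,
            min_pct_cells_genotyped = min_pct_cells_genotyped,
            min_pct_cells_mutant = min_pct_cells_mutant)
  pct <- unlist(t[c("vaf_ref_max", "vaf_hom_min", "vaf_het_min",
                    "min_pct_cells_genotyped", "min_pct_cells_mutant")])
  if (any(pct < 0) || any(pct > 100)) stop("percent thresholds must be in [0, 100]")
  if (!(vaf_ref_max < vaf_het_min && vaf_het_min <= vaf_hom_min))
    stop("need vaf_ref_max < vaf_het_min <= vaf_hom_min")
  structure(t, class = "filter_thresholds")
}

#' Call a genotype from depth, quality and alternate-read count
#'
#' Vectorized elementwise genotype caller. A site-cell is missing when depth
#' or quality is below threshold; otherwise the VAF `100 * ad_alt / dp`
#' determines the code: `<= vaf_ref_max` REF, `>= vaf_hom_min` HOM,
#' `>= vaf_het_min` HET, and anything in an ambiguous band is missing rather
#' than forced to the nearest code.
#'
#' @param dp total read depth (non-negative).
#' @param gq genotype quality; `NA` quality gates on depth only.
#' @param ad_alt alternate-allele read count, `<= dp`.
#' @param t a [filter_thresholds()].
#' @return integer genotype codes (`GT_REF`/`GT_HET`/`GT_HOM`/`NA`).
#' @export
call_genotype <- function(dp, gq, ad_alt, t = filter_thresholds()) {
  if (any(dp == 0 & ad_alt > 0, na.rm = TRUE))
    stop("ad_alt > 0 with dp = 0 is inconsistent")
  if (any(ad_alt > dp, na.rm = TRUE)) stop("ad_alt cannot exceed dp")
  n <- max(length(dp), length(gq), length(ad_alt))
  dp <- rep_len(dp, n); gq <- rep_len(gq, n); ad_alt <- rep_len(ad_alt, n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(dp) & dp >= t$min_depth & (is.na(gq) | gq >= t$min_gq)
  vaf <- ifelse(dp > 0, 100 * ad_alt / dp, 0)
  out[ok & vaf <= t$vaf_ref_max] <- GT_REF
  out[ok & vaf >= t$vaf_hom_min] <- GT_HOM
  out[ok & vaf >= t$vaf_het_min & vaf < t$vaf_hom_min] <- GT_HET
  out
}

#' Recompute all genotype calls of a matrix from DP/AD/GQ
#'
#' Applies [call_genotype()] elementwise; idempotent (the call depends only on
#' the read-level matrices, which are untouched).
#'
#' @param x a `genotype_matrix` with DP/AD (and optionally GQ) populated.
#' @param t a [filter_thresholds()].
#' @return `x` with `GT` replaced by the refined calls.
#' @export
refine_matrix <- function(x, t = filter_thresholds()) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt <- call_genotype(as.vector(x$DP), as.vector(x$GQ), as.vector(x$AD), t)
  x$GT <- matrix(gt, nrow(x$variants), length(x$cell_ids),
                 dimnames = dimnames(x$GT))
  x
}

#' Select germline heterozygous SNVs
#'
#' Variant-level retention for the LOH analysis: keep variants genotyped in at
#' least `min_pct_cells_genotyped` percent of cells, mutant (HET or HOM) in at
#' least `min_pct_cells_mutant` percent of *genotyped* cells, and annotated in
#' dbSNP; optionally drop indels. Whitelisted somatic anchor variants
#' (`is_anchor`) are always retained — somatic variants would not otherwise
#' survive filters designed to extract germline polymorphisms.
#'
#' @param x a refined `genotype_matrix`.
#' @param t a [filter_thresholds()].
#' @param snv_only drop indels (default `TRUE`, limiting the analysis to
#'   single-nucleotide changes to avoid alignment and call biases).
#' @return the subsetted `genotype_matrix`; warns if nothing is retained.
#' @export
select_germline_snvs <- function(x, t = filter_thresholds(), snv_only = TRUE) {
  stopifnot(inherits(x, "genotype_matrix"))
  nc <- length(x$cell_ids)
  n_called <- rowSums(!is.na(x$GT))
  n_mut <- rowSums(x$GT == GT_HET | x$GT == GT_HOM, na.rm = TRUE)
  pct_called <- 100 * n_called / nc
  pct_mut <- ifelse(n_called > 0, 100 * n_mut / n_called, 0)
  keep <- pct_called >= t$min_pct_cells_genotyped &
    pct_mut >= t$min_pct_cells_mutant &
    x$variants$in_dbsnp
  if (snv_only) keep <- keep & !x$variants$is_indel
  keep <- keep | x$variants$is_anchor
  if (!any(keep)) warning("no variants pass germline-SNV selection")
  subset_matrix(x, variants = which(keep))
}

#' High-confidence subset for a candidate deletion region
#'
#' Stringent QC preceding the deletion-missingness test: region variants must
#' have mean depth strictly above `min_depth` (default 50 reads) and retained
#' cells must have strictly more than `min_cell_genotyped_frac` (default 0.5)
#' of their panel-wide genotypes present.
#'
#' @param x a `genotype_matrix`.
#' @param region_variants integer indices or `"chrom:pos:ref:alt"` keys of the
#'   region's variants.
#' @param min_depth mean-depth cutoff (strict `>`).
#' @param min_cell_genotyped_frac per-cell genotyped-fraction cutoff (strict `>`).
#' @return list with `variant_idx` (indices into `x` passing depth QC) and
#'   `cell_ids` (cells passing genotyped-fraction QC).
#' @export
region_high_confidence <- function(x, region_variants, min_depth = 50,
                                   min_cell_genotyped_frac = 0.5) {
  stopifnot(inherits(x, "genotype_matrix"))
  idx <- resolve_variants(x, region_variants)
  if (length(idx) == 0L) stop("empty region")
  mean_dp <- rowMeans(x$DP[idx, , drop = FALSE])
  keep_var <- idx[mean_dp > min_depth]
  frac_called <- colMeans(!is.na(x$GT))
  keep_cell <- x$cell_ids[frac_called > min_cell_genotyped_frac]
  list(variant_idx = keep_var, cell_ids = keep_cell)
}

# map variant keys or indices onto row indices
resolve_variants <- function(x, region_variants) {
  if (is.character(region_variants)) {
    idx <- match(region_variants, variant_keys(x))
    if (anyNA(idx))
      stop("variants not in matrix: ",
           paste(region_variants[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(region_variants)
    if (any(idx < 1L | idx > nrow(x$variants)))
      stop("variant index out of range")
    idx
  }
}
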