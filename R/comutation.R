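#' Co-mutation test configuration
#'
#' Read-level evidence thresholds for calling a cell mutant at a somatic
#' variant, and the droplet-loading rate for the doublet null. All read
#' thresholds are strict (`>`): depth above 20 at *all* tested loci for a cell
#' to be evaluable, alternate-allele count above 10 and alternate-allele
#' frequency above 0.1 for a mutant call. Heterozygous and homozygous calls
#' count identically as mutant.
#'
#' @param min_depth evaluability depth threshold (strict `>`, default 20).
#' @param min_alt_count mutant-call alternate-read threshold (strict `>`,
#'   default 10).
#' @param min_aaf mutant-call alternate-allele-frequency threshold (strict
#'   `>`, default 0.1).
#' @param loading_lambda mean nuclei per droplet of the Poisson loading model
#'   (default 0.1).
#' @return a `comut_config` object.
#' @export
comut_config <- function(min_depth = 20, min_alt_count = 10, min_aaf = 0.1,
                         loading_lambda = 0.1) {
  stopifnot(min_depth > 0, min_alt_count > 0, min_aaf > 0, loading_lambda > 0)
  structure(list(min_depth = min_depth, min_alt_count = min_alt_count,
                 min_aaf = min_aaf, loading_lambda = loading_lambda),
            class = "comut_config")
}

#' Per-cell mutant status at a somatic variant
#'
#' A cell is unevaluable unless its depth exceeds `min_depth` at *every*
#' variant in `all_variants` (the full set of loci under joint test); among
#' evaluable cells it is mutant iff the alternate-read count and
#' alternate-allele frequency at `variant` exceed their thresholds.
#'
#' @param x a `genotype_matrix`.
#' @param variant key or index of the tested variant.
#' @param cfg a [comut_config()].
#' @param all_variants keys/indices of all loci in the joint test (defaults to
#'   `variant` alone).
#' @return character vector per cell: `"mutant"`, `"wildtype"` or
#'   `"unevaluable"`.
#' @export
mutant_status <- function(x, variant, cfg = comut_config(),
                          all_variants = variant) {
  i <- resolve_variants(x, variant)
  stopifnot(length(i) == 1L)
  all_idx <- resolve_variants(x, all_variants)
  evaluable <- colSums(x$DP[all_idx, , drop = FALSE] > cfg$min_depth) ==
    length(all_idx)
  ad <- x$AD[i, ]
  dp <- x$DP[i, ]
  aaf <- ifelse(dp > 0, ad / dp, 0)
  out <- ifelse(!evaluable, "unevaluable",
                ifelse(ad > cfg$min_alt_count & aaf > cfg$min_aaf,
                       "mutant", "wildtype"))
  stats::setNames(out, x$cell_ids)
}

#' Co-occurrence table of two mutant-status vectors
#'
#' @param status_a,status_b per-cell statuses from [mutant_status()] over the
#'   same cells; cells unevaluable in either are dropped.
#' @return 2x2 integer matrix with rows `A+`/`A-` and columns `B+`/`B-`,
#'   summing to the evaluable-cell count.
#' @export
cooccurrence_table <- function(status_a, status_b) {
  stopifnot(length(status_a) == length(status_b))
  keep <- status_a != "unevaluable" & status_b != "unevaluable"
  a <- status_a[keep] == "mutant"
  b <- status_b[keep] == "mutant"
  if (sum(keep) < 2L) stop("fewer than 2 evaluable cells")
  matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
         2, 2, byrow = TRUE,
         dimnames = list(c("A+", "A-"), c("B+", "B-")))
}

#' Two-tailed chi-squared test of co-occurrence
#'
#' Pearson chi-squared test of independence on the 2x2 table, without
#' continuity correction. If any expected count is zero the p-value is
#' undefined and returned as `NA` with a warning.
#'
#' @param table 2x2 co-occurrence matrix.
#' @return two-tailed p-value (or `NA`).
#' @export
chi_squared_cooccurrence <- function(table) {
  stopifnot(all(dim(table) == c(2L, 2L)))
  exp_counts <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(exp_counts == 0)) {
    warning("expected count 0 in a cell; chi-squared p undefined")
    return(NA_real_)
  }
  suppressWarnings(stats::chisq.test(table, correct = FALSE)$p.value)
}

#' Multiplet fraction of observed barcodes under Poisson loading
#'
#' With nuclei loaded into droplets at rate `lambda`, the fraction of
#' *occupied* droplets (observed barcodes) that contain two or more nuclei is
#' `P(N >= 2 | N >= 1) = (1 - e^-lambda - lambda e^-lambda)/(1 - e^-lambda)`.
#'
#' @param loading_lambda mean nuclei per droplet (> 0).
#' @return multiplet fraction in `(0, 1)`.
#' @export
doublet_fraction <- function(loading_lambda) {
  stopifnot(loading_lambda > 0)
  p0 <- exp(-loading_lambda)
  (1 - p0 - loading_lambda * p0) / (1 - p0)
}

#' Expected doublet-driven double mutants under exclusive clones
#'
#' Null model: variants A and B live in separate clonal populations with cell
#' fractions `f = 2 * VAF` (heterozygous clone assumption). A barcode is then
#' a double mutant only when a doublet co-encapsulates one A-clone and one
#' B-clone nucleus: `E = n_cells * doublet_frac * 2 * f_A * f_B` (the factor
#' 2 counts the unordered clone pairing, validated against droplet
#' simulation).
#'
#' @param n_cells observed barcodes entering the test.
#' @param vaf_a,vaf_b variant allele frequencies of A and B.
#' @param doublet_frac multiplet fraction (see [doublet_fraction()]).
#' @return expected double-mutant barcode count.
#' @export
expected_doublet_multimutants <- function(n_cells, vaf_a, vaf_b,
                                          doublet_frac) {
  f_a <- 2 * vaf_a
  f_b <- 2 * vaf_b
  if (f_a + f_b > 1)
    stop("clone fractions 2*VAF sum to > 1; clones cannot be exclusive")
  n_cells * doublet_frac * 2 * f_a * f_b
}

#' Upper-tail Poisson p-value for multi-mutant enrichment
#'
#' `P(X >= observed)` for `X ~ Poisson(expected)`. A zero expectation is
#' replaced by `expected_floor`.
#'
#' @param observed observed multi-mutant count.
#' @param expected expected count under the exclusive-clone doublet null.
#' @param expected_floor pseudo-expectation used when `expected` is 0
#'   (default 1e-6).
#' @return upper-tail p-value.
#' @export
poisson_pvalue <- function(observed, expected, expected_floor = 1e-6) {
  if (expected <= 0) expected <- expected_floor
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Full co-mutation enrichment test for two somatic variants
#'
#' Builds per-cell statuses, the 2x2 co-occurrence table, the two-tailed
#' chi-squared p-value, and the doublet-aware Poisson p-value comparing the
#' observed double-mutant count with the exclusive-clone expectation. Clone
#' fractions are estimated from the evaluable-cell mutant fractions as
#' `f = mutant fraction` (each mutant cell carries the variant, het or hom
#' alike), i.e. `VAF = f / 2`.
#'
#' @param x a `genotype_matrix`.
#' @param variant_a,variant_b keys/indices of the two somatic variants.
#' @param cfg a [comut_config()].
#' @return list: `n_cells`, `table`, `chi2_p`, `expected_multimutants`,
#'   `observed_multimutants`, `poisson_p`.
#' @export
comutation_test <- function(x, variant_a, variant_b, cfg = comut_config()) {
  loci <- c(resolve_variants(x, variant_a), resolve_variants(x, variant_b))
  sa <- mutant_status(x, variant_a, cfg, all_variants = loci)
  sb <- mutant_status(x, variant_b, cfg, all_variants = loci)
  tab <- cooccurrence_table(sa, sb)
  n <- sum(tab)
  f_a <- sum(tab[1, ]) / n
  f_b <- sum(tab[, 1]) / n
  dfrac <- doublet_fraction(cfg$loading_lambda)
  expd <- expected_doublet_multimutants(n, f_a / 2, f_b / 2, dfrac)
  list(n_cells = n, table = tab,
       chi2_p = chi_squared_cooccurrence(tab),
       observed_multimutants = tab[1, 1],
       expected_multimutants = expd,
       poisson_p = poisson_pvalue(tab[1, 1], expd))
}
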