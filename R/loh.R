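#' Partition cells by an anchor somatic variant
#'
#' Nuclei heterozygous for the anchor somatic variant (e.g. an activating
#' PIK3CA hotspot mutation) form the lesion-clone ("GoF") group; nuclei called
#' reference form the wild-type group. Cells homozygous or missing at the
#' anchor are excluded from both groups: homozygous anchor calls are often
#' driven by allelic dropout or chromosomal loss, and missing calls give no
#' clone information.
#'
#' @param x a `genotype_matrix`.
#' @param anchor variant key `"chrom:pos:ref:alt"`, row index, or `NULL` to
#'   use the unique variant flagged `is_anchor`.
#' @return a `cell_partition`: list with character vectors `gof_cells`,
#'   `wt_cells`, `excluded_cells` (disjoint, covering all cells).
#' @export
partition_by_anchor <- function(x, anchor = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(anchor)) {
    idx <- which(x$variants$is_anchor)
    if (length(idx) != 1L)
      stop("need exactly one is_anchor variant (found ", length(idx),
           "); pass `anchor` explicitly")
  } else {
    idx <- resolve_variants(x, anchor)
    if (length(idx) != 1L) stop("anchor must identify a single variant")
  }
  g <- x$GT[idx, ]
  gof <- x$cell_ids[!is.na(g) & g == GT_HET]
  wt <- x$cell_ids[!is.na(g) & g == GT_REF]
  if (length(gof) == 0L) stop("no anchor-positive cells (anchor HET in none)")
  structure(list(gof_cells = gof, wt_cells = wt,
                 excluded_cells = setdiff(x$cell_ids, c(gof, wt)),
                 anchor_idx = idx),
            class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat("cell_partition:", length(x$gof_cells), "anchor-het (GoF),",
      length(x$wt_cells), "wild-type,",
      length(x$excluded_cells), "excluded (hom/missing at anchor)\n")
  invisible(x)
}

#' Per-cell proportion of heterozygous calls
#'
#' The core LOH statistic: the fraction of a cell's *non-missing* genotypes in
#' a bin that are heterozygous. Missing genotypes drop out of numerator and
#' denominator — a bin of 6 SNPs with 3 het, 2 hom and 1 missing call gives
#' 3/5 = 0.6. A cell with all bin genotypes missing has an undefined
#' proportion (`NA`) and is excluded from downstream tests.
#'
#' @param gt integer vector of genotype codes for one cell over the bin's SNPs.
#' @return proportion in `[0, 1]`, or `NA` if every genotype is missing.
#' @export
prop_het <- function(gt) {
  called <- !is.na(gt)
  if (!any(called)) return(NA_real_)
  sum(gt[called] == GT_HET) / sum(called)
}

#' Per-cell heterozygous proportions over a bin
#'
#' @param x a `genotype_matrix`.
#' @param bin a bin from [make_snp_bins()] / [make_arm_bins()], or an integer
#'   vector of variant indices.
#' @param cells cell ids to evaluate (default all).
#' @return named numeric vector of proportions (`NA` = undefined).
#' @export
bin_prop_het <- function(x, bin, cells = x$cell_ids) {
  idx <- if (is.list(bin)) bin$snp_idx else as.integer(bin)
  gt <- x$GT[idx, cells, drop = FALSE]
  n_called <- colSums(!is.na(gt))
  n_het <- colSums(gt == GT_HET, na.rm = TRUE)
  ifelse(n_called > 0L, n_het / n_called, NA_real_)
}

make_bin <- function(label, snp_idx, kind) {
  list(label = label, snp_idx = as.integer(snp_idx), kind = kind)
}

#' Sliding or tiling SNP-window bins within chromosome arms
#'
#' Emits bins of `k` consecutive SNPs that never span a centromere. Sliding
#' mode (default, step 1) tests every window of `k` consecutive within-arm
#' SNPs; tiling mode emits disjoint consecutive blocks, dropping a trailing
#' remainder. Arms with fewer than `k` SNPs produce no bins.
#'
#' @param x a `genotype_matrix` (variants sorted by position).
#' @param k SNPs per bin (>= 2; default 4).
#' @param mode `"sliding"` or `"tiling"`.
#' @param arms an [arm_table()].
#' @return list of bins (`label`, `snp_idx`, `kind = "window"`).
#' @export
make_snp_bins <- function(x, k = 4, mode = c("sliding", "tiling"),
                          arms = arm_table()) {
  stopifnot(inherits(x, "genotype_matrix"), k >= 2)
  mode <- match.arg(mode)
  arm <- variant_arms(x, arms)
  bins <- list()
  for (a in unique(arm)) {
    idx <- which(arm == a)
    if (length(idx) < k) next
    starts <- if (mode == "sliding") seq_len(length(idx) - k + 1L)
              else seq(1L, length(idx) - k + 1L, by = k)
    for (s in starts) {
      sel <- idx[s:(s + k - 1L)]
      bins[[length(bins) + 1L]] <- make_bin(
        sprintf("%s:%d-%d", a, x$variants$pos[sel[1L]],
                x$variants$pos[sel[k]]),
        sel, "window")
    }
  }
  bins
}

#' One bin per chromosome arm
#'
#' Arm bins contain every retained SNP on the arm; single-SNP arms are
#' allowed, empty arms omitted.
#'
#' @inheritParams make_snp_bins
#' @return list of bins (`kind = "arm"`), labelled e.g. `"7q"`.
#' @export
make_arm_bins <- function(x, arms = arm_table()) {
  stopifnot(inherits(x, "genotype_matrix"))
  arm <- variant_arms(x, arms)
  lapply(unique(arm), function(a) make_bin(a, which(arm == a), "arm"))
}

#' One-sided rank-sum comparison of heterozygous proportions
#'
#' Tests whether cells carrying the anchor variant have stochastically
#' *smaller* per-cell heterozygous proportions than wild-type cells over a bin
#' — the signature of loss-of-heterozygosity in the lesion clone. Ties are
#' handled by midranks. When both groups have at most `exact_max` cells the
#' p-value is the exact permutation tail over all group relabelings;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used.
#'
#' @param x a `genotype_matrix`.
#' @param partition a [partition_by_anchor()] result.
#' @param bin a bin (see [make_snp_bins()]).
#' @param min_cells minimum cells with a defined proportion required in each
#'   group (default 5); below it the bin is flagged untested, not an error.
#' @param exact_max exact-permutation cutoff per group (default 8).
#' @return one-row data.frame: `label`, `kind`, `n_gof`, `n_wt`,
#'   `median_gof`, `median_wt`, `statistic` (Mann-Whitney U of the GoF
#'   group), `p_raw` (one-sided), `tested`.
#' @export
loh_test <- function(x, partition, bin, min_cells = 5, exact_max = 8) {
  pg <- bin_prop_het(x, bin, partition$gof_cells)
  pw <- bin_prop_het(x, bin, partition$wt_cells)
  g <- pg[!is.na(pg)]
  w <- pw[!is.na(pw)]
  res <- data.frame(label = bin$label, kind = bin$kind,
                    n_gof = length(g), n_wt = length(w),
                    median_gof = if (length(g)) stats::median(g) else NA_real_,
                    median_wt = if (length(w)) stats::median(w) else NA_real_,
                    statistic = NA_real_, p_raw = NA_real_, tested = FALSE,
                    stringsAsFactors = FALSE)
  if (length(g) < min_cells || length(w) < min_cells) return(res)
  rs <- rank_sum_less(g, w, exact_max = exact_max)
  res$statistic <- rs$U
  res$p_raw <- rs$p
  res$tested <- TRUE
  res
}

# One-sided (first group smaller) Mann-Whitney/Wilcoxon rank-sum p-value.
# Midranks; exact permutation when both groups <= exact_max, else normal
# approximation with tie correction and continuity correction.
rank_sum_less <- function(g, w, exact_max = 8) {
  n1 <- length(g); n2 <- length(w); n <- n1 + n2
  r <- rank(c(g, w))
  W1 <- sum(r[seq_len(n1)])
  U <- W1 - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(sums <= W1 + 1e-9)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    p <- stats::pnorm((U + 0.5 - mu) / sqrt(sigma2))
  }
  list(U = U, p = min(1, p))
}

#' Bonferroni correction over a family of bin tests
#'
#' Adjusts raw one-sided p-values by the number of bins actually tested in
#' the family (untested bins contribute no inference and do not inflate `m`),
#' capping at 1.
#'
#' @param results data.frame of stacked [loh_test()] rows from one family
#'   (one sample, one bin kind).
#' @param alpha family-wise significance level (default 0.05).
#' @return `results` with columns `m`, `p_adj` and `significant` added.
#' @export
bonferroni <- function(results, alpha = 0.05) {
  m <- sum(results$tested)
  results$m <- m
  results$p_adj <- ifelse(results$tested, pmin(1, m * results$p_raw), NA_real_)
  results$significant <- !is.na(results$p_adj) & results$p_adj < alpha
  results
}

#' Run the LOH scan over a set of bins
#'
#' Convenience wrapper: [loh_test()] on every bin, Bonferroni-corrected as one
#' family.
#'
#' @inheritParams loh_test
#' @param bins list of bins of one kind.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame, one row per bin, ordered as `bins`.
#' @export
loh_scan <- function(x, partition, bins, min_cells = 5, alpha = 0.05,
                     exact_max = 8) {
  rows <- lapply(bins, function(b)
    loh_test(x, partition, b, min_cells = min_cells, exact_max = exact_max))
  bonferroni(do.call(rbind, rows), alpha = alpha)
}

#' Per-SNP heterozygous-call proportions by cell group
#'
#' The basis of per-locus bar charts: for every variant, the fraction of
#' genotyped cells called heterozygous, separately in anchor-mutant and
#' wild-type cells. Groups with zero genotyped cells yield `NA`.
#'
#' @param x a `genotype_matrix`.
#' @param partition a [partition_by_anchor()] result.
#' @return data.frame: `variant`, `arm`-free location columns, `n_gof_called`,
#'   `prop_gof`, `n_wt_called`, `prop_wt`.
#' @export
per_snp_het_proportion <- function(x, partition) {
  prop_grp <- function(cells) {
    gt <- x$GT[, cells, drop = FALSE]
    n_called <- rowSums(!is.na(gt))
    n_het <- rowSums(gt == GT_HET, na.rm = TRUE)
    list(n = n_called, p = ifelse(n_called > 0L, n_het / n_called, NA_real_))
  }
  g <- prop_grp(partition$gof_cells)
  w <- prop_grp(partition$wt_cells)
  data.frame(variant = variant_keys(x),
             chrom = x$variants$chrom, pos = x$variants$pos,
             n_gof_called = g$n, prop_gof = g$p,
             n_wt_called = w$n, prop_wt = w$p,
             stringsAsFactors = FALSE)
}

#' Binomial test for deletion-driven genotype missingness
#'
#' A region lost on one allele in cells that also carry a germline deletion of
#' the other allele yields *no* genotypes at all: every region SNP missing.
#' This test asks whether complete-region missingness is enriched in
#' anchor-mutant cells. Each GoF cell scores 1 if all region SNPs are missing,
#' 0 otherwise; the null all-missing rate `p0` is estimated from wild-type
#' cells, floored at `p0_floor` (default half a pseudo-count, `1/(2 n_wt)`)
#' when no wild-type cell is all-missing. The p-value is the exact upper
#' binomial tail `P(X >= k | n, p0)`.
#'
#' Apply [region_high_confidence()] first so that missingness reflects the
#' deletion rather than poor amplicons or low-quality cells.
#'
#' @param x a `genotype_matrix`.
#' @param partition a [partition_by_anchor()] result.
#' @param region_variants indices or keys of the region's SNPs.
#' @param cells optional cell-id subset (e.g. the QC-passing cells from
#'   [region_high_confidence()]).
#' @param p0_floor pseudo-rate used when the wild-type all-missing rate is 0;
#'   `NULL` (default) uses `1/(2 * n_wt)`.
#' @return list: `k` (all-missing GoF cells), `n` (GoF cells), `p0`, `p`.
#' @export
deletion_missingness_test <- function(x, partition, region_variants,
                                      cells = NULL, p0_floor = NULL) {
  idx <- resolve_variants(x, region_variants)
  if (length(idx) == 0L) stop("empty region after QC")
  gof <- partition$gof_cells
  wt <- partition$wt_cells
  if (!is.null(cells)) {
    gof <- intersect(gof, cells)
    wt <- intersect(wt, cells)
  }
  if (length(gof) < 1L) stop("no anchor-mutant cells in region test")
  if (length(wt) < 1L) stop("no wild-type cells to estimate the null rate")
  all_missing <- function(cc)
    colSums(!is.na(x$GT[idx, cc, drop = FALSE])) == 0L
  k <- sum(all_missing(gof))
  n <- length(gof)
  p0 <- mean(all_missing(wt))
  if (p0 == 0) p0 <- if (is.null(p0_floor)) 1 / (2 * length(wt)) else p0_floor
  p <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
  list(k = k, n = n, p0 = p0, p = p)
}

#' Haplotype bias of homozygous calls within an LOH region
#'
#' Copy-neutral LOH retains one parental haplotype, so homozygous calls at a
#' germline-heterozygous site inside the region should all fall on the *same*
#' allele in LOH cells, while dropout-driven homozygous calls in unaffected
#' cells split between alleles. For each region SNP and cell group the
#' statistic is `max(hom_ref, hom_alt) / (hom_ref + hom_alt)`, in
#' `[0.5, 1]`.
#'
#' A reference (hom-REF) call only counts as homozygous where the site is a
#' *known* germline heterozygous site — otherwise true hom-REF genotypes are
#' indistinguishable from dropout. Sites are taken as germline-het from
#' `germline_het_sites` when supplied (e.g. simulation truth), else from
#' wild-type consensus (called HET in at least half of genotyped WT cells).
#'
#' @param x a `genotype_matrix`.
#' @param partition a [partition_by_anchor()] result.
#' @param region_variants indices or keys of the region's SNPs.
#' @param min_hom_cells minimum homozygous anchor-mutant cells for a SNP to be
#'   reported (default 5).
#' @param germline_het_sites optional indices/keys of known germline-het sites.
#' @return data.frame: `variant`, `n_hom_gof`, `ratio_gof`, `n_hom_wt`,
#'   `ratio_wt` (ratios `NA` when a group has no homozygous calls).
#' @export
haplotype_bias <- function(x, partition, region_variants, min_hom_cells = 5,
                           germline_het_sites = NULL) {
  idx <- resolve_variants(x, region_variants)
  if (is.null(germline_het_sites)) {
    wt_gt <- x$GT[, partition$wt_cells, drop = FALSE]
    n_called <- rowSums(!is.na(wt_gt))
    het_frac <- ifelse(n_called > 0,
                       rowSums(wt_gt == GT_HET, na.rm = TRUE) / n_called, 0)
    is_germ_het <- het_frac >= 0.5
  } else {
    is_germ_het <- rep(FALSE, nrow(x$variants))
    is_germ_het[resolve_variants(x, germline_het_sites)] <- TRUE
  }
  stat_grp <- function(i, cells) {
    g <- x$GT[i, cells]
    hom_alt <- sum(g == GT_HOM, na.rm = TRUE)
    hom_ref <- if (is_germ_het[i]) sum(g == GT_REF, na.rm = TRUE) else 0L
    tot <- hom_alt + hom_ref
    c(n = tot, ratio = if (tot > 0) max(hom_ref, hom_alt) / tot else NA_real_)
  }
  rows <- lapply(idx, function(i) {
    g <- stat_grp(i, partition$gof_cells)
    w <- stat_grp(i, partition$wt_cells)
    data.frame(variant = variant_keys(x)[i],
               n_hom_gof = g["n"], ratio_gof = g["ratio"],
               n_hom_wt = w["n"], ratio_wt = w["ratio"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[out$n_hom_gof >= min_hom_cells, , drop = FALSE]
}

#' Flag SNPs whose heterozygosity inside called LOH regions is suspect
#'
#' SNPs inside a called LOH region that remain heterozygous in most
#' anchor-mutant cells (GoF het proportion > 0.8) are candidates for
#' alignment or call artifacts. They are annotated — never auto-removed —
#' with three reasons: overlapping a panel indel, heterozygous for two
#' alternate alleles at the locus, or within 10 bp of a panel indel.
#'
#' @param x a `genotype_matrix` (its indel variants define proximity).
#' @param loh_region_variants indices or keys of SNPs in called LOH regions.
#' @param partition a [partition_by_anchor()] result.
#' @param het_prop_min GoF het-proportion above which a SNP is investigated
#'   (default 0.8, strict `>`).
#' @param near_bp proximity window to an indel in base pairs (default 10,
#'   inclusive).
#' @return data.frame of investigated SNPs: `variant`, `prop_gof`,
#'   `overlaps_indel`, `multi_alt_het`, `near_indel`.
#' @export
flag_confounded_snps <- function(x, loh_region_variants, partition,
                                 het_prop_min = 0.8, near_bp = 10) {
  idx <- resolve_variants(x, loh_region_variants)
  props <- per_snp_het_proportion(x, partition)
  cand <- idx[!is.na(props$prop_gof[idx]) & props$prop_gof[idx] > het_prop_min]
  indels <- x$variants[x$variants$is_indel, , drop = FALSE]
  rows <- lapply(cand, function(i) {
    v <- x$variants[i, ]
    same <- indels[indels$chrom == v$chrom, , drop = FALSE]
    overlaps <- FALSE; near <- FALSE
    if (nrow(same)) {
      span_end <- same$pos + pmax(nchar(same$ref), nchar(same$alt)) - 1L
      overlaps <- any(v$pos >= same$pos & v$pos <= span_end)
      near <- any(abs(v$pos - same$pos) <= near_bp |
                    abs(v$pos - span_end) <= near_bp)
    }
    data.frame(variant = variant_keys(x)[i], prop_gof = props$prop_gof[i],
               overlaps_indel = overlaps,
               multi_alt_het = isTRUE(v$multi_alt),
               near_indel = near && !overlaps,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(variant = character(), prop_gof = numeric(),
                      overlaps_indel = logical(), multi_alt_het = logical(),
                      near_indel = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
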