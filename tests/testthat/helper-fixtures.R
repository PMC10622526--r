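# Small in-code fixtures shared across test files.

# Genotype matrix from a GT code matrix, with read-level matrices chosen so
# that refine_matrix() reproduces the given calls (dp 100, gq 99; ad 0/50/100
# for REF/HET/HOM; missing entries get gq 0).
gm_from_gt <- function(gt, chrom = "7", start_pos = 1000L, spacing = 1000L,
                       cell_ids = sprintf("c%d", seq_len(ncol(gt))),
                       in_dbsnp = TRUE) {
  gt <- matrix(as.integer(gt), nrow(gt), ncol(gt))
  nv <- nrow(gt)
  variants <- data.frame(
    chrom = rep(chrom, length.out = nv),
    pos = start_pos + spacing * (seq_len(nv) - 1L),
    ref = "A", alt = "G",
    var_id = sprintf("rs%d", seq_len(nv)),
    in_dbsnp = in_dbsnp, stringsAsFactors = FALSE)
  ad <- matrix(0L, nv, ncol(gt))
  ad[gt == 1L] <- 50L
  ad[gt == 2L] <- 100L
  dp <- matrix(100L, nv, ncol(gt))
  gq <- matrix(99L, nv, ncol(gt))
  gq[is.na(gt)] <- 0L
  genotype_matrix(variants, cell_ids, gt, dp, ad, gq)
}

# Independent brute-force oracle: exact one-sided permutation p-value that
# the first group's rank sum is as small or smaller, over all relabelings.
perm_rank_sum_p <- function(g, w) {
  n1 <- length(g)
  r <- rank(c(g, w))
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  mean(apply(combs, 2, function(i) sum(r[i])) <= obs + 1e-9)
}

# partition object built directly from known cell groups (simulation truth)
partition_from_truth <- function(truth) {
  structure(list(
    gof_cells = truth$cells$cell_id[truth$cells$group == "gof"],
    wt_cells = truth$cells$cell_id[truth$cells$group == "wt"],
    excluded_cells = character(0), anchor_idx = NA_integer_),
    class = "cell_partition")
}
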