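test_that("anchor partition groups cells by anchor genotype", {
  gt <- rbind(c(GT_HET, GT_REF, GT_HOM, NA),
              rep(GT_HET, 4))
  gm <- gm_from_gt(gt)
  gm$variants$is_anchor[1] <- TRUE
  p <- partition_by_anchor(gm)
  expect_equal(p$gof_cells, "c1")
  expect_equal(p$wt_cells, "c2")
  expect_setequal(p$excluded_cells, c("c3", "c4"))
  # disjoint cover
  expect_setequal(c(p$gof_cells, p$wt_cells, p$excluded_cells), gm$cell_ids)

  gm_ref <- gm_from_gt(rbind(rep(GT_REF, 4), rep(GT_HET, 4)))
  expect_error(partition_by_anchor(gm_ref, anchor = 1), "no anchor-positive")
})

test_that("prop_het excludes missing calls from both numerator and denominator", {
  expect_equal(prop_het(c(GT_HET, GT_HET, GT_HET, GT_HOM, GT_HOM, NA)), 0.6)
  expect_equal(prop_het(rep(GT_HET, 4)), 1)
  expect_equal(prop_het(c(GT_REF, GT_HOM)), 0)
  expect_true(is.na(prop_het(rep(NA_integer_, 6))))
  # matrix form agrees with the scalar form cell by cell
  set.seed(8)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                      prob = c(.2, .5, .2, .1)), 6, 10)
  gm <- gm_from_gt(gt)
  v <- bin_prop_het(gm, 1:6)
  expect_equal(unname(v), apply(gt, 2, prop_het))
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
})

test_that("window bins slide within arms and never cross the centromere", {
  # 6 SNPs on 7p, 5 on 7q (centromere at 59.9 Mb)
  gm <- gm_from_gt(matrix(GT_HET, 11, 5), start_pos = 1000000L,
                   spacing = 10000000L)
  arms <- variant_arms(gm)
  expect_equal(sum(arms == "7p"), 6L)
  sliding <- make_snp_bins(gm, k = 4, mode = "sliding")
  expect_equal(sum(vapply(sliding, function(b) all(arms[b$snp_idx] == "7p"),
                          TRUE)), 3L)  # 6 - 4 + 1
  expect_equal(sum(vapply(sliding, function(b) all(arms[b$snp_idx] == "7q"),
                          TRUE)), 2L)  # 5 - 4 + 1
  # no bin mixes arms
  expect_true(all(vapply(sliding, function(b)
    length(unique(arms[b$snp_idx])) == 1L, TRUE)))
  tiling <- make_snp_bins(gm, k = 4, mode = "tiling")
  expect_equal(length(tiling), 2L)  # one block per arm, remainders dropped
  # arm bins: one per arm, all SNPs, single-SNP arms allowed
  gm1 <- gm_from_gt(matrix(GT_HET, 1, 5), start_pos = 1000000L)
  expect_equal(length(make_arm_bins(gm1)), 1L)
  ab <- make_arm_bins(gm)
  expect_setequal(vapply(ab, `[[`, "", "label"), c("7p", "7q"))
  expect_equal(sum(lengths(lapply(ab, `[[`, "snp_idx"))), 11L)
})

test_that("rank-sum p matches exhaustive permutation enumeration", {
  # the frozen 3-vs-3 example: complete separation over C(6,3)=20 relabelings
  g <- c(0.25, 0.25, 0.5); w <- c(0.75, 1, 1)
  expect_equal(perm_rank_sum_p(g, w), 1 / 20)
  expect_equal(snloh:::rank_sum_less(g, w)$p, 1 / 20)
  # property: equality over random tied fixtures for all group sizes <= 8
  set.seed(42)
  for (rep in 1:120) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    vals <- sample(seq(0, 1, 0.25), n1 + n2, replace = TRUE)
    g <- vals[seq_len(n1)]; w <- vals[-seq_len(n1)]
    expect_equal(snloh:::rank_sum_less(g, w)$p, perm_rank_sum_p(g, w),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p agrees with wilcox.test on tie-free samples", {
  set.seed(99)
  for (rep in 1:30) {
    g <- runif(6); w <- runif(7)
    expect_equal(snloh:::rank_sum_less(g, w)$p,
                 wilcox.test(g, w, alternative = "less", exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("loh_test flags separation, symmetry and insufficient cells", {
  gt <- rbind(matrix(rep(c(rep(GT_HOM, 10), rep(GT_HET, 10)), 4), 4, 20,
                     byrow = TRUE))
  gm <- gm_from_gt(gt)
  part <- structure(list(gof_cells = sprintf("c%d", 1:10),
                         wt_cells = sprintf("c%d", 11:20),
                         excluded_cells = character(0)),
                    class = "cell_partition")
  bin <- list(label = "7p", snp_idx = 1:4, kind = "arm")
  res <- loh_test(gm, part, bin)
  expect_true(res$tested)
  expect_lt(res$p_raw, 1e-4)  # GoF all 0 vs WT all 1
  # identical distributions: one-sided p >= 0.5
  gm2 <- gm_from_gt(matrix(GT_HET, 4, 20))
  expect_gte(loh_test(gm2, part, bin)$p_raw, 0.5)
  # too few cells -> untested, not an error
  small <- structure(list(gof_cells = c("c1", "c2"),
                          wt_cells = sprintf("c%d", 11:20),
                          excluded_cells = character(0)),
                     class = "cell_partition")
  expect_false(loh_test(gm, small, bin)$tested)
})

test_that("Bonferroni correction counts only tested bins and caps at one", {
  res <- data.frame(label = c("a", "b", "c"), tested = c(TRUE, TRUE, FALSE),
                    p_raw = c(0.004, 0.3, NA))
  out <- bonferroni(res, alpha = 0.05)
  expect_equal(out$m[1], 2L)          # untested bin excluded from m
  expect_equal(out$p_adj, c(0.008, 0.6, NA))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  one <- bonferroni(data.frame(label = "a", tested = TRUE, p_raw = 0.04))
  expect_equal(one$p_adj, one$p_raw)  # m = 1
  big <- bonferroni(data.frame(label = letters[1:5], tested = TRUE,
                               p_raw = rep(0.3, 5)))
  expect_equal(big$p_adj, rep(1, 5))  # capped
})

test_that("per-SNP heterozygous proportions are computed per group", {
  gt <- rbind(c(rep(GT_HET, 8), rep(GT_HOM, 2), rep(GT_HET, 5)),
              c(rep(NA, 10), rep(GT_HET, 5)))
  gm <- gm_from_gt(gt)
  part <- structure(list(gof_cells = sprintf("c%d", 11:15),
                         wt_cells = sprintf("c%d", 1:10),
                         excluded_cells = character(0)),
                    class = "cell_partition")
  tab <- per_snp_het_proportion(gm, part)
  expect_equal(tab$prop_wt[1], 0.8)   # 8 of 10 genotyped WT cells het
  expect_equal(tab$prop_gof[1], 1)
  expect_true(is.na(tab$prop_wt[2]))  # zero genotyped WT cells
  expect_true(all(tab$prop_gof >= 0 & tab$prop_gof <= 1, na.rm = TRUE))
})

test_that("deletion-missingness test equals the exact binomial upper tail", {
  # oracle: direct summation of the binomial mass over outcomes k..n
  direct_tail <- function(k, n, p0)
    sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
  # 9 of 12 anchor cells all-missing, WT all-missing rate 0.5 by construction
  gof_gt <- cbind(matrix(NA_integer_, 5, 9), matrix(GT_HET, 5, 3))
  wt_gt <- cbind(matrix(NA_integer_, 5, 10), matrix(GT_HET, 5, 10))
  gm <- gm_from_gt(cbind(gof_gt, wt_gt),
                   cell_ids = c(sprintf("g%d", 1:12), sprintf("w%d", 1:20)))
  part <- structure(list(gof_cells = sprintf("g%d", 1:12),
                         wt_cells = sprintf("w%d", 1:20),
                         excluded_cells = character(0)),
                    class = "cell_partition")
  res <- deletion_missingness_test(gm, part, 1:5)
  expect_equal(res$k, 9L)
  expect_equal(res$n, 12L)
  expect_equal(res$p0, 0.5)
  expect_equal(res$p, direct_tail(9, 12, 0.5), tolerance = 1e-12)
  # k = 0 -> upper tail P(X >= 0) = 1
  gm0 <- gm_from_gt(matrix(GT_HET, 5, 32),
                    cell_ids = c(sprintf("g%d", 1:12), sprintf("w%d", 1:20)))
  expect_equal(deletion_missingness_test(gm0, part, 1:5)$p, 1)
  # zero WT all-missing rate floored at 1/(2 n_wt)
  gm_f <- gm_from_gt(cbind(matrix(NA_integer_, 5, 12), matrix(GT_HET, 5, 20)),
                     cell_ids = c(sprintf("g%d", 1:12), sprintf("w%d", 1:20)))
  res_f <- deletion_missingness_test(gm_f, part, 1:5)
  expect_equal(res_f$p0, 1 / 40)
  expect_equal(deletion_missingness_test(gm_f, part, 1:5,
                                         p0_floor = 0.01)$p0, 0.01)
})

test_that("haplotype bias ratios reflect allele-consistent homozygosity", {
  # GoF: site 1 all hom-alt (ratio 1); site 2 split 5 hom-ref / 5 hom-alt at a
  # germline-het site (ratio 0.5). WT cells het everywhere (consensus source).
  gof_gt <- rbind(rep(GT_HOM, 10), c(rep(GT_REF, 5), rep(GT_HOM, 5)))
  wt_gt <- matrix(GT_HET, 2, 10)
  gm <- gm_from_gt(cbind(gof_gt, wt_gt),
                   cell_ids = c(sprintf("g%d", 1:10), sprintf("w%d", 1:10)))
  part <- structure(list(gof_cells = sprintf("g%d", 1:10),
                         wt_cells = sprintf("w%d", 1:10),
                         excluded_cells = character(0)),
                    class = "cell_partition")
  hb <- haplotype_bias(gm, part, 1:2)
  expect_equal(hb$ratio_gof, c(1, 0.5))
  expect_true(all(hb$ratio_gof >= 0.5 & hb$ratio_gof <= 1))
  # SNPs with too few homozygous GoF cells are excluded
  expect_equal(nrow(haplotype_bias(gm, part, 1:2, min_hom_cells = 11)), 0L)
})

test_that("confounded-SNP flags honour the 10 bp indel window", {
  nc <- 12
  build <- function(snp_pos, indel_pos) {
    gm <- gm_from_gt(matrix(GT_HET, 2, nc))
    gm$variants$pos <- c(snp_pos, indel_pos)
    gm$variants$ref <- c("A", "CA")
    genotype_matrix(gm$variants, gm$cell_ids, gm$GT, gm$DP, gm$AD, gm$GQ)
  }
  part <- structure(list(gof_cells = sprintf("c%d", 1:6),
                         wt_cells = sprintf("c%d", 7:12),
                         excluded_cells = character(0)),
                    class = "cell_partition")
  snp_flag <- function(gm) {
    f <- flag_confounded_snps(gm, which(!gm$variants$is_indel), part)
    expect_equal(nrow(f), 1L)  # the SNP is het in >80% of GoF cells
    f
  }
  # SNP at 1000, indel at 1008: within 10 bp
  expect_true(snp_flag(build(1000L, 1008L))$near_indel)
  # SNP at 1000, indel at 1011: 11 bp away, outside the window
  f_far <- snp_flag(build(1000L, 1011L))
  expect_false(f_far$near_indel)
  expect_false(f_far$overlaps_indel)
  # SNP inside the indel footprint counts as overlapping, not near
  f_in <- snp_flag(build(1009L, 1008L))
  expect_true(f_in$overlaps_indel)
  expect_false(f_in$near_indel)
  # het-two-alt loci propagate the multi_alt flag
  gm <- build(1000L, 1008L)
  gm$variants$multi_alt[1] <- TRUE
  f_ma <- flag_confounded_snps(gm, 1, part)
  expect_true(f_ma$multi_alt_het)
  # SNPs below the GoF het-proportion cutoff are not investigated
  gm_low <- build(1000L, 1008L)
  gm_low$GT[1, 1:6] <- GT_HOM
  expect_equal(nrow(flag_confounded_snps(gm_low, 1, part)), 0L)
})
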