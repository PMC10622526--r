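test_that("call_genotype implements the depth/quality/VAF bands", {
  t <- filter_thresholds()
  expect_equal(call_genotype(100, 99, 50, t), GT_HET)
  expect_true(is.na(call_genotype(9, 99, 9, t)))      # below min depth
  expect_true(is.na(call_genotype(100, 29, 50, t)))   # below min GQ
  expect_true(is.na(call_genotype(100, 99, 10, t)))   # ambiguous 5-15% band
  expect_equal(call_genotype(100, 99, 5, t), GT_REF)  # 5% inclusive
  expect_equal(call_genotype(100, 99, 95, t), GT_HOM) # 95% inclusive
  expect_equal(call_genotype(100, 99, 15, t), GT_HET) # 15% inclusive
  expect_equal(call_genotype(100, NA, 50, t), GT_HET) # absent GQ passes
  expect_error(call_genotype(0, 99, 3, t), "inconsistent")
  expect_error(call_genotype(10, 99, 11, t), "exceed")
})

test_that("call_genotype partitions VAF space and is monotone in VAF", {
  t <- filter_thresholds()
  dp <- 200L
  codes <- call_genotype(rep(dp, dp + 1), 99, 0:dp, t)
  # every valid input maps to exactly one of the four outcomes
  expect_true(all(codes %in% c(GT_REF, GT_HET, GT_HOM) | is.na(codes)))
  # band ordering: REF then HET then HOM, with gaps only between bands
  called <- codes[!is.na(codes)]
  expect_true(all(diff(called) >= 0))
  expect_equal(sort(unique(called)), c(GT_REF, GT_HET, GT_HOM))
})

test_that("refine_matrix is idempotent and honours degenerate inputs", {
  set.seed(5)
  nv <- 8; nc <- 6
  dp <- matrix(rpois(nv * nc, 60), nv, nc)
  ad <- matrix(rbinom(nv * nc, as.vector(dp), 0.5), nv, nc)
  gm <- genotype_matrix(
    data.frame(chrom = "7", pos = 1000L * (1:nv), ref = "A", alt = "G"),
    sprintf("c%d", 1:nc), matrix(NA_integer_, nv, nc), dp, ad,
    matrix(99L, nv, nc))
  once <- refine_matrix(gm)
  expect_identical(refine_matrix(once)$GT, once$GT)

  zero <- genotype_matrix(gm$variants, gm$cell_ids,
                          matrix(NA_integer_, nv, nc))
  expect_true(all(is.na(refine_matrix(zero)$GT)))

  half <- genotype_matrix(gm$variants, gm$cell_ids,
                          matrix(NA_integer_, nv, nc),
                          DP = matrix(100L, nv, nc),
                          AD = matrix(50L, nv, nc),
                          GQ = matrix(99L, nv, nc))
  expect_true(all(refine_matrix(half)$GT == GT_HET))
})

test_that("germline-SNV selection keeps anchors and drops failing variants", {
  nc <- 50
  gt <- rbind(
    rep(GT_HET, nc),                                   # good germline SNP
    c(rep(GT_HET, 4), rep(GT_REF, nc - 4)),            # somatic-like: 8% mutant
    c(rep(GT_HET, 25), rep(NA, nc - 25)),              # genotyped in 50% < 75%
    rep(GT_HET, nc),                                   # indel (set below)
    rep(GT_HET, nc))                                   # not in dbSNP
  gm <- gm_from_gt(gt)
  gm$variants$ref[4] <- "CA"
  gm <- genotype_matrix(gm$variants, gm$cell_ids, gm$GT, gm$DP, gm$AD, gm$GQ)
  gm$variants$in_dbsnp <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  gm$variants$is_anchor <- c(FALSE, TRUE, FALSE, FALSE, FALSE)

  out <- select_germline_snvs(gm)
  keys <- variant_keys(out)
  expect_setequal(keys, variant_keys(gm)[c(1, 2)])  # anchor kept by whitelist
  # idempotent, output subset of input
  expect_identical(variant_keys(select_germline_snvs(out)), keys)
  expect_true(all(keys %in% variant_keys(gm)))
  # indel retained when snv_only = FALSE
  expect_true(variant_keys(gm)[4] %in%
                variant_keys(select_germline_snvs(gm, snv_only = FALSE)))
  # nothing passing warns instead of erroring
  gm2 <- gm
  gm2$variants$in_dbsnp <- FALSE
  gm2$variants$is_anchor <- FALSE
  expect_warning(select_germline_snvs(gm2), "no variants")
})

test_that("region QC uses strict thresholds on depth and cell completeness", {
  nv <- 4; nc <- 10
  gm <- gm_from_gt(matrix(GT_HET, nv, nc))
  gm$DP[1, ] <- 51L  # mean 51 -> kept
  gm$DP[2, ] <- 50L  # mean 50 -> dropped (strict >)
  gm$GT[1:2, 1] <- NA  # cell 1 has exactly 50% genotypes -> dropped
  qc <- region_high_confidence(gm, 1:4)
  expect_true(1 %in% qc$variant_idx)
  expect_false(2 %in% qc$variant_idx)
  expect_false("c1" %in% qc$cell_ids)
  expect_setequal(qc$cell_ids, sprintf("c%d", 2:10))
  expect_error(region_high_confidence(gm, integer(0)), "empty region")
})
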