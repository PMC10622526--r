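#' End-to-end LOH analysis pipeline
#'
#' Runs the full analysis on a genotype matrix: genotype refinement,
#' germline-SNV selection, anchor partition, sliding 4-SNP-bin tests, arm
#' tests (each Bonferroni-corrected as its own family), per-SNP heterozygous
#' proportions, and confounded-SNP flags plus haplotype-bias statistics for
#' significant regions. Result tables are written as TSV when `out_dir` is
#' given; re-running with identical inputs reproduces them byte for byte.
#'
#' @param x a `genotype_matrix` (raw; refinement is applied here), or a
#'   directory/path accepted by [read_matrix_tsv()].
#' @param anchor anchor variant key, or `NULL` to use the `is_anchor` flag.
#' @param thresholds a [filter_thresholds()].
#' @param k SNPs per window bin (default 4).
#' @param bin_mode `"sliding"` or `"tiling"`.
#' @param alpha family-wise significance level (default 0.05).
#' @param arms an [arm_table()].
#' @param min_cells minimum cells per group per bin (default 5).
#' @param snv_only restrict to single-nucleotide variants (default `TRUE`).
#' @param out_dir optional output directory for TSV reports and a run log.
#' @return list: `matrix` (filtered), `partition`, `bin_results`,
#'   `arm_results`, `per_snp`, `flags`, `haplotype_bias`,
#'   `significant_arms`.
#' @export
run_pipeline <- function(x, anchor = NULL, thresholds = filter_thresholds(),
                         k = 4, bin_mode = "sliding", alpha = 0.05,
                         arms = arm_table(), min_cells = 5, snv_only = TRUE,
                         out_dir = NULL) {
  if (is.character(x)) x <- read_matrix_tsv(x)
  stopifnot(inherits(x, "genotype_matrix"))
  m <- refine_matrix(x, thresholds)
  m <- select_germline_snvs(m, thresholds, snv_only = snv_only)
  part <- partition_by_anchor(m, anchor)
  germ <- subset_matrix(m, variants = which(!m$variants$is_anchor))

  bin_res <- loh_scan(germ, part, make_snp_bins(germ, k = k, mode = bin_mode,
                                                arms = arms),
                      min_cells = min_cells, alpha = alpha)
  arm_res <- loh_scan(germ, part, make_arm_bins(germ, arms),
                      min_cells = min_cells, alpha = alpha)
  per_snp <- per_snp_het_proportion(germ, part)
  sig_arms <- arm_res$label[arm_res$significant]

  arm_of <- variant_arms(germ, arms)
  sig_idx <- which(arm_of %in% sig_arms)
  flags <- flag_confounded_snps(germ, sig_idx, part)
  hapb <- if (length(sig_idx))
    haplotype_bias(germ, part, sig_idx) else NULL

  res <- list(matrix = germ, partition = part, bin_results = bin_res,
              arm_results = arm_res, per_snp = per_snp, flags = flags,
              haplotype_bias = hapb, significant_arms = sig_arms,
              alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA")
    wr(bin_res, "bin_tests.tsv")
    wr(arm_res, "arm_tests.tsv")
    wr(per_snp, "per_snp_het.tsv")
    if (nrow(flags)) wr(flags, "confounded_snp_flags.tsv")
    if (!is.null(hapb) && nrow(hapb)) wr(hapb, "haplotype_bias.tsv")
    writeLines(c(
      paste0("snloh ", as.character(utils::packageVersion("snloh"))),
      paste0("cells: ", length(m$cell_ids),
             " (gof ", length(part$gof_cells),
             ", wt ", length(part$wt_cells), ")"),
      paste0("variants after selection: ", nrow(m$variants)),
      paste0("k = ", k, ", bin_mode = ", bin_mode, ", alpha = ", alpha,
             ", min_cells = ", min_cells),
      paste0("significant arms: ",
             if (length(sig_arms)) paste(sig_arms, collapse = ", ")
             else "none")),
      file.path(out_dir, "run_log.txt"))
  }
  res
}

#' Human-readable summary of a pipeline run
#'
#' Text report of the arm-level scan, significant windows, and flagged SNPs.
#' When ggplot2 is installed and `plot = TRUE`, also returns a grouped
#' bar chart of per-SNP heterozygous proportions (anchor-mutant vs
#' wild-type cells) for the significant arms; otherwise the report is
#' text-only.
#'
#' @param res a [run_pipeline()] result.
#' @param plot attempt a ggplot2 bar chart (default `TRUE`).
#' @return list: `text` (character vector of report lines) and `plot` (a
#'   ggplot object or `NULL`).
#' @export
render_report <- function(res, plot = TRUE) {
  lines <- c("LOH analysis report", "===================",
             sprintf("Cells: %d anchor-het (GoF), %d wild-type",
                     length(res$partition$gof_cells),
                     length(res$partition$wt_cells)),
             "")
  arm <- res$arm_results
  lines <- c(lines, "Chromosome-arm tests (one-sided rank-sum, Bonferroni):")
  for (i in seq_len(nrow(arm))) {
    lines <- c(lines, sprintf(
      "  %-6s n_gof=%3d n_wt=%3d med_gof=%s med_wt=%s p_adj=%s%s",
      arm$label[i], arm$n_gof[i], arm$n_wt[i],
      formatC(arm$median_gof[i], digits = 3, format = "f"),
      formatC(arm$median_wt[i], digits = 3, format = "f"),
      if (arm$tested[i]) formatC(arm$p_adj[i], digits = 3, format = "g")
      else "untested",
      if (isTRUE(arm$significant[i])) "  *" else ""))
  }
  lines <- c(lines, "",
             if (length(res$significant_arms))
               paste("Somatic LOH evidence on:",
                     paste(res$significant_arms, collapse = ", "))
             else "No LOH evidence at the configured level.")
  n_sig_bins <- sum(res$bin_results$significant, na.rm = TRUE)
  lines <- c(lines, sprintf("Significant SNP windows: %d of %d tested",
                            n_sig_bins, sum(res$bin_results$tested)))
  if (nrow(res$flags)) {
    lines <- c(lines, "", "Flagged SNPs inside called LOH regions:")
    for (i in seq_len(nrow(res$flags))) {
      reasons <- c("overlaps_indel", "multi_alt_het",
                   "near_indel")[unlist(res$flags[i, c("overlaps_indel",
                                                       "multi_alt_het",
                                                       "near_indel")])]
      lines <- c(lines, sprintf("  %s (GoF het %.2f): %s",
                                res$flags$variant[i], res$flags$prop_gof[i],
                                if (length(reasons))
                                  paste(reasons, collapse = ", ")
                                else "no known confounder"))
    }
  }
  p <- NULL
  if (plot && length(res$significant_arms) &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    arms_of <- variant_arms(res$matrix)
    df <- res$per_snp[arms_of %in% res$significant_arms, ]
    long <- data.frame(
      variant = rep(df$variant, 2),
      pos = rep(df$pos, 2),
      group = rep(c("GoF", "WT"), each = nrow(df)),
      prop = c(df$prop_gof, df$prop_wt))
    p <- ggplot2::ggplot(long,
                         ggplot2::aes(x = factor(pos), y = prop,
                                      fill = group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "SNP position", y = "Proportion heterozygous",
                    title = paste("Per-SNP heterozygosity:",
                                  paste(res$significant_arms,
                                        collapse = ", "))) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         size = 5))
  } else if (plot && length(res$significant_arms)) {
    warning("ggplot2 not available; text-only report")
  }
  list(text = lines, plot = p)
}
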