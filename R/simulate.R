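#' Default simulated amplicon panel
#'
#' A targeted-panel layout mirroring the analysis setting: germline
#' heterozygous SNPs on two chromosomes covered on both arms (25 SNPs per
#' arm), one germline indel, and one somatic anchor site on a third
#' chromosome (the activating-variant hotspot lies on a different chromosome
#' than the LOH region it tags).
#'
#' @param n_snps_per_arm SNPs per covered arm (default 25).
#' @param chroms two chromosomes covered on both arms (default 7 and 11).
#' @param anchor_chrom chromosome of the anchor site (default 3).
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `var_id`, `type`
#'   (`"snp"`, `"indel"` or `"anchor"`), `in_dbsnp`.
#' @export
default_panel <- function(n_snps_per_arm = 25, chroms = c("7", "11"),
                          anchor_chrom = "3") {
  arms <- arm_table()
  rows <- list()
  bases <- c("A", "C", "G", "T")
  rs <- 0L
  for (ch in chroms) {
    cen <- unclass(arms)[[ch]]
    for (arm in c("p", "q")) {
      pos <- if (arm == "p")
        round(seq(1e6, cen - 1e6, length.out = n_snps_per_arm))
      else
        round(seq(cen + 1e6, cen + 60e6, length.out = n_snps_per_arm))
      for (p in pos) {
        rs <- rs + 1L
        ref <- bases[1L + (p %% 4L)]
        alt <- bases[1L + ((p + 1L) %% 4L)]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = as.integer(p), ref = ref, alt = alt,
          var_id = paste0("rs", 100000L + rs), type = "snp",
          in_dbsnp = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  # one germline indel on the q arm of the first chromosome
  cen1 <- unclass(arms)[[chroms[1]]]
  rows[[length(rows) + 1L]] <- data.frame(
    chrom = chroms[1], pos = as.integer(cen1 + 30e6 + 12345L),
    ref = "CA", alt = "C", var_id = paste0("rs", 100000L + rs + 1L),
    type = "indel", in_dbsnp = TRUE, stringsAsFactors = FALSE)
  # somatic anchor hotspot
  rows[[length(rows) + 1L]] <- data.frame(
    chrom = anchor_chrom, pos = 178952085L, ref = "A", alt = "G",
    var_id = NA_character_, type = "anchor", in_dbsnp = FALSE,
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Simulation configuration
#'
#' Defines the generative model for synthetic single-nucleus genotype data:
#' a wild-type population and an anchor-variant (lesion-clone) population, an
#' optional LOH sub-clone over one chromosome arm, allelic dropout, random
#' missingness, negative-binomial read depth and droplet doublets.
#'
#' Per cell and germline site, total depth is negative-binomial
#' (`depth_mean`, `depth_dispersion`); a true heterozygote emits alternate
#' reads Binomial(depth, 0.5) unless an allelic-dropout event (probability
#' `ado_rate`) channels all reads to one uniformly chosen allele — giving a
#' heterozygous-call rate of about `1 - ado_rate` (0.8 at the default).
#' LOH-carrier cells in the region retain one parental haplotype, the same
#' haplotype for every carrier (a clonal event): under `copy_neutral` each
#' region site is driven homozygous for the retained allele with probability
#' `loh_strength` (1 = full clonal LOH; the carrier het-call rate is
#' `(1 - ado_rate) * (1 - loh_strength)`); under `copy_loss` region depth
#' halves and genotypes are additionally forced missing with probability
#' `loh_missing_rate`. Doublet barcodes merge the read counts of the host
#' cell and a freshly drawn partner cell before genotyping. Genotypes are
#' called from the simulated reads through [call_genotype()], so the filter
#' stack is exercised end to end.
#'
#' @param seed integer RNG seed.
#' @param n_wt,n_gof wild-type and anchor-variant cell counts (default 100
#'   and 30).
#' @param frac_gof_loh fraction of anchor-variant cells carrying LOH
#'   (default 1).
#' @param panel panel data.frame (see [default_panel()]).
#' @param loh_region arm label (e.g. `"7q"`) or character vector of panel
#'   variant keys.
#' @param loh_type `"copy_neutral"` or `"copy_loss"`.
#' @param loh_strength per-site penetrance of copy-neutral LOH in carrier
#'   cells (default 1).
#' @param ado_rate allelic-dropout probability per true-het site (default
#'   0.2).
#' @param missing_rate random missing-genotype probability (default 0.05).
#' @param depth_mean,depth_dispersion negative-binomial depth model (defaults
#'   80, 8).
#' @param loh_missing_rate missing probability at region sites of copy-loss
#'   carriers (default 0.9).
#' @param doublet_rate fraction of emitted barcodes that are doublets
#'   (default 0.05).
#' @param clones optional data.frame (`name`, `fraction`) of somatic clones
#'   for co-mutation scenarios; fractions sum to at most 1.
#' @param clone_variants named list mapping clone names to panel variant keys
#'   carried by that clone (truly heterozygous in its cells).
#' @param thresholds [filter_thresholds()] used for genotype calling.
#' @param arms an [arm_table()].
#' @return a `sim_config` object.
#' @export
sim_config <- function(seed = 1, n_wt = 100, n_gof = 30, frac_gof_loh = 1,
                       panel = default_panel(), loh_region = "7q",
                       loh_type = c("copy_neutral", "copy_loss"),
                       loh_strength = 1, ado_rate = 0.2, missing_rate = 0.05,
                       depth_mean = 80, depth_dispersion = 8,
                       loh_missing_rate = 0.9, doublet_rate = 0.05,
                       clones = NULL, clone_variants = NULL,
                       thresholds = filter_thresholds(), arms = arm_table()) {
  loh_type <- match.arg(loh_type)
  stopifnot(n_wt + n_gof >= 2,
            frac_gof_loh >= 0, frac_gof_loh <= 1,
            ado_rate >= 0, ado_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            loh_strength >= 0, loh_strength <= 1,
            doublet_rate >= 0, doublet_rate < 1,
            depth_mean > 0, depth_dispersion > 0)
  if (!is.null(clones)) {
    stopifnot(all(c("name", "fraction") %in% names(clones)),
              sum(clones$fraction) <= 1,
              !is.null(clone_variants),
              all(clones$name %in% names(clone_variants)))
  }
  structure(list(seed = as.integer(seed), n_wt = n_wt, n_gof = n_gof,
                 frac_gof_loh = frac_gof_loh, panel = panel,
                 loh_region = loh_region, loh_type = loh_type,
                 loh_strength = loh_strength, ado_rate = ado_rate,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 loh_missing_rate = loh_missing_rate,
                 doublet_rate = doublet_rate, clones = clones,
                 clone_variants = clone_variants, thresholds = thresholds,
                 arms = arms, deletion_full_dropout = FALSE),
            class = "sim_config")
}

panel_keys <- function(panel) {
  paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")
}

resolve_region <- function(cfg) {
  keys <- panel_keys(cfg$panel)
  if (length(cfg$loh_region) == 1L &&
      grepl("^[0-9XY]+[pq]$", cfg$loh_region)) {
    site_arms <- assign_arm(cfg$panel$chrom, cfg$panel$pos, cfg$arms)
    idx <- which(site_arms == cfg$loh_region & cfg$panel$type != "anchor")
  } else {
    idx <- match(cfg$loh_region, keys)
    if (anyNA(idx)) stop("loh_region keys not in panel: ",
                         paste(cfg$loh_region[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 0L) stop("loh_region matches no panel sites")
  idx
}

# read-level simulation for a set of cells with known truth
# groups: "gof"/"wt"; carrier: logical; clone: character or NA
sim_reads <- function(cfg, groups, carrier, clone, phase_alt, region_idx) {
  panel <- cfg$panel
  nv <- nrow(panel)
  nc <- length(groups)
  germline <- panel$type %in% c("snp", "indel")

  # true genotype codes
  truth <- matrix(GT_REF, nv, nc)
  truth[germline, ] <- GT_HET
  anchor_i <- which(panel$type == "anchor")
  if (length(anchor_i))
    truth[anchor_i, groups == "gof"] <- GT_HET
  if (!is.null(cfg$clones)) {
    for (nm in cfg$clones$name) {
      vi <- match(cfg$clone_variants[[nm]], panel_keys(panel))
      if (anyNA(vi)) stop("clone_variants keys not in panel for clone ", nm)
      truth[vi, clone == nm] <- GT_HET
    }
  }

  # copy-neutral LOH: carrier cells become hom for the retained haplotype
  # (phase_alt gives, per site, whether the retained haplotype carries alt)
  loh_mask <- matrix(FALSE, nv, nc)
  if (cfg$loh_type == "copy_neutral" && any(carrier)) {
    ev <- matrix(stats::rbinom(length(region_idx) * sum(carrier), 1,
                               cfg$loh_strength) == 1,
                 length(region_idx), sum(carrier))
    loh_mask[region_idx, carrier] <- ev
    hom_code <- ifelse(phase_alt[region_idx], GT_HOM, GT_REF)
    truth[region_idx, carrier][ev] <-
      matrix(hom_code, length(region_idx), sum(carrier))[ev]
  }

  # depth; copy-loss halves region depth in carriers
  mu <- matrix(cfg$depth_mean, nv, nc)
  if (cfg$loh_type == "copy_loss" && any(carrier))
    mu[region_idx, carrier] <- cfg$depth_mean / 2
  dp <- matrix(stats::rnbinom(nv * nc, size = cfg$depth_dispersion,
                              mu = as.vector(mu)), nv, nc)

  # alternate reads
  ad <- matrix(0L, nv, nc)
  is_het <- truth == GT_HET
  ado <- matrix(stats::rbinom(nv * nc, 1, cfg$ado_rate) == 1, nv, nc) & is_het
  ado_to_alt <- matrix(stats::rbinom(nv * nc, 1, 0.5) == 1, nv, nc)
  bal <- is_het & !ado
  ad[bal] <- stats::rbinom(sum(bal), dp[bal], 0.5)
  ad[ado & ado_to_alt] <- dp[ado & ado_to_alt]
  ad[truth == GT_HOM] <- dp[truth == GT_HOM]

  # genotype quality: high unless a random-missingness event
  gq <- matrix(99L, nv, nc)
  miss <- matrix(stats::rbinom(nv * nc, 1, cfg$missing_rate) == 1, nv, nc)
  gq[miss] <- 0L
  if (cfg$loh_type == "copy_loss" && any(carrier)) {
    prob <- if (cfg$deletion_full_dropout) 1 else cfg$loh_missing_rate
    drop <- matrix(stats::rbinom(length(region_idx) * sum(carrier), 1,
                                 prob) == 1,
                   length(region_idx), sum(carrier))
    sub <- gq[region_idx, carrier, drop = FALSE]
    sub[drop] <- 0L
    gq[region_idx, carrier] <- sub
  }
  list(dp = dp, ad = ad, gq = gq, truth = truth)
}

#' Simulate a single-nucleus genotype matrix
#'
#' Draws a full synthetic lesion according to a [sim_config()]: per-cell
#' clone structure, read counts, allelic dropout, LOH, missingness and
#' doublets, then calls genotypes through the standard filter thresholds.
#' Fully reproducible for a fixed config (including seed).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `matrix` (a `genotype_matrix`) and `truth`
#'   (a list: per-cell data.frame `cells` with `cell_id`, `group`, `clone`,
#'   `loh_carrier`, `doublet`; `retained_hap`; `phase_alt` — per panel site,
#'   whether the retained haplotype carries the alternate allele;
#'   `region_keys`; `anchor_key`; `germline_keys`).
#' @export
simulate_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panel <- cfg$panel
  nv <- nrow(panel)
  n <- cfg$n_wt + cfg$n_gof
  region_idx <- resolve_region(cfg)

  groups <- c(rep("wt", cfg$n_wt), rep("gof", cfg$n_gof))
  clone <- rep(NA_character_, n)
  if (!is.null(cfg$clones)) {
    clone <- sample(c(cfg$clones$name, "none"), n, replace = TRUE,
                    prob = c(cfg$clones$fraction,
                             max(0, 1 - sum(cfg$clones$fraction))))
    anchor_key <- panel_keys(panel)[panel$type == "anchor"]
    carries_anchor <- vapply(
      clone, function(cl) length(anchor_key) == 1L && cl != "none" &&
        anchor_key %in% cfg$clone_variants[[cl]], logical(1))
    groups <- ifelse(carries_anchor, "gof", "wt")
  }
  carrier <- groups == "gof" &
    stats::rbinom(n, 1, cfg$frac_gof_loh) == 1
  retained_hap <- sample(c("A", "B"), 1)
  phase_A_alt <- stats::rbinom(nv, 1, 0.5) == 1
  phase_alt <- if (retained_hap == "A") phase_A_alt else !phase_A_alt

  host <- sim_reads(cfg, groups, carrier, clone, phase_alt, region_idx)

  # doublets: merge each selected host barcode with a fresh partner cell
  is_doublet <- stats::rbinom(n, 1, cfg$doublet_rate) == 1
  if (any(is_doublet)) {
    nd <- sum(is_doublet)
    pgroups <- sample(groups, nd, replace = TRUE)
    pclone <- if (!is.null(cfg$clones))
      sample(clone, nd, replace = TRUE) else rep(NA_character_, nd)
    if (!is.null(cfg$clones)) {
      anchor_key <- panel_keys(panel)[panel$type == "anchor"]
      pgroups <- vapply(pclone, function(cl)
        if (length(anchor_key) == 1L && !is.na(cl) && cl != "none" &&
            anchor_key %in% cfg$clone_variants[[cl]]) "gof" else "wt",
        character(1))
    }
    pcarrier <- pgroups == "gof" &
      stats::rbinom(nd, 1, cfg$frac_gof_loh) == 1
    part <- sim_reads(cfg, pgroups, pcarrier, pclone, phase_alt, region_idx)
    host$dp[, is_doublet] <- host$dp[, is_doublet] + part$dp
    host$ad[, is_doublet] <- host$ad[, is_doublet] + part$ad
    host$gq[, is_doublet] <- pmax(host$gq[, is_doublet], part$gq)
  }

  gt <- matrix(call_genotype(as.vector(host$dp), as.vector(host$gq),
                             as.vector(host$ad), cfg$thresholds), nv, n)
  cell_ids <- sprintf("cell_%04d", seq_len(n))
  variants <- data.frame(chrom = panel$chrom, pos = panel$pos,
                         ref = panel$ref, alt = panel$alt,
                         var_id = panel$var_id, in_dbsnp = panel$in_dbsnp,
                         is_anchor = panel$type == "anchor",
                         multi_alt = FALSE, stringsAsFactors = FALSE)
  # genotype_matrix sorts variants by (chrom, pos); apply the same order here
  ord <- order(variants$chrom, variants$pos)
  mat <- genotype_matrix(variants[ord, ], cell_ids, gt[ord, , drop = FALSE],
                         host$dp[ord, , drop = FALSE],
                         host$ad[ord, , drop = FALSE],
                         host$gq[ord, , drop = FALSE])
  keys <- panel_keys(panel)
  truth <- list(
    cells = data.frame(cell_id = cell_ids, group = groups, clone = clone,
                       loh_carrier = carrier, doublet = is_doublet,
                       stringsAsFactors = FALSE),
    retained_hap = retained_hap,
    phase_alt = stats::setNames(phase_alt, keys),
    region_keys = keys[region_idx],
    anchor_key = if (any(panel$type == "anchor"))
      keys[panel$type == "anchor"] else NA_character_,
    germline_keys = keys[panel$type %in% c("snp", "indel")])
  list(matrix = mat, truth = truth)
}

#' Simulate a null lesion (no LOH)
#'
#' [simulate_matrix()] with `frac_gof_loh = 0`: both populations follow the
#' same generative law at every germline site. Used for type-I-error suites.
#'
#' @param cfg a [sim_config()].
#' @return as [simulate_matrix()].
#' @export
simulate_null <- function(cfg) {
  cfg$frac_gof_loh <- 0
  simulate_matrix(cfg)
}

#' Simulate a deletion lesion with complete region dropout in carriers
#'
#' Copy-loss scenario in which LOH-carrier cells lose all genotypes across
#' the region (as when a somatic deletion overlaps a germline deletion of the
#' other allele): carrier cells are forced missing at every region site,
#' so [deletion_missingness_test()] applied to the output recovers the
#' carriers.
#'
#' @param cfg a [sim_config()]; `loh_type` is forced to `"copy_loss"`.
#' @return as [simulate_matrix()].
#' @export
simulate_deletion_lesion <- function(cfg) {
  cfg$loh_type <- "copy_loss"
  cfg$deletion_full_dropout <- TRUE
  simulate_matrix(cfg)
}
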