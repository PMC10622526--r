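#' Power-model specification for LOH detection
#'
#' The sample-size model treats each cell's heterozygous proportion over a bin
#' as driven by independent Bernoulli genotype calls with baseline
#' heterozygous-call probability `p_het` (a conservative ~0.8 in wild-type
#' nuclei) and asks how many anchor-variant cells are needed to detect an
#' absolute reduction `delta` in the proportion.
#'
#' The effect size is `delta` divided by a Bernoulli standard deviation,
#' under one of two conventions: `"per_snp"`, `sqrt(p(1-p))` (the default —
#' the single-call SD, independent of bin size), or `"per_bin"`,
#' `sqrt(p(1-p)/k)` (the SD of a k-SNP bin mean). The default rejection
#' quantile is `alpha/2` (a two-sided criterion at `alpha`), which together
#' with the per-SNP SD reproduces the model's reference operating points;
#' both conventions stay configurable (see the methods vignette for the
#' calibration rationale).
#'
#' @param p_het baseline heterozygous-call probability (default 0.8).
#' @param delta absolute reduction in the heterozygous proportion (0 < delta
#'   < p_het).
#' @param k SNPs per bin (default 4).
#' @param alpha significance level (default 0.01).
#' @param power target sensitivity (default 0.90).
#' @param sd_convention `"per_snp"` or `"per_bin"`.
#' @param two_sided_alpha if `TRUE` (default) the rejection quantile is
#'   `alpha/2`; if `FALSE`, `alpha`.
#' @return a `power_spec` object.
#' @export
power_spec <- function(p_het = 0.8, delta = 0.3, k = 4, alpha = 0.01,
                       power = 0.90, sd_convention = c("per_snp", "per_bin"),
                       two_sided_alpha = TRUE) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(p_het > 0, p_het < 1, delta >= 0, delta < p_het, k >= 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  structure(list(p_het = p_het, delta = delta, k = k, alpha = alpha,
                 power = power, sd_convention = sd_convention,
                 two_sided_alpha = two_sided_alpha),
            class = "power_spec")
}

#' Bernoulli standard deviation of the heterozygous proportion
#'
#' @param p_het heterozygous-call probability.
#' @param k SNPs per bin (used by the per-bin convention only).
#' @param convention `"per_snp"` -> `sqrt(p(1-p))`; `"per_bin"` ->
#'   `sqrt(p(1-p)/k)`.
#' @return standard deviation.
#' @export
bernoulli_sd <- function(p_het, k = 1, convention = c("per_snp", "per_bin")) {
  convention <- match.arg(convention)
  base <- sqrt(p_het * (1 - p_het))
  if (convention == "per_bin") base / sqrt(k) else base
}

# power of the one-sample t rejection at sample size n, effect size d
t_power_at_n <- function(n, d, level) {
  stats::pt(stats::qt(1 - level, df = n - 1), df = n - 1,
            ncp = d * sqrt(n), lower.tail = FALSE)
}

#' Required number of anchor-variant cells
#'
#' Smallest integer `n` such that a one-sample Student-t rejection with
#' noncentrality `d * sqrt(n)` (effect size `d = delta / bernoulli_sd`)
#' reaches the target power at the configured rejection level. With the
#' defaults (per-SNP SD at `p_het = 0.8`, rejection quantile 0.005, power
#' 0.90) a reduction of 0.3 requires 30 cells and a reduction of 0.2 requires
#' 63.
#'
#' @param spec a [power_spec()].
#' @return integer cell count (>= 2).
#' @export
required_cells <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  d <- spec$delta / bernoulli_sd(spec$p_het, spec$k, spec$sd_convention)
  if (d <= 0) stop("zero effect size: target power unattainable")
  level <- if (spec$two_sided_alpha) spec$alpha / 2 else spec$alpha
  n <- 2L
  while (t_power_at_n(n, d, level) < spec$power) {
    n <- n + 1L
    if (n > 1e6L) stop("required sample size exceeds 1e6; check the spec")
  }
  n
}

#' Table of required cell counts over bin sizes and effect sizes
#'
#' @param k_values bin sizes (rows).
#' @param delta_values reductions in heterozygous proportion (columns).
#' @param ... further arguments to [power_spec()].
#' @return integer matrix `length(k_values) x length(delta_values)` with
#'   dimnames.
#' @export
power_table <- function(k_values = c(4, 8, 16), delta_values = c(0.2, 0.3),
                        ...) {
  out <- matrix(NA_integer_, length(k_values), length(delta_values),
                dimnames = list(paste0("k=", k_values),
                                paste0("delta=", delta_values)))
  for (i in seq_along(k_values))
    for (j in seq_along(delta_values))
      out[i, j] <- required_cells(power_spec(k = k_values[i],
                                             delta = delta_values[j], ...))
  out
}

#' Monte-Carlo power of the rank-sum LOH test
#'
#' Simulation oracle for the analytic sample-size model: per-cell proportions
#' are drawn as `Binomial(k, p_het) / k` for wild-type cells and
#' `Binomial(k, p_het - delta) / k` for anchor-variant cells, the one-sided
#' rank-sum comparison is applied, and the rejection frequency at `spec$alpha`
#' is returned.
#'
#' @param spec a [power_spec()].
#' @param n_gof,n_wt cells per group.
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed RNG seed.
#' @return empirical power (rejection frequency).
#' @export
simulate_power <- function(spec, n_gof, n_wt, reps = 1000, seed = 1) {
  stopifnot(inherits(spec, "power_spec"), reps >= 100)
  set.seed(seed)
  p_gof <- spec$p_het - spec$delta
  rej <- vapply(seq_len(reps), function(r) {
    g <- stats::rbinom(n_gof, spec$k, p_gof) / spec$k
    w <- stats::rbinom(n_wt, spec$k, spec$p_het) / spec$k
    rank_sum_less(g, w)$p < spec$alpha
  }, logical(1))
  mean(rej)
}
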