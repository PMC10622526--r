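---
title: "Statistical methods for single-nucleus LOH detection"
author: "snloh authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for single-nucleus LOH detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snloh)
```

# The model

Targeted single-nucleus DNA sequencing genotypes a panel of germline
heterozygous SNPs in hundreds of nuclei. In a nucleus unaffected by somatic
loss-of-heterozygosity (LOH), each panel SNP should be called heterozygous;
in practice allelic dropout (ADO) — amplification failure of one allele —
converts roughly 20% of true heterozygotes into homozygous calls, so the
observed heterozygous-call rate is about 0.8. In a nucleus carrying LOH over
a region, true heterozygosity is *absent* there: copy-neutral LOH yields
consistent homozygous calls for the retained haplotype, copy-loss yields
low depth and missing genotypes.

The framework treats each cell as a set of independent Bernoulli genotype
calls and summarises a cell's state over a genomic bin by

$$\mathrm{Prop}_{het} = \frac{\#\,\text{heterozygous calls}}{\#\,\text{non-missing calls}},$$

missing genotypes appearing in neither numerator nor denominator (a 6-SNP
bin with 3 het, 2 hom, 1 missing gives $3/5 = 0.6$; a cell with all bin
genotypes missing is undefined and excluded from tests on that bin).

Cells are partitioned by a whitelisted **anchor** somatic variant (an
activating hotspot mutation marking the lesion clone). Only
anchor-*heterozygous* cells form the lesion ("GoF") group: homozygous anchor
calls can be produced by ADO or loss of the anchor's own chromosome, so both
homozygous and missing anchor cells are excluded from both groups rather
than defaulted to wild-type. This costs a predictable fraction of lesion
cells (about the ADO rate) but avoids contaminating either group.

Per bin, a one-sided unpaired Wilcoxon rank-sum test asks whether
$\mathrm{Prop}_{het}$ in GoF cells is stochastically smaller than in
wild-type cells. Two bin families are scanned: every sliding window of
$k = 4$ consecutive within-arm SNPs, and one bin per chromosome arm.
Each family is Bonferroni-corrected separately, with $m$ equal to the number
of bins *actually tested* — bins skipped for insufficient cells contribute
no inference and do not inflate the correction.

# Numerical choices in the rank-sum test

The published description of the statistic does not fix tie handling or the
exact-versus-approximate policy, so the package makes these choices
explicit and configurable:

- **Ties** are handled by midranks throughout (proportions over small bins
  are heavily tied by construction).
- **Exact permutation** p-values are used when both groups have at most 8
  cells with defined proportions: the one-sided p is the fraction of all
  $\binom{n_1+n_2}{n_1}$ relabelings whose rank sum is as small as observed.
  The test suite verifies this equals brute-force enumeration and, on
  tie-free data, `stats::wilcox.test(exact = TRUE)`.
- **Large groups** use the normal approximation with the standard tie
  correction and a continuity correction of 1/2; this is conservative under
  heavy ties, which the null-calibration suite confirms (family-wise
  false-positive rate below the nominal level).
- **Minimum cells**: bins with fewer than 5 cells with defined proportions
  in either group are reported as untested. The power model implies ~30
  variant cells for reliable detection; 5 is a floor below which the exact
  test has essentially no resolution, not a recommendation.

# The power model

For planning, each cell's $\mathrm{Prop}_{het}$ is modelled as a Bernoulli
mean with baseline $p = 0.8$ and the LOH effect as an absolute reduction
$\delta$. The effect size is $d = \delta / \sigma$ with
$\sigma = \sqrt{p(1-p)}$ — the *per-SNP* Bernoulli standard deviation, 0.4
at $p = 0.8$ — and the required number of variant cells is the smallest $n$
for which the one-sample noncentral-$t$ rejection at quantile $\alpha/2$
(a two-sided criterion at $\alpha = 0.01$) reaches power 0.90:
$n = 30$ for $\delta = 0.3$ ($d = 0.75$) and $n = 63$ for $\delta = 0.2$
($d = 0.5$).

This configuration deserves a note. A strictly one-sided level-0.01
rejection, or a per-bin standard deviation $\sqrt{p(1-p)/k}$, cannot produce
both 30 and 63 under any standard one- or two-sample normal/$t$ formula;
the per-SNP SD with the $\alpha/2$ quantile reproduces both reference
operating points simultaneously and is therefore the default. Both the SD
convention (`sd_convention`) and the sidedness (`two_sided_alpha`) are
arguments of `power_spec()`, so other conventions are one keyword away. The
analytic answer is cross-checked by `simulate_power()`, a Monte-Carlo oracle
that draws per-cell proportions as $\mathrm{Binomial}(k, p)/k$ versus
$\mathrm{Binomial}(k, p-\delta)/k$ and applies the actual rank-sum test;
at the returned $n$ the empirical power comfortably exceeds the target.
Note the per-SNP convention makes the required $n$ independent of $k$;
the bin size matters for *localization*, not for this planning number.

```{r power}
required_cells(power_spec(delta = 0.3))
required_cells(power_spec(delta = 0.2))
```

# Genotype filtering

Raw per-cell calls are refined elementwise from read-level evidence with
the standard targeted-panel thresholds: minimum depth 10, minimum genotype
quality 30, and VAF bands — REF at $\le 5\%$, HET at $\ge 15\%$, HOM at
$\ge 95\%$. VAFs in the ambiguous 5–15% band (and between the HET and HOM
bands if configured apart) become *missing* rather than being forced to the
nearest code, mirroring genotype-quality semantics. When GQ is absent (bare
TSV input) only the depth gate applies.

Variant-level selection retains germline heterozygous SNVs: genotyped in at
least 75% of cells, mutant (het or hom) in at least 50% of *genotyped*
cells, present in dbSNP, and single-nucleotide (indels excluded by default
for alignment-bias reasons). "Mutant percent" is interpreted among genotyped
cells, not all cells: the filter's purpose is to select germline
polymorphisms robustly, and normalising by genotyped cells keeps the
criterion meaningful when missingness varies across variants. Anchor
variants are whitelisted past all criteria — somatic variants cannot pass
filters designed to extract germline ones.

# Deletion-missingness and haplotype bias

When the LOH mechanism is a somatic deletion over a region already carrying
a germline deletion of the other allele, affected cells have *no* template
at region SNPs, so all genotypes are missing. After stringent region QC
(mean variant depth strictly above 50; cells with strictly more than half of
panel genotypes present), each GoF cell is scored 1 if all region SNPs are
missing; the p-value is the exact binomial upper tail at the wild-type
all-missing rate $p_0$. When no wild-type cell is all-missing, $p_0$ is
floored at $1/(2 n_{wt})$ — half a pseudo-count — to avoid a degenerate
zero null; the floor is an argument.

Copy-neutral LOH leaves a second signature: homozygous calls inside the
region all fall on the retained haplotype, whereas dropout-driven homozygous
calls split between alleles. `haplotype_bias()` reports
$\max(\text{hom}_{ref}, \text{hom}_{alt}) / \text{hom}_{total}$ per SNP and
group, counting hom-REF calls as homozygous only at *known* germline-het
sites — from simulation truth when available, otherwise from wild-type
consensus (HET in at least half of genotyped wild-type cells) — because
genotype codes alone cannot distinguish a true hom-REF site from dropout at
a het site. SNPs with fewer than 5 homozygous GoF cells are suppressed.

SNPs that stay heterozygous (GoF proportion > 0.8) inside a called LOH
region are annotated — never removed — with candidate explanations:
overlapping a panel indel, heterozygous for two alternate alleles, or within
10 bp of an indel.

# Co-mutation tests and the doublet null

Whether two somatic variants co-occur in the same nuclei is tested on cells
with depth strictly above 20 at *all* tested loci; a cell is mutant at a
locus when the alternate-read count exceeds 10 and the alternate-allele
frequency exceeds 0.1 (het and hom calls count identically). Association is
assessed by a two-tailed Pearson chi-squared test without continuity
correction, and against a doublet-aware null: if the variants lived in
exclusive clones at cell fractions $f = 2 \times \mathrm{VAF}$, double
mutants arise only from droplet doublets, in expectation
$n \cdot P(\ge 2 \mid \ge 1) \cdot 2 f_A f_B$ under Poisson loading at rate
$\lambda$. The pairing factor 2 is fixed by a droplet-simulation oracle in
the test suite, since printed formulas for it are not available; $\lambda$
is a configuration parameter (default 0.1, a typical droplet loading).
Enrichment over this expectation is reported as a Poisson upper-tail
p-value. The triple-mutant case reduces to the pairwise formula when one
variant is carried by all cells.

# The synthetic generator

`simulate_matrix()` draws the full data-generating process so that every
stage — filters, partition, tests — is exercised end to end on data with
known truth:

- **Panel**: by default 2 chromosomes × 2 arms × 25 germline-het SNPs, one
  germline indel, and one anchor hotspot on a third chromosome (the anchor
  gene and the LOH region live on different chromosomes, as in the
  motivating disease setting).
- **Depth**: negative-binomial (mean 80, dispersion 8), halved in copy-loss
  regions of carrier cells.
- **ADO**: per true-het site with probability 0.2, all reads switch to one
  uniformly chosen allele, independently across sites — calibrated to the
  observed ~80% heterozygous-call rate. Real ADO is correlated within
  amplicons and varies per site; no published decomposition was available to
  calibrate such structure, so it is deliberately not modelled.
- **LOH**: carriers (a configurable fraction of lesion cells) retain one
  haplotype — the *same* haplotype for all carriers, as a clonal event, with
  per-site random phase. `loh_strength` is the per-site penetrance: 1 gives
  full clonal LOH; intermediate values emulate partial effects, with carrier
  het-call rate $(1-\mathrm{ado})(1-s)$ — strength 0.375 at ADO 0.2 realises
  an absolute $\mathrm{Prop}_{het}$ reduction of 0.3, the power model's
  reference effect. Copy-loss carriers additionally lose region genotypes
  with probability 0.9 (1.0 in the deletion-lesion scenario).
- **Missingness**: random per call (default 0.05) via the genotype-quality
  gate, so the filters are exercised rather than bypassed.
- **Doublets**: a configurable fraction of barcodes (default 0.05) merge
  read counts with a freshly drawn partner cell before genotyping.
- Genotypes are then called through `call_genotype()` with the standard
  thresholds, and everything is reproducible from the single seed.

What passing tests on this generator do **not** show: robustness to
amplicon-specific dropout bias, ADO correlation structure, ambient/chimeric
reads, or segmentation of partial-arm events — real-data artifacts the
generator intentionally omits.

# Validation suite and problem sizes

The acceptance-style tests run at sizes chosen to balance statistical
resolution against a comfortably fast default test run:

- exact-permutation equivalence over 100+ random tied fixtures with groups
  of 3–8 cells;
- family-wise type-I error over 200 seeded null lesions (130 cells, 101
  sites each), required ≤ 0.07 at a nominal 0.05;
- recovery *and* localization of an injected 7q copy-neutral LOH
  (reduction 0.3, 30 lesion vs 100 wild-type cells) in ≥ 85% of 200
  replicates;
- the deletion scenario (12 lesion cells, expected 9 carriers) significant
  at p < 0.01 in every replicate;
- the exclusive-clone doublet null within 3 standard errors of the analytic
  expectation over 100 replicates of 1000 barcodes.

# Interfaces and conventions

Coordinates are 1-based (VCF convention); intervals closed. A site exactly
at the centromere position belongs to the p arm. Genome build is metadata
(default hg19, matching the built-in centromere table; a UCSC `cytoBand.txt`
overrides it). The TSV quartet written by `write_matrix_tsv()` is the
canonical interchange format; multi-sample VCF is ingested with
multi-allelic records split into biallelic rows (a `1/2` genotype is HET on
both rows and flagged `multi_alt`). The package is driven from R —
`run_pipeline()` / `render_report()` are the entry points and this vignette
plus the test suite document the configuration surface; no shell wrapper is
shipped.

# Limitations

The framework detects *evidence of* LOH at bin or arm resolution; it does
not distinguish copy-neutral from copy-loss mechanisms from read depth,
refine breakpoints below bin resolution, infer clonal phylogenies, or
identify which barcodes are doublets. Power calculations assume no missing
genotypes and a homogeneous per-SNP het rate; heterogeneous panels will need
the Monte-Carlo route.
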