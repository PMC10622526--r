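Package: snloh
Title: Somatic Loss-of-Heterozygosity Detection from Single-Nucleus DNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for detecting somatic loss-of-heterozygosity
    (LOH) in targeted single-nucleus DNA sequencing data. Cells are partitioned
    by an anchor somatic variant (e.g. an activating PIK3CA hotspot mutation)
    and the per-cell proportion of heterozygous calls over genomic bins
    (sliding SNP windows or whole chromosome arms) is compared between
    anchor-mutant and wild-type nuclei with a one-sided rank-sum test and
    Bonferroni correction. Includes mosaic-style genotype filters, a Bernoulli
    power model for required cell numbers, doublet-aware co-mutation enrichment
    tests, a binomial test for deletion-driven genotype missingness, a
    haplotype-bias statistic, and a synthetic snDNA-seq genotype generator with
    allelic dropout, missing data, droplet doublets and clonal structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
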