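Package: nestkin
Title: Kinship and Breeding-Habit Reconstruction for Sea Turtle Nesting
    Populations from SNP and mtDNA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct mothers, fathers, mating events and breeding
    habits of sea turtle nesting populations from hatchling-only samples.
    Implements pairwise identity-by-state (IBS) kinship from biallelic SNP
    genotypes with a group-baseline normalization, permutation confidence
    intervals for within-group means, mitochondrial control-region AT-repeat
    haplotype barcoding with heteroplasmy resolution, VCF genotype filtering
    (depth, missingness, minor allele frequency), sibship clustering and
    rule-based parentage assignment combining kinship bands, matrilines and
    nest metadata, and summaries of remigration intervals, internesting
    intervals and nest-site fidelity. Includes a seeded synthetic pedigree
    and nest generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
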