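Package: msatclone
Title: Clonal Lineage Inference from Sequenced Microsatellite Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the origin of clonal diversity in hybrid parthenogenetic
    animals from sequenced microsatellite alleles. Decomposes each allele into
    tandem repeat clusters plus fixed-position flanking single nucleotide
    variants (SNVs), assigns alleles a parental-species origin against a
    diagnostic catalog, calls canonical multilocus genotypes (presumptive
    clones), counts independent hybridization founder events from
    parent-specific SNV combinations, attributes residual clone differences to
    stepwise microsatellite mutations, links clones in a parsimony mutation
    network, and computes per-population diversity statistics (allele counts,
    hypergeometric rarefied allelic richness, Nei gene diversity, observed
    heterozygosity) and multilocus linkage-disequilibrium indices of
    association with permutation tests. Includes a forward clonal simulator
    with full ground truth and a reconstructed reference cohort fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
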