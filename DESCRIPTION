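Package: hexmap
Title: Double-Simplex SNP Linkage Maps and Homologous Groups for
    Autohexaploid S1 Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds high-density SNP linkage maps for autohexaploid species
    from read-depth annotated VCF genotypes of a selfed (S1) population.
    Pooled ALT-allele frequencies computed from per-genotype DP/RD/AD depth
    fields classify allele dosage, double-simplex loci are selected and
    dichotomized into dominant-like homozygous/not-homozygous calls tested
    against the expected 1:3 ratio, two-point recombination fractions and
    LOD scores group and order the markers into per-homolog linkage groups,
    map-order-based error masking and imputation clean the calls before a
    second mapping pass, and linkage groups are clustered into homologous
    groups by shared anchoring scaffolds on a diploid reference. A simulator
    of hexaploid bivalent meiosis, S1 selfing and ddRAD-style read depths
    with full truth tracking makes every stage verifiable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
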