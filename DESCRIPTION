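Package: autozygr
Title: Homozygosity Mapping and Recessive-Variant Prioritization in
    Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping autozygous regions and prioritizing
    autosomal-recessive candidate variants in consanguineous families.
    Detects runs of homozygosity from exome or genome variant calls using a
    rule of at least four consecutive high-quality homozygous SNVs
    uninterrupted by heterozygous calls, intersects them across affected
    individuals, and filters shared homozygous variants through a
    segregation, population-frequency, control-homozygote, phenotype and
    deleteriousness cascade. Includes a gene-dropping simulator of
    first-cousin matings (expected inbreeding coefficient 1/16) that emits
    VCF/PED/annotation files with truth records, a splice-boundary
    frameshift consequence predictor for transcript models, and small
    morphometry utilities (mitotic spindle-plane angle, Cavalieri section
    volume, dye-dilution proliferation index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
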