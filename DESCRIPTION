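Package: rdnadiv
Title: Diagnosing DNA Barcode Failure from Multicopy rDNA Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing why rDNA barcoding (ITS, LSU D1/D2) fails in
    yeast groups with heterogeneous, non-homogenized rDNA repeats, modelled on
    the situation in the Metschnikowia pulcherrima clade. Quantifies
    intragenomic versus interstrain barcode diversity and barcode gaps from
    cloned repeat sequences, classifies variable alignment sites against RNA
    secondary-structure pairing (wobble, compensatory base changes,
    mismatches/pseudogenes), detects reticulation with neighbour-net split
    systems and quartet delta scores, mines dispersed rDNA repeats and
    multi-copy genes from genome assemblies by seed-and-extend search, and
    builds polymorphic IUPAC consensus barcodes including an in-silico Sanger
    consensus with a minor-variant detection threshold. A forward simulator of
    repeat evolution under concerted homogenization, birth-and-death turnover
    and hybrid genome admixture generates every input the pipeline consumes,
    with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
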