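Package: tohscan
Title: Tracts of Homozygosity and Case-Control Association Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects tracts of homozygosity (TOH) in SNP genotype data,
    calls consensus regions shared by many subjects (cTOH) and
    allelically-matched carrier subgroups within them (aTOH), tests each
    region for case-control association under covariate adjustment
    (logistic regression with Wald tests, Benjamini-Hochberg FDR and
    Storey q-values, smoking and age interaction models), and integrates
    significant regions with a gene-expression matrix to nominate
    candidate genes. Includes a synthetic-cohort generator with planted
    homozygous tracts and known effect sizes, readers and writers for
    PLINK text, VCF and BED, the study quality-control filters, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    yaml,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
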