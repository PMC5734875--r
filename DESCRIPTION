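Package: karyoevolve
Title: Karyotype Evolution of Free-Living Human Cell Lines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study chromosome-level evolution in cultured (free
    living) human cell lines. Calls per-chromosome loss of heterozygosity,
    integer copy number and Y loss from probe-level SNP-array genotype
    tables; infers sex-chromosome genotypes and active-X counts; assigns
    C(Xa:A) karyotype labels and tallies karyotype-cluster frequencies;
    computes the X-to-autosome expression ratio E_X/A and X-linked dosage
    contrasts; tests whether autosome copy gains are cohesive or independent
    (Poisson) via a chi-square goodness-of-fit test; and fits a Markov model
    of karyotype-cluster evolution, neutral and with selection, to observed
    genotype frequencies. A synthetic-data module generates probe tables,
    expression matrices and subline copy profiles with planted ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
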