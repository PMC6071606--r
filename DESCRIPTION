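Package: homoeoscan
Title: Detection of Homoeologous Recombination, Segmental Duplication and
    Aneuploidy from SNP-Array Intensities in Allopolyploid Testcrosses
Version: 0.1.0
Authors@R:
    person("homoeoscan", "developers", email = "homoeoscan@example.org",
           role = c("aut", "cre"))
Description: Calls 8-state testcross genotypes (AA, AB, BB, A0, B0, AAB, ABB,
    no-call) from two-channel SNP-array intensities (theta/R) anchored on the
    two parents of an F1 testcross, converts per-individual allele-dosage
    vectors into classified chromosomal events (homoeologous recombination
    with reciprocal gain/loss across subgenomes, segmental deletion and
    duplication, whole-chromosome aneuploidy), classifies inheritance
    (de novo, segregating, fixed), and confirms fixed exchanges from windowed
    read-depth profiles. Includes probe subgenome classification from
    alignment hit tables, construction of the A/C homoeology block map,
    a synthetic testcross-population generator with planted truth events,
    and summary tables of event counts per line and per chromosome.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
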