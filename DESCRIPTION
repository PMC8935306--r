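Package: homeophase
Title: Homeolog Phasing and Sex-Chromosome Introgression from Long-Read Amplicons
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers allopolyploid origins and sex-chromosome introgression from
    multi-locus long-read amplicon data. Reads of each sample and locus are
    clustered into unique template sequences, consensus haplotypes are called
    and depth-filtered, allelic variants are separated from homeologous copies,
    and homeologs are phased across loci into per-subgenome concatenated
    alignments using phylogenetic anchoring on diploid samples. A hemizygous
    male-specific (Y-linked) locus is analysed for sex-specific amplification,
    shared indels and tree incongruence to flag Y-chromosome introgression.
    A synthetic-data module simulates allopolyploid amplicon datasets with
    full ground truth, including nanopore-like indel-rich read errors, so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
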