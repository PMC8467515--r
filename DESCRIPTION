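Package: dornaseq
Title: Discovery and Quantitation of Ultra-Short rRNA-Derived dodecaRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for ultra-short (8-30 nt) small RNA
    sequencing with a focus on dodecaRNAs (doRNAs), the 12-nt fragments of
    the 5.8S ribosomal RNA 5' end, and their 5'-extended variants such as
    the 13-nt C-doRNA. Provides adapter trimming into the 8-30 nt insert
    window, collapsing to unique reads with reads-per-million
    normalisation, read-length profiling, an exact/near-exact mapper for
    ultra-short queries against rRNA references, classification of reads
    into the doRNA 5'-extension ladder anchored at the invariant 5.8S G13,
    bootstrap estimation of the C-doRNA/doRNA ratio, peptide-count
    filtering and Venn partitioning of pull-down protein candidates, qPCR
    standard-curve quantitation, and seeded simulators so that every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
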