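Package: clonemin
Title: Minimal Diagnostic Clone Sets from Copy-Number Mosaicism in Serial Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the clonal architecture of acute lymphoblastic
    leukaemia (and similar tumours) from segment-level copy-number-alteration
    (CNA) calls with mosaicism status across a patient's diagnostic sample and
    serially xenotransplanted descendants. Under a perfect-phylogeny,
    no-new-mutation model it enumerates every way of resolving ambiguous
    breakpoint merges and zygosity second-hit linkings, computes the exact
    minimum number of diagnostic clones needed to explain each resolution by
    branch-and-bound, and reports the range of minima together with all
    co-minimal clone sets. Clone trees and diagnosis/remission/relapse
    pre-leukemic hierarchies are built by event-containment ordering and
    exported as annotated Newick. A synthetic-cohort generator emulates
    branching clone trees with het-deletion to homozygous-deletion/cnLOH
    zygosity chains, Dirichlet diagnostic clone frequencies, multinomial
    transplant bottlenecks and detection-threshold censoring, with full ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    yaml,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
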