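Package: rnadesign
Title: RNA Inverse Folding by Monte Carlo Tree Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs RNA sequences that fold into a user-specified secondary
    structure (given in dot-bracket notation, optionally pseudoknotted),
    optionally at a target GC content. The sequence space is explored with a
    Monte Carlo tree search over base-assignment events scored by an upper
    confidence bound; candidate sequences produced during playouts are
    refined by local rewriting rules that create missing base pairs and break
    spurious ones while conserving GC count. Structure prediction is
    pluggable: an RNAfold-compatible engine for nested structures, a
    pKiss-compatible engine for pseudoknots, or a built-in deterministic
    maximum-pairing folder that makes the whole design loop self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    seqinr,
    stats,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
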