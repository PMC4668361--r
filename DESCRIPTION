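Package: abdisplay
Title: Antibody Framework Variant Libraries and Display Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering antibody expression and stability from natural
    framework diversity. Implements Kabat numbering and germline-deviation calling
    for variable-domain sequences, mining of somatic-hypermutation repertoires into
    filtered single-variant framework libraries (buried, framework-only,
    paratope-excluded positions), stochastic simulation of multi-round
    fluorescence-gated bacterial display selections, quantification of selection
    outcomes from plating ratios and sequenced-clone counts (Wilson intervals,
    fold enrichment, enrichment calls), and biophysical readout analysis:
    differential scanning fluorimetry melt-transition extraction and global 1:1
    Langmuir fitting of surface plasmon resonance sensorgrams in multi-cycle and
    single-cycle injection designs, with equilibrium dissociation constants
    derived from fitted rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
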