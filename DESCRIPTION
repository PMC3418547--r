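Package: mitorf
Title: Sequence-Structure Divergence Analysis of Mitochondrial Release-Factor Paralogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse the functional divergence of the vertebrate
    mitochondrial class I release-factor paralogs mtRF1 and mtRF1a.
    Detects subfamily-discriminating alignment positions and
    subfamily-specific insertions in a two-family protein alignment, maps
    them to reference numbering, and interprets them in the ribosome
    context with geometric primitives (hydrogen-bond and steric-clash
    detection, rigid superposition), decoding-center state classification
    and binding-compatibility verdicts. Also scans annotated mitochondrial
    genomes for stop-codon terminability by mtRF1a, including U-preceded
    AGA/AGG minus-one frameshift termination and incomplete-stop
    polyadenylation completion. Ships a deterministic synthetic-fixture
    generator (alignments, coordinate files, mitogenomes) with
    machine-readable manifests of planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
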