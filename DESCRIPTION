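Package: sgidpep
Title: Screening of Digestion-Resistant Bioactive Peptides from De Novo
    Sequencing Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies peptides that survive simulated gastrointestinal
    digestion (SGID) by comparing de novo sequenced peptide pools from an
    intestinal digest against those of the undigested protein concentrate,
    using amino-acid composition cosine similarity with a length-difference
    guard. Computes the physicochemical descriptors used to characterize
    the resistant peptides (molecular weight, isoelectric point, net
    charge, residue-class composition, length class, solubility),
    screens terminal-residue motifs for alpha-amylase inhibitor
    candidates, provides plate-assay calculators (maltose standard curve
    with percent inhibition, Griess nitrite quantification), and ships a
    seeded in-silico digestion and sequencing-noise simulator with
    ground-truth resistant labels so the whole pipeline can be exercised
    and benchmarked without mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
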