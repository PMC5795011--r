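Package: glysearch
Title: Intact Glycopeptide Identification with Linearized Glycan Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for identifying intact N- and O-linked glycopeptides
    from MS2 spectra using a linearized-glycan encoding. Monosaccharides are
    encoded as extra one-letter residue codes (O = HexNAc, J = Hex,
    U = Neu5Ac, fucose as a variable modification on O), glycan structures
    are written as linear sequences prepended to tryptic peptides, and the
    resulting glycopeptides are searched like ordinary peptides: theoretical
    b/y fragment ions are generated over the mixed glycan+peptide alphabet,
    matched against observed peaks, and scored with a binomial-tail ion
    score. Includes in-silico tryptic digestion with N-/O-glycosylation
    site scanning, combinatorial glycopeptide FASTA database construction,
    an MGF reader/writer, decoy generation, fucose core-vs-antenna
    localization, and a seedable stepped-collision-energy spectrum
    simulator for ground-truth testing.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
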