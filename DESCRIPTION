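Package: seqtracks
Title: Element Maps and Track Figures for Biological Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses heterogeneous sequence-annotation results (GFF3/GTF gene
    structure, MEME/MAST motif occurrences, InterProScan and Batch CD-Search
    domain tables, SMART batch text, PlantCARE cis-regulatory element lists)
    into one canonical element-location model, and renders deterministic
    publication-style figures from it: per-sequence element tracks drawn with
    rounded-rectangle glyphs, phylogeny-aligned multi-panel composites, and
    cis-element count heatmap/stacked-bar panels. Also computes gene
    coordinate and exon/intron statistics from annotations and a
    ProtParam-style panel of protein physicochemical properties, splits
    promoter FASTA files at the PlantCARE upload size limit, and ships a
    seeded fixture generator that emits internally consistent files in every
    supported format with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    rtracklayer,
    xml2,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
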