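---
title: "seqtracks: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqtracks: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the data model behind `seqtracks`, the
conventions each parser applies, the numerical and stylistic choices in
the renderer, and what the synthetic fixture generator does and does not
emulate. It is the place where genuinely open design decisions are
recorded.

## The element-location model

Everything in the package flows through one structure, the `loc_table`:
an ordered set of sequences with lengths (bp for nucleotide tracks, aa
for protein tracks) and a set of element records
`(seq_id, element, start, end, strand, score, source)`.

Conventions and invariants:

* **Coordinates are 1-based inclusive throughout**, matching GFF. Every
  parser converts its dialect into this convention; renderers convert to
  a continuous axis as `[start − 1, end]`, so a length-1 element still
  has visible width.
* `1 ≤ start ≤ end ≤ length(seq)`; element names are non-empty and
  **case-sensitive, taken verbatim from the source file**. PlantCARE
  names are meaningful as-is, so normalization is deliberately left to
  the caller via `filter_elements()` or renaming.
* A sequence with zero records is legal and keeps its row: tree-aligned
  composites need rows for leaves without hits.
* `merge_loc()` treats conflicting lengths for one id as an error rather
  than resolving silently — first-wins resolution would corrupt
  row-aligned figures downstream.
* `validate_loc()` reports violations instead of raising, so whole files
  can be checked and the offending records named.

The on-disk form is a pair of TSVs (`ID/length`;
`ID/element/start/end/strand/score/source`), UTF-8 with LF endings and an
empty cell (not `"NA"`) for an absent score. The tab-separated dialect is
this package's canonical format. `read_loc_files(write_loc_files(T))`
reproduces `T` field by field, which the test suite exercises on
randomized tables.

## Parser conventions

**GFF3/GTF.** Files are read with `rtracklayer`; dialect `auto` inspects
the first feature line's attribute column (`key=value;` vs
`key "value";`). Each selected transcript becomes one row: its length is
the genomic span (max exon end − min exon start + 1) and coordinates are
re-based so the transcript starts at 1. Transcripts are **not**
strand-flipped — figures show genomic orientation, and flipping silently
would corrupt cross-references against motif tracks drawn from the same
promoters; the strand is carried on every record instead. CDS intervals
are emitted as `CDS`; exon-minus-CDS is split into
`five_prime_UTR`/`three_prime_UTR` by position relative to the CDS on the
annotated strand, unless the file carries explicit UTR features, which
are then used verbatim. Gaps between consecutive exons become `intron`;
CDS-free transcripts fall back to plain `exon` records. The default
transcript policy is `longest` (one row per gene, keeping tree-aligned
figures one-row-per-gene); `all` renders every isoform as its own row
suffixed with the transcript id, and `first` takes file order. A CDS
outside its transcript's exon union is a structural error naming the
transcript.

**MEME/MAST XML.** `meme.xml` stores 0-based site positions and carries
the aligned site letters (used by `meme_seq()`); `mast.xml` stores
1-based hit positions and references motifs by index. Both are converted
to 1-based starts with `end = start + width − 1`. The element name is the
motif's display name (`alt` attribute — the "MEME-k" label — when
present, else `name`, else `id`).

**InterProScan TSV.** The standard headerless 13-column layout; sequences
come from column 1 with lengths from column 3, records only from rows
whose analysis is in the filter (`Pfam` by default). Empty signature
descriptions fall back to the signature accession.

**Batch CD-Search.** The `hitdata.txt` dialect; the sequence id is the
first whitespace-delimited token after the first `>` in the
`Q#k - >seqid` Query cell, which is the stable part of a truncated FASTA
header. Only `specific` hits are kept by default. The table carries no
lengths, so a companion FASTA (or an explicit length frame) is required.

**SMART batch text.** SMART's bulk output varies by retrieval route, so
the grammar consumed here is declared rather than inferred: per-protein
blocks introduced by `NAME=<id>`, optional `LEN=`, and features built
from `DOMAIN=`/`START=`/`END=`/`EVALUE=` lines. A feature missing
`START` or `END` is skipped with a warning. The fixture generator emits
exactly this dialect.

**PlantCARE.** Tab rows with site name, position, matrix sequence,
strand and function description; `end = position + nchar(matrix) − 1`.
Rows whose site name is empty or begins with `Unnamed` are unannotated
matrix hits and are dropped by default. The per-element function
descriptions are kept on the returned table for classification.

All parsers **warn and skip** records that fall outside their sequence
bounds rather than aborting the file; `strict = TRUE` (CLI `--strict`)
upgrades those warnings to errors.

## PlantCARE workflow choices

* The upload limit is interpreted as **100,000 bytes of the serialized
  chunk** (60-column-wrapped, LF endings), not 102,400; the limit is a
  `max_kb` argument, so either reading is selectable. Packing is greedy
  and order-preserving, and a single oversized record is an explicit
  error rather than a silent truncation.
* The category map is **data, not code**: an ordered
  `pattern → category` TSV (`inst/extdata/plantcare_categories.tsv`)
  with case-insensitive regular-expression patterns, first match wins,
  fallback `Others`. The shipped groupings (light responsiveness,
  hormone responsiveness, stress/defense responsiveness, growth &
  development, promoter core) follow the common convention for promoter
  analyses; no authoritative taxonomy exists, which is exactly why the
  map is editable.
* Classification matches the element's function description when one is
  known and the element name itself otherwise, relabels every record
  exactly once (total and idempotent), and never drops records — the
  count-matrix grand total is conserved.
* In the stacked-bar panel, **percent mode normalizes per gene** (each
  non-empty bar totals 100); per-category normalization is a plausible
  alternative reading but answers a different question ("where does this
  category sit?" rather than "what is this promoter made of") and is
  left as a possible mode extension. Zero-total genes stay as empty
  rows; dropping them would break tree alignment.

## Rendering

The renderer is split into a backend-free layout step and two backends.
`build_track_figure()` produces rows (uniform spacing of 1 y-unit, first
sequence on top), backbone segments, glyph geometry, a palette and a
legend. One display list of pixel-space primitives is then built per
figure; the package's own SVG writer serializes it verbatim, and PNG/PDF
devices replay the identical list.

Numerical and stylistic defaults, all overridable:

* Corner arcs use **16 segments per corner** (64 for nothing — the
  polygon area error against the closed form `w·h − (4−π)r²` is already
  below 10⁻³ at 16); the effective radius is clamped to
  `min(r, w/2, h/2)`, which guarantees a simple outline.
* Glyph height 0.6 row units; UTRs 0.35 in the `gff` preset; introns in
  that preset are drawn as backbone only (no chevrons). These constants
  are declared style defaults — no authoritative geometry exists for
  such figures.
* Element colors are assigned by sorting the distinct names with a
  **byte-order (radix) sort** — deliberately locale-independent — and
  cycling the palette, so the same element set gets the same colors in
  every panel and every session.
* Each panel keeps its own x axis (a protein panel and a gene panel have
  different scales); only rows are shared. Trees are drawn as rectangular
  cladograms ignoring branch lengths by default (`use_branch_lengths`
  switches the layout to a phylogram).
* SVG determinism comes from fixed number formatting (`%.2f`),
  sequential element ids and the absence of any timestamp or creation
  metadata. PNG and PDF go through `grDevices` and are *not* promised to
  be byte-stable — only visually identical.

Composition requires **exact id equality** between panels and tree
leaves. Isoform-suffixed rows (`transcript_policy = "all"` produces
`gene_tx` ids) must be renamed before composing against a tree labeled
with gene ids; the package keeps this explicit rather than guessing a
mapping.

## Sequence statistics

`gene_stats()` derives from the same gene models as `gff_to_loc()`, so
exon/intron counts can never disagree with the drawn structure.

`protein_stats()` computes the conventional ProtParam-style panel. The
choices that matter numerically:

* **Average** (not monoisotopic) residue masses, plus one water per
  chain.
* pI by bisection (tolerance 10⁻⁴ pH) on a Henderson–Hasselbalch charge
  model. The **EMBOSS pKa set is the default** with Bjellqvist
  selectable; the two sets differ by up to ~0.5 pH units on real
  proteins, which is why the choice is an explicit argument rather than
  a constant.
* GRAVY is the plain mean of Kyte–Doolittle values; the instability
  index uses the published Guruprasad dipeptide weight table;
  aromaticity is the F/W/Y fraction.
* Non-standard residues are skipped with a warning by default
  (`on_nonstandard = "error"` to refuse), so lightly degenerate FASTA
  files still produce a table.

## The fixture generator

`generate_fixtures()` writes an internally consistent bundle — shared id
set, nucleotide and protein FASTA, Newick tree, and one file per result
format encoding planted records — plus the planted truth as location
TSVs and a JSON manifest. Design points:

* Each file type draws from its own RNG stream (`seed +` a fixed
  per-format offset), so adding a format never perturbs existing files;
  identical specs give byte-identical bundles.
* Gene structures are generated *forward* from block layouts
  (UTR/CDS/intron partitions of the planted length), so the expected
  derivation is known by construction rather than recomputed by the code
  under test.
* MEME sites are the planted consensus with a 0.1 per-position mutation
  probability, which makes the per-column majority of `meme_seq()`
  output recover the consensus.
* Scores are stored as the parsed-back value of the formatted string
  written to the file, so round-trip comparisons are exact to the last
  bit.

What the bundles **emulate** is format structure and referential
consistency; what they do **not** emulate is biology: no GC bias, codon
structure, realistic domain architectures, E-value distributions or the
quirks of real tool output (header truncation variants, wrapped tables,
locale-dependent decimals). Passing round-trips therefore demonstrate
parser correctness on well-formed files, not robustness to every
real-world mutation of these formats.

The routine checks run on deliberately small problems — bundles of 5–20
sequences, twenty seeds for the round-trip closure, a ~250 kB FASTA for
the splitter — sizes chosen to exercise every code path many times while
keeping the whole suite fast enough to run on every change.

## Known limitations

* Interval logic stops at validity: no overlap merging, strand-aware
  clipping or liftover.
* GenBank/EMBL flat files and live access to the PlantCARE/SMART web
  services are out of scope; the splitter produces upload-ready chunks
  and the parsers consume whatever the services return.
* No motif discovery or domain scanning — the package visualizes other
  tools' results.
* SVG text extents are not measured, so very long element names can
  overrun their legend column; widths are fixed, not content-fitted.
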