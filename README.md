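# seqtracks

Gene-family papers routinely need one figure that lines up, per gene, the
gene structure (CDS/UTR/intron), the motifs found by MEME, the protein
domains reported by Pfam/CDD/SMART and the cis-regulatory elements found
by PlantCARE — usually next to a phylogeny of the family. The results of
those tools arrive in six mutually incompatible formats (XML, hit tables,
batch text, tab files), none of which is directly drawable.

`seqtracks` is an R toolkit that solves the format problem once: every
supported result file is parsed into one canonical *element-location
model* — a set of sequences with lengths plus a set of element intervals
`(seq_id, element, start, end, strand, score, source)`, 1-based inclusive
— and every figure is drawn from that model. The package renders:

* per-sequence **track figures** with rounded-rectangle glyphs (the
  corner radius `r` is clamped to `min(r, w/2, h/2)` so the outline is
  always a simple polygon; its area converges to `w·h − (4−π)r²`),
* **tree-aligned composites** where the depth-first leaf order of a
  Newick tree fixes one shared row order across any number of panels,
* a **cis-element overview**: per-gene × per-category count heatmap with
  printed counts plus stacked bars of category totals (sum or percent).

It also splits promoter FASTA files at the PlantCARE 100 kB upload limit,
classifies cis-elements into functional categories via an editable rule
table, and computes per-gene exon/intron statistics and a ProtParam-style
panel of protein properties (average-mass MW, Henderson–Hasselbalch pI,
Kyte–Doolittle GRAVY, Guruprasad instability index, aromaticity, net
charge at pH 7).

SVG output is produced by the package's own writer and is **byte-stable**:
the same figure always serializes to the same bytes, and the "one step"
route (raw file → figure) is byte-identical to the "step by step" route
(raw file → location TSVs → figure).

## Worked example

The package ships a seeded fixture generator that writes an internally
consistent bundle (FASTA, tree, and every result format) with known
ground truth — useful both for testing and for trying the package:

```r
library(seqtracks)
res <- generate_fixtures("demo", fixture_spec(seed = 1, n_seqs = 5))

tab <- gff_to_loc("demo/annotation.gff3")
tab
#> loc_table: 5 sequence(s), 31 record(s)
#> elements: CDS, five_prime_UTR, intron, three_prime_UTR
#> sources:  gff
head(tab$records[, c("seq_id", "element", "start", "end", "strand")], 4)
#>   seq_id         element start end strand
#> 1    g01 three_prime_UTR     1  82      -
#> 2    g01             CDS    83 195      -
#> 3    g01          intron   196 280      -
#> 4    g01             CDS   281 306      -
```

Each transcript is re-based to start at 1; the UTR left of the CDS is the
3′ UTR here because `g01` is on the minus strand. Draw it, and compose it
with a motif panel against the tree:

```r
fig <- preset_plot(tab, "gff")      # CDS tall, UTRs short, introns as line
render(fig, "structure.svg")

comp <- compose(
  list(fig, meme_plot("demo/meme.xml")),
  tree = "demo/tree.nwk", labels = c("A", "B", "C"))
render(comp, "family.svg")
```

PlantCARE results classify into functional categories and count up:

```r
pc <- plantcare_classify(
  plantcare_to_loc("demo/plantcare.tab", fasta = "demo/seqs.fa"))
count_matrix(pc, by = "category")
#> count_matrix: 5 sequence(s) x 5 column(s), 11 element(s) total
#>     Growth & development Hormone responsiveness Light responsiveness ...
#> g01                    0                      2                    0
#> g02                    1                      0                    1
render(advance_plot(pc, tree = "demo/tree.nwk", mode = "sum"), "cis.svg")
```

The grand total of the count matrix always equals the record count —
classification relabels, never drops. Protein properties:

```r
protein_stats(c(P1 = "MKWVTFISLLFLFSSAYS"))
#>   seq_id length mol_weight      pI    gravy instability_index aromaticity charge_pH7
#> 1     P1     18   2140.568 9.29829 1.233333          17.56667   0.2777778  0.9749424
```

A command-line wrapper covering the same pipelines (subcommands `to-loc`,
`plot`, `plot-one`, `combi`, `plantcare split|classify|advance`,
`stats gene|protein`, `fixtures make`) is installed at
`inst/cli/seqtracks`:

```sh
Rscript inst/cli/seqtracks plot-one --format gff3 -i demo/annotation.gff3 -o out.svg
```

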