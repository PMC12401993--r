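# Domain-table and cis-element parsers: InterProScan TSV, Batch CD-Search,
# SMART batch text, PlantCARE tab files.

ipr_row <- function(acc, len, analysis, sig, desc, start, stop, score) {
  paste(c(acc, "md5", len, analysis, sig, desc, start, stop, score, "T",
          "25-04-2025", "IPR000001", desc), collapse = "\t")
}

test_that("analysis filter keeps Pfam rows by default; empty descriptions fall back to accessions", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    ipr_row("p1", 500, "Pfam", "PF00069", "Protein kinase domain", 10, 280, "1.2e-40"),
    ipr_row("p1", 500, "Pfam", "PF00989", "", 300, 400, "3.0e-10"),
    ipr_row("p2", 350, "Pfam", "PF00400", "WD40 repeat", 5, 44, "2.0e-08"),
    ipr_row("p1", 500, "PANTHER", "PTHR24420", "FAMILY", 1, 500, "1e-80"),
    ipr_row("p2", 350, "PANTHER", "PTHR19877", "FAMILY", 1, 350, "1e-60")),
    path)
  tab <- interpro_to_loc(path)
  expect_equal(tab$sequences$seq_id, c("p1", "p2"))
  expect_equal(tab$sequences$length, c(500L, 350L))
  expect_equal(nrow(tab$records), 3L)
  expect_equal(tab$records$element[2], "PF00989")  # empty description
  all_rows <- interpro_to_loc(path, analysis_filter = NULL)
  expect_equal(nrow(all_rows$records), 5L)
  expect_equal(nrow(interpro_to_loc(path, analysis_filter = c("Pfam", "PANTHER"))$records), 5L)
})

test_that("an InterPro row with stop before start is a parse error with the line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(ipr_row("p1", 500, "Pfam", "PF1", "x", 300, 200, "1e-5"), path)
  expect_error(interpro_to_loc(path), "line 1")
})

cdd_fixture <- function(path) {
  writeLines(c(
    "#Batch CD-search tool\tNIH/NLM/NCBI",
    "#status\t0",
    paste("Query", "Hit type", "PSSM-ID", "From", "To", "E-Value",
          "Bitscore", "Accession", "Short name", "Incomplete",
          "Superfamily", sep = "\t"),
    "Q#1 - >p1\tspecific\t214567\t15\t120\t2.1e-30\t110.2\tcd00180\tPKc\t-\tcl21453",
    "Q#1 - >p1\tsuperfamily\t355743\t15\t120\t2.1e-30\t110.2\tcl21453\tPKc_like\t-\t-",
    "Q#2 - >p2\tspecific\t201234\t40\t95\t4.0e-12\t60.1\tcd00130\tPAS\t-\tcl02459",
    "Q#2 - >p2\tnon-specific\t198776\t42\t93\t1.0e-05\t35.0\tpfam00989\tPAS_2\t-\t-"),
    path)
  path
}

write_protein_fasta <- function(path, ids = c("p1", "p2"),
                                lens = c(200L, 150L)) {
  lines <- unlist(lapply(seq_along(ids), function(i)
    c(paste0(">", ids[i]),
      paste(rep("M", lens[i]), collapse = ""))))
  writeLines(lines, path)
  path
}

test_that("CD-Search hit types are filtered and the Query cell is unwrapped", {
  hits <- cdd_fixture(tempfile())
  fa <- write_protein_fasta(tempfile(fileext = ".fa"))
  tab <- cdd_to_loc(hits, fasta = fa)
  expect_equal(nrow(tab$records), 2L)  # default: specific only
  expect_equal(tab$records$seq_id, c("p1", "p2"))
  expect_equal(tab$records$element, c("PKc", "PAS"))
  expect_equal(tab$records$start, c(15L, 40L))
  wide <- cdd_to_loc(hits, hit_type_filter = c("specific", "superfamily"),
                     fasta = fa)
  expect_equal(nrow(wide$records), 3L)
  expect_equal(nrow(cdd_to_loc(hits, hit_type_filter = NULL,
                               fasta = fa)$records), 4L)
})

test_that("a query missing from the companion FASTA is a missing-length error", {
  hits <- cdd_fixture(tempfile())
  fa <- write_protein_fasta(tempfile(), ids = "p1", lens = 200L)
  expect_error(cdd_to_loc(hits, fasta = fa), "p2")
  expect_error(cdd_to_loc(hits), "length source")
})

test_that("SMART blocks yield one sequence per NAME and one record per complete triple", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("NAME=p1", "LEN=500",
               "DOMAIN=PAS", "START=10", "END=70", "EVALUE=0.0012",
               "TYPE=SMART", "",
               "DOMAIN=HisKA", "START=100", "END=160",
               "NAME=p2", "LEN=300",
               "DOMAIN=orphan"), path)
  expect_warning(tab <- smart_to_loc(path), "lacks START/END")
  expect_equal(tab$sequences$seq_id, c("p1", "p2"))
  expect_equal(tab$sequences$length, c(500L, 300L))
  expect_equal(nrow(tab$records), 2L)
  expect_equal(tab$records$element, c("PAS", "HisKA"))
  expect_equal(tab$records$score[1], 0.0012)
  expect_true(is.na(tab$records$score[2]))
})

test_that("SMART END before START is an error naming the block", {
  path <- tempfile()
  writeLines(c("NAME=p1", "LEN=100", "DOMAIN=X", "START=50", "END=10"),
             path)
  expect_error(smart_to_loc(path), "p1")
  no_len <- tempfile()
  writeLines(c("NAME=p1", "DOMAIN=X", "START=5", "END=10"), no_len)
  expect_error(smart_to_loc(no_len), "length")
})

pc_row <- function(seq, site, pos, mseq, strand = "+", descr = "desc") {
  paste(c(seq, site, "Arabidopsis thaliana", pos, mseq, strand, "7",
          descr), collapse = "\t")
}

test_that("PlantCARE intervals are position..position+matrix-length-1", {
  path <- tempfile()
  writeLines(pc_row("g1", "ABRE", 120, "ACGTG"), path)
  tab <- plantcare_to_loc(
    path, lengths = data.frame(seq_id = "g1", length = 1500L))
  expect_equal(tab$records$element, "ABRE")
  expect_equal(tab$records$start, 120L)
  expect_equal(tab$records$end, 124L)
})

test_that("unnamed matrix hits are dropped by default and kept on request", {
  path <- tempfile()
  writeLines(c(pc_row("g1", "ABRE", 10, "ACGTG"),
               pc_row("g1", "Unnamed__1", 50, "CCGTCC", descr = ""),
               pc_row("g1", "TATA-box", 90, "TATAA"),
               pc_row("g2", "G-Box", 15, "CACGTG"),
               pc_row("g2", "Unnamed__4", 70, "AAGG", descr = ""),
               pc_row("g2", "MBS", 200, "CAACTG")), path)
  lens <- data.frame(seq_id = c("g1", "g2"), length = c(1000L, 1000L))
  expect_equal(nrow(plantcare_to_loc(path, lengths = lens)$records), 4L)
  expect_equal(nrow(plantcare_to_loc(path, drop_unnamed = FALSE,
                                     lengths = lens)$records), 6L)
})

test_that("non-integer positions and absent length sources are errors", {
  path <- tempfile()
  writeLines(pc_row("g1", "ABRE", "abc", "ACGTG"), path)
  expect_error(plantcare_to_loc(
    path, lengths = data.frame(seq_id = "g1", length = 100L)),
    "non-integer position")
  ok <- tempfile()
  writeLines(pc_row("g1", "ABRE", 10, "ACGTG"), ok)
  expect_error(plantcare_to_loc(ok), "length source")
})

test_that("every parser's output passes validation on well-formed fixtures", {
  dir <- withr::local_tempdir()
  res <- generate_fixtures(dir, fixture_spec(seed = 3))
  tabs <- list(
    gff_to_loc(res$files$gff3),
    meme_to_loc(res$files$meme_xml),
    meme_to_loc(res$files$mast_xml),
    interpro_to_loc(res$files$interpro),
    cdd_to_loc(res$files$cdd, fasta = res$files$protein_fasta),
    smart_to_loc(res$files$smart),
    plantcare_to_loc(res$files$plantcare, fasta = res$files$fasta))
  for (tab in tabs) expect_length(validate_loc(tab), 0L)
})
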