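# MEME and MAST XML parsing.

write_mini_meme <- function(path, len1 = 300L, len2 = 250L, pos = c(5L, 11L)) {
  # positions are written 0-based, as in the discovery output
  writeLines(c(
    '<?xml version="1.0"?>',
    '<MEME version="5.5.0">',
    '<training_set>',
    sprintf('<sequence id="sequence_0" name="s1" length="%d"/>', len1),
    sprintf('<sequence id="sequence_1" name="s2" length="%d"/>', len2),
    '</training_set>',
    '<motifs>',
    '<motif id="motif_1" name="ACGTACGT" alt="MEME-1" width="8">',
    '<contributing_sites>',
    sprintf('<contributing_site sequence_id="sequence_0" position="%d" strand="plus" pvalue="1.5e-08">',
            pos[1] - 1L),
    paste0('<site>', paste(sprintf('<letter_ref letter_id="%s"/>',
                                   strsplit("ACGTACGT", "")[[1]]),
                           collapse = ""), '</site>'),
    '</contributing_site>',
    sprintf('<contributing_site sequence_id="sequence_1" position="%d" strand="plus" pvalue="2.0e-06">',
            pos[2] - 1L),
    paste0('<site>', paste(sprintf('<letter_ref letter_id="%s"/>',
                                   strsplit("ACGAACGT", "")[[1]]),
                           collapse = ""), '</site>'),
    '</contributing_site>',
    '</contributing_sites>',
    '</motif>',
    '</motifs>',
    '</MEME>'), path)
  path
}

test_that("occurrence intervals are start..start+width-1 with the file's p-value", {
  tab <- meme_to_loc(write_mini_meme(tempfile(fileext = ".xml")))
  expect_equal(tab$sequences$seq_id, c("s1", "s2"))
  expect_equal(tab$sequences$length, c(300L, 250L))
  expect_equal(tab$records$element, c("MEME-1", "MEME-1"))
  expect_equal(tab$records$start, c(5L, 11L))
  expect_equal(tab$records$end, c(12L, 18L))
  expect_equal(tab$records$score, c(1.5e-08, 2.0e-06))
  expect_true(all(tab$records$end - tab$records$start + 1L == 8L))
})

test_that("a site running past the declared length is skipped with a warning", {
  path <- write_mini_meme(tempfile(fileext = ".xml"), len2 = 15L,
                          pos = c(5L, 11L))  # 11..18 > 15
  expect_warning(tab <- meme_to_loc(path), "exceeds length")
  expect_equal(nrow(tab$records), 1L)
  expect_error(meme_to_loc(path, strict = TRUE), "exceeds length")
})

test_that("mast parsing: declared sequences without hits stay as empty rows", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>', '<mast version="5.5.0">', '<motifs>',
    '<motif id="motif_1" alt="MEME-1" width="6"/>', '</motifs>',
    '<sequences>',
    '<sequence id="q0" name="s1" length="100">',
    '<seg start="1"><hit pos="21" idx="0" rc="n" pvalue="3.1e-05"/></seg>',
    '</sequence>',
    '<sequence id="q1" name="s2" length="80"/>',
    '</sequences>', '</mast>'), path)
  tab <- meme_to_loc(path)
  expect_equal(tab$sequences$seq_id, c("s1", "s2"))
  expect_equal(nrow(tab$records), 1L)
  expect_equal(tab$records$start, 21L)
  expect_equal(tab$records$end, 26L)
  expect_equal(tab$records$source, "mast")
})

test_that("a hit referencing an undeclared motif is a cross-reference error", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>', '<mast version="5.5.0">', '<motifs>',
    '<motif id="motif_1" alt="MEME-1" width="6"/>', '</motifs>',
    '<sequences>', '<sequence id="q0" name="s1" length="100">',
    '<seg start="1"><hit pos="5" idx="7" rc="n" pvalue="1e-04"/></seg>',
    '</sequence>', '</sequences>', '</mast>'), path)
  expect_error(meme_to_loc(path), "undeclared motif")
})

test_that("meme_seq returns width-length site strings and rejects mast input", {
  path <- write_mini_meme(tempfile(fileext = ".xml"))
  sites <- meme_seq(path)
  expect_named(sites, "MEME-1")
  expect_length(sites[["MEME-1"]], 2L)
  expect_true(all(nchar(sites[["MEME-1"]]) == 8L))
  mast <- tempfile(fileext = ".xml")
  writeLines(c('<mast version="5.5.0"><sequences/></mast>'), mast)
  expect_error(meme_seq(mast), "mast")
})

test_that("planted-consensus fixtures: per-column majority recovers the consensus", {
  dir <- withr::local_tempdir()
  res <- generate_fixtures(dir, fixture_spec(seed = 7, n_seqs = 12))
  sites <- meme_seq(res$files$meme_xml)
  for (m in names(res$motif_consensus)) {
    s <- sites[[m]]
    if (length(s) < 5L) next  # majority vote needs a few sites
    mat <- do.call(rbind, strsplit(s, ""))
    maj <- apply(mat, 2, function(col)
      names(sort(table(col), decreasing = TRUE))[1])
    cons <- strsplit(res$motif_consensus[[m]], "")[[1]]
    # 10% per-position mutation: allow a stray column to flip
    expect_gte(mean(maj == cons), 0.8)
  }
})

test_that("truncated XML is a parse error", {
  path <- tempfile(fileext = ".xml")
  writeLines('<MEME version="5.5"><training_set>', path)
  expect_error(meme_to_loc(path))
})
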