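# Gene structure statistics and protein physicochemical properties.

test_that("gene_stats matches the worked gene model and gff_to_loc's records", {
  path <- write_worked_gff3(tempfile(fileext = ".gff3"), offset = 900L)
  gs <- gene_stats(path)
  expect_equal(gs$gene_id, "g1")
  expect_equal(gs$gene_length, 300L)
  expect_equal(gs$exon_count, 2L)
  expect_equal(gs$intron_count, 1L)
  expect_equal(gs$cds_length, 100L)
  expect_equal(gs$start, 901L)
  expect_equal(gs$end, 1200L)
  tab <- gff_to_loc(path)
  expect_equal(gs$intron_count, sum(tab$records$element == "intron"))
  expect_equal(gs$cds_length,
               sum(tab$records$end[tab$records$element == "CDS"] -
                   tab$records$start[tab$records$element == "CDS"] + 1L))
})

test_that("exon counts match an independent recount of exon lines", {
  dir <- withr::local_tempdir()
  res <- generate_fixtures(dir, fixture_spec(seed = 12, n_seqs = 10))
  gs <- gene_stats(res$files$gff3)
  raw <- readLines(res$files$gff3)
  exon_lines <- raw[grepl("\texon\t", raw)]
  parents <- sub(".*Parent=([^;]+).*", "\\1", exon_lines)
  recount <- table(sub("\\.t1$", "", parents))
  expect_equal(gs$exon_count,
               as.integer(recount[gs$gene_id]), ignore_attr = TRUE)
  expect_equal(gs$intron_count, gs$exon_count - 1L)
  # single-exon genes have zero introns by construction of the law above
  expect_true(all(gs$intron_count[gs$exon_count == 1L] == 0L))
})

test_that("molecular weight is the sum of average residue masses plus water", {
  ps <- protein_stats(c(g = "G"))
  expect_equal(ps$mol_weight, 57.0519 + 18.0153, tolerance = 0.05 / 75)
  # additivity: chain of n glycines = n residues + one water
  p5 <- protein_stats(c(g5 = "GGGGG"))
  expect_equal(p5$mol_weight, 5 * 57.0519 + 18.0153, tolerance = 1e-6)
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  ps <- protein_stats(c(a = "AAA"))
  expect_equal(ps$gravy, 1.8)
  # length-weighted mean over halves equals the whole
  withr::with_seed(21, {
    for (k in 1:5) {
      n <- sample(10:60, 1)
      s <- paste(sample(seqtracks:::AA20, n, replace = TRUE),
                 collapse = "")
      half <- sample(2:(n - 2), 1)
      s1 <- substr(s, 1, half); s2 <- substr(s, half + 1, n)
      g <- protein_stats(stats::setNames(c(s, s1, s2), c("w", "a", "b")))
      expect_equal(g$gravy[1],
                   (half * g$gravy[2] + (n - half) * g$gravy[3]) / n)
    }
  })
})

test_that("net charge at the returned pI is within the bisection tolerance", {
  withr::with_seed(31, {
    for (k in 1:25) {
      s <- paste(sample(seqtracks:::AA20, sample(5:80, 1), replace = TRUE),
                 collapse = "")
      pI <- protein_pi(s)
      expect_lt(abs(protein_charge(s, pI)), 1e-3)
      pIb <- protein_pi(s, pka_set = "bjellqvist")
      expect_lt(abs(protein_charge(s, pIb, pka_set = "bjellqvist")), 1e-3)
    }
  })
})

test_that("pI moves monotonically with basic and acidic residues", {
  withr::with_seed(41, {
    for (k in 1:10) {
      s <- paste(sample(seqtracks:::AA20, 30, replace = TRUE),
                 collapse = "")
      expect_gte(protein_pi(paste0(s, "K")), protein_pi(s) - 1e-3)
      expect_lte(protein_pi(paste0(s, "D")), protein_pi(s) + 1e-3)
    }
  })
})

test_that("instability and aromaticity agree with hand-checked values", {
  # reference peptide: values computed independently from the published
  # dipeptide weight table and the F/W/Y fraction definition
  ps <- protein_stats(c(p = "MKWVTFISLLFLFSSAYS"))
  expect_equal(ps$instability_index, 17.5666667, tolerance = 1e-6)
  expect_equal(ps$aromaticity, 5 / 18)
  expect_equal(ps$length, 18L)
})

test_that("non-standard residues are skipped with a warning or rejected", {
  expect_warning(ps <- protein_stats(c(x = "AAXAA")), "non-standard")
  expect_equal(ps$length, 4L)
  expect_error(protein_stats(c(x = "AAXAA"), on_nonstandard = "error"),
               "non-standard")
})
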