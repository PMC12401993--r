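# Gene-structure derivation from GFF3/GTF.

test_that("two-exon plus-strand model derives UTR/CDS/intron exactly", {
  path <- write_worked_gff3(tempfile(fileext = ".gff3"), strand = "+",
                            offset = 5000L)
  tab <- gff_to_loc(path)
  expect_equal(tab$sequences$seq_id, "g1")
  expect_equal(tab$sequences$length, 300L)
  r <- tab$records
  expect_equal(
    r[c("element", "start", "end")],
    data.frame(element = c("five_prime_UTR", "CDS", "intron", "CDS",
                           "three_prime_UTR"),
               start = c(1L, 51L, 101L, 201L, 251L),
               end = c(50L, 100L, 200L, 250L, 300L)),
    ignore_attr = TRUE)
  expect_true(all(r$strand == "+"))
  expect_true(all(r$source == "gff"))
})

test_that("the minus-strand mirror swaps the UTR labels only", {
  plus <- gff_to_loc(write_worked_gff3(tempfile(), "+"))
  minus <- gff_to_loc(write_worked_gff3(tempfile(), "-"))
  rp <- plus$records; rm_ <- minus$records
  expect_equal(rm_$start, rp$start)
  expect_equal(rm_$end, rp$end)
  expect_equal(rm_$element[rp$element == "five_prime_UTR"],
               "three_prime_UTR")
  expect_equal(rm_$element[rp$element == "three_prime_UTR"],
               "five_prime_UTR")
  expect_equal(rm_$element[rp$element %in% c("CDS", "intron")],
               rp$element[rp$element %in% c("CDS", "intron")])
})

test_that("single-exon full-CDS transcript has one CDS, no introns or UTRs", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t101\t400\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t101\t400\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\tt\texon\t101\t400\t.\t+\t.\tParent=m1",
               "chr1\tt\tCDS\t101\t400\t.\t+\t0\tParent=m1"), path)
  tab <- gff_to_loc(path)
  expect_equal(tab$records$element, "CDS")
  expect_equal(tab$records$start, 1L)
  expect_equal(tab$records$end, 300L)
})

test_that("CDS outside the exon union is a structural error naming the transcript", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=m1",
               "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=m1",
               "chr1\tt\tCDS\t150\t200\t.\t+\t0\tParent=m1"), path)
  expect_error(gff_to_loc(path), "m1.*CDS lies outside")
})

test_that("dialect auto-detection distinguishes GFF3 and GTF attributes", {
  g3 <- write_worked_gff3(tempfile(fileext = ".gff3"))
  expect_equal(seqtracks:::detect_gff_dialect(g3), "gff3")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tt\ttranscript\t1\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"m1\";",
               "chr1\tt\texon\t1\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"m1\";",
               "chr1\tt\tCDS\t51\t250\t.\t+\t0\tgene_id \"g1\"; transcript_id \"m1\";"),
             gtf)
  expect_equal(seqtracks:::detect_gff_dialect(gtf), "gtf")
  tab <- gff_to_loc(gtf)
  expect_true(all(tab$records$source == "gtf"))
  expect_equal(tab$records$element,
               c("five_prime_UTR", "CDS", "three_prime_UTR"))
  bad <- tempfile()
  writeLines("chr1\tt\texon\t1\t10\t.\t+\t.\tjusttext", bad)
  expect_error(gff_to_loc(bad), "dialect")
})

test_that("transcript policies: longest per gene by default, all keeps isoforms", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t500\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t500\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\tt\texon\t1\t500\t.\t+\t.\tParent=m1",
               "chr1\tt\tmRNA\t1\t200\t.\t+\t.\tID=m2;Parent=g1",
               "chr1\tt\texon\t1\t200\t.\t+\t.\tParent=m2"), path)
  longest <- gff_to_loc(path)
  expect_equal(longest$sequences$seq_id, "g1")
  expect_equal(longest$sequences$length, 500L)
  all_tx <- gff_to_loc(path, transcript_policy = "all")
  expect_setequal(all_tx$sequences$seq_id, c("g1_m1", "g1_m2"))
  first <- gff_to_loc(path, transcript_policy = "first")
  expect_equal(first$sequences$length, 500L)
})

test_that("explicit UTR features in the file are used verbatim", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=m1",
               "chr1\tt\texon\t1\t300\t.\t+\t.\tParent=m1",
               "chr1\tt\tfive_prime_UTR\t1\t40\t.\t+\t.\tParent=m1",
               "chr1\tt\tCDS\t41\t260\t.\t+\t0\tParent=m1",
               "chr1\tt\tthree_prime_UTR\t261\t300\t.\t+\t.\tParent=m1"),
             path)
  tab <- gff_to_loc(path)
  expect_equal(tab$records$element,
               c("five_prime_UTR", "CDS", "three_prime_UTR"))
  expect_equal(tab$records$end, c(40L, 260L, 300L))
})
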