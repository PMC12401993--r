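# FASTA splitting at the upload limit, category classification, and the
# count matrix.

make_fasta <- function(path, n_records, seq_len) {
  lines <- unlist(lapply(seq_len(n_records), function(i)
    seqtracks:::serialize_fasta_record(
      sprintf("prom%02d", i),
      paste(rep(c("A", "C", "G", "T"), length.out = seq_len),
            collapse = ""))))
  writeLines(lines, path)
  path
}

read_records <- function(paths) {
  ss <- do.call(c, lapply(paths, Biostrings::readBStringSet))
  data.frame(id = names(ss), seq = as.character(ss),
             stringsAsFactors = FALSE)
}

test_that("an input under the limit stays one chunk with identical records", {
  dir <- withr::local_tempdir()
  fa <- make_fasta(file.path(dir, "small.fa"), 5, 2000)  # ~10 kB
  chunks <- split_fasta(fa, max_kb = 100, outdir = dir)
  expect_length(chunks, 1L)
  expect_equal(read_records(chunks), read_records(fa))
})

test_that("six ~40 kB records at a 100 kB limit pack into 3 chunks of 2", {
  dir <- withr::local_tempdir()
  # 39996 sequence chars -> 667 wrapped lines + header ~ 40.7 kB per record
  fa <- make_fasta(file.path(dir, "six.fa"), 6, 39996)
  chunks <- split_fasta(fa, max_kb = 100, outdir = dir)
  expect_length(chunks, 3L)
  expect_true(all(file.size(chunks) <= 100000))
  for (k in seq_along(chunks)) {
    expect_equal(nrow(read_records(chunks[k])), 2L)
  }
  expect_equal(read_records(chunks), read_records(fa))
})

test_that("a single record over the limit is an unsplittable-record error", {
  dir <- withr::local_tempdir()
  fa <- make_fasta(file.path(dir, "huge.fa"), 1, 150000)
  expect_error(split_fasta(fa, max_kb = 100), "unsplittable")
  expect_error(split_fasta(fa, max_kb = 100), "prom01")
})

test_that("classification applies the first matching rule and falls back to Others", {
  cmap <- category_map(
    patterns = c("abscisic acid", "light respons"),
    categories = c("Hormone responsiveness", "Light responsiveness"))
  tab <- loc_table(
    sequences = data.frame(seq_id = "g1", length = 1000L),
    records = data.frame(seq_id = "g1",
                         element = c("ABRE", "G-Box", "XYZ"),
                         start = c(1L, 10L, 20L), end = c(5L, 15L, 25L)))
  descr <- c(
    ABRE = "cis-acting element involved in the abscisic acid responsiveness",
    `G-Box` = "cis-acting regulatory element involved in light responsiveness")
  out <- plantcare_classify(tab, descriptions = descr, cmap = cmap)
  expect_equal(out$records$category,
               c("Hormone responsiveness", "Light responsiveness", "Others"))
  expect_equal(nrow(out$records), nrow(tab$records))
  # idempotent
  again <- plantcare_classify(out, descriptions = descr, cmap = cmap)
  expect_equal(again$records$category, out$records$category)
})

test_that("rule order decides ties: the first matching rule wins", {
  tab <- loc_table(
    sequences = data.frame(seq_id = "g1", length = 100L),
    records = data.frame(seq_id = "g1", element = "E", start = 1L,
                         end = 4L))
  descr <- c(E = "light responsive and stress responsive element")
  ab <- category_map(c("light respons", "stress respons"), c("Light", "Stress"))
  ba <- category_map(c("stress respons", "light respons"), c("Stress", "Light"))
  expect_equal(plantcare_classify(tab, descr, ab)$records$category, "Light")
  expect_equal(plantcare_classify(tab, descr, ba)$records$category, "Stress")
})

test_that("elements with no description are matched on their own name", {
  tab <- loc_table(
    sequences = data.frame(seq_id = "g1", length = 100L),
    records = data.frame(seq_id = "g1", element = "TATA-box", start = 1L,
                         end = 5L))
  out <- plantcare_classify(tab, descriptions = NULL,
                            cmap = default_category_map())
  expect_equal(out$records$category, "Promoter core")
})

test_that("count_matrix matches a brute-force recount and keeps zero rows", {
  tab <- loc_table(
    sequences = data.frame(seq_id = c("g1", "g2"), length = c(500L, 500L)),
    records = data.frame(
      seq_id = c("g1", "g1", "g1", "g2"),
      element = c("ABRE", "ABRE", "TATA", "ABRE"),
      start = c(1L, 10L, 20L, 30L), end = c(5L, 14L, 24L, 34L)))
  m <- count_matrix(tab, by = "element")
  expect_equal(unclass(m),
               matrix(c(2L, 1L, 1L, 0L), 2, 2,
                      dimnames = list(c("g1", "g2"), c("ABRE", "TATA"))),
               ignore_attr = FALSE)
  empty <- loc_table(sequences = data.frame(
    seq_id = c("a", "b", "c"), length = rep(10L, 3)))
  m0 <- count_matrix(empty)
  expect_equal(dim(m0), c(3L, 0L))
})

test_that("counts are conserved: grand total equals record count, with or without classification", {
  withr::with_seed(5, {
    for (k in 1:5) {
      tab <- random_loc(n_seqs = sample(3:12, 1), n_recs = sample(0:80, 1))
      m <- count_matrix(tab, by = "element")
      expect_equal(sum(m), nrow(tab$records))
      # brute-force recount oracle, cell by cell
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(ncol(m))) {
          expect_equal(m[i, j],
                       sum(tab$records$seq_id == rownames(m)[i] &
                           tab$records$element == colnames(m)[j]))
        }
      }
      cl <- plantcare_classify(tab, cmap = default_category_map())
      expect_equal(sum(count_matrix(cl, by = "category")),
                   nrow(tab$records))
    }
  })
})

test_that("the shipped category map loads and matches hormone wording", {
  cmap <- default_category_map()
  expect_s3_class(cmap, "category_map")
  expect_gt(length(cmap$patterns), 10L)
  got <- seqtracks:::apply_category_map(
    "cis-acting element involved in the abscisic acid responsiveness",
    cmap)
  expect_equal(got, "Hormone responsiveness")
})
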