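# The canonical element-location model and its two-file TSV format.

test_that("validate reports each broken invariant by record", {
  ok <- loc_table(sequences = data.frame(seq_id = "s1", length = 100L),
                  records = data.frame(seq_id = "s1", element = "CDS",
                                       start = 10L, end = 40L,
                                       strand = "+"))
  expect_length(validate_loc(ok), 0L)

  bad <- structure(list(
    sequences = data.frame(seq_id = "s1", length = 100L),
    records = seqtracks:::normalize_records(data.frame(
      seq_id = c("s1", "sX", "s1"),
      element = c("CDS", "M1", "  "),
      start = c(10L, 5L, 1L),
      end = c(150L, 20L, 10L)))), class = "loc_table")
  v <- validate_loc(bad)
  expect_true(any(grepl("end exceeds length", v)))
  expect_true(any(grepl("unknown sequence", v)))
  expect_true(any(grepl("empty element name", v)))
})

test_that("constructor refuses invalid tables, reversed intervals included", {
  expect_error(
    loc_table(sequences = data.frame(seq_id = "s1", length = 100L),
              records = data.frame(seq_id = "s1", element = "M",
                                   start = 50L, end = 10L)),
    "end precedes start")
})

test_that("two-file format round-trips field by field", {
  withr::with_seed(11, {
    for (k in 1:5) {
      tab <- random_loc(n_seqs = sample(2:50, 1), n_recs = sample(0:500, 1))
      lp <- tempfile(fileext = ".tsv"); ep <- tempfile(fileext = ".tsv")
      write_loc_files(tab, lp, ep)
      back <- read_loc_files(lp, ep)
      expect_loc_equal(back, tab)
    }
  })
})

test_that("absent scores are empty cells, not the string NA", {
  tab <- loc_table(sequences = data.frame(seq_id = "s1", length = 100L),
                   records = data.frame(seq_id = "s1", element = "M1",
                                        start = 5L, end = 30L))
  lp <- tempfile(); ep <- tempfile()
  write_loc_files(tab, lp, ep)
  lines <- readLines(ep)
  expect_false(grepl("NA", lines[2], fixed = TRUE))
  expect_equal(strsplit(lines[2], "\t")[[1]][6], "")
})

test_that("empty table writes header-only files that read back empty", {
  tab <- loc_table()
  lp <- tempfile(); ep <- tempfile()
  write_loc_files(tab, lp, ep)
  expect_equal(readLines(lp), "ID\tlength")
  back <- read_loc_files(lp, ep)
  expect_equal(nrow(back$sequences), 0L)
  expect_equal(nrow(back$records), 0L)
})

test_that("elements file with only a header is a legal empty record set", {
  lp <- tempfile(); ep <- tempfile()
  writeLines("ID\tlength\ns1\t300", lp)
  writeLines("ID\telement\tstart\tend\tstrand\tscore\tsource", ep)
  tab <- read_loc_files(lp, ep)
  expect_equal(tab$sequences$seq_id, "s1")
  expect_equal(nrow(tab$records), 0L)
})

test_that("reader names the missing column and the bad line", {
  lp <- tempfile(); ep <- tempfile()
  writeLines(c("ID\tlen", "s1\t300"), lp)
  writeLines("ID\telement\tstart\tend", ep)
  expect_error(read_loc_files(lp, ep), "column 'length'")
  writeLines(c("ID\tlength", "s1\t300"), lp)
  writeLines(c("ID\telement\tstart\tend", "s1\tM\tfive\t30"), ep)
  expect_error(read_loc_files(lp, ep), "line 2.*non-integer|non-integer start")
})

test_that("merge unions sequences, conserves records, rejects length conflicts", {
  t1 <- loc_table(sequences = data.frame(seq_id = c("a", "b"),
                                         length = c(100L, 200L)),
                  records = data.frame(seq_id = "a", element = "M1",
                                       start = 1L, end = 10L))
  t2 <- loc_table(sequences = data.frame(seq_id = c("c", "d"),
                                         length = c(300L, 400L)),
                  records = data.frame(seq_id = c("c", "d"),
                                       element = "M2",
                                       start = c(5L, 6L), end = c(9L, 20L)))
  m <- merge_loc(list(t1, t2))
  expect_equal(m$sequences$seq_id, c("a", "b", "c", "d"))
  expect_equal(nrow(m$records), nrow(t1$records) + nrow(t2$records))
  # identity
  expect_loc_equal(merge_loc(list(t1)), t1)
  # associativity on disjoint sets
  t3 <- loc_table(sequences = data.frame(seq_id = "e", length = 50L))
  expect_loc_equal(merge_loc(list(merge_loc(list(t1, t2)), t3)),
                   merge_loc(list(t1, merge_loc(list(t2, t3)))))
  # conflict
  t1b <- loc_table(sequences = data.frame(seq_id = "a", length = 999L))
  expect_error(merge_loc(list(t1, t1b)), "conflict.*'a'")
})

test_that("filter keeps sequences and composes like a conjunction", {
  tab <- demo_loc()
  all_kept <- filter_elements(tab, function(r) TRUE)
  expect_loc_equal(all_kept, tab)
  cds <- filter_elements(tab, "CDS")
  expect_equal(nrow(cds$records), 3L)
  expect_equal(cds$sequences$seq_id, tab$sequences$seq_id)
  none <- filter_elements(tab, function(r) FALSE)
  expect_equal(nrow(none$records), 0L)
  expect_equal(nrow(none$sequences), 3L)
  # sequential filtering == single conjunctive filter
  p <- function(r) r$element == "CDS"
  q <- function(r) r$start > 50
  expect_loc_equal(
    filter_elements(filter_elements(tab, p), q),
    filter_elements(tab, function(r) p(r) && q(r)))
})
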