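# Shared test helpers: tiny in-code fixtures and independent oracles.

expect_loc_equal <- function(a, b, check_score = TRUE) {
  expect_equal(a$sequences$seq_id, b$sequences$seq_id)
  expect_equal(a$sequences$length, b$sequences$length)
  ra <- a$records; rb <- b$records
  rownames(ra) <- NULL; rownames(rb) <- NULL
  cols <- c("seq_id", "element", "start", "end", "strand", "source")
  if (check_score) cols <- c(cols, "score")
  expect_equal(ra[cols], rb[cols], ignore_attr = TRUE)
}

# the worked two-exon gene model: exons 1..100 and 201..300, CDS 51..100
# and 201..250, written as GFF3 at a genomic offset
write_worked_gff3 <- function(path, strand = "+", offset = 0L) {
  o <- offset
  lines <- c(
    "##gff-version 3",
    sprintf("chr1\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=g1", o + 1, o + 300, strand),
    sprintf("chr1\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=m1;Parent=g1",
            o + 1, o + 300, strand),
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=m1", o + 1, o + 100, strand),
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=m1", o + 201, o + 300, strand),
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t%s\t0\tParent=m1", o + 51, o + 100, strand),
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t%s\t0\tParent=m1", o + 201, o + 250, strand)
  )
  writeLines(lines, path)
  path
}

# a small valid loc_table used across tests
demo_loc <- function() {
  loc_table(
    sequences = data.frame(seq_id = c("s1", "s2", "s3"),
                           length = c(300L, 250L, 400L)),
    records = data.frame(
      seq_id = c("s1", "s1", "s2", "s1", "s3"),
      element = c("CDS", "intron", "CDS", "CDS", "UTR"),
      start = c(10L, 41L, 5L, 101L, 350L),
      end = c(40L, 100L, 60L, 200L, 390L),
      strand = "+")
  )
}

# randomized valid loc_table for property-style round trips
random_loc <- function(n_seqs = 10L, n_recs = 50L) {
  lens <- sample(100:500, n_seqs, replace = TRUE)
  ids <- sprintf("seq%03d", seq_len(n_seqs))
  which_seq <- sample.int(n_seqs, n_recs, replace = TRUE)
  start <- vapply(which_seq, function(i) sample.int(lens[i] - 10L, 1L),
                  integer(1))
  len <- vapply(seq_len(n_recs), function(k)
    sample.int(lens[which_seq[k]] - start[k] + 1L, 1L), integer(1))
  loc_table(
    sequences = data.frame(seq_id = ids, length = lens),
    records = data.frame(
      seq_id = ids[which_seq],
      element = sample(c("M1", "M2", "ABRE", "CDS", "PAS domain"), n_recs,
                       replace = TRUE),
      start = start, end = start + len - 1L,
      strand = sample(c("+", "-", "."), n_recs, replace = TRUE),
      score = ifelse(runif(n_recs) < 0.3, NA_real_,
                     signif(10^-runif(n_recs, 1, 10), 6)),
      source = sample(c("meme", "plantcare", "user"), n_recs,
                      replace = TRUE))
  )
}

# independent recursive-descent Newick leaf-order oracle (no ape)
newick_leaves_oracle <- function(newick) {
  s <- sub(";\\s*$", "", trimws(newick))
  leaves <- character()
  walk <- function(str) {
    if (!startsWith(str, "(")) {
      leaves <<- c(leaves, sub(":.*$", "", str))
      return(invisible())
    }
    # strip outer parens and any trailing label/branch length
    depth <- 0L
    chars <- strsplit(str, "")[[1]]
    end <- NA_integer_
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") { depth <- depth - 1L
        if (depth == 0L) { end <- i; break } }
    }
    inner <- substr(str, 2L, end - 1L)
    # split on top-level commas
    depth <- 0L; last <- 1L; parts <- character()
    ic <- strsplit(inner, "")[[1]]
    for (i in seq_along(ic)) {
      if (ic[i] == "(") depth <- depth + 1L
      if (ic[i] == ")") depth <- depth - 1L
      if (ic[i] == "," && depth == 0L) {
        parts <- c(parts, substr(inner, last, i - 1L)); last <- i + 1L
      }
    }
    parts <- c(parts, substr(inner, last, nchar(inner)))
    for (p in parts) walk(trimws(p))
  }
  walk(s)
  leaves
}
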