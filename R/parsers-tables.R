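# Parsers for domain/element result tables: InterProScan TSV (Pfam rows),
# NCBI Batch CD-Search hit tables, SMART batch text and PlantCARE tab files.

#' Sequence lengths from a FASTA file
#'
#' @param path FASTA file (nucleotide or protein).
#' @return data frame with `seq_id` (first whitespace-delimited token of the
#'   header) and `length`, in file order.
#' @export
fasta_lengths <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[`, character(1), 1L)
  data.frame(seq_id = ids, length = Biostrings::width(ss),
             stringsAsFactors = FALSE)
}

resolve_lengths <- function(ids, lengths, fasta, what) {
  if (is.null(lengths) && !is.null(fasta)) lengths <- fasta_lengths(fasta)
  if (is.null(lengths)) {
    stop(what, ": no length source; supply `lengths` or a companion `fasta`",
         call. = FALSE)
  }
  miss <- setdiff(ids, lengths$seq_id)
  if (length(miss) > 0L) {
    stop(sprintf("%s: no length available for sequence(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  # keep the full length source: a sequence without hits still gets a row,
  # so that figure rows stay aligned across panels
  out <- lengths[, c("seq_id", "length"), drop = FALSE]
  out$length <- as.integer(out$length)
  rownames(out) <- NULL
  out
}

drop_oob <- function(rec, seqs, strict, what) {
  len <- stats::setNames(seqs$length, seqs$seq_id)
  bad <- which(rec$end > len[rec$seq_id] | rec$start < 1L)
  if (length(bad) > 0L) {
    warn_or_stop(strict, "%s: %d record(s) outside their sequence bounds; skipped",
                 what, length(bad))
    rec <- rec[-bad, , drop = FALSE]
  }
  rec
}

#' Extract domains from an InterProScan TSV file
#'
#' The standard headerless 13+ column InterProScan layout is expected:
#' protein accession, md5, sequence length, analysis, signature accession,
#' signature description, start, stop, score, status, date, InterPro
#' accession, InterPro description. Sequences come from column 1 with
#' lengths from column 3; only rows whose analysis is in `analysis_filter`
#' become records (`"Pfam"` by default, so Pfam domain rows are kept and
#' e.g. PANTHER family rows are not). The element name is the signature
#' description, falling back to the signature accession when the
#' description cell is empty.
#'
#' @param path InterProScan TSV.
#' @param analysis_filter character set of analysis names to keep, or
#'   `NULL` to keep every row.
#' @param strict upgrade skip-warnings to errors.
#' @return a [loc_table()] with source `"interpro"`.
#' @export
interpro_to_loc <- function(path, analysis_filter = "Pfam", strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty InterProScan file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(cells, length, integer(1))
  if (any(ncol < 9L)) {
    stop(sprintf("%s line %d: expected >= 9 tab-separated columns, got %d",
                 path, which(ncol < 9L)[1], min(ncol)), call. = FALSE)
  }
  get <- function(j) vapply(cells, function(x) if (length(x) >= j) x[j] else "",
                            character(1))
  acc <- get(1); slen <- as.integer(get(3)); analysis <- get(4)
  sig_acc <- get(5); sig_desc <- get(6)
  start <- suppressWarnings(as.integer(get(7)))
  stop_ <- suppressWarnings(as.integer(get(8)))
  score <- suppressWarnings(as.numeric(get(9)))
  bad <- which(is.na(start) | is.na(stop_) | stop_ < start)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: invalid interval %s..%s", path, bad[1],
                 get(7)[bad[1]], get(8)[bad[1]]), call. = FALSE)
  }
  # one sequence row per accession, first-seen length wins
  first <- !duplicated(acc)
  seqs <- data.frame(seq_id = acc[first], length = slen[first],
                     stringsAsFactors = FALSE)
  keep <- if (is.null(analysis_filter)) rep(TRUE, length(acc)) else
    analysis %in% analysis_filter
  element <- ifelse(nzchar(trimws(sig_desc)), sig_desc, sig_acc)
  rec <- data.frame(seq_id = acc[keep], element = element[keep],
                    start = start[keep], end = stop_[keep], strand = ".",
                    score = score[keep], source = "interpro",
                    stringsAsFactors = FALSE)
  rec <- drop_oob(rec, seqs, strict, "interpro_to_loc")
  loc_table(sequences = seqs, records = rec)
}

#' Extract domains from an NCBI Batch CD-Search hit table
#'
#' Expects the `hitdata.txt` dialect: `#`-comment lines, a header line
#' (`Query<TAB>Hit type<TAB>...`), then tab-separated rows whose Query cell
#' looks like `Q#1 - >seqid`. The sequence id is the first
#' whitespace-delimited token after the first `>` (Batch CD-Search
#' truncates long FASTA headers; the first token is the stable part).
#' Lengths are not in the table, so a companion FASTA (or an explicit
#' lengths frame) is required.
#'
#' @param path hit table file.
#' @param hit_type_filter hit types to keep (default `"specific"`); `NULL`
#'   keeps all.
#' @param fasta companion FASTA supplying sequence lengths.
#' @param lengths alternatively, a data frame with `seq_id` and `length`.
#' @param strict upgrade skip-warnings to errors.
#' @return a [loc_table()] with source `"cdd"`.
#' @export
cdd_to_loc <- function(path, hit_type_filter = "specific", fasta = NULL,
                       lengths = NULL, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr_i <- which(startsWith(lines, "Query\t"))[1]
  if (is.na(hdr_i)) stop("no 'Query' header line found in ", path, call. = FALSE)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_i)]
  col <- function(name) {
    j <- match(name, hdr)
    if (is.na(j)) stop("CD-Search table missing column '", name, "'",
                       call. = FALSE)
    j
  }
  jq <- col("Query"); jt <- col("Hit type"); jf <- col("From"); jT <- col("To")
  je <- col("E-Value"); js <- col("Short name")
  cells <- strsplit(body, "\t", fixed = TRUE)
  parse_query <- function(q) {
    m <- regmatches(q, regexpr(">\\S+", q))
    if (length(m) == 0L) {
      stop(sprintf("malformed Query cell '%s' (expected 'Q#k - >seqid')", q),
           call. = FALSE)
    }
    sub("^>", "", m)
  }
  rows <- lapply(cells, function(x) {
    data.frame(seq_id = parse_query(x[jq]), hit_type = x[jt],
               start = as.integer(x[jf]), end = as.integer(x[jT]),
               score = suppressWarnings(as.numeric(x[je])),
               element = x[js], stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(seq_id = character(), hit_type = character(),
                                  start = integer(), end = integer(),
                                  score = numeric(), element = character())
  seqs <- resolve_lengths(unique(d$seq_id), lengths, fasta, "cdd_to_loc")
  keep <- if (is.null(hit_type_filter)) rep(TRUE, nrow(d)) else
    d$hit_type %in% hit_type_filter
  rec <- data.frame(seq_id = d$seq_id[keep], element = d$element[keep],
                    start = d$start[keep], end = d$end[keep], strand = ".",
                    score = d$score[keep], source = "cdd",
                    stringsAsFactors = FALSE)
  rec <- drop_oob(rec, seqs, strict, "cdd_to_loc")
  loc_table(sequences = seqs, records = rec)
}

#' Extract domains from SMART batch text output
#'
#' Parses per-protein blocks introduced by a `NAME=<seqid>` line, followed
#' by repeated feature records built from `DOMAIN=`, `START=`, `END=` and
#' optionally `EVALUE=`/`TYPE=` lines (a new `DOMAIN=` or `NAME=` line
#' closes the previous feature). Features missing `START` or `END` are
#' skipped with a warning. Sequence lengths come from `LEN=` lines when
#' present, else from a companion FASTA.
#'
#' @param path SMART batch text file.
#' @param fasta,lengths length sources for blocks without a `LEN=` line.
#' @param strict upgrade skip-warnings to errors.
#' @return a [loc_table()] with source `"smart"`.
#' @export
smart_to_loc <- function(path, fasta = NULL, lengths = NULL, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  cur_seq <- NA_character_
  seq_ids <- character(); seq_len <- list()
  feats <- list(); cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$start) || is.null(cur$end)) {
      warn_or_stop(strict,
        "smart_to_loc: feature '%s' on '%s' lacks START/END; skipped",
        cur$domain, cur$seq)
    } else if (cur$end < cur$start) {
      stop(sprintf("smart_to_loc: block '%s': END (%d) precedes START (%d)",
                   cur$seq, cur$end, cur$start), call. = FALSE)
    } else {
      feats[[length(feats) + 1L]] <<- data.frame(
        seq_id = cur$seq, element = cur$domain, start = cur$start,
        end = cur$end, strand = ".",
        score = if (is.null(cur$evalue)) NA_real_ else cur$evalue,
        source = "smart", stringsAsFactors = FALSE)
    }
    cur <<- NULL
  }
  for (raw in lines) {
    line <- trimws(raw)
    if (!nzchar(line) || startsWith(line, "#") || !grepl("=", line, fixed = TRUE))
      next
    eq <- regexpr("=", line, fixed = TRUE)
    key <- toupper(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    if (key == "NAME") {
      flush()
      cur_seq <- val
      seq_ids <- c(seq_ids, val)
    } else if (key == "LEN") {
      seq_len[[cur_seq]] <- as.integer(val)
    } else if (key == "DOMAIN") {
      flush()
      if (is.na(cur_seq)) stop("smart_to_loc: DOMAIN= before any NAME= line",
                               call. = FALSE)
      cur <- list(seq = cur_seq, domain = val)
    } else if (!is.null(cur)) {
      if (key == "START") cur$start <- as.integer(val)
      if (key == "END") cur$end <- as.integer(val)
      if (key == "EVALUE") cur$evalue <- suppressWarnings(as.numeric(val))
    }
  }
  flush()
  seq_ids <- unique(seq_ids)
  have_len <- seq_ids %in% names(seq_len)
  seqs <- data.frame(seq_id = seq_ids,
                     length = vapply(seq_ids, function(id)
                       if (id %in% names(seq_len)) seq_len[[id]] else NA_integer_,
                       integer(1)),
                     stringsAsFactors = FALSE)
  if (any(!have_len)) {
    ext <- resolve_lengths(seq_ids[!have_len], lengths, fasta, "smart_to_loc")
    seqs$length[!have_len] <- ext$length[match(seq_ids[!have_len], ext$seq_id)]
  }
  rec <- if (length(feats)) do.call(rbind, feats) else NULL
  if (!is.null(rec)) rec <- drop_oob(rec, seqs, strict, "smart_to_loc")
  loc_table(sequences = seqs, records = rec)
}

#' Extract cis-regulatory elements from a PlantCARE result table
#'
#' Expects the tab-delimited PlantCARE result layout (no header): sequence
#' name, site name, organism, position, matrix sequence, strand, matrix
#' score, function description. Each row becomes one record with the site
#' name as element, `start = position` and
#' `end = position + nchar(matrix sequence) - 1`. Rows whose site name is
#' empty or begins with `"Unnamed"` are dropped by default (they are
#' unannotated matrix hits). Promoter lengths come from a companion FASTA.
#'
#' The per-element function descriptions seen in the file are returned in
#' the `descriptions` attribute, ready for [plantcare_classify()].
#'
#' @param path PlantCARE tab file.
#' @param drop_unnamed drop empty/"Unnamed..." site rows (default `TRUE`).
#' @param fasta,lengths length sources for the promoter sequences.
#' @param strict upgrade skip-warnings to errors.
#' @return a [loc_table()] with source `"plantcare"` and a `descriptions`
#'   attribute (named character vector element -> function text).
#' @export
plantcare_to_loc <- function(path, drop_unnamed = TRUE, fasta = NULL,
                             lengths = NULL, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(x, j) if (length(x) >= j) x[j] else ""
  rows <- lapply(seq_along(cells), function(i) {
    x <- cells[[i]]
    pos <- suppressWarnings(as.integer(get(x, 4)))
    if (is.na(pos)) {
      stop(sprintf("%s line %d: non-integer position '%s'", path, i, get(x, 4)),
           call. = FALSE)
    }
    matrix_seq <- get(x, 5)
    data.frame(seq_id = get(x, 1), element = trimws(get(x, 2)),
               start = pos, end = pos + nchar(matrix_seq) - 1L,
               strand = if (get(x, 6) %in% c("+", "-")) get(x, 6) else ".",
               score = suppressWarnings(as.numeric(get(x, 7))),
               descr = get(x, 8), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(seq_id = character(), element = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), score = numeric(),
                                  descr = character())
  if (drop_unnamed) {
    d <- d[nzchar(d$element) & !startsWith(d$element, "Unnamed"), ,
           drop = FALSE]
  }
  seqs <- resolve_lengths(unique(d$seq_id), lengths, fasta, "plantcare_to_loc")
  descr <- d$descr[nzchar(d$descr)]
  names(descr) <- d$element[nzchar(d$descr)]
  descr <- descr[!duplicated(names(descr))]
  rec <- data.frame(seq_id = d$seq_id, element = d$element, start = d$start,
                    end = d$end, strand = d$strand, score = d$score,
                    source = "plantcare", stringsAsFactors = FALSE)
  rec <- drop_oob(rec, seqs, strict, "plantcare_to_loc")
  out <- loc_table(sequences = seqs, records = rec)
  attr(out, "descriptions") <- descr
  out
}

#' @rdname interpro_to_loc
#' @export
pfam_to_loc <- function(path, analysis_filter = "Pfam", strict = FALSE) {
  interpro_to_loc(path, analysis_filter = analysis_filter, strict = strict)
}
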