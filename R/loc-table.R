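#' Canonical element-location table
#'
#' A `loc_table` is the hub data structure of the package: every parser
#' writes one and every plotting function reads one. It couples a set of
#' sequences (with their lengths, in bp for nucleotide tracks or aa for
#' protein tracks) with a set of element occurrences on those sequences.
#' Coordinates are 1-based inclusive throughout, matching GFF convention;
#' renderers convert to a continuous axis as `[start - 1, end]`.
#'
#' A sequence with no elements is legal and still gets a rendered backbone
#' line: tree-aligned composites need rows for leaves without hits.
#'
#' @param sequences data frame with columns `seq_id` (character, unique) and
#'   `length` (integer >= 1). Row order is preserved exactly: it is the
#'   default row order of every figure when no tree is supplied.
#' @param records data frame with columns `seq_id`, `element`, `start`,
#'   `end`, and optionally `strand` (one of `"+"`, `"-"`, `"."`), `score`
#'   (numeric, `NA` for absent) and `source` (provenance tag). Missing
#'   optional columns are filled with `"."`, `NA` and `"user"`.
#' @param check if `TRUE` (default) the constructor stops on any invariant
#'   violation; see [validate_loc()].
#' @return an object of class `loc_table`.
#' @seealso [validate_loc()], [read_loc_files()], [write_loc_files()],
#'   [merge_loc()], [filter_elements()]
#' @examples
#' tab <- loc_table(
#'   sequences = data.frame(seq_id = "s1", length = 100L),
#'   records   = data.frame(seq_id = "s1", element = "CDS",
#'                          start = 10L, end = 40L, strand = "+")
#' )
#' tab
#' @export
loc_table <- function(sequences = NULL, records = NULL, check = TRUE) {
  sequences <- normalize_sequences(sequences)
  records <- normalize_records(records)
  tab <- structure(list(sequences = sequences, records = records),
                   class = "loc_table")
  if (check) {
    v <- validate_loc(tab)
    if (length(v) > 0L) {
      stop("invalid loc_table:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
    }
  }
  tab
}

VALID_SOURCES <- c("gff", "gtf", "meme", "mast", "interpro", "cdd", "smart",
                   "plantcare", "user")

normalize_sequences <- function(sequences) {
  if (is.null(sequences)) {
    sequences <- data.frame(seq_id = character(), length = integer())
  }
  stopifnot(is.data.frame(sequences))
  if (!all(c("seq_id", "length") %in% names(sequences))) {
    stop("sequences must have columns 'seq_id' and 'length'", call. = FALSE)
  }
  data.frame(seq_id = as.character(sequences$seq_id),
             length = as.integer(sequences$length),
             stringsAsFactors = FALSE)
}

normalize_records <- function(records) {
  empty <- data.frame(seq_id = character(), element = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) return(empty)
  stopifnot(is.data.frame(records))
  need <- c("seq_id", "element", "start", "end")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    seq_id  = as.character(records$seq_id),
    element = as.character(records$element),
    start   = as.integer(records$start),
    end     = as.integer(records$end),
    strand  = if ("strand" %in% names(records))
                as.character(records$strand) else ".",
    score   = if ("score" %in% names(records))
                as.numeric(records$score) else NA_real_,
    source  = if ("source" %in% names(records))
                as.character(records$source) else "user",
    stringsAsFactors = FALSE
  )
  out$strand[is.na(out$strand) | !(out$strand %in% c("+", "-"))] <- "."
  rownames(out) <- NULL
  if ("category" %in% names(records)) out$category <- as.character(records$category)
  out
}

#' Validate a loc_table against its invariants
#'
#' Checks every model invariant and reports violations instead of raising:
#' coordinates 1-based with `start <= end`, non-empty element names, unique
#' sequence ids, positive lengths, every record's `seq_id` declared, and
#' every record's `end` within its sequence length.
#'
#' @param table a [loc_table()] (or a bare list with `sequences`/`records`).
#' @return character vector of human-readable violation descriptions; empty
#'   when all invariants hold. Each violation names the offending sequence or
#'   record and the broken rule.
#' @export
validate_loc <- function(table) {
  s <- table$sequences
  r <- table$records
  out <- character()
  dup <- unique(s$seq_id[duplicated(s$seq_id)])
  for (id in dup) out <- c(out, sprintf("sequence '%s': duplicated seq_id", id))
  bad_len <- which(is.na(s$length) | s$length < 1L)
  for (i in bad_len) {
    out <- c(out, sprintf("sequence '%s': length must be >= 1", s$seq_id[i]))
  }
  if (nrow(r) > 0L) {
    len <- stats::setNames(s$length, s$seq_id)
    for (i in seq_len(nrow(r))) {
      tag <- sprintf("record %d (%s, %s)", i, r$seq_id[i], r$element[i])
      if (is.na(r$start[i]) || is.na(r$end[i]) || r$start[i] < 1L) {
        out <- c(out, paste0(tag, ": start must be >= 1"))
      } else if (r$end[i] < r$start[i]) {
        out <- c(out, paste0(tag, ": end precedes start"))
      }
      if (!nzchar(trimws(r$element[i]))) {
        out <- c(out, paste0(tag, ": empty element name"))
      }
      if (!(r$seq_id[i] %in% s$seq_id)) {
        out <- c(out, paste0(tag, ": unknown sequence"))
      } else if (!is.na(r$end[i]) && !is.na(len[[r$seq_id[i]]]) &&
                 r$end[i] > len[[r$seq_id[i]]]) {
        out <- c(out, sprintf("%s: end exceeds length (%d > %d)",
                              tag, r$end[i], len[[r$seq_id[i]]]))
      }
    }
  }
  out
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("loc_table: %d sequence(s), %d record(s)\n",
              nrow(x$sequences), nrow(x$records)))
  if (nrow(x$records) > 0L) {
    el <- sort(unique(x$records$element))
    cat("elements: ", paste(utils::head(el, 8L), collapse = ", "),
        if (length(el) > 8L) sprintf(", ... (%d total)", length(el)) else "",
        "\n", sep = "")
    cat("sources:  ", paste(sort(unique(x$records$source)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.loc_table <- function(object, ...) {
  r <- object$records
  cat(sprintf("loc_table with %d sequence(s) (length %s..%s) and %d record(s)\n",
              nrow(object$sequences),
              if (nrow(object$sequences)) min(object$sequences$length) else "-",
              if (nrow(object$sequences)) max(object$sequences$length) else "-",
              nrow(r)))
  if (nrow(r) > 0L) {
    print(table(element = r$element))
  }
  invisible(object)
}

# --- the two-file on-disk format ------------------------------------------
# lengths TSV:  ID <TAB> length
# elements TSV: ID <TAB> element <TAB> start <TAB> end <TAB> strand
#               <TAB> score <TAB> source        (empty score cell = absent)
# UTF-8, LF line endings.

#' Read the canonical two-file element-location format
#'
#' @param lengths_path path to the lengths TSV (`ID<TAB>length` header).
#' @param elements_path path to the elements TSV
#'   (`ID element start end strand score source` header, tab-separated).
#'   The `strand`, `score` and `source` columns are optional; absent values
#'   default to `"."`, `NA` and `"user"`.
#' @return a validated [loc_table()].
#' @export
read_loc_files <- function(lengths_path, elements_path) {
  for (p in c(lengths_path, elements_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  for (col in c("ID", "length")) {
    if (!(col %in% names(len))) {
      stop(sprintf("lengths file '%s' missing mandatory column '%s'",
                   lengths_path, col), call. = FALSE)
    }
  }
  lnum <- suppressWarnings(as.integer(len$length))
  bad <- which(is.na(lnum) & nzchar(len$length))
  if (length(bad) > 0L) {
    stop(sprintf("lengths file '%s' line %d: non-integer length '%s'",
                 lengths_path, bad[1] + 1L, len$length[bad[1]]), call. = FALSE)
  }
  el <- utils::read.delim(elements_path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  for (col in c("ID", "element", "start", "end")) {
    if (!(col %in% names(el))) {
      stop(sprintf("elements file '%s' missing mandatory column '%s'",
                   elements_path, col), call. = FALSE)
    }
  }
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(el[[col]]))
    bad <- which(is.na(v) & nzchar(el[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("elements file '%s' line %d: non-integer %s '%s'",
                   elements_path, bad[1] + 1L, col, el[[col]][bad[1]]),
           call. = FALSE)
    }
  }
  rec <- data.frame(
    seq_id  = el$ID,
    element = el$element,
    start   = as.integer(el$start),
    end     = as.integer(el$end),
    strand  = if ("strand" %in% names(el)) el$strand else ".",
    score   = if ("score" %in% names(el))
                suppressWarnings(as.numeric(ifelse(nzchar(el$score),
                                                   el$score, NA))) else NA_real_,
    source  = if ("source" %in% names(el)) el$source else "user",
    stringsAsFactors = FALSE
  )
  if ("category" %in% names(el)) rec$category <- el$category
  loc_table(
    sequences = data.frame(seq_id = len$ID, length = lnum,
                           stringsAsFactors = FALSE),
    records = rec
  )
}

fmt_score <- function(score) {
  ifelse(is.na(score), "",
         vapply(score, function(v) format(v, digits = 15, scientific = NA,
                                          trim = TRUE), character(1)))
}

#' Write a loc_table to the canonical two-file format
#'
#' Emits UTF-8, LF-terminated TSVs. An absent score is an empty cell, never
#' the string `"NA"`. [read_loc_files()] on the output reproduces the input
#' field by field.
#'
#' @param table a valid [loc_table()]; refused (with the full
#'   [validate_loc()] report) otherwise.
#' @param lengths_path,elements_path output paths.
#' @return invisibly, the two paths.
#' @export
write_loc_files <- function(table, lengths_path, elements_path) {
  v <- validate_loc(table)
  if (length(v) > 0L) {
    stop("refusing to write invalid loc_table:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  s <- table$sequences
  r <- table$records
  lines_len <- c("ID\tlength",
                 if (nrow(s)) paste(s$seq_id, s$length, sep = "\t"))
  has_cat <- "category" %in% names(r)
  hdr <- "ID\telement\tstart\tend\tstrand\tscore\tsource"
  if (has_cat) hdr <- paste0(hdr, "\tcategory")
  body <- if (nrow(r) > 0L) {
    cells <- cbind(r$seq_id, r$element, r$start, r$end, r$strand,
                   fmt_score(r$score), r$source,
                   if (has_cat) r$category)
    apply(cells, 1L, paste, collapse = "\t")
  }
  writeLines(c(lines_len), lengths_path, sep = "\n", useBytes = TRUE)
  writeLines(c(hdr, body), elements_path, sep = "\n", useBytes = TRUE)
  invisible(c(lengths_path, elements_path))
}

#' Merge several loc_tables
#'
#' The sequence set of the result is the union of the inputs' sequences in
#' first-appearance order; records are concatenated in input order. The same
#' `seq_id` carrying two different lengths is an error, never a silent
#' first-wins: silent resolution would corrupt tree-aligned panels.
#'
#' @param tables a list of [loc_table()] objects.
#' @return a [loc_table()].
#' @export
merge_loc <- function(tables) {
  stopifnot(is.list(tables))
  if (length(tables) == 0L) return(loc_table())
  seqs <- data.frame(seq_id = character(), length = integer())
  recs <- list()
  for (tab in tables) {
    stopifnot(inherits(tab, "loc_table"))
    for (i in seq_len(nrow(tab$sequences))) {
      id <- tab$sequences$seq_id[i]
      ln <- tab$sequences$length[i]
      j <- match(id, seqs$seq_id)
      if (is.na(j)) {
        seqs <- rbind(seqs, data.frame(seq_id = id, length = ln))
      } else if (seqs$length[j] != ln) {
        stop(sprintf(
          "merge conflict: sequence '%s' has length %d in one table and %d in another",
          id, seqs$length[j], ln), call. = FALSE)
      }
    }
    recs[[length(recs) + 1L]] <- tab$records
  }
  loc_table(sequences = seqs, records = do.call(rbind, recs))
}

#' Filter the records of a loc_table
#'
#' Sequences are never dropped: a sequence with zero surviving records stays
#' in the table so that figure rows remain aligned across panels.
#'
#' @param table a [loc_table()].
#' @param keep either a predicate `function(record_row) TRUE/FALSE` applied
#'   to each one-row data frame, or a logical/character vector: a character
#'   vector keeps records whose `element` is in the set.
#' @return a [loc_table()] with the surviving records, order preserved.
#' @export
filter_elements <- function(table, keep) {
  stopifnot(inherits(table, "loc_table"))
  r <- table$records
  sel <- if (is.function(keep)) {
    if (nrow(r) == 0L) logical(0) else
      vapply(seq_len(nrow(r)), function(i) isTRUE(keep(r[i, , drop = FALSE])),
             logical(1))
  } else if (is.character(keep)) {
    r$element %in% keep
  } else if (is.logical(keep)) {
    if (length(keep) != nrow(r)) stop("logical keep has wrong length")
    keep
  } else stop("keep must be a function, character or logical vector")
  loc_table(sequences = table$sequences, records = r[sel, , drop = FALSE])
}

# identical-content comparison used by tests and fixtures round-trips
loc_equal <- function(a, b, check_score = TRUE) {
  sa <- a$sequences; sb <- b$sequences
  if (!identical(sa$seq_id, sb$seq_id) || !identical(sa$length, sb$length))
    return(FALSE)
  ra <- a$records; rb <- b$records
  if (nrow(ra) != nrow(rb)) return(FALSE)
  cols <- c("seq_id", "element", "start", "end", "strand", "source")
  for (col in cols) if (!identical(ra[[col]], rb[[col]])) return(FALSE)
  if (check_score) {
    same_na <- identical(is.na(ra$score), is.na(rb$score))
    ok <- same_na && all(abs(ra$score - rb$score) <= 1e-12 * pmax(1, abs(ra$score)),
                         na.rm = TRUE)
    if (!ok) return(FALSE)
  }
  TRUE
}
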