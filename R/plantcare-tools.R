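# PlantCARE workflow pieces: splitting promoter FASTA files at the upload
# size limit, classifying cis-elements into functional categories, and the
# gene x category count matrix behind the advance plot.

serialize_fasta_record <- function(header, seq, wrap = 60L) {
  n <- nchar(seq)
  starts <- seq.int(1L, max(n, 1L), by = wrap)
  body <- substring(seq, starts, pmin(starts + wrap - 1L, n))
  if (n == 0L) body <- character()
  c(paste0(">", header), body)
}

#' Split a multi-FASTA at an upload size limit
#'
#' The PlantCARE submission form rejects files larger than 100 kb, so
#' larger promoter sets have to be sent in pieces. Records are packed
#' greedily in input order: each record is appended to the current chunk
#' until adding the next one would push the chunk past the limit, then a
#' new chunk starts. Sequences are re-wrapped at 60 columns with LF line
#' endings; the limit applies to the serialized chunk bytes. Concatenating
#' the chunks reproduces the input records in order.
#'
#' @param path multi-FASTA file.
#' @param max_kb size limit per chunk in kilobytes of 1000 bytes
#'   (default 100, the PlantCARE limit).
#' @param outdir output directory (default: directory of `path`).
#' @return character vector of chunk file paths
#'   (`<stem>_part1.fa`, `_part2.fa`, ...), length 1 when the input fits.
#' @export
split_fasta <- function(path, max_kb = 100, outdir = dirname(path)) {
  ss <- Biostrings::readBStringSet(path)
  limit <- as.numeric(max_kb) * 1000
  recs <- lapply(seq_along(ss),
                 function(i) serialize_fasta_record(names(ss)[i],
                                                    as.character(ss[[i]])))
  sizes <- vapply(recs, function(r) sum(nchar(r, type = "bytes") + 1L),
                  numeric(1))
  too_big <- which(sizes > limit)
  if (length(too_big) > 0L) {
    stop(sprintf(
      "record '%s' alone serializes to %d bytes, over the %d byte limit; unsplittable",
      names(ss)[too_big[1]], as.integer(sizes[too_big[1]]), as.integer(limit)),
      call. = FALSE)
  }
  chunks <- list(); cur <- integer(); cur_size <- 0
  for (i in seq_along(recs)) {
    if (length(cur) > 0L && cur_size + sizes[i] > limit) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- integer(); cur_size <- 0
    }
    cur <- c(cur, i); cur_size <- cur_size + sizes[i]
  }
  if (length(cur) > 0L) chunks[[length(chunks) + 1L]] <- cur
  stem <- sub("\\.(fa|fasta|fna|txt)$", "", basename(path))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(length(chunks))
  for (k in seq_along(chunks)) {
    paths[k] <- file.path(outdir, sprintf("%s_part%d.fa", stem, k))
    writeLines(unlist(recs[chunks[[k]]]), paths[k], sep = "\n",
               useBytes = TRUE)
  }
  paths
}

#' Category rules for cis-regulatory elements
#'
#' A category map is an ordered rule list: each rule pairs a
#' case-insensitive pattern (matched as a regular expression against the
#' element's function description, or against the element name itself when
#' no description is available) with a category name. The first matching
#' rule wins; unmatched records fall into `fallback_category`.
#'
#' `read_category_map()` loads a two-column TSV (`pattern<TAB>category`
#' header, `#`-comments allowed); `default_category_map()` loads the map
#' shipped with the package, which follows the conventional PlantCARE
#' groupings (light responsiveness, hormone responsiveness, stress/defense
#' responsiveness, growth & development, promoter core, Others).
#'
#' @param path category map TSV.
#' @param fallback_category category used when no rule matches.
#' @return an object of class `category_map`.
#' @export
read_category_map <- function(path, fallback_category = "Others") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (length(cells) > 0L && identical(tolower(cells[[1]][1]), "pattern")) {
    cells <- cells[-1]
  }
  bad <- which(vapply(cells, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: rule line %d lacks a category column", path, bad[1]),
         call. = FALSE)
  }
  category_map(
    patterns = vapply(cells, `[`, character(1), 1L),
    categories = vapply(cells, `[`, character(1), 2L),
    fallback_category = fallback_category)
}

#' @rdname read_category_map
#' @param patterns,categories parallel character vectors of rules, applied
#'   in order.
#' @export
category_map <- function(patterns, categories, fallback_category = "Others") {
  stopifnot(length(patterns) == length(categories), length(patterns) > 0L,
            all(nzchar(categories)), nzchar(fallback_category))
  structure(list(patterns = as.character(patterns),
                 categories = as.character(categories),
                 fallback_category = fallback_category),
            class = "category_map")
}

#' @rdname read_category_map
#' @export
default_category_map <- function(fallback_category = "Others") {
  read_category_map(system.file("extdata", "plantcare_categories.tsv",
                                package = "seqtracks", mustWork = TRUE),
                    fallback_category = fallback_category)
}

#' @export
print.category_map <- function(x, ...) {
  cat(sprintf("category_map: %d rule(s), fallback '%s'\n",
              length(x$patterns), x$fallback_category))
  for (i in seq_along(x$patterns)) {
    cat(sprintf("  %-40s -> %s\n", x$patterns[i], x$categories[i]))
  }
  invisible(x)
}

apply_category_map <- function(texts, cmap) {
  out <- rep(cmap$fallback_category, length(texts))
  undecided <- rep(TRUE, length(texts))
  for (i in seq_along(cmap$patterns)) {
    hit <- undecided & grepl(cmap$patterns[i], texts, ignore.case = TRUE)
    out[hit] <- cmap$categories[i]
    undecided[hit] <- FALSE
  }
  out
}

#' Classify cis-elements into functional categories
#'
#' Adds a `category` column to the records of a [loc_table()]: each record
#' is matched — first on its function description (from `descriptions` or
#' the table's own `descriptions` attribute set by [plantcare_to_loc()]),
#' falling back to the element name when no description exists — against
#' the category map's rules in order; the first match wins and unmatched
#' records get the fallback category. Classification relabels, never
#' drops: the record count is unchanged and the operation is idempotent.
#'
#' @param table a [loc_table()].
#' @param descriptions named character vector, element name -> function
#'   text; defaults to the table's `descriptions` attribute.
#' @param cmap a [category_map()]; defaults to [default_category_map()].
#' @return the table with a `category` column on its records.
#' @export
plantcare_classify <- function(table, descriptions = NULL, cmap = NULL) {
  stopifnot(inherits(table, "loc_table"))
  if (is.null(descriptions)) descriptions <- attr(table, "descriptions")
  if (is.null(cmap)) cmap <- default_category_map()
  stopifnot(inherits(cmap, "category_map"))
  r <- table$records
  texts <- r$element
  if (!is.null(descriptions) && length(descriptions) > 0L) {
    has <- r$element %in% names(descriptions) &
      nzchar(descriptions[r$element])
    texts[has] <- unname(descriptions[r$element[has]])
  }
  r$category <- apply_category_map(texts, cmap)
  out <- loc_table(sequences = table$sequences, records = r)
  attr(out, "descriptions") <- descriptions
  out
}

#' Count elements (or categories) per sequence
#'
#' @param table a [loc_table()]; must carry a `category` column (see
#'   [plantcare_classify()]) when `by = "category"`.
#' @param by count distinct `"element"` names or `"category"` labels.
#' @return an integer matrix of class `count_matrix`: one row per sequence
#'   of the table (including all-zero rows for sequences without records,
#'   in table order), one column per distinct name in sorted order. The
#'   grand total equals the table's record count.
#' @export
count_matrix <- function(table, by = c("element", "category")) {
  by <- match.arg(by)
  stopifnot(inherits(table, "loc_table"))
  r <- table$records
  labels <- if (by == "element") r$element else {
    if (!("category" %in% names(r))) {
      stop("count by category needs a classified table; run plantcare_classify first",
           call. = FALSE)
    }
    r$category
  }
  rows <- table$sequences$seq_id
  cols <- sort(unique(labels), method = "radix")
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  if (nrow(r) > 0L) {
    tab <- table(factor(r$seq_id, levels = rows),
                 factor(labels, levels = cols))
    m[] <- as.integer(tab)
  }
  structure(m, class = c("count_matrix", class(m)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d sequence(s) x %d column(s), %d element(s) total\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}
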