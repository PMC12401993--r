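# MEME suite result parsing. Two XML flavors are supported:
#   meme.xml — de novo discovery output; declares the training set, motif
#     definitions and contributing sites (0-based positions, with the
#     aligned site letters inline);
#   mast.xml — scanning output; declares motifs (id/alt/width) and hits per
#     sequence (1-based positions, motif referenced by index or id).

meme_flavor <- function(doc) {
  root <- xml2::xml_name(xml2::xml_root(doc))
  if (toupper(root) == "MEME") return("meme_xml")
  if (tolower(root) == "mast") return("mast_xml")
  stop("not a MEME suite XML file (root element <", root, ">)", call. = FALSE)
}

motif_display_name <- function(node) {
  alt <- xml2::xml_attr(node, "alt")
  nm <- xml2::xml_attr(node, "name")
  id <- xml2::xml_attr(node, "id")
  if (!is.na(alt) && nzchar(alt)) alt else if (!is.na(nm) && nzchar(nm)) nm else id
}

warn_or_stop <- function(strict, ...) {
  msg <- sprintf(...)
  if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
}

#' Extract motif occurrences from a MEME or MAST XML file
#'
#' Sequences (with their declared lengths) come from the file's training
#' set (`meme.xml`) or `<sequences>` section (`mast.xml`); each motif
#' occurrence becomes one record with the motif's display name as element,
#' `end = start + width - 1` and the occurrence p-value as score.
#' Occurrences extending past the declared sequence length are skipped with
#' a warning (or an error under `strict`).
#'
#' @param path XML file.
#' @param flavor `"meme_xml"`, `"mast_xml"` or `"auto"` (root element).
#' @param strict upgrade skip-warnings to errors.
#' @return a [loc_table()] with source `"meme"` or `"mast"`.
#' @export
meme_to_loc <- function(path, flavor = c("auto", "meme_xml", "mast_xml"),
                        strict = FALSE) {
  flavor <- match.arg(flavor)
  doc <- xml2::read_xml(path)
  actual <- meme_flavor(doc)
  if (flavor != "auto" && flavor != actual) {
    stop(sprintf("file is %s but flavor %s was requested", actual, flavor),
         call. = FALSE)
  }
  if (actual == "meme_xml") parse_meme_xml(doc, strict) else
    parse_mast_xml(doc, strict)
}

parse_meme_xml <- function(doc, strict) {
  seq_nodes <- xml2::xml_find_all(doc, ".//training_set/sequence")
  if (length(seq_nodes) == 0L) stop("meme.xml: no <training_set> sequences",
                                    call. = FALSE)
  seq_ids <- xml2::xml_attr(seq_nodes, "id")
  seqs <- data.frame(
    seq_id = xml2::xml_attr(seq_nodes, "name"),
    length = as.integer(xml2::xml_attr(seq_nodes, "length")),
    stringsAsFactors = FALSE)
  id2name <- stats::setNames(seqs$seq_id, seq_ids)
  len <- stats::setNames(seqs$length, seqs$seq_id)

  recs <- list()
  for (motif in xml2::xml_find_all(doc, ".//motifs/motif")) {
    mname <- motif_display_name(motif)
    width <- as.integer(xml2::xml_attr(motif, "width"))
    for (site in xml2::xml_find_all(motif, ".//contributing_site")) {
      sid <- xml2::xml_attr(site, "sequence_id")
      name <- id2name[[sid]]
      if (is.null(name)) {
        stop(sprintf("meme.xml: contributing_site references undeclared sequence '%s'",
                     sid), call. = FALSE)
      }
      start <- as.integer(xml2::xml_attr(site, "position")) + 1L  # 0-based in file
      end <- start + width - 1L
      if (end > len[[name]]) {
        warn_or_stop(strict,
          "meme.xml: site of %s at %d..%d exceeds length %d of '%s'; skipped",
          mname, start, end, len[[name]], name)
        next
      }
      strand <- xml2::xml_attr(site, "strand")
      recs[[length(recs) + 1L]] <- data.frame(
        seq_id = name, element = mname, start = start, end = end,
        strand = if (identical(strand, "minus")) "-" else "+",
        score = as.numeric(xml2::xml_attr(site, "pvalue")),
        source = "meme", stringsAsFactors = FALSE)
    }
  }
  loc_table(sequences = seqs,
            records = if (length(recs)) do.call(rbind, recs))
}

parse_mast_xml <- function(doc, strict) {
  motif_nodes <- xml2::xml_find_all(doc, ".//motifs/motif")
  mids <- xml2::xml_attr(motif_nodes, "id")
  mnames <- vapply(motif_nodes, motif_display_name, character(1))
  mwidths <- as.integer(xml2::xml_attr(motif_nodes, "width"))
  seq_nodes <- xml2::xml_find_all(doc, ".//sequences/sequence")
  if (length(seq_nodes) == 0L) stop("mast.xml: no <sequences>", call. = FALSE)
  seqs <- data.frame(
    seq_id = xml2::xml_attr(seq_nodes, "name"),
    length = as.integer(xml2::xml_attr(seq_nodes, "length")),
    stringsAsFactors = FALSE)
  recs <- list()
  for (i in seq_along(seq_nodes)) {
    for (hit in xml2::xml_find_all(seq_nodes[[i]], ".//hit")) {
      idx <- xml2::xml_attr(hit, "idx")
      mid <- xml2::xml_attr(hit, "motif")
      k <- if (!is.na(idx)) as.integer(idx) + 1L else match(mid, mids)
      if (is.na(k) || k < 1L || k > length(mids)) {
        stop(sprintf("mast.xml: hit on '%s' references undeclared motif '%s'",
                     seqs$seq_id[i], if (!is.na(idx)) idx else mid),
             call. = FALSE)
      }
      start <- as.integer(xml2::xml_attr(hit, "pos"))  # 1-based in file
      end <- start + mwidths[k] - 1L
      if (end > seqs$length[i] || start < 1L) {
        warn_or_stop(strict,
          "mast.xml: hit of %s at %d..%d outside sequence '%s' (length %d); skipped",
          mnames[k], start, end, seqs$seq_id[i], seqs$length[i])
        next
      }
      recs[[length(recs) + 1L]] <- data.frame(
        seq_id = seqs$seq_id[i], element = mnames[k], start = start, end = end,
        strand = if (identical(xml2::xml_attr(hit, "rc"), "y")) "-" else "+",
        score = as.numeric(xml2::xml_attr(hit, "pvalue")),
        source = "mast", stringsAsFactors = FALSE)
    }
  }
  loc_table(sequences = seqs,
            records = if (length(recs)) do.call(rbind, recs))
}

#' Extract the aligned site sequences of every motif from meme.xml
#'
#' Site strings are only present in `meme.xml` (MAST reports hits without
#' the matched letters), so a `mast.xml` input is an error.
#'
#' @param path a `meme.xml` file.
#' @return named list, one character vector of site strings per motif
#'   display name, in file order; every string's length equals the motif
#'   width.
#' @export
meme_seq <- function(path) {
  doc <- xml2::read_xml(path)
  if (meme_flavor(doc) != "meme_xml") {
    stop("meme_seq needs meme.xml input: mast.xml does not carry site sequences",
         call. = FALSE)
  }
  out <- list()
  for (motif in xml2::xml_find_all(doc, ".//motifs/motif")) {
    mname <- motif_display_name(motif)
    sites <- character()
    for (site in xml2::xml_find_all(motif, ".//contributing_site")) {
      letters <- xml2::xml_attr(
        xml2::xml_find_all(site, ".//site/letter_ref"), "letter_id")
      sites <- c(sites, paste(letters, collapse = ""))
    }
    out[[mname]] <- sites
  }
  out
}
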