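# Gene models from GFF3/GTF, and their conversion to element locations.
# File reading goes through rtracklayer; everything downstream (transcript
# selection, re-basing, UTR/intron derivation) is interval arithmetic here.

# interval utilities: matrices with columns start, end, 1-based inclusive ----

iv <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

iv_union_len <- function(m) {
  if (nrow(m) == 0L) return(0L)
  tot <- 0L; cur_s <- m[1, 1]; cur_e <- m[1, 2]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur_e + 1L) cur_e <- max(cur_e, m[i, 2])
    else { tot <- tot + (cur_e - cur_s + 1L); cur_s <- m[i, 1]; cur_e <- m[i, 2] }
  }
  tot + (cur_e - cur_s + 1L)
}

# a \ b for sorted non-overlapping interval sets
iv_setdiff <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    segs <- list(c(a[i, 1], a[i, 2]))
    for (j in seq_len(nrow(b))) {
      nxt <- list()
      for (s in segs) {
        if (b[j, 2] < s[1] || b[j, 1] > s[2]) { nxt[[length(nxt) + 1L]] <- s; next }
        if (b[j, 1] > s[1]) nxt[[length(nxt) + 1L]] <- c(s[1], b[j, 1] - 1L)
        if (b[j, 2] < s[2]) nxt[[length(nxt) + 1L]] <- c(b[j, 2] + 1L, s[2])
      }
      segs <- nxt
    }
    out <- c(out, segs)
  }
  if (length(out) == 0L) return(iv(integer(), integer()))
  iv(vapply(out, `[`, integer(1), 1L), vapply(out, `[`, integer(1), 2L))
}

# gaps between consecutive intervals (the introns of an exon chain)
iv_gaps <- function(m) {
  if (nrow(m) < 2L) return(iv(integer(), integer()))
  s <- integer(); e <- integer()
  for (i in seq_len(nrow(m) - 1L)) {
    if (m[i + 1L, 1] > m[i, 2] + 1L) {
      s <- c(s, m[i, 2] + 1L); e <- c(e, m[i + 1L, 1] - 1L)
    }
  }
  iv(s, e)
}

# TRUE iff every interval of a lies inside the union of b
iv_within <- function(a, b) {
  nrow(iv_setdiff(a, b)) == 0L
}

# dialect detection: attribute column syntax of the first feature line ------

detect_gff_dialect <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("no feature lines in ", path, call. = FALSE)
    if (startsWith(line, "#") || !nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L) stop("malformed feature line in ", path, call. = FALSE)
    attr9 <- fields[9]
    if (grepl("\\w+ +\"[^\"]*\"", attr9)) return("gtf")
    if (grepl("\\w+=[^;]*", attr9)) return("gff3")
    stop("cannot detect annotation dialect of ", path,
         ": attribute column is neither key=value (GFF3) nor key \"value\" (GTF)",
         call. = FALSE)
  }
}

#' Read gene models from a GFF3 or GTF file
#'
#' Parses the file with `rtracklayer` and assembles one model per
#' transcript: its gene, strand, chromosome, exon chain, CDS intervals and
#' any explicit UTR features. This is the single source of truth behind both
#' [gff_to_loc()] and [gene_stats()].
#'
#' @param path annotation file.
#' @param dialect `"gff3"`, `"gtf"` or `"auto"` (inspects the attribute
#'   syntax of the first feature line).
#' @return a list with `dialect` and `transcripts`, the latter a list of
#'   per-transcript models (gene_id, transcript_id, chrom, strand, exons,
#'   cds, utr5, utr3 as start/end interval matrices) in file order of first
#'   appearance.
#' @export
read_gene_models <- function(path, dialect = c("auto", "gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") dialect <- detect_gff_dialect(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  df$seqnames <- as.character(df$seqnames)

  if (dialect == "gtf") {
    df$tx <- as.character(df$transcript_id)
    df$gene <- as.character(df$gene_id)
  } else {
    # flatten Parent (CharacterList): a feature with several parents counts
    # once per parent
    par <- df$Parent
    if (is.list(par) || inherits(par, "CharacterList")) {
      par <- vapply(as.list(par), function(p)
        if (length(p) == 0L) NA_character_ else as.character(p[[1]]),
        character(1))
    }
    df$tx <- par
    id2type <- stats::setNames(df$type, as.character(df$ID))
    id2par <- stats::setNames(par, as.character(df$ID))
    df$gene <- ifelse(is.na(df$tx), NA_character_,
                      ifelse(is.na(id2par[df$tx]), df$tx, id2par[df$tx]))
  }

  part_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR",
                  "5UTR", "3UTR", "five_prime_utr", "three_prime_utr")
  parts <- df[df$type %in% part_types & !is.na(df$tx), , drop = FALSE]
  if (nrow(parts) == 0L) stop("no exon/CDS features found in ", path, call. = FALSE)

  tx_ids <- unique(parts$tx)
  transcripts <- vector("list", length(tx_ids))
  for (k in seq_along(tx_ids)) {
    p <- parts[parts$tx == tx_ids[k], , drop = FALSE]
    get_iv <- function(types) {
      q <- p[p$type %in% types, , drop = FALSE]
      iv(q$start, q$end)
    }
    exons <- get_iv("exon")
    cds <- get_iv("CDS")
    if (nrow(exons) == 0L) exons <- cds  # CDS-only annotations
    if (nrow(cds) > 0L && !iv_within(cds, exons)) {
      stop(sprintf("transcript '%s': CDS lies outside its exons", tx_ids[k]),
           call. = FALSE)
    }
    transcripts[[k]] <- list(
      gene_id = p$gene[1],
      transcript_id = tx_ids[k],
      chrom = p$seqnames[1],
      strand = if (p$strand[1] %in% c("+", "-")) p$strand[1] else "+",
      exons = exons,
      cds = cds,
      utr5 = get_iv(c("five_prime_UTR", "5UTR", "five_prime_utr")),
      utr3 = get_iv(c("three_prime_UTR", "3UTR", "three_prime_utr"))
    )
  }
  list(dialect = dialect, transcripts = transcripts)
}

tx_span <- function(tx) c(min(tx$exons[, 1]), max(tx$exons[, 2]))

select_transcripts <- function(transcripts, policy) {
  if (policy == "all") return(transcripts)
  genes <- vapply(transcripts, `[[`, character(1), "gene_id")
  keep <- integer()
  for (g in unique(genes)) {
    idx <- which(genes == g)
    if (policy == "first") { keep <- c(keep, idx[1]); next }
    spans <- vapply(idx, function(i) diff(tx_span(transcripts[[i]])) + 1L,
                    integer(1))
    keep <- c(keep, idx[which.max(spans)])  # ties: first in file order
  }
  transcripts[keep]
}

# derive the element chain of one transcript, re-based so it starts at 1
tx_elements <- function(tx) {
  off <- tx_span(tx)[1] - 1L
  sh <- function(m) { m[, 1] <- m[, 1] - off; m[, 2] <- m[, 2] - off; m }
  exons <- sh(tx$exons); cds <- sh(tx$cds)
  utr5 <- sh(tx$utr5); utr3 <- sh(tx$utr3)
  rows <- list()
  add <- function(m, name) {
    for (i in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <<- data.frame(
        element = name, start = m[i, 1], end = m[i, 2],
        stringsAsFactors = FALSE)
    }
  }
  add(cds, "CDS")
  if (nrow(utr5) > 0L || nrow(utr3) > 0L) {
    # explicit UTR features are used verbatim
    add(utr5, "five_prime_UTR")
    add(utr3, "three_prime_UTR")
  } else if (nrow(cds) > 0L) {
    utr <- iv_setdiff(exons, cds)
    if (nrow(utr) > 0L) {
      before <- utr[, 2] < min(cds[, 1])  # genomically left of the CDS
      lab_left <- if (tx$strand == "-") "three_prime_UTR" else "five_prime_UTR"
      lab_right <- if (tx$strand == "-") "five_prime_UTR" else "three_prime_UTR"
      add(utr[before, , drop = FALSE], lab_left)
      add(utr[!before, , drop = FALSE], lab_right)
    }
  } else {
    add(exons, "exon")
  }
  add(iv_gaps(exons), "intron")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element = character(), start = integer(), end = integer())
  out[order(out$start, out$end), , drop = FALSE]
}

#' Extract gene-structure elements from a GFF3/GTF file
#'
#' Each selected transcript becomes one row of the resulting [loc_table()]:
#' its length is the transcript genomic span (max exon end - min exon start
#' + 1) and its coordinates are re-based so the transcript starts at 1.
#' Records are the CDS intervals (`"CDS"`), exon-minus-CDS split into
#' `"five_prime_UTR"`/`"three_prime_UTR"` by position relative to the CDS on
#' the annotated strand (explicit UTR features in the file are used
#' verbatim), gaps between consecutive exons as `"intron"`, and bare
#' `"exon"` records for transcripts without any CDS. Transcripts are never
#' strand-flipped; the strand is carried on every record.
#'
#' @inheritParams read_gene_models
#' @param transcript_policy `"longest"` (default; one row per gene, the
#'   transcript with the largest genomic span, first in file order on ties),
#'   `"first"`, or `"all"` (every isoform as its own row, id suffixed with
#'   the transcript id).
#' @return a [loc_table()] with source tag `"gff"` or `"gtf"`.
#' @examples
#' \dontrun{
#' tab <- gff_to_loc("annotation.gff3")
#' plot(preset_plot(tab, "gff"))
#' }
#' @export
gff_to_loc <- function(path, dialect = c("auto", "gff3", "gtf"),
                       transcript_policy = c("longest", "all", "first")) {
  dialect <- match.arg(dialect)
  transcript_policy <- match.arg(transcript_policy)
  models <- read_gene_models(path, dialect)
  txs <- select_transcripts(models$transcripts, transcript_policy)
  src <- if (models$dialect == "gtf") "gtf" else "gff"
  seqs <- list(); recs <- list()
  for (tx in txs) {
    id <- if (transcript_policy == "all")
      paste0(tx$gene_id, "_", tx$transcript_id) else tx$gene_id
    span <- tx_span(tx)
    seqs[[length(seqs) + 1L]] <- data.frame(
      seq_id = id, length = span[2] - span[1] + 1L, stringsAsFactors = FALSE)
    el <- tx_elements(tx)
    if (nrow(el) > 0L) {
      recs[[length(recs) + 1L]] <- data.frame(
        seq_id = id, element = el$element, start = el$start, end = el$end,
        strand = tx$strand, score = NA_real_, source = src,
        stringsAsFactors = FALSE)
    }
  }
  loc_table(sequences = do.call(rbind, seqs),
            records = if (length(recs)) do.call(rbind, recs))
}
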