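# Sequence statistics: gene coordinate/exon-intron tables from annotation
# files, and a ProtParam-style panel of protein physicochemical properties.

#' Per-gene coordinate and structure statistics
#'
#' One row per gene under the chosen transcript policy, derived from the
#' same gene models as [gff_to_loc()] (single source of truth): genomic
#' coordinates and strand, gene length (`end - start + 1` of the selected
#' transcript span), the gene's transcript count, the selected
#' transcript's exon and intron counts (introns are the gaps between
#' consecutive exons, so `introns = exons - 1` for gapless chains) and its
#' total CDS length in bp.
#'
#' @inheritParams gff_to_loc
#' @return data frame with columns gene_id, chrom, start, end, strand,
#'   gene_length, transcript_count, exon_count, intron_count, cds_length.
#' @export
gene_stats <- function(path, dialect = c("auto", "gff3", "gtf"),
                       transcript_policy = c("longest", "first")) {
  dialect <- match.arg(dialect)
  transcript_policy <- match.arg(transcript_policy)
  models <- read_gene_models(path, dialect)
  all_genes <- vapply(models$transcripts, `[[`, character(1), "gene_id")
  tx_count <- table(all_genes)
  txs <- select_transcripts(models$transcripts, transcript_policy)
  rows <- lapply(txs, function(tx) {
    span <- tx_span(tx)
    introns <- iv_gaps(tx$exons)
    data.frame(
      gene_id = tx$gene_id, chrom = tx$chrom,
      start = span[1], end = span[2], strand = tx$strand,
      gene_length = span[2] - span[1] + 1L,
      transcript_count = as.integer(tx_count[[tx$gene_id]]),
      exon_count = nrow(tx$exons),
      intron_count = nrow(introns),
      cds_length = if (nrow(tx$cds)) iv_union_len(tx$cds) else 0L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- protein physicochemical constants ------------------------------------

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# average (not monoisotopic) residue masses, Da; + one water per chain
AA_AVG_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_AVG_MASS <- 18.0153

# Kyte-Doolittle hydropathy
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Guruprasad dipeptide instability weights, row = first residue
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(sort(AA20), sort(AA20)))

# pKa sets for the Henderson-Hasselbalch charge model; pI depends on the
# chosen set, so both conventions are selectable
PKA_SETS <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  bjellqvist = c(Nterm = 7.5, Cterm = 3.55, C = 9.0, D = 4.05, E = 4.45,
                 H = 5.98, K = 10.0, R = 12.0, Y = 10.0)
)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch model: positive groups (N-terminus, K, R, H)
#' contribute `1 / (1 + 10^(pH - pKa))`, negative groups (C-terminus, D,
#' E, C, Y) contribute `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param seq protein sequence string (standard 20-letter alphabet).
#' @param pH pH value (may be a vector).
#' @param pka_set `"emboss"` or `"bjellqvist"`.
#' @return numeric net charge, one value per `pH`.
#' @export
protein_charge <- function(seq, pH = 7.0, pka_set = c("emboss", "bjellqvist")) {
  pka <- PKA_SETS[[match.arg(pka_set)]]
  aa <- strsplit(toupper(seq), "")[[1]]
  counts <- table(factor(aa, levels = AA20))
  pos_groups <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos_groups) <- c("Nterm", "K", "R", "H")
  neg_groups <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg_groups) <- c("Cterm", "D", "E", "C", "Y")
  vapply(pH, function(p) {
    pos <- sum(pos_groups / (1 + 10^(p - pka[names(pos_groups)])))
    neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - p)))
    pos - neg
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the modeled net charge crosses zero, found by bisection
#' on [protein_charge()] over pH 0..14 to a tolerance of 1e-4 pH units.
#'
#' @inheritParams protein_charge
#' @param tol bisection tolerance in pH units.
#' @return the pI.
#' @export
protein_pi <- function(seq, pka_set = c("emboss", "bjellqvist"), tol = 1e-4) {
  pka_set <- match.arg(pka_set)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(seq, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

protein_stats_one <- function(seq_id, seq, pka_set, on_nonstandard) {
  aa <- strsplit(toupper(seq), "")[[1]]
  aa <- aa[aa != "*"]
  bad <- !(aa %in% AA20)
  if (any(bad)) {
    if (on_nonstandard == "error") {
      stop(sprintf("sequence '%s' contains non-standard residue(s): %s",
                   seq_id, paste(unique(aa[bad]), collapse = ", ")),
           call. = FALSE)
    }
    warning(sprintf("sequence '%s': %d non-standard residue(s) skipped",
                    seq_id, sum(bad)), call. = FALSE)
    aa <- aa[!bad]
  }
  if (length(aa) == 0L) {
    stop(sprintf("sequence '%s' has no standard residues", seq_id),
         call. = FALSE)
  }
  s <- paste(aa, collapse = "")
  n <- length(aa)
  ii <- if (n >= 2L) {
    w <- vapply(seq_len(n - 1L), function(i) DIWV[aa[i], aa[i + 1L]],
                numeric(1))
    10 / n * sum(w)
  } else 0
  data.frame(
    seq_id = seq_id,
    length = n,
    mol_weight = sum(AA_AVG_MASS[aa]) + WATER_AVG_MASS,
    pI = protein_pi(s, pka_set),
    gravy = mean(KYTE_DOOLITTLE[aa]),
    instability_index = ii,
    aromaticity = mean(aa %in% c("F", "W", "Y")),
    charge_pH7 = protein_charge(s, 7.0, pka_set),
    stringsAsFactors = FALSE)
}

#' ProtParam-style protein physicochemical properties
#'
#' For every sequence of a protein FASTA: length, molecular weight
#' (average residue masses plus one water), theoretical pI (bisection on
#' the Henderson-Hasselbalch charge model with the chosen pKa set, 1e-4 pH
#' tolerance), GRAVY (mean Kyte-Doolittle hydropathy), instability index
#' (Guruprasad dipeptide weights), aromaticity (fraction of F/W/Y) and net
#' charge at pH 7.0.
#'
#' @param fasta protein FASTA path, or a named character vector of
#'   sequences.
#' @param pka_set `"emboss"` (default) or `"bjellqvist"`; the pI differs
#'   between the two conventions.
#' @param on_nonstandard `"skip"` (drop non-standard residues with a
#'   warning) or `"error"`.
#' @return data frame of one row per sequence.
#' @export
protein_stats <- function(fasta, pka_set = c("emboss", "bjellqvist"),
                          on_nonstandard = c("skip", "error")) {
  pka_set <- match.arg(pka_set)
  on_nonstandard <- match.arg(on_nonstandard)
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
    ids <- vapply(strsplit(names(ss), "[ \t]+"), `[`, character(1), 1L)
    stats::setNames(as.character(ss), ids)
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else {
    stop("fasta must be a file path or a named character vector",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(seqs), function(id)
    protein_stats_one(id, seqs[[id]], pka_set, on_nonstandard)))
  rownames(out) <- NULL
  out
}
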