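# Seeded synthetic fixture bundles: one shared id set with a nucleotide
# and a protein FASTA, a Newick tree, and a well-formed file in every
# supported result format encoding a known planted ground truth, so every
# parser and renderer is testable without any download. All files are
# synthetic; none comes from a real analysis run.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# each file type draws from its own stream (seed + fixed offset), so
# adding a format never perturbs the others
FIXTURE_STREAMS <- c(ids = 0L, fasta = 1L, newick = 2L, gff = 3L, meme = 4L,
                     mast = 5L, interpro = 6L, cdd = 7L, smart = 8L,
                     plantcare = 9L)

FIXTURE_FORMATS <- c("gff3", "gtf", "meme_xml", "mast_xml", "interpro",
                     "cdd", "smart", "plantcare")

#' Specification of a synthetic fixture bundle
#'
#' @param seed integer; identical specs produce byte-identical bundles.
#' @param n_seqs number of sequences (>= 2 when a tree is requested).
#' @param seq_len_range min/max sequence length.
#' @param n_motifs number of planted motifs for the MEME/MAST files.
#' @param motif_width_range min/max motif width.
#' @param elements_per_seq min/max planted elements per sequence for the
#'   domain/cis-element formats.
#' @param formats subset of `r paste(FIXTURE_FORMATS, collapse = ", ")`.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_seqs = 8L,
                         seq_len_range = c(240L, 600L), n_motifs = 3L,
                         motif_width_range = c(6L, 12L),
                         elements_per_seq = c(1L, 4L),
                         formats = FIXTURE_FORMATS) {
  stopifnot(n_seqs >= 1L, seq_len_range[1] >= 120L,
            all(formats %in% FIXTURE_FORMATS))
  structure(list(seed = as.integer(seed), n_seqs = as.integer(n_seqs),
                 seq_len_range = as.integer(seq_len_range),
                 n_motifs = as.integer(n_motifs),
                 motif_width_range = as.integer(motif_width_range),
                 elements_per_seq = as.integer(elements_per_seq),
                 formats = formats),
            class = "fixture_spec")
}

rand_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# partition total into m parts, each >= lo, deterministically under seed
rand_partition <- function(total, m, lo = 10L) {
  stopifnot(total >= m * lo)
  rem <- total - m * lo
  cuts <- sort(sample.int(rem + 1L, m - 1L, replace = TRUE) - 1L)
  as.integer(lo + diff(c(0L, cuts, rem)))
}

wl <- function(lines, path) writeLines(lines, path, sep = "\n",
                                       useBytes = TRUE)

new_record <- function(seq_id, element, start, end, strand, score, source) {
  data.frame(seq_id = seq_id, element = element, start = as.integer(start),
             end = as.integer(end), strand = strand, score = score,
             source = source, stringsAsFactors = FALSE)
}

# write a score the way the file will carry it and keep the parsed-back
# value, so ground truth and parser agree to the last bit
fmt_eval <- function(p) {
  s <- sprintf("%.3e", p)
  list(str = s, val = as.numeric(s))
}

#' Generate a synthetic fixture bundle with known ground truth
#'
#' Writes, under `outdir`: `seqs.fa` (nucleotide) and `proteins.fa`
#' (amino-acid) over one shared id set, `tree.nwk`, one file per requested
#' result format encoding exactly the planted records, the planted truth
#' as `ground_truth.lengths.tsv`/`ground_truth.elements.tsv`, and a
#' `manifest.json`. For every format `f`, parsing the emitted file
#' reproduces the planted records with source `f` exactly.
#'
#' @param outdir output directory (created if needed).
#' @param spec a [fixture_spec()].
#' @return invisibly, a list with `files` (named paths), `ground_truth`
#'   (the planted [loc_table()]) and `motif_consensus`.
#' @export
generate_fixtures <- function(outdir, spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_seqs < 2L) {
    stop("a tree needs at least 2 leaves; use n_seqs >= 2", call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- list()
  fp <- function(name) file.path(outdir, name)

  ids <- sprintf("g%02d", seq_len(spec$n_seqs))
  lens <- with_seed(spec$seed + FIXTURE_STREAMS[["ids"]],
    sample(spec$seq_len_range[1]:spec$seq_len_range[2], spec$n_seqs,
           replace = TRUE))
  seqs <- data.frame(seq_id = ids, length = as.integer(lens),
                     stringsAsFactors = FALSE)
  truth <- list()

  # FASTA pair -------------------------------------------------------------
  with_seed(spec$seed + FIXTURE_STREAMS[["fasta"]], {
    nt <- unlist(lapply(seq_along(ids), function(i)
      serialize_fasta_record(ids[i], rand_string(lens[i],
                                                 c("A", "C", "G", "T")))))
    aa <- unlist(lapply(seq_along(ids), function(i)
      serialize_fasta_record(ids[i], rand_string(lens[i], AA20))))
    wl(nt, fp("seqs.fa")); wl(aa, fp("proteins.fa"))
  })
  files$fasta <- fp("seqs.fa"); files$protein_fasta <- fp("proteins.fa")

  # Newick -----------------------------------------------------------------
  with_seed(spec$seed + FIXTURE_STREAMS[["newick"]], {
    nodes <- ids
    while (length(nodes) > 1L) {
      i <- sort(sample.int(length(nodes), 2L))
      bl <- sprintf("%.3f", stats::runif(2, 0.02, 0.5))
      joined <- sprintf("(%s:%s,%s:%s)", nodes[i[1]], bl[1], nodes[i[2]],
                        bl[2])
      nodes <- c(joined, nodes[-i])
    }
    wl(paste0(nodes, ";"), fp("tree.nwk"))
  })
  files$newick <- fp("tree.nwk")

  # gene structure (shared by gff3 and gtf) ---------------------------------
  if (any(c("gff3", "gtf") %in% spec$formats)) {
    gm <- with_seed(spec$seed + FIXTURE_STREAMS[["gff"]], {
      lapply(seq_along(ids), function(i) {
        L <- lens[i]
        k <- sample(1:3, 1L)            # CDS exons
        parts <- rand_partition(L, 2L * k + 1L, lo = 12L)
        # blocks left to right: UTR, then CDS/intron alternating, then UTR
        strand <- sample(c("+", "-"), 1L)
        pos <- cumsum(c(1L, parts))
        blocks <- data.frame(
          kind = c("UTR_L", rep(c("CDS", "intron"), k)[-(2L * k)], "UTR_R"),
          start = pos[-length(pos)],
          end = pos[-1] - 1L, stringsAsFactors = FALSE)
        list(id = ids[i], strand = strand, blocks = blocks, length = L,
             offset = 1000L * i)
      })
    })
    gff_truth_records <- function(source_tag) {
      do.call(rbind, lapply(gm, function(g) {
        b <- g$blocks
        lab <- ifelse(b$kind == "CDS", "CDS",
               ifelse(b$kind == "intron", "intron",
               ifelse(b$kind == "UTR_L",
                      if (g$strand == "-") "three_prime_UTR" else "five_prime_UTR",
                      if (g$strand == "-") "five_prime_UTR" else "three_prime_UTR")))
        new_record(g$id, lab, b$start, b$end, g$strand, NA_real_, source_tag)
      }))
    }
    model_features <- function(g) {
      # exon chain: contiguous runs of non-intron blocks
      b <- g$blocks
      runs <- split(seq_len(nrow(b)), cumsum(b$kind == "intron"))
      exons <- do.call(rbind, lapply(runs, function(idx) {
        idx <- idx[b$kind[idx] != "intron"]
        c(min(b$start[idx]), max(b$end[idx]))
      }))
      cds <- b[b$kind == "CDS", c("start", "end")]
      list(exons = exons, cds = cds)
    }
    if ("gff3" %in% spec$formats) {
      out <- c("##gff-version 3")
      for (g in gm) {
        f <- model_features(g)
        o <- g$offset
        out <- c(out, sprintf("chr1\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              o + 1L, o + g$length, g$strand, g$id))
        tid <- paste0(g$id, ".t1")
        out <- c(out, sprintf("chr1\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              o + 1L, o + g$length, g$strand, tid, g$id))
        for (e in seq_len(nrow(f$exons))) {
          out <- c(out, sprintf("chr1\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                o + f$exons[e, 1], o + f$exons[e, 2],
                                g$strand, tid))
        }
        for (e in seq_len(nrow(f$cds))) {
          out <- c(out, sprintf("chr1\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                                o + f$cds$start[e], o + f$cds$end[e],
                                g$strand, tid, tid))
        }
      }
      wl(out, fp("annotation.gff3"))
      files$gff3 <- fp("annotation.gff3")
      truth$gff <- gff_truth_records("gff")
    }
    if ("gtf" %in% spec$formats) {
      out <- character()
      for (g in gm) {
        f <- model_features(g)
        o <- g$offset
        tid <- paste0(g$id, ".t1")
        attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", g$id, tid)
        out <- c(out, sprintf("chr1\tsynth\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              o + 1L, o + g$length, g$strand, attrs))
        for (e in seq_len(nrow(f$exons))) {
          out <- c(out, sprintf("chr1\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
                                o + f$exons[e, 1], o + f$exons[e, 2],
                                g$strand, attrs))
        }
        for (e in seq_len(nrow(f$cds))) {
          out <- c(out, sprintf("chr1\tsynth\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                o + f$cds$start[e], o + f$cds$end[e],
                                g$strand, attrs))
        }
      }
      wl(out, fp("annotation.gtf"))
      files$gtf <- fp("annotation.gtf")
      truth$gtf <- gff_truth_records("gtf")
    }
  }

  # MEME / MAST -------------------------------------------------------------
  motif_consensus <- NULL
  if (any(c("meme_xml", "mast_xml") %in% spec$formats)) {
    widths <- with_seed(spec$seed + FIXTURE_STREAMS[["meme"]] + 100L,
      sample(spec$motif_width_range[1]:spec$motif_width_range[2],
             spec$n_motifs, replace = TRUE))
    motif_consensus <- with_seed(spec$seed + FIXTURE_STREAMS[["meme"]] + 200L,
      vapply(widths, function(w) rand_string(w, c("A", "C", "G", "T")),
             character(1)))
    names(motif_consensus) <- sprintf("MEME-%d", seq_len(spec$n_motifs))
  }
  if ("meme_xml" %in% spec$formats) {
    res <- with_seed(spec$seed + FIXTURE_STREAMS[["meme"]], {
      out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<MEME version=\"5.5.0\">", "<training_set>")
      for (i in seq_along(ids)) {
        out <- c(out, sprintf(
          "<sequence id=\"sequence_%d\" name=\"%s\" length=\"%d\" weight=\"1.0\"/>",
          i - 1L, ids[i], lens[i]))
      }
      out <- c(out, "</training_set>", "<motifs>")
      recs <- list()
      for (m in seq_len(spec$n_motifs)) {
        w <- widths[m]
        mname <- sprintf("MEME-%d", m)
        out <- c(out, sprintf(
          "<motif id=\"motif_%d\" name=\"%s\" alt=\"%s\" width=\"%d\">",
          m, motif_consensus[m], mname, w))
        out <- c(out, "<contributing_sites>")
        for (i in seq_along(ids)) {
          if (stats::runif(1) > 0.7) next
          start <- sample.int(lens[i] - w + 1L, 1L)
          ev <- fmt_eval(10^-stats::runif(1, 5, 12))
          out <- c(out, sprintf(
            "<contributing_site sequence_id=\"sequence_%d\" position=\"%d\" strand=\"plus\" pvalue=\"%s\">",
            i - 1L, start - 1L, ev$str))
          site <- strsplit(motif_consensus[m], "")[[1]]
          mut <- stats::runif(w) < 0.1
          site[mut] <- sample(c("A", "C", "G", "T"), sum(mut),
                              replace = TRUE)
          out <- c(out, paste0("<site>",
                               paste(sprintf("<letter_ref letter_id=\"%s\"/>",
                                             site), collapse = ""),
                               "</site>"),
                   "</contributing_site>")
          recs[[length(recs) + 1L]] <- new_record(ids[i], mname, start,
                                                  start + w - 1L, "+",
                                                  ev$val, "meme")
        }
        out <- c(out, "</contributing_sites>", "</motif>")
      }
      out <- c(out, "</motifs>", "</MEME>")
      list(lines = out, recs = recs)
    })
    wl(res$lines, fp("meme.xml"))
    files$meme_xml <- fp("meme.xml")
    truth$meme <- if (length(res$recs)) do.call(rbind, res$recs)
  }
  if ("mast_xml" %in% spec$formats) {
    res <- with_seed(spec$seed + FIXTURE_STREAMS[["mast"]], {
      out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<mast version=\"5.5.0\">", "<motifs>")
      for (m in seq_len(spec$n_motifs)) {
        out <- c(out, sprintf(
          "<motif id=\"motif_%d\" alt=\"MEME-%d\" width=\"%d\"/>",
          m, m, widths[m]))
      }
      out <- c(out, "</motifs>", "<sequences>")
      recs <- list()
      for (i in seq_along(ids)) {
        out <- c(out, sprintf(
          "<sequence id=\"seq_%d\" name=\"%s\" length=\"%d\">",
          i - 1L, ids[i], lens[i]))
        hits <- list()
        for (m in seq_len(spec$n_motifs)) {
          if (stats::runif(1) > 0.5) next
          w <- widths[m]
          pos <- sample.int(lens[i] - w + 1L, 1L)
          rc <- stats::runif(1) < 0.2
          ev <- fmt_eval(10^-stats::runif(1, 4, 10))
          hits[[length(hits) + 1L]] <- list(pos = pos, m = m, rc = rc,
                                            ev = ev)
        }
        if (length(hits) > 0L) {
          ord <- order(vapply(hits, `[[`, integer(1), "pos"))
          out <- c(out, "<seg start=\"1\">")
          for (h in hits[ord]) {
            out <- c(out, sprintf(
              "<hit pos=\"%d\" idx=\"%d\" rc=\"%s\" pvalue=\"%s\"/>",
              h$pos, h$m - 1L, if (h$rc) "y" else "n", h$ev$str))
            recs[[length(recs) + 1L]] <- new_record(
              ids[i], sprintf("MEME-%d", h$m), h$pos,
              h$pos + widths[h$m] - 1L, if (h$rc) "-" else "+",
              h$ev$val, "mast")
          }
          out <- c(out, "</seg>")
        }
        out <- c(out, "</sequence>")
      }
      out <- c(out, "</sequences>", "</mast>")
      list(lines = out, recs = recs)
    })
    wl(res$lines, fp("mast.xml"))
    files$mast_xml <- fp("mast.xml")
    truth$mast <- if (length(res$recs)) do.call(rbind, res$recs)
  }

  # InterProScan TSV ---------------------------------------------------------
  DOMAIN_POOL <- data.frame(
    name = c("Protein kinase domain", "PAS domain", "WD40 repeat",
             "Zinc finger C2H2 type", "Leucine-rich repeat",
             "Ankyrin repeat", "EF-hand domain", "Homeobox domain"),
    pfam = c("PF00069", "PF00989", "PF00400", "PF00096", "PF13855",
             "PF00023", "PF13499", "PF00046"),
    short = c("PKc", "PAS", "WD40", "ZnF_C2H2", "LRR_8", "ANK", "EFh",
              "HOX"), stringsAsFactors = FALSE)
  plant_domains <- function(i) {
    n <- sample(spec$elements_per_seq[1]:spec$elements_per_seq[2], 1L)
    idx <- sample.int(nrow(DOMAIN_POOL), n, replace = TRUE)
    w <- sample(25:70, n, replace = TRUE)
    s <- vapply(w, function(wi) sample.int(lens[i] - wi + 1L, 1L),
                integer(1))
    d <- data.frame(pool = idx, start = s, end = s + w - 1L)
    d[order(d$start), , drop = FALSE]
  }
  if ("interpro" %in% spec$formats) {
    res <- with_seed(spec$seed + FIXTURE_STREAMS[["interpro"]], {
      out <- character(); recs <- list()
      for (i in seq_along(ids)) {
        d <- plant_domains(i)
        for (j in seq_len(nrow(d))) {
          p <- DOMAIN_POOL[d$pool[j], ]
          ev <- fmt_eval(10^-stats::runif(1, 3, 30))
          desc <- if (stats::runif(1) < 0.1) "" else p$name
          element <- if (nzchar(desc)) desc else p$pfam
          out <- c(out, paste(
            c(ids[i], "d41d8cd98f00b204e9800998ecf8427e", lens[i], "Pfam",
              p$pfam, desc, d$start[j], d$end[j], ev$str, "T",
              "25-04-2025", "IPR000719", p$name), collapse = "\t"))
          recs[[length(recs) + 1L]] <- new_record(ids[i], element,
                                                  d$start[j], d$end[j],
                                                  ".", ev$val, "interpro")
        }
        # one non-Pfam decoy row per sequence (filtered out by default)
        out <- c(out, paste(
          c(ids[i], "d41d8cd98f00b204e9800998ecf8427e", lens[i], "PANTHER",
            "PTHR24420", "FAMILY NOT NAMED", 1L, lens[i], "1.0e-40", "T",
            "25-04-2025", "-", "-"), collapse = "\t"))
      }
      list(lines = out, recs = recs)
    })
    wl(res$lines, fp("interpro.tsv"))
    files$interpro <- fp("interpro.tsv")
    truth$interpro <- do.call(rbind, res$recs)
  }

  # Batch CD-Search hit table -------------------------------------------------
  if ("cdd" %in% spec$formats) {
    res <- with_seed(spec$seed + FIXTURE_STREAMS[["cdd"]], {
      out <- c("#Batch CD-search tool\tNIH/NLM/NCBI", "#cdsid\tsynthetic",
               "#datatype\thitsConcise Results", "#status\t0",
               paste("Query", "Hit type", "PSSM-ID", "From", "To",
                     "E-Value", "Bitscore", "Accession", "Short name",
                     "Incomplete", "Superfamily", sep = "\t"))
      recs <- list()
      for (i in seq_along(ids)) {
        d <- plant_domains(i)
        for (j in seq_len(nrow(d))) {
          p <- DOMAIN_POOL[d$pool[j], ]
          ev <- fmt_eval(10^-stats::runif(1, 3, 30))
          out <- c(out, paste(
            c(sprintf("Q#%d - >%s", i, ids[i]), "specific",
              sample(100000:500000, 1L), d$start[j], d$end[j], ev$str,
              sprintf("%.2f", stats::runif(1, 50, 400)),
              sprintf("cd%05d", sample.int(30000, 1L)), p$short, "-",
              "cl00000"), collapse = "\t"))
          recs[[length(recs) + 1L]] <- new_record(ids[i], p$short,
                                                  d$start[j], d$end[j],
                                                  ".", ev$val, "cdd")
        }
        if (stats::runif(1) < 0.5) {
          # superfamily decoy (excluded by the default hit-type filter)
          out <- c(out, paste(
            c(sprintf("Q#%d - >%s", i, ids[i]), "superfamily",
              sample(100000:500000, 1L), 1L, lens[i], "1.0e-10", "100.00",
              "cl02566", "SUPFAM", "-", "-"), collapse = "\t"))
        }
      }
      list(lines = out, recs = recs)
    })
    wl(res$lines, fp("cdd_hitdata.txt"))
    files$cdd <- fp("cdd_hitdata.txt")
    truth$cdd <- do.call(rbind, res$recs)
  }

  # SMART batch text ----------------------------------------------------------
  if ("smart" %in% spec$formats) {
    res <- with_seed(spec$seed + FIXTURE_STREAMS[["smart"]], {
      out <- character(); recs <- list()
      for (i in seq_along(ids)) {
        out <- c(out, sprintf("NAME=%s", ids[i]), sprintf("LEN=%d", lens[i]))
        d <- plant_domains(i)
        for (j in seq_len(nrow(d))) {
          p <- DOMAIN_POOL[d$pool[j], ]
          ev <- fmt_eval(10^-stats::runif(1, 2, 20))
          out <- c(out, sprintf("DOMAIN=%s", p$short),
                   sprintf("START=%d", d$start[j]),
                   sprintf("END=%d", d$end[j]),
                   sprintf("EVALUE=%s", ev$str), "TYPE=SMART", "")
          recs[[length(recs) + 1L]] <- new_record(ids[i], p$short,
                                                  d$start[j], d$end[j],
                                                  ".", ev$val, "smart")
        }
      }
      list(lines = out, recs = recs)
    })
    wl(res$lines, fp("smart.txt"))
    files$smart <- fp("smart.txt")
    truth$smart <- do.call(rbind, res$recs)
  }

  # PlantCARE tab file ---------------------------------------------------------
  if ("plantcare" %in% spec$formats) {
    CARE_POOL <- data.frame(
      site = c("ABRE", "G-Box", "GT1-motif", "MBS", "ARE",
               "TC-rich repeats", "TATA-box", "CAAT-box", "CGTCA-motif",
               "P-box", "CAT-box"),
      descr = c(
        "cis-acting element involved in the abscisic acid responsiveness",
        "cis-acting regulatory element involved in light responsiveness",
        "light responsive element",
        "MYB binding site involved in drought-inducibility",
        "cis-acting regulatory element essential for the anaerobic induction",
        "cis-acting element involved in defense and stress responsiveness",
        "core promoter element around -30 of transcription start",
        "common cis-acting element in promoter and enhancer regions",
        "cis-acting regulatory element involved in the MeJA-responsiveness",
        "gibberellin-responsive element",
        "cis-acting regulatory element related to meristem expression"),
      stringsAsFactors = FALSE)
    res <- with_seed(spec$seed + FIXTURE_STREAMS[["plantcare"]], {
      out <- character(); recs <- list()
      for (i in seq_along(ids)) {
        n <- sample(spec$elements_per_seq[1]:spec$elements_per_seq[2], 1L)
        idx <- sample.int(nrow(CARE_POOL), n, replace = TRUE)
        w <- sample(4:10, n, replace = TRUE)
        pos <- vapply(w, function(wi) sample.int(lens[i] - wi + 1L, 1L),
                      integer(1))
        ord <- order(pos)
        for (j in ord) {
          p <- CARE_POOL[idx[j], ]
          mseq <- rand_string(w[j], c("A", "C", "G", "T"))
          strand <- sample(c("+", "-"), 1L)
          score <- sample(4:10, 1L)
          out <- c(out, paste(c(ids[i], p$site, "Arabidopsis thaliana",
                                pos[j], mseq, strand, score, p$descr),
                              collapse = "\t"))
          recs[[length(recs) + 1L]] <- new_record(ids[i], p$site, pos[j],
                                                  pos[j] + w[j] - 1L,
                                                  strand, score,
                                                  "plantcare")
        }
        # unannotated matrix hits, dropped by the default filter
        out <- c(out, paste(c(ids[i], "Unnamed__1", "Zea mays", 5L,
                              "CCGTCC", "+", 4L, ""), collapse = "\t"))
      }
      list(lines = out, recs = recs)
    })
    wl(res$lines, fp("plantcare.tab"))
    files$plantcare <- fp("plantcare.tab")
    truth$plantcare <- do.call(rbind, res$recs)
  }

  # ground truth + manifest ----------------------------------------------------
  src_order <- c("gff", "gtf", "meme", "mast", "interpro", "cdd", "smart",
                 "plantcare")
  all_recs <- do.call(rbind, truth[intersect(src_order, names(truth))])
  gt <- loc_table(sequences = seqs, records = all_recs)
  write_loc_files(gt, fp("ground_truth.lengths.tsv"),
                  fp("ground_truth.elements.tsv"))
  files$ground_truth_lengths <- fp("ground_truth.lengths.tsv")
  files$ground_truth_elements <- fp("ground_truth.elements.tsv")

  manifest <- list(seed = spec$seed, n_seqs = spec$n_seqs,
                   formats = spec$formats,
                   files = lapply(files, basename),
                   motif_consensus = as.list(motif_consensus))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  files$manifest <- fp("manifest.json")

  invisible(list(files = files, ground_truth = gt,
                 motif_consensus = motif_consensus))
}

#' Ground truth restricted to one source tag
#'
#' Convenience for round-trip checks: the planted [loc_table()] with only
#' the records of the given source.
#'
#' @param ground_truth the full planted table.
#' @param source one source tag (`"gff"`, `"meme"`, ...).
#' @return a [loc_table()].
#' @export
truth_for_source <- function(ground_truth, source) {
  src <- source
  loc_table(sequences = ground_truth$sequences,
            records = ground_truth$records[
              ground_truth$records$source == src, , drop = FALSE])
}
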