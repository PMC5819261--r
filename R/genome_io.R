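#' Genome records
#'
#' A genome record holds one virus: its accession, taxonomy labels, one or
#' more nucleotide segments, the genome topology, and (optionally) the
#' annotated protein sequences taken from the source record. Records with
#' annotations keep them; protein prediction from the nucleotide sequence is
#' used only when annotations are missing.
#'
#' @param accession unique accession string.
#' @param segments character vector of nucleotide sequences (IUPAC alphabet),
#'   at least one.
#' @param taxonomy named character vector; recognised names are
#'   `baltimore_group`, `order`, `family`, `genus`, `species`. Missing labels
#'   are stored as `""`.
#' @param topology `"linear"` or `"circular"`. Circular genomes are used as
#'   provided in linear form; no breakpoint search is attempted.
#' @param annotated_proteins `NULL`, or a data.frame with columns `id`,
#'   `sequence`, `description`.
#'
#' @return an object of class `"genome_record"`.
#' @export
genome_record <- function(accession, segments,
                          taxonomy = character(),
                          topology = c("linear", "circular"),
                          annotated_proteins = NULL) {
  topology <- match.arg(topology)
  if (length(segments) < 1L) stop("no segments")
  segments <- toupper(as.character(segments))
  bad <- grepl("[^ACGTNRYSWKMBDHV]", segments)
  if (any(bad)) stop("segment sequence contains non-IUPAC characters")
  tax <- c(baltimore_group = "", order = "", family = "",
           genus = "", species = "")
  if (length(taxonomy)) tax[names(taxonomy)] <- unname(taxonomy)
  if (!is.null(annotated_proteins)) {
    stopifnot(is.data.frame(annotated_proteins),
              all(c("id", "sequence") %in% names(annotated_proteins)))
    if (is.null(annotated_proteins$description)) {
      annotated_proteins$description <- ""
    }
  }
  structure(list(accession = as.character(accession),
                 taxonomy = tax,
                 segments = segments,
                 topology = topology,
                 annotated_proteins = annotated_proteins),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d segment(s), %d nt total, family '%s'%s\n",
              x$accession, length(x$segments),
              sum(nchar(x$segments)), x$taxonomy[["family"]],
              if (is.null(x$annotated_proteins)) "" else
                sprintf(", %d annotated proteins",
                        nrow(x$annotated_proteins))))
  invisible(x)
}

#' Concatenate genome segments, largest to smallest
#'
#' Segmented genomes are represented by a single sequence before annotation:
#' segments are concatenated from the largest to the smallest. Equal-length
#' segments keep their input order (stable sort), so the result is
#' deterministic.
#'
#' @param segments character vector of nucleotide sequences.
#' @return a single nucleotide sequence string.
#' @export
concatenate_segments <- function(segments) {
  if (length(segments) < 1L) stop("no segments")
  ord <- order(-nchar(segments))   # radix order is stable
  paste0(segments[ord], collapse = "")
}

#' Six-frame translation
#'
#' Translates the three forward frames of `seq` and the three frames of its
#' reverse complement under the standard genetic code. Stop codons are
#' emitted as `"*"`; ambiguous codons translate to `"X"`; trailing partial
#' codons are dropped.
#'
#' @param seq nucleotide sequence string, length >= 3.
#' @return named character vector of 6 amino-acid sequences
#'   (`F1`,`F2`,`F3`,`R1`,`R2`,`R3`).
#' @export
six_frame_translate <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, f) {
    len <- length(s) - f + 1L
    len <- len - (len %% 3L)
    if (len < 3L) return("")
    aa <- Biostrings::translate(Biostrings::subseq(s, f, f + len - 1L),
                                if.fuzzy.codon = "X",
                                no.init.codon = TRUE)
    as.character(aa)
  }
  c(F1 = one(fwd, 1L), F2 = one(fwd, 2L), F3 = one(fwd, 3L),
    R1 = one(rev, 1L), R2 = one(rev, 2L), R3 = one(rev, 3L))
}

#' Predict proteins from a nucleotide sequence
#'
#' Six-frame translates the sequence, splits each frame at every stop codon,
#' and keeps, per inter-stop fragment, at most one hypothetical protein
#' running from the fragment's first methionine to the fragment end.
#' Proteins shorter than `min_len` are discarded. The default 100 aa cut-off
#' is conservative: it suppresses the large number of short spurious open
#' reading frames found in unannotated sequence.
#'
#' @param seq nucleotide sequence string.
#' @param min_len minimum protein length (aa), default 100.
#' @param source_accession accession recorded in the output.
#' @return data.frame with columns `id`, `source_accession`, `sequence`,
#'   `provenance`, `description` (possibly 0 rows).
#' @export
predict_proteins <- function(seq, min_len = 100L, source_accession = NA_character_) {
  frames <- six_frame_translate(seq)
  out_seq <- character()
  out_frame <- character()
  for (fr in names(frames)) {
    if (!nzchar(frames[[fr]])) next
    frags <- strsplit(frames[[fr]], "*", fixed = TRUE)[[1]]
    for (frag in frags) {
      m <- regexpr("M", frag, fixed = TRUE)
      if (m < 0L) next
      prot <- substring(frag, m)
      if (nchar(prot) >= min_len) {
        out_seq <- c(out_seq, prot)
        out_frame <- c(out_frame, fr)
      }
    }
  }
  n <- length(out_seq)
  data.frame(
    id = if (n) paste0(source_accession, "|orf", seq_len(n)) else character(),
    source_accession = rep(source_accession, n),
    sequence = out_seq,
    provenance = rep("predicted", n),
    description = if (n) paste0("hypothetical protein (frame ", out_frame, ")")
                  else character(),
    stringsAsFactors = FALSE
  )
}

#' Extract proteins from a genome record
#'
#' Uses annotated proteins when the record has them (predicted ORFs are
#' never added to an annotated record); otherwise predicts proteins from the
#' concatenated genome. The minimum-length filter applies in both cases.
#'
#' @param record a [genome_record()].
#' @param min_len minimum protein length (aa).
#' @return data.frame of protein records (see [predict_proteins()]).
#' @export
extract_proteins <- function(record, min_len = 100L) {
  stopifnot(inherits(record, "genome_record"))
  if (sum(nchar(record$segments)) == 0L) stop("genome has no sequence")
  if (!is.null(record$annotated_proteins)) {
    ap <- record$annotated_proteins
    keep <- nchar(ap$sequence) >= min_len
    ap <- ap[keep, , drop = FALSE]
    n <- nrow(ap)
    return(data.frame(
      id = if (n) paste0(record$accession, "|", ap$id) else character(),
      source_accession = rep(record$accession, n),
      sequence = ap$sequence,
      provenance = rep("annotated", n),
      description = ap$description,
      stringsAsFactors = FALSE
    ))
  }
  predict_proteins(concatenate_segments(record$segments),
                   min_len = min_len,
                   source_accession = record$accession)
}

#' Read genomes from FASTA (plus optional taxonomy table)
#'
#' Each FASTA record is one genome segment. Records whose identifiers match
#' `"<accession>.seg<k>"` are grouped into one segmented genome; all other
#' records are single-segment genomes named by their identifier.
#'
#' @param path FASTA file of nucleotide sequences.
#' @param taxonomy optional data.frame as returned by [read_taxonomy()].
#' @return named list of [genome_record()] objects.
#' @export
read_genomes_fasta <- function(path, taxonomy = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  acc <- sub("\\.seg\\d+$", "", ids)
  out <- list()
  for (a in unique(acc)) {
    segs <- as.character(ss[acc == a])
    tax <- character()
    if (!is.null(taxonomy) && a %in% taxonomy$accession) {
      row <- taxonomy[match(a, taxonomy$accession), ]
      tax <- c(baltimore_group = row$baltimore_group, order = row$order,
               family = row$family, genus = row$genus, species = row$species)
      tax[is.na(tax)] <- ""
    }
    out[[a]] <- genome_record(a, unname(segs), taxonomy = tax)
  }
  out
}

#' Read a taxonomy sidecar table
#'
#' Tab-separated file with columns `accession`, `baltimore_group`, `order`,
#' `family`, `genus`, `species`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("accession", "baltimore_group", "order", "family",
            "genus", "species")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("taxonomy table lacks columns: ", paste(missing, collapse = ", "))
  }
  tab
}

#' Write a taxonomy table
#' @param genomes list of genome records.
#' @param path output TSV path.
#' @export
write_taxonomy <- function(genomes, path) {
  tab <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(accession = g$accession, t(g$taxonomy),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genomes to FASTA
#'
#' Segmented genomes are written as one record per segment, identified as
#' `"<accession>.seg<k>"`, the convention [read_genomes_fasta()] reads back.
#'
#' @param genomes list of genome records.
#' @param path output FASTA path.
#' @export
write_genomes_fasta <- function(genomes, path) {
  seqs <- character(); ids <- character()
  for (g in genomes) {
    if (length(g$segments) == 1L) {
      ids <- c(ids, g$accession); seqs <- c(seqs, g$segments)
    } else {
      ids <- c(ids, paste0(g$accession, ".seg", seq_along(g$segments)))
      seqs <- c(seqs, g$segments)
    }
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write protein records to FASTA
#' @param proteins protein data.frame (see [extract_proteins()]).
#' @param path output FASTA path.
#' @export
write_protein_fasta <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(proteins$sequence)
  names(ss) <- proteins$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read genomes from a GenBank flat file
#'
#' Light-weight reader for GenBank flat files: parses `LOCUS`/`ACCESSION`,
#' the `ORGANISM` line, CDS features with `/translation` and `/product`
#' qualifiers, and the `ORIGIN` sequence block. CDS translations are stored
#' as annotated proteins. Multi-record files are supported; one genome per
#' record (segmented genomes split across records are grouped only when
#' accessions share a `".seg<k>"` suffix, as in the FASTA reader).
#'
#' @param path GenBank flat file.
#' @param taxonomy optional taxonomy data.frame keyed by accession.
#' @return named list of [genome_record()] objects.
#' @export
read_genbank <- function(path, taxonomy = NULL) {
  lines <- readLines(path)
  starts <- grep("^LOCUS", lines)
  ends <- grep("^//\\s*$", lines)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("malformed GenBank file: unbalanced LOCUS...// records")
  }
  out <- list()
  for (r in seq_along(starts)) {
    blk <- lines[starts[r]:ends[r]]
    acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
               grep("^ACCESSION", blk, value = TRUE)[1])
    if (is.na(acc)) acc <- strsplit(blk[1], "\\s+")[[1]][2]
    topo <- if (grepl("circular", blk[1], ignore.case = TRUE))
      "circular" else "linear"
    # ORIGIN block
    oi <- grep("^ORIGIN", blk)
    seq <- ""
    if (length(oi)) {
      body <- blk[(oi[1] + 1L):(length(blk) - 1L)]
      seq <- toupper(gsub("[^A-Za-z]", "", paste0(body, collapse = "")))
    }
    # CDS features with /translation
    prot <- .gb_cds_translations(blk)
    rec <- genome_record(acc, seq, topology = topo,
                         annotated_proteins =
                           if (nrow(prot)) prot else NULL)
    if (!is.null(taxonomy) && acc %in% taxonomy$accession) {
      row <- taxonomy[match(acc, taxonomy$accession), ]
      rec$taxonomy[c("baltimore_group", "order", "family",
                     "genus", "species")] <-
        unlist(row[c("baltimore_group", "order", "family",
                     "genus", "species")])
    }
    out[[acc]] <- rec
  }
  out
}

# Pull /translation and /product qualifiers out of CDS features.
.gb_cds_translations <- function(blk) {
  fi <- grep("^FEATURES", blk)
  oi <- grep("^ORIGIN", blk)
  id <- character(); sq <- character(); de <- character()
  if (length(fi)) {
    feat <- blk[(fi[1] + 1L):(if (length(oi)) oi[1] - 1L else length(blk))]
    is_key <- grepl("^ {5}\\S", feat)
    key_idx <- which(is_key)
    cds_idx <- key_idx[grepl("^ {5}CDS\\b", feat[key_idx])]
    for (ci in cds_idx) {
      nxt <- key_idx[key_idx > ci]
      end <- if (length(nxt)) nxt[1] - 1L else length(feat)
      body <- paste0(trimws(feat[ci:end]), collapse = " ")
      tr <- regmatches(body, regexpr('/translation="[^"]*"', body))
      if (!length(tr)) next
      trs <- gsub("\\s", "", sub('/translation="([^"]*)"', "\\1", tr))
      pr <- regmatches(body, regexpr('/product="[^"]*"', body))
      prs <- if (length(pr)) sub('/product="([^"]*)"', "\\1", pr) else ""
      pid <- regmatches(body, regexpr('/protein_id="[^"]*"', body))
      pids <- if (length(pid)) sub('/protein_id="([^"]*)"', "\\1", pid)
              else paste0("cds", length(id) + 1L)
      id <- c(id, pids); sq <- c(sq, trs); de <- c(de, prs)
    }
  }
  data.frame(id = id, sequence = sq, description = de,
             stringsAsFactors = FALSE)
}
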