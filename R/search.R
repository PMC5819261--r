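#' All-versus-all pairwise protein search
#'
#' Runs every protein against every other and returns similarity edges
#' (bit score, E-value, percent identity, query and subject coverage).
#' The external adapter shells out to BLASTp (`makeblastdb` + `blastp`,
#' default parameters except the reported alignment number, which is raised
#' so that all significant hits are retrieved). The native fallback screens
#' pairs with a shared k-mer prefilter and aligns survivors with
#' Smith-Waterman local alignment under BLOSUM62 (gap open 11 / extend 1),
#' converting raw scores to bit scores with the standard Karlin-Altschul
#' scaling and defining coverage as aligned span over sequence length.
#'
#' @param proteins protein data.frame (columns `id`, `sequence`).
#' @param config a [pipeline_config()]; `config$engine` selects the engine.
#' @return data.frame of edges with columns `query_id`, `subject_id`,
#'   `bit_score`, `e_value`, `pct_identity`, `query_coverage`,
#'   `subject_coverage`. Fewer than two proteins give zero rows.
#' @export
pairwise_protein_search <- function(proteins, config = pipeline_config()) {
  if (nrow(proteins) < 2L) return(.empty_edges())
  if (anyDuplicated(proteins$id)) stop("protein ids must be unique")
  engine <- resolve_engine(config, c("makeblastdb", "blastp"))
  if (engine == "external") {
    .search_blast(proteins)
  } else {
    .search_native(proteins)
  }
}

.empty_edges <- function() {
  data.frame(query_id = character(), subject_id = character(),
             bit_score = numeric(), e_value = numeric(),
             pct_identity = numeric(), query_coverage = numeric(),
             subject_coverage = numeric(), stringsAsFactors = FALSE)
}

.search_blast <- function(proteins) {
  wd <- tempfile("blast")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  faa <- file.path(wd, "prot.faa")
  write_protein_fasta(proteins, faa)
  dbp <- file.path(wd, "protdb")
  st <- system2("makeblastdb",
                c("-in", faa, "-dbtype", "prot", "-out", dbp),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("makeblastdb failed")
  outp <- file.path(wd, "hits.tsv")
  st <- system2("blastp",
                c("-query", faa, "-db", dbp, "-out", outp,
                  "-max_target_seqs", "1000000", "-num_threads", "1",
                  "-outfmt",
                  shQuote(paste("6 qseqid sseqid pident length evalue",
                                "bitscore qstart qend sstart send qlen slen"))),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("blastp failed")
  edges <- read_search_tsv(outp)
  edges[edges$query_id != edges$subject_id, , drop = FALSE]
}

#' Read tabular search results (BLAST outfmt-6 style)
#'
#' Expects 12 tab-separated columns: qseqid sseqid pident length evalue
#' bitscore qstart qend sstart send qlen slen. Coverage per side is the
#' aligned span divided by the full sequence length.
#'
#' @param path TSV path.
#' @return edge data.frame (see [pairwise_protein_search()]).
#' @export
read_search_tsv <- function(path) {
  if (file.size(path) == 0) return(.empty_edges())
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("qseqid", "sseqid", "pident",
                                         "length", "evalue", "bitscore",
                                         "qstart", "qend", "sstart", "send",
                                         "qlen", "slen"))
  data.frame(query_id = tab$qseqid, subject_id = tab$sseqid,
             bit_score = tab$bitscore, e_value = tab$evalue,
             pct_identity = tab$pident,
             query_coverage = 100 * (abs(tab$qend - tab$qstart) + 1) / tab$qlen,
             subject_coverage = 100 * (abs(tab$send - tab$sstart) + 1) / tab$slen,
             stringsAsFactors = FALSE)
}

# Karlin-Altschul parameters for gapped BLOSUM62 (open 11 / extend 1)
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

.search_native <- function(proteins, kmer = 4L, min_shared = 3L) {
  ids <- proteins$id
  seqs <- proteins$sequence
  n <- length(ids)
  cand <- .kmer_candidate_pairs(seqs, kmer, min_shared)
  if (nrow(cand) == 0L) return(.empty_edges())
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- ids
  mat <- "BLOSUM62"
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    aln <- Biostrings::pairwiseAlignment(
      aas[[i]], aas[[j]], type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    raw <- Biostrings::score(aln)
    bits <- (.KA_LAMBDA * raw - log(.KA_K)) / log(2)
    m <- nchar(seqs[i]); s <- nchar(seqs[j])
    evalue <- m * s * 2^(-bits)
    pident <- Biostrings::pid(aln, type = "PID1")
    qspan <- Biostrings::width(Biostrings::pattern(aln))
    sspan <- Biostrings::width(Biostrings::subject(aln))
    rows[[r]] <- data.frame(
      query_id = ids[i], subject_id = ids[j],
      bit_score = bits, e_value = evalue, pct_identity = pident,
      query_coverage = 100 * qspan / m,
      subject_coverage = 100 * sspan / s,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# unordered candidate pairs sharing at least `min_shared` distinct k-mers
.kmer_candidate_pairs <- function(seqs, kmer, min_shared) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < kmer) return(character())
    unique(substring(s, seq_len(L - kmer + 1L),
                     seq_len(L - kmer + 1L) + kmer - 1L))
  })
  counts <- new.env(parent = emptyenv())
  index <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (w in km[[i]]) {
      index[[w]] <- c(index[[w]], i)
    }
  }
  pair_count <- list()
  for (w in ls(index)) {
    members <- index[[w]]
    if (length(members) < 2L) next
    prs <- utils::combn(members, 2L)
    for (c0 in seq_len(ncol(prs))) {
      key <- paste0(prs[1, c0], "_", prs[2, c0])
      pair_count[[key]] <- (pair_count[[key]] %||% 0L) + 1L
    }
  }
  keys <- names(pair_count)[vapply(pair_count, function(x)
    x >= min_shared, logical(1))]
  if (!length(keys)) {
    return(data.frame(i = integer(), j = integer()))
  }
  ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter similarity edges
#'
#' Retains an edge only when its E-value is at most `blast_evalue_max`, its
#' percent identity at least `blast_identity_min`, and both query and
#' subject coverage at least `blast_coverage_min` (defaults 0.001 / 30% /
#' 75%). Idempotent.
#'
#' @param edges edge data.frame.
#' @param config a [pipeline_config()].
#' @return the retained edges.
#' @export
filter_edges <- function(edges, config = pipeline_config()) {
  keep <- edges$e_value <= config$blast_evalue_max &
    edges$pct_identity >= config$blast_identity_min &
    edges$query_coverage >= config$blast_coverage_min &
    edges$subject_coverage >= config$blast_coverage_min
  edges[keep, , drop = FALSE]
}

#' Best-hit reduction to one weight per protein pair
#'
#' When several hits survive for a pair (either direction, multiple HSPs),
#' only the best bit score is kept as the pair's clustering weight.
#'
#' @param edges filtered edge data.frame.
#' @return data.frame with columns `a`, `b` (protein ids, `a < b`) and
#'   `weight`.
#' @export
best_hit_reduction <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(a = character(), b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  a <- pmin(edges$query_id, edges$subject_id)
  b <- pmax(edges$query_id, edges$subject_id)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; w <- edges$bit_score[keep]
  key <- paste0(a, "\r", b)
  best <- tapply(w, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, character(1), 1),
             b = vapply(parts, `[`, character(1), 2),
             weight = as.numeric(best), stringsAsFactors = FALSE)
}
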