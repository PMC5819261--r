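#' Six-frame concatenated translation of a genome
#'
#' Translates the six frames (order `F1,F2,F3,R1,R2,R3`) and joins them
#' into a single query string with one `"X"` separator between frames;
#' stop codons are also rendered as `"X"` so that the query stays within
#' the amino-acid alphabet of downstream scanners (an `X` scores as
#' background, breaking alignments the way a stop would).
#'
#' @param seq nucleotide sequence.
#' @return list: `query` (the concatenated string), `frames` (frame
#'   names), `offsets` (1-based start of each frame within the query),
#'   `lens` (frame lengths, aa), `n` (genome length, nt).
#' @keywords internal
#' @export
six_frame_concat <- function(seq) {
  fr <- six_frame_translate(seq)
  fr <- gsub("*", "X", fr, fixed = TRUE)
  lens <- nchar(fr)
  offsets <- cumsum(c(1L, utils::head(lens, -1) + 1L))
  list(query = paste(fr, collapse = "X"),
       frames = names(fr), offsets = offsets, lens = lens,
       n = nchar(seq))
}

# map a position in the concatenated query to (frame name, within-frame aa
# position); positions falling on separators return NA
.frame_of <- function(pos, offsets, lens) {
  k <- findInterval(pos, offsets)
  within <- pos - offsets[k] + 1L
  ifelse(within >= 1L & within <= lens[k], k, NA_integer_)
}

#' Scan genomes against a profile database
#'
#' Each genome sequence is six-frame translated and concatenated
#' ([six_frame_concat()]) and the query scanned against every database
#' profile. Hits with conditional E-value above `config$cevalue_max` or
#' with non-positive score are discarded. The external adapter runs
#' `hmmscan` (bias-composition filter disabled) over all queries in one
#' call; the native engine scores the best gapless local PSSM run per
#' profile, with approximate conditional E-values from the profile's
#' fitted Gumbel null.
#'
#' @param seqs named character vector of (concatenated) genome sequences.
#' @param db a `"profile_db"`.
#' @param config a [pipeline_config()].
#' @return named list (per genome) of hit data.frames with columns
#'   `profile_id`, `score` (overall per-profile score), `dom_score`,
#'   `c_evalue`, `qstart`, `qend` (concatenated-translation coordinates).
#' @export
scan_genomes <- function(seqs, db, config = pipeline_config()) {
  stopifnot(inherits(db, "profile_db"), length(seqs) >= 1L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  sf <- lapply(seqs, six_frame_concat)
  queries <- vapply(sf, `[[`, character(1), "query")
  if (db$meta$engine == "hmmer") {
    if (!all(nzchar(Sys.which(c("hmmpress", "hmmscan"))))) {
      stop("database was built with HMMER but hmmscan is not on PATH")
    }
    hits <- .hmmscan_queries(queries, db,
                             cevalue_max = config$cevalue_max,
                             min_score = 0)
  } else {
    hits <- .native_scan_queries(queries, db,
                                 cevalue_max = config$cevalue_max)
  }
  hits
}

#' @rdname scan_genomes
#' @param seq a single nucleotide sequence.
#' @return `scan_genome()`: one hit data.frame.
#' @export
scan_genome <- function(seq, db, config = pipeline_config()) {
  scan_genomes(c(genome = seq), db, config)[["genome"]]
}

.hmmscan_queries <- function(queries, db, cevalue_max, min_score) {
  wd <- tempfile("scan"); dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  hmmdb <- file.path(wd, "db.hmm")
  con <- file(hmmdb, "w")
  for (p in db$profiles) writeLines(p$hmm_lines, con)
  close(con)
  st <- system2("hmmpress", hmmdb, stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("hmmpress failed")
  qf <- file.path(wd, "queries.faa")
  ss <- Biostrings::AAStringSet(queries)
  Biostrings::writeXStringSet(ss, qf)
  dom <- file.path(wd, "scan.domtbl")
  st <- system2("hmmscan",
                c("--nobias", "--domtblout", dom, "--noali",
                  "--cpu", "1", hmmdb, qf),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("hmmscan failed")
  tab <- .read_domtbl(dom)
  out <- setNames(vector("list", length(queries)), names(queries))
  for (q in names(queries)) {
    rows <- tab[tab$query == q, , drop = FALSE]
    rows <- rows[rows$c_evalue <= cevalue_max &
                   rows$dom_score > min_score &
                   rows$full_score > min_score, , drop = FALSE]
    out[[q]] <- data.frame(profile_id = rows$target,
                           score = rows$full_score,
                           dom_score = rows$dom_score,
                           c_evalue = rows$c_evalue,
                           qstart = rows$ali_from, qend = rows$ali_to,
                           stringsAsFactors = FALSE)
  }
  out
}

# hmmscan --domtblout parser (fixed 22 whitespace columns + description)
.read_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) {
    return(data.frame(target = character(), query = character(),
                      full_score = numeric(), c_evalue = numeric(),
                      dom_score = numeric(), ali_from = integer(),
                      ali_to = integer(), stringsAsFactors = FALSE))
  }
  f <- strsplit(trimws(lines), "\\s+")
  data.frame(target = vapply(f, `[`, character(1), 1),
             query = vapply(f, `[`, character(1), 4),
             full_score = as.numeric(vapply(f, `[`, character(1), 8)),
             c_evalue = as.numeric(vapply(f, `[`, character(1), 12)),
             dom_score = as.numeric(vapply(f, `[`, character(1), 14)),
             ali_from = as.integer(vapply(f, `[`, character(1), 18)),
             ali_to = as.integer(vapply(f, `[`, character(1), 20)),
             stringsAsFactors = FALSE)
}

.native_scan_queries <- function(queries, db, cevalue_max) {
  out <- setNames(vector("list", length(queries)), names(queries))
  enc <- lapply(queries, .encode_aa)
  for (q in names(queries)) {
    idx <- enc[[q]]
    N <- length(idx)
    rows <- list()
    for (p in db$profiles) {
      hit <- .gapless_best(p$pssm, idx)
      if (hit$score <= 0) next
      # location-shifted Gumbel: searching N positions instead of the
      # null's fitted length shifts the location by beta * log(N / len)
      mu <- p$null$mu + p$null$beta * log(max(N, 1) / p$null$len)
      z <- (hit$score - mu) / p$null$beta
      pval <- 1 - exp(-exp(-z))
      if (pval > cevalue_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        profile_id = p$profile_id, score = hit$score,
        dom_score = hit$score, c_evalue = pval,
        qstart = hit$from, qend = hit$to, stringsAsFactors = FALSE)
    }
    out[[q]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(profile_id = character(), score = numeric(),
                 dom_score = numeric(), c_evalue = numeric(),
                 qstart = integer(), qend = integer(),
                 stringsAsFactors = FALSE)
  }
  out
}

#' Signed gene locations from scan hits
#'
#' Per profile: 0 when the profile has no retained hit; otherwise the
#' nucleotide midpoint of the best hit (highest domain score). The
#' amino-acid midpoint of the hit span is mapped back through the
#' six-frame concatenation: a position `p` in forward frame
#' `f` maps to nucleotide `(f-1) + 3(p-1) + 2` (the codon midpoint,
#' 1-based on the input strand); positions in reverse frames map to the
#' codon midpoint on the reverse-complement strand, and the value is
#' negated. This convention makes annotation exactly strand-invariant:
#' reverse-complementing the genome maps every location to its negative.
#'
#' @param hits hit data.frame from [scan_genomes()].
#' @param genome_length genome length (nt).
#' @param db the `"profile_db"` the hits were produced against.
#' @return list: `scores` (named per-profile overall scores) and
#'   `locations` (named signed nucleotide midpoints).
#' @export
gene_locations <- function(hits, genome_length, db) {
  pid <- vapply(db$profiles, `[[`, character(1), "profile_id")
  scores <- setNames(numeric(length(pid)), pid)
  locs <- setNames(numeric(length(pid)), pid)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(scores = scores, locations = locs))
  }
  n <- as.integer(genome_length)
  lens <- vapply(1:3, function(f) (n - f + 1L) %/% 3L, integer(1))
  lens <- c(lens, lens)                       # F1 F2 F3 R1 R2 R3
  offsets <- cumsum(c(1L, utils::head(lens, -1) + 1L))
  for (p in unique(hits$profile_id)) {
    h <- hits[hits$profile_id == p, , drop = FALSE]
    best <- h[which.max(h$dom_score), , drop = FALSE]
    scores[p] <- max(h$score)
    mid <- (best$qstart + best$qend) %/% 2L
    k <- .frame_of(mid, offsets, lens)
    if (is.na(k)) {     # midpoint on a separator: nudge to span start frame
      k <- .frame_of(best$qstart, offsets, lens)
      mid <- best$qstart
    }
    if (is.na(k)) stop("hit span outside any frame (mapping bug)")
    pth <- mid - offsets[k] + 1L
    f <- ((k - 1L) %% 3L) + 1L
    loc <- (f - 1L) + 3L * (pth - 1L) + 2L
    if (loc < 1L || loc > n) stop("mapped location outside genome (mapping bug)")
    locs[p] <- if (k <= 3L) loc else -loc
  }
  list(scores = scores, locations = locs)
}
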