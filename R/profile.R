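#' Build a protein profile from a cluster alignment
#'
#' The external adapter builds a profile hidden Markov model with
#' `hmmbuild` (default settings). The native fallback builds a
#' position-specific scoring model: match columns are alignment columns
#' with at most 50% gaps; per-column residue frequencies get a Laplace
#' pseudocount of 1 and are log-odds scored (bits) against the BLOSUM62
#' background frequencies. Native profiles carry Gumbel null parameters
#' fitted on the scores of randomly drawn background sequences so that
#' scan hits can be assigned approximate conditional E-values.
#'
#' @param alignment named character vector of aligned rows (equal length).
#' @param profile_id identifier of the profile.
#' @param annotation concatenated member descriptions (used later for gene
#'   categorisation).
#' @param config a [pipeline_config()].
#' @param background named residue-frequency vector used for native
#'   log-odds scoring and the null fit; [build_database()] passes the
#'   pooled composition of the database's own proteins, which keeps
#'   log-odds centred for queries of like composition. `NULL` falls back
#'   to the BLOSUM62 background.
#' @return object of class `"protein_profile"` with fields `profile_id`,
#'   `length` (match columns), `engine`, `alignment`, `annotation`,
#'   `members`, and engine-specific scoring data.
#' @export
build_profile <- function(alignment, profile_id = "p0001",
                          annotation = "", config = pipeline_config(),
                          background = NULL) {
  if (length(alignment) < 1L) stop("empty alignment")
  widths <- unique(nchar(alignment))
  if (length(widths) != 1L) stop("alignment rows must have equal length")
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  if (all(chars %in% c("-", "."))) stop("all-gap alignment")
  engine <- resolve_engine(config, "hmmbuild")
  base <- list(profile_id = profile_id,
               alignment = alignment,
               annotation = annotation,
               members = names(alignment))
  if (engine == "external") {
    wd <- tempfile("hmm"); dir.create(wd)
    on.exit(unlink(wd, recursive = TRUE))
    afa <- file.path(wd, "in.afa")
    ss <- Biostrings::AAStringSet(alignment)
    Biostrings::writeXStringSet(ss, afa)
    hmm <- file.path(wd, "out.hmm")
    st <- system2("hmmbuild", c("--amino", "-n", profile_id, hmm, afa),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0) stop("hmmbuild failed for ", profile_id)
    lines <- readLines(hmm)
    leng <- as.integer(sub("^LENG\\s+", "",
                           grep("^LENG", lines, value = TRUE)[1]))
    return(structure(c(base, list(length = leng, engine = "hmmer",
                                  hmm_lines = lines)),
                     class = "protein_profile"))
  }
  ## native position-specific scoring model
  if (is.null(background)) background <- .AA_BACKGROUND
  gap_frac <- colMeans(chars == "-" | chars == ".")
  match_cols <- which(gap_frac <= 0.5)
  if (!length(match_cols)) match_cols <- which.min(gap_frac)
  L <- length(match_cols)
  pssm <- matrix(0, 20, L, dimnames = list(.AA20, NULL))
  for (k in seq_len(L)) {
    col <- chars[, match_cols[k]]
    col <- col[col %in% .AA20]
    cnt <- setNames(rep(1, 20), .AA20)     # Laplace pseudocount 1
    if (length(col)) {
      t0 <- table(col)
      cnt[names(t0)] <- cnt[names(t0)] + as.numeric(t0)
    }
    freq <- cnt / sum(cnt)
    pssm[, k] <- log2(freq / background)
  }
  null <- .fit_profile_null(pssm, seed = config$seed,
                            background = background)
  structure(c(base, list(length = L, engine = "native", pssm = pssm,
                         match_cols = match_cols, null = null)),
            class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("<protein_profile> %s: %d match columns, %d member(s), engine %s\n",
              x$profile_id, x$length, length(x$members), x$engine))
  invisible(x)
}

# pooled residue frequencies of a protein set, Laplace-smoothed; scoring
# against the training set's own composition keeps log-odds centred for
# queries of like composition
.protein_background <- function(sequences) {
  counts <- setNames(rep(1, 20), .AA20)
  t0 <- table(strsplit(paste0(sequences, collapse = ""), "")[[1]])
  t0 <- t0[names(t0) %in% .AA20]
  counts[names(t0)] <- counts[names(t0)] + as.numeric(t0)
  counts / sum(counts)
}

# BLOSUM62 background amino-acid frequencies (Robinson & Robinson)
.AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

# Gumbel null for the gapless local score of a native profile, fitted by
# moments on scores of random background sequences (seeded).
.fit_profile_null <- function(pssm, seed, n = 200L, len = 500L,
                              background = .AA_BACKGROUND) {
  scores <- withr::with_seed(seed + ncol(pssm), {
    vapply(seq_len(n), function(i) {
      idx <- sample.int(20, len, replace = TRUE, prob = background)
      .gapless_best(pssm, idx)$score
    }, numeric(1))
  })
  beta <- stats::sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  list(mu = mu, beta = beta, len = len)
}

# Best gapless local run of a PSSM along an integer-encoded sequence.
# R_j[i] = max(0, R_{j-1}[i-1]) + s_j[i]; start positions tracked so the
# hit span can be reported.
.gapless_best <- function(pssm, idx, na_score = -2) {
  N <- length(idx)
  L <- ncol(pssm)
  run <- numeric(N)
  start <- seq_len(N)
  best <- -Inf; best_end <- 0L; best_start <- 0L
  for (j in seq_len(L)) {
    sc <- rep(na_score, N)
    ok <- !is.na(idx) & idx >= 1L
    sc[ok] <- pssm[idx[ok] + (j - 1L) * 20L]
    prev <- c(0, run[-N])
    prev_start <- c(1L, start[-N])
    reset <- prev <= 0
    run <- ifelse(reset, 0, prev) + sc
    start <- ifelse(reset, seq_len(N), prev_start)
    w <- which.max(run)
    if (run[w] > best) {
      best <- run[w]; best_end <- w; best_start <- start[w]
    }
  }
  list(score = best, from = best_start, to = best_end)
}

# integer encoding of an amino-acid string over the 20-letter alphabet;
# anything else (X, *, separator) becomes NA and scores na_score
.encode_aa <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], .AA20)
  m
}

#' Score an amino-acid sequence against one profile
#'
#' For native profiles this is the best gapless local PSSM score (bits);
#' for external profiles the sequence is scored with `hmmscan` and the
#' full-sequence bit score is returned (0 when no hit is reported).
#'
#' @param profile a `"protein_profile"`.
#' @param sequence amino-acid string.
#' @return numeric score.
#' @export
profile_score <- function(profile, sequence) {
  if (profile$engine == "native") {
    return(.gapless_best(profile$pssm, .encode_aa(sequence))$score)
  }
  db <- structure(list(group = "", profiles = list(profile),
                       meta = list(engine = "hmmer", id = "tmp")),
                  class = "profile_db")
  hits <- .hmmscan_queries(setNames(sequence, "q1"), db,
                           cevalue_max = Inf, min_score = -Inf)
  h <- hits[["q1"]]
  if (is.null(h) || nrow(h) == 0L) return(0)
  max(h$score)
}

#' Build a protein-profile database from reference genomes
#'
#' Runs the full chain: protein extraction (with the minimum-length
#' filter), all-vs-all search, hit filtering, best-hit reduction, Markov
#' clustering, per-cluster alignment, and profile construction. One
#' database serves one Baltimore group (groups VI and VII are pooled, as
#' reverse-transcribing viruses share substantial protein similarity).
#' Deterministic for a fixed seed and input order.
#'
#' @param genomes named list of [genome_record()] objects sharing a
#'   Baltimore group label.
#' @param config a [pipeline_config()].
#' @param group database label; defaults to the genomes' common group
#'   (with `"VI"`/`"VII"` pooled as `"VI+VII"`).
#' @return object of class `"profile_db"`: fields `group`, `profiles`
#'   (ordered list, the order signature vectors index into), `meta`.
#' @export
build_database <- function(genomes, config = pipeline_config(),
                           group = NULL) {
  stopifnot(length(genomes) >= 1L)
  groups <- unique(vapply(genomes, function(g)
    g$taxonomy[["baltimore_group"]], character(1)))
  groups <- groups[nzchar(groups)]
  if (is.null(group)) {
    pooled <- unique(ifelse(groups %in% c("VI", "VII"), "VI+VII", groups))
    if (length(pooled) > 1L) {
      stop("genomes span multiple Baltimore groups: ",
           paste(pooled, collapse = ", "))
    }
    group <- if (length(pooled)) pooled else "unspecified"
  }
  proteins <- do.call(rbind, lapply(genomes, extract_proteins,
                                    min_len = config$protein_min_len))
  if (is.null(proteins) || nrow(proteins) == 0L) {
    stop("no proteins survive the length filter")
  }
  rownames(proteins) <- NULL
  edges <- pairwise_protein_search(proteins, config)
  edges <- filter_edges(edges, config)
  weights <- best_hit_reduction(edges)
  clusters <- mcl_cluster(weights, node_ids = proteins$id,
                          inflation = config$mcl_inflation)
  bg <- .protein_background(proteins$sequence)
  profiles <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    members <- proteins[match(clusters[[k]], proteins$id), , drop = FALSE]
    aln <- align_cluster(members, config)
    ann <- paste(unique(members$description[nzchar(members$description)]),
                 collapse = "; ")
    profiles[[k]] <- build_profile(aln, sprintf("p%04d", k), ann, config,
                                   background = bg)
  }
  engine <- if (length(profiles) &&
                profiles[[1]]$engine == "hmmer") "hmmer" else "native"
  structure(list(group = group, profiles = profiles,
                 meta = list(id = sprintf("%s-%dp-%s", group,
                                          length(profiles), engine),
                             engine = engine,
                             n_proteins = nrow(proteins),
                             thresholds = list(
                               protein_min_len = config$protein_min_len,
                               evalue = config$blast_evalue_max,
                               identity = config$blast_identity_min,
                               coverage = config$blast_coverage_min),
                             seed = config$seed)),
            class = "profile_db")
}

#' @export
print.profile_db <- function(x, ...) {
  cat(sprintf("<profile_db> group %s: %d profiles (engine %s)\n",
              x$group, length(x$profiles), x$meta$engine))
  invisible(x)
}

#' Update a profile database with genes from additional genomes
#'
#' Pools the proteins of the new genomes (all of them -- including genomes
#' that a length filter excluded from classification) with the proteins of
#' the genomes the database was built from, and rebuilds clustering and
#' profiles from scratch. With no new genomes the database is rebuilt
#' identically.
#'
#' @param db_genomes genomes the current database was built from.
#' @param new_genomes additional (e.g. unclassified metagenomic) genomes.
#' @param config a [pipeline_config()].
#' @return a new `"profile_db"`.
#' @export
update_database <- function(db_genomes, new_genomes = list(),
                            config = pipeline_config()) {
  all_genomes <- c(db_genomes, new_genomes)
  grp <- unique(vapply(db_genomes, function(g)
    g$taxonomy[["baltimore_group"]], character(1)))
  grp <- grp[nzchar(grp)]
  grp <- if (length(grp)) {
    pooled <- unique(ifelse(grp %in% c("VI", "VII"), "VI+VII", grp))
    pooled[1]
  } else "unspecified"
  build_database(all_genomes, config, group = grp)
}

#' Write / read a profile database
#'
#' The database is serialised as a versioned plain-text directory:
#' `meta.json` (group, engine, thresholds, profile order), one alignment
#' FASTA per profile under `alignments/`, and per-profile scoring data
#' under `profiles/` (`.hmm` text for external profiles, a PSSM TSV plus
#' null parameters for native ones).
#'
#' @param db a `"profile_db"`.
#' @param dir target directory (created).
#' @export
write_profile_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  meta <- db$meta
  meta$format_version <- 1L
  meta$group <- db$group
  meta$profile_ids <- vapply(db$profiles, `[[`, character(1), "profile_id")
  meta$annotations <- vapply(db$profiles, `[[`, character(1), "annotation")
  meta$members <- lapply(db$profiles, `[[`, "members")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (p in db$profiles) {
    ss <- Biostrings::AAStringSet(p$alignment)
    Biostrings::writeXStringSet(
      ss, file.path(dir, "alignments", paste0(p$profile_id, ".afa")))
    if (p$engine == "hmmer") {
      writeLines(p$hmm_lines,
                 file.path(dir, "profiles", paste0(p$profile_id, ".hmm")))
    } else {
      pf <- file.path(dir, "profiles", paste0(p$profile_id, ".pssm.tsv"))
      tab <- data.frame(aa = rownames(p$pssm),
                        apply(p$pssm, 2, sprintf, fmt = "%.17g"))
      utils::write.table(tab, pf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(
        c(p$null, list(match_cols = p$match_cols)),
        file.path(dir, "profiles", paste0(p$profile_id, ".null.json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' @rdname write_profile_db
#' @export
read_profile_db <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ids <- meta$profile_ids
  profiles <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    afa <- Biostrings::readAAStringSet(
      file.path(dir, "alignments", paste0(ids[k], ".afa")))
    aln <- as.character(afa)
    base <- list(profile_id = ids[k], alignment = aln,
                 annotation = meta$annotations[k],
                 members = if (is.list(meta$members)) meta$members[[k]]
                           else meta$members)
    hmmf <- file.path(dir, "profiles", paste0(ids[k], ".hmm"))
    if (file.exists(hmmf)) {
      lines <- readLines(hmmf)
      leng <- as.integer(sub("^LENG\\s+", "",
                             grep("^LENG", lines, value = TRUE)[1]))
      profiles[[k]] <- structure(
        c(base, list(length = leng, engine = "hmmer", hmm_lines = lines)),
        class = "protein_profile")
    } else {
      tab <- utils::read.delim(
        file.path(dir, "profiles", paste0(ids[k], ".pssm.tsv")),
        stringsAsFactors = FALSE)
      pssm <- as.matrix(tab[, -1, drop = FALSE])
      storage.mode(pssm) <- "double"
      rownames(pssm) <- tab$aa; colnames(pssm) <- NULL
      nl <- jsonlite::read_json(
        file.path(dir, "profiles", paste0(ids[k], ".null.json")),
        simplifyVector = TRUE)
      profiles[[k]] <- structure(
        c(base, list(length = ncol(pssm), engine = "native", pssm = pssm,
                     match_cols = nl$match_cols,
                     null = nl[c("mu", "beta", "len")])),
        class = "protein_profile")
    }
  }
  structure(list(group = meta$group, profiles = profiles,
                 meta = meta[setdiff(names(meta),
                                     c("profile_ids", "annotations",
                                       "members", "group"))]),
            class = "profile_db")
}
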