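#' Align the members of a protein cluster
#'
#' Singleton clusters return the sequence unchanged as a one-row alignment.
#' The external adapter shells out to MAFFT with the configured gap opening
#' and extension costs (default 3.0 / 0.0); if the adapter fails the native
#' fallback runs with a warning. The native fallback is a progressive
#' aligner: a k-mer distance matrix gives a UPGMA guide tree, and profiles
#' are merged bottom-up by global profile-profile dynamic programming under
#' BLOSUM62 column scores with gap opening cost `gap_open` and free gap
#' extension.
#'
#' @param proteins protein data.frame (columns `id`, `sequence`) for one
#'   cluster.
#' @param config a [pipeline_config()].
#' @return named character vector: aligned rows (equal length, `-` gaps) in
#'   input order.
#' @export
align_cluster <- function(proteins, config = pipeline_config()) {
  if (nrow(proteins) < 1L) stop("empty cluster")
  if (nrow(proteins) == 1L) {
    return(setNames(proteins$sequence, proteins$id))
  }
  engine <- resolve_engine(config, "mafft")
  if (engine == "external") {
    aln <- tryCatch(.align_mafft(proteins, config), error = function(e) NULL)
    if (!is.null(aln)) return(aln)
    warning("external aligner failed; using native progressive aligner")
  }
  .align_native(proteins, config)
}

.align_mafft <- function(proteins, config) {
  wd <- tempfile("mafft"); dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  inp <- file.path(wd, "in.faa"); outp <- file.path(wd, "out.faa")
  write_protein_fasta(proteins, inp)
  st <- system2("mafft",
                c("--quiet", "--auto", "--amino",
                  "--op", format(config$gap_open),
                  "--ep", format(config$gap_extend), inp),
                stdout = outp, stderr = FALSE)
  if (st != 0) stop("mafft failed")
  aln <- Biostrings::readAAStringSet(outp)
  out <- toupper(as.character(aln))
  names(out) <- sub("\\s.*$", "", names(aln))
  out[proteins$id]
}

## ---- native progressive aligner ----

.align_native <- function(proteins, config) {
  ids <- proteins$id
  seqs <- proteins$sequence
  n <- length(ids)
  D <- .kmer_distance_matrix(seqs)
  dimnames(D) <- list(ids, ids)
  guide <- upgma(structure(D, class = c("dist_matrix", "matrix")))
  profs <- lapply(seqs, function(s) {
    matrix(strsplit(s, "")[[1]], nrow = 1)
  })
  names(profs) <- ids
  # walk merges bottom-up; each node's profile is a character matrix
  node_prof <- vector("list", nrow(guide$merge))
  node_rows <- vector("list", nrow(guide$merge))
  get_prof <- function(k) {
    if (k < 0) list(prof = profs[[-k]], rows = ids[-k])
    else list(prof = node_prof[[k]], rows = node_rows[[k]])
  }
  for (m in seq_len(nrow(guide$merge))) {
    L <- get_prof(guide$merge[m, 1])
    R <- get_prof(guide$merge[m, 2])
    merged <- .profile_align(L$prof, R$prof, config$gap_open)
    node_prof[[m]] <- merged
    node_rows[[m]] <- c(L$rows, R$rows)
  }
  final <- node_prof[[nrow(guide$merge)]]
  rows <- node_rows[[nrow(guide$merge)]]
  out <- apply(final, 1, paste0, collapse = "")
  names(out) <- rows
  out[ids]
}

.kmer_distance_matrix <- function(seqs, kmer = 3L) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < kmer) return(character())
    unique(substring(s, seq_len(L - kmer + 1L),
                     seq_len(L - kmer + 1L) + kmer - 1L))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(km[[i]], km[[j]]))
      denom <- min(length(km[[i]]), length(km[[j]]))
      d <- if (denom == 0) 1 else 1 - shared / denom
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

.b62_cache <- new.env(parent = emptyenv())
.B62 <- function() {
  if (is.null(.b62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .b62_cache$m <- e$BLOSUM62[.AA20, .AA20]
  }
  .b62_cache$m
}

# column residue-frequency matrix (20 x L) of an alignment block
.col_freqs <- function(prof) {
  L <- ncol(prof)
  f <- matrix(0, 20, L, dimnames = list(.AA20, NULL))
  for (j in seq_len(L)) {
    col <- prof[, j]
    col <- col[col %in% .AA20]
    if (length(col)) {
      t0 <- table(col)
      f[names(t0), j] <- as.numeric(t0) / length(col)
    }
  }
  f
}

# Global profile-profile alignment, gap open `go`, gap extension 0.
# With free extension a gap run of any length costs `go` once, so the two
# gap states reduce to running maxima and the DP vectorises row by row.
.profile_align <- function(A, B, go) {
  fa <- .col_freqs(A); fb <- .col_freqs(B)
  n <- ncol(A); m <- ncol(B)
  S <- t(fa) %*% .B62() %*% fb      # n x m column-pair scores
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # match state ending at (i,j)
  C <- matrix(NEG, n + 1L, m + 1L)  # gap run consuming rows of A
  R <- matrix(NEG, n + 1L, m + 1L)  # gap run consuming rows of B
  M[1, 1] <- 0
  C[, 1] <- -go; C[1, ] <- NEG
  R[1, ] <- -go; R[, 1] <- NEG
  C[1, 1] <- R[1, 1] <- NEG
  for (i in 2L:(n + 1L)) {
    M[i, 2L:(m + 1L)] <- S[i - 1L, ] +
      pmax(M[i - 1L, 1L:m], C[i - 1L, 1L:m], R[i - 1L, 1L:m])
    C[i, ] <- pmax(C[i - 1L, ], M[i - 1L, ] - go, R[i - 1L, ] - go)
    mc <- pmax(M[i, ], C[i, ])
    R[i, 2L:(m + 1L)] <- cummax(mc[1L:m]) - go
  }
  # traceback
  ai <- n + 1L; aj <- m + 1L
  state <- which.max(c(M[ai, aj], C[ai, aj], R[ai, aj]))
  outA <- list(); outB <- list()
  gapA <- rep("-", nrow(A)); gapB <- rep("-", nrow(B))
  while (ai > 1L || aj > 1L) {
    if (state == 1L) {                 # column from both
      outA <- c(outA, list(A[, ai - 1L])); outB <- c(outB, list(B[, aj - 1L]))
      prev <- c(M[ai - 1L, aj - 1L], C[ai - 1L, aj - 1L], R[ai - 1L, aj - 1L])
      ai <- ai - 1L; aj <- aj - 1L
      state <- which.max(prev)
    } else if (state == 2L) {          # column from A, gap in B
      outA <- c(outA, list(A[, ai - 1L])); outB <- c(outB, list(gapB))
      prev <- c(M[ai - 1L, aj] - go, C[ai - 1L, aj], R[ai - 1L, aj] - go)
      ai <- ai - 1L
      state <- if (ai == 1L && aj > 1L) 3L else which.max(prev)
    } else {                           # column from B, gap in A
      outA <- c(outA, list(gapA)); outB <- c(outB, list(B[, aj - 1L]))
      prev <- c(M[ai, aj - 1L] - go, C[ai, aj - 1L] - go, R[ai, aj - 1L])
      aj <- aj - 1L
      state <- if (aj == 1L && ai > 1L) 2L else which.max(prev)
    }
  }
  cols <- rev(c(outA))
  colsB <- rev(c(outB))
  out <- matrix("", nrow(A) + nrow(B), length(cols))
  for (k in seq_along(cols)) {
    out[, k] <- c(cols[[k]], colsB[[k]])
  }
  out
}
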