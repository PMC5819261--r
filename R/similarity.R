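#' Generalised Jaccard index of two nonnegative vectors
#'
#' \deqn{J(x, y) = \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)}
#'
#' When both vectors are identically zero there is no detectable similarity
#' and the index is defined as 0.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return a number in `[0, 1]`.
#' @export
generalized_jaccard <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("entries must be nonnegative")
  den <- sum(pmax(x, y))
  if (den == 0) return(0)
  sum(pmin(x, y)) / den
}

#' Composite generalised Jaccard (CGJ) similarity
#'
#' Geometric mean of the generalised Jaccard indices computed over the
#' profile-score signatures (`Jp`) and the genome-organisation signatures
#' (`Jo`): \deqn{J = \sqrt{J_p J_o}.}
#'
#' @param Jp,Jo generalised Jaccard indices in `[0, 1]`.
#' @return a number in `[0, 1]`.
#' @export
cgj_similarity <- function(Jp, Jo) {
  if (any(Jp < 0 | Jp > 1) || any(Jo < 0 | Jo > 1)) {
    stop("Jaccard indices must lie in [0, 1]")
  }
  sqrt(Jp * Jo)
}

# CGJ similarity between every row of one signature table and every row of
# another (or itself). Returns a matrix of J values.
cgj_cross <- function(table_a, table_b = table_a) {
  sa <- table_a$scores; sb <- table_b$scores
  ga <- table_a$gom_sigs; gb <- table_b$gom_sigs
  na <- nrow(sa); nb <- nrow(sb)
  out <- matrix(0, na, nb, dimnames = list(rownames(sa), rownames(sb)))
  for (i in seq_len(na)) {
    xi <- sa[i, ]; gi <- ga[i, ]
    jp <- .gj_rows(xi, sb)
    jo <- .gj_rows(gi, gb)
    out[i, ] <- sqrt(jp * jo)
  }
  out
}

# generalised Jaccard of vector x against every row of matrix M (vectorised)
.gj_rows <- function(x, M) {
  X <- matrix(x, nrow(M), length(x), byrow = TRUE)
  den <- rowSums(pmax(X, M))
  num <- rowSums(pmin(X, M))
  ifelse(den == 0, 0, num / den)
}

#' Pairwise CGJ distance matrix of a signature table
#'
#' For each pair of rows, `D = 1 - sqrt(Jp * Jo)` where `Jp` is the
#' generalised Jaccard index over the profile-score signatures and `Jo` the
#' one over the GOM signatures. Symmetric with zero diagonal, entries in
#' `[0, 1]`.
#'
#' @param table a `"signature_table"` (see [annotate()]).
#' @return object of class `"dist_matrix"`: a labelled symmetric matrix.
#' @export
pairwise_distance_matrix <- function(table) {
  stopifnot(inherits(table, "signature_table"))
  if (nrow(table$scores) < 2L) stop("need at least two rows")
  J <- cgj_cross(table)
  D <- 1 - J
  D[abs(D) < .Machine$double.eps * 4] <- 0
  diag(D) <- 0
  D <- (D + t(D)) / 2   # guard against asymmetric rounding
  structure(D, class = c("dist_matrix", "matrix"))
}

#' Write / read a distance matrix
#'
#' `write_distance_matrix()` writes either a square tab-separated table with
#' row and column labels (`format = "tsv"`) or a square PHYLIP-style matrix
#' (`format = "phylip"`). `read_distance_matrix()` reads the TSV form back.
#'
#' @param D a `"dist_matrix"`.
#' @param path output path.
#' @param format `"tsv"` or `"phylip"`.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  M <- unclass(D)
  if (format == "tsv") {
    tab <- data.frame(label = rownames(M),
                      format(M, digits = 17, trim = TRUE, scientific = FALSE),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(M)), con)
    for (i in seq_len(nrow(M))) {
      writeLines(paste(formatC(rownames(M)[i], width = -10),
                       paste(sprintf("%.6f", M[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  labels <- tab$label
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  dimnames(M) <- list(labels, labels)
  structure(M, class = c("dist_matrix", "matrix"))
}
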