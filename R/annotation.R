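#' Signature tables
#'
#' A signature table holds, per virus: the profile-score signature (one
#' score per database profile, 0 = no significant hit), the signed
#' gene-location vector (nucleotide midpoint of the best profile hit,
#' negative when the gene lies on the complementary strand, 0 = absent) and
#' the GOM signature (one distance-correlation value per reference family's
#' genome-organisation model).
#'
#' @param accessions character vector of row labels.
#' @param taxonomy data.frame with one row per accession (columns
#'   `accession`, `baltimore_group`, `order`, `family`, `genus`, `species`).
#' @param scores,locations numeric matrices, rows = accessions, columns =
#'   database profiles (identical column order).
#' @param gom_sigs numeric matrix, rows = accessions, columns = reference
#'   GOM labels.
#' @param meta free-form provenance list.
#' @return object of class `"signature_table"`.
#' @export
signature_table <- function(accessions, taxonomy, scores, locations,
                            gom_sigs, meta = list()) {
  accessions <- as.character(unname(accessions))
  stopifnot(nrow(scores) == length(accessions),
            nrow(locations) == length(accessions),
            nrow(gom_sigs) == length(accessions),
            identical(colnames(scores), colnames(locations)))
  rownames(scores) <- rownames(locations) <- rownames(gom_sigs) <- accessions
  if (any(scores < 0)) stop("profile scores must be nonnegative")
  structure(list(accessions = accessions, taxonomy = taxonomy,
                 scores = scores, locations = locations,
                 gom_sigs = gom_sigs, meta = meta),
            class = "signature_table")
}

#' @export
print.signature_table <- function(x, ...) {
  cat(sprintf("<signature_table> %d viruses x %d profiles, %d GOMs\n",
              nrow(x$scores), ncol(x$scores), ncol(x$gom_sigs)))
  invisible(x)
}

# subset rows of a signature table
subset_signature_table <- function(table, accessions) {
  i <- match(accessions, table$accessions)
  if (anyNA(i)) stop("unknown accession(s)")
  signature_table(table$accessions[i], table$taxonomy[i, , drop = FALSE],
                  table$scores[i, , drop = FALSE],
                  table$locations[i, , drop = FALSE],
                  table$gom_sigs[i, , drop = FALSE], table$meta)
}

#' Genome-organisation model (GOM) of a taxonomic group
#'
#' A GOM is a matrix whose rows are the signed gene-location vectors of the
#' group's member genomes (columns = database profiles).
#'
#' @param location_vectors numeric matrix (rows = member genomes) or a
#'   single vector.
#' @param label group label (virus family).
#' @return the matrix, with attributes `label`.
#' @export
build_gom <- function(location_vectors, label) {
  if (is.null(dim(location_vectors))) {
    location_vectors <- matrix(location_vectors, nrow = 1)
  }
  if (nrow(location_vectors) < 1L) stop("GOM needs at least one member")
  structure(location_vectors, label = label)
}

#' Build one GOM per family from a location matrix
#'
#' @param locations matrix of signed gene locations (rows = genomes).
#' @param families family label per row.
#' @return named list of GOMs, ordered by sorted family label (the fixed
#'   GOM ordering that GOM signatures index into).
#' @export
build_gom_set <- function(locations, families) {
  stopifnot(nrow(locations) == length(families))
  fams <- sort(unique(families))
  out <- lapply(fams, function(f) {
    build_gom(locations[families == f, , drop = FALSE], f)
  })
  names(out) <- fams
  out
}

#' Distance correlation between a gene-location vector and a GOM
#'
#' Szekely's distance correlation between paired observations indexed by
#' profile: observation i pairs the query's location for profile i (a
#' scalar) with the GOM's column i (the locations of that gene across the
#' group's member genomes). Profiles absent from both the query and the GOM
#' (location 0 everywhere) are ignored. Pairwise Euclidean distance
#' matrices of the two samples are double-centred to `A` and `B`;
#' `dCov^2 = mean(A*B)`, and
#' `dCor = sqrt(dCov^2 / sqrt(dVar_x dVar_y))`. A sample with zero distance
#' variance (constant series) gives 0 by convention.
#'
#' @param x numeric vector of signed gene locations (length = number of
#'   database profiles).
#' @param gom a GOM matrix (see [build_gom()]).
#' @return a value in `[0, 1]`.
#' @export
distance_correlation <- function(x, gom) {
  if (is.null(dim(gom))) gom <- matrix(gom, nrow = 1)
  if (length(x) != ncol(gom)) stop("length mismatch between x and GOM")
  keep <- !(x == 0 & colSums(abs(gom)) == 0)
  if (sum(keep) < 2L) {
    warning("fewer than 2 usable profiles; distance correlation set to 0")
    return(0)
  }
  x <- x[keep]
  Y <- gom[, keep, drop = FALSE]
  a <- abs(outer(x, x, "-"))
  b <- as.matrix(stats::dist(t(Y)))
  A <- .double_centre(a)
  B <- .double_centre(b)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  dcov2 <- mean(A * B)
  if (dcov2 <= 0) return(0)
  min(1, sqrt(dcov2 / sqrt(dvx * dvy)))
}

.double_centre <- function(m) {
  rm <- rowMeans(m); cm <- colMeans(m); gm <- mean(m)
  m - outer(rm, rep(1, ncol(m))) - outer(rep(1, nrow(m)), cm) + gm
}

#' GOM signature of a gene-location vector
#'
#' Element j is the distance correlation between the location vector and
#' the j-th reference GOM.
#'
#' @param locations signed gene-location vector.
#' @param goms named list of GOMs ([build_gom_set()]).
#' @return named numeric vector in `[0, 1]`.
#' @export
gom_signature <- function(locations, goms) {
  vapply(goms, function(g) suppressWarnings(
    distance_correlation(locations, g)), numeric(1))
}

#' @rdname gom_signature
#' @param locations_matrix matrix of location vectors (rows = genomes).
#' @export
gom_signature_matrix <- function(locations_matrix, goms) {
  out <- t(apply(locations_matrix, 1, gom_signature, goms = goms))
  if (length(goms) == 1L) out <- matrix(out, ncol = 1,
                                        dimnames = list(rownames(locations_matrix),
                                                        names(goms)))
  colnames(out) <- names(goms)
  out
}

#' Annotate genomes against a profile database
#'
#' Each genome is concatenated (largest segment first), six-frame
#' translated, and scanned against the database; hits with conditional
#' E-value above the cut-off or non-positive score are discarded. The
#' per-profile score and the signed nucleotide midpoint of the best hit
#' form the profile-score signature and gene-location vector. GOM
#' signatures are then computed against `goms`; when `goms` is `NULL`
#' (reference mode) the GOMs are first built from the annotated rows,
#' grouped by the family labels of the genomes themselves.
#'
#' @param genomes named list of [genome_record()] objects.
#' @param db a profile database ([build_database()]).
#' @param goms named list of reference GOMs, or `NULL` to build them from
#'   these genomes' own family labels.
#' @param config a [pipeline_config()].
#' @return a `"signature_table"`; when `goms` was `NULL` the built GOM set
#'   is attached as attribute `"goms"`.
#' @export
annotate <- function(genomes, db, goms = NULL, config = pipeline_config()) {
  stopifnot(length(genomes) >= 1L)
  accs <- vapply(genomes, function(g) g$accession, character(1))
  if (anyDuplicated(accs)) stop("duplicate accessions in genome set")
  names(genomes) <- accs
  seqs <- vapply(genomes, function(g)
    concatenate_segments(g$segments), character(1))
  hits <- scan_genomes(seqs, db, config)
  p <- length(db$profiles)
  pid <- vapply(db$profiles, function(x) x$profile_id, character(1))
  scores <- matrix(0, length(accs), p, dimnames = list(accs, pid))
  locs <- matrix(0, length(accs), p, dimnames = list(accs, pid))
  for (i in seq_along(accs)) {
    h <- hits[[accs[i]]]
    if (is.null(h) || nrow(h) == 0L) next
    gl <- gene_locations(h, nchar(seqs[[i]]), db)
    scores[i, ] <- gl$scores
    locs[i, ] <- gl$locations
  }
  tax <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(accession = g$accession, t(g$taxonomy),
               stringsAsFactors = FALSE)
  }))
  rownames(tax) <- NULL
  built_goms <- NULL
  if (is.null(goms)) {
    fams <- tax$family
    if (all(fams == "")) stop("reference mode needs family labels")
    built_goms <- build_gom_set(locs, fams)
    goms <- built_goms
  }
  gs <- gom_signature_matrix(locs, goms)
  out <- signature_table(accs, tax, scores, locs, gs,
                         meta = list(db_id = db$meta$id,
                                     gom_labels = names(goms)))
  if (!is.null(built_goms)) attr(out, "goms") <- built_goms
  attr(out, "annotations") <- vapply(db$profiles, `[[`, character(1),
                                     "annotation")
  out
}

#' Write / read a signature table
#'
#' Tab-separated with a `#`-prefixed header block recording the database
#' id, profile ordering and GOM ordering. Scores and locations are written
#' with full precision so the round trip is bit-exact.
#'
#' @param table a `"signature_table"`.
#' @param path file path.
#' @export
write_signature_table <- function(table, path) {
  con <- file(path, "w"); on.exit(close(con))
  pid <- colnames(table$scores)
  gl <- colnames(table$gom_sigs)
  writeLines(c(
    paste0("#db_id\t", if (is.null(table$meta$db_id)) "" else table$meta$db_id),
    paste0("#profiles\t", paste(pid, collapse = ",")),
    paste0("#goms\t", paste(gl, collapse = ","))
  ), con)
  num <- function(m) apply(m, 2, function(col) sprintf("%.17g", col))
  tab <- data.frame(table$taxonomy,
                    setNames(as.data.frame(num(table$scores)),
                             paste0("score.", pid)),
                    setNames(as.data.frame(num(table$locations)),
                             paste0("loc.", pid)),
                    setNames(as.data.frame(num(table$gom_sigs)),
                             paste0("gom.", gl)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_table
#' @export
read_signature_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^#", key, "\t"), hdr, value = TRUE)
    if (!length(ln)) return(character())
    strsplit(sub(paste0("^#", key, "\t"), "", ln), ",")[[1]]
  }
  pid <- get("profiles"); gl <- get("goms")
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste0(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  taxcols <- c("accession", "baltimore_group", "order", "family",
               "genus", "species")
  tax <- tab[, taxcols, drop = FALSE]
  getm <- function(prefix, ids) {
    m <- as.matrix(tab[, paste0(prefix, ids), drop = FALSE])
    storage.mode(m) <- "double"
    colnames(m) <- ids
    m
  }
  signature_table(tab$accession, tax,
                  getm("score.", pid), getm("loc.", pid), getm("gom.", gl),
                  meta = list(db_id = get("db_id")))
}
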