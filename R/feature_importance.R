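#' Mutual information between a feature and class labels
#'
#' Nonnegative estimate in nats of the mutual dependence between a
#' (profile-score) feature and discrete taxonomy labels. Features with at
#' most `discrete_max` unique values are scored with the discrete plug-in
#' formula; continuous features use the k-nearest-neighbour estimator for
#' a continuous variable against a discrete one (Ross 2014), which is
#' invariant under strictly monotone transforms of the feature. Exact ties
#' are broken by an infinitesimal deterministic jitter.
#'
#' @param feature numeric vector.
#' @param labels vector of class labels (same length).
#' @param k neighbours for the kNN estimator (default 3).
#' @param discrete_max unique-value count at or below which the plug-in
#'   estimator is used.
#' @return MI estimate in nats (>= 0; 0 for a single class or a constant
#'   feature).
#' @export
mutual_information <- function(feature, labels, k = 3L, discrete_max = 8L) {
  if (length(feature) != length(labels)) stop("length mismatch")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) return(0)
  if (length(unique(feature)) <= discrete_max) {
    return(.mi_discrete(feature, labels))
  }
  .mi_knn(feature, labels, k)
}

.mi_discrete <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  ee <- outer(px, py)
  max(0, sum(p[nz] * log(p[nz] / ee[nz])))
}

# Ross (2014): radius of point i = distance to its k-th nearest neighbour
# within its own class; m_i = number of points of any class strictly
# inside that radius (self excluded).
# MI = psi(N) - <psi(n_c)> + <psi(k_i)> - <psi(m_i + 1)>.
.mi_knn <- function(x, y, k) {
  if (anyDuplicated(x)) {
    scale <- max(1e-10, 1e-10 * stats::sd(x))
    x <- x + withr::with_seed(0L, stats::rnorm(length(x), 0, scale))
  }
  cls <- split(seq_along(x), y)
  cls <- cls[lengths(cls) >= 2L]
  use <- sort(unlist(cls, use.names = FALSE))
  N <- length(use)
  if (N < 3L) return(0)
  n_c <- lengths(cls)[y[use]]
  terms <- vapply(use, function(i) {
    same <- cls[[y[i]]]
    same <- same[same != i]
    ki <- min(k, length(same))
    radius <- sort(abs(x[same] - x[i]))[ki]
    m_i <- sum(abs(x[use] - x[i]) < radius) - 1L
    c(digamma(ki), digamma(m_i + 1L))
  }, numeric(2))
  mi <- digamma(N) - mean(digamma(n_c)) + mean(terms[1, ]) -
    mean(terms[2, ])
  max(0, mi)
}

#' Mutual-information scores of all profiles in a signature table
#'
#' Because group sizes vary greatly, each of the `reps` estimates is
#' computed on a subsample holding at most `max_per_group` viruses per
#' group; the reported score per profile is the mean across repeats.
#' Profiles are flagged as informative when the mean exceeds
#' `display_threshold` (default 0.1 nats).
#'
#' @param table a `"signature_table"`.
#' @param rank taxonomy rank providing the labels (default `"family"`).
#' @param reps number of repeats (default 100).
#' @param max_per_group per-group subsample cap (default 2).
#' @param seed integer seed; fixed seed reproduces identical means.
#' @param display_threshold mean-MI cut-off for the `informative` flag.
#' @param labels optional explicit label vector overriding `rank` (used by
#'   [family_shared_features()]).
#' @return data.frame: `profile_id`, `mean_mi` (nats), `category`
#'   (keyword-based gene category of the profile annotation), `n_reps`,
#'   `informative`; sorted by decreasing mean MI. The estimator name is
#'   recorded in attribute `"estimator"`.
#' @export
mi_profile <- function(table, rank = "family", reps = 100L,
                       max_per_group = 2L, seed = 1L,
                       display_threshold = 0.1, labels = NULL) {
  stopifnot(inherits(table, "signature_table"), reps >= 1)
  if (is.null(labels)) labels <- table$taxonomy[[rank]]
  scores <- table$scores
  p <- ncol(scores)
  acc <- withr::with_seed(seed, {
    tot <- matrix(0, reps, p)
    for (r in seq_len(reps)) {
      idx <- unlist(lapply(split(seq_along(labels), labels), function(m) {
        if (length(m) > max_per_group) sample(m, max_per_group) else m
      }), use.names = FALSE)
      sub_lab <- labels[idx]
      for (j in seq_len(p)) {
        tot[r, j] <- mutual_information(scores[idx, j], sub_lab)
      }
    }
    tot
  })
  ann <- vapply(seq_len(p), function(j) {
    a <- attr(table, "annotations")
    if (is.null(a)) "" else a[j]
  }, character(1))
  out <- data.frame(profile_id = colnames(scores),
                    mean_mi = colMeans(acc),
                    category = vapply(ann, categorize_profile, character(1)),
                    n_reps = as.integer(reps),
                    stringsAsFactors = FALSE)
  out$informative <- out$mean_mi > display_threshold
  out <- out[order(-out$mean_mi, out$profile_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "estimator") <- "kNN (k=3) / discrete plug-in, nats"
  out
}

#' Features shared by a set of families
#'
#' Relabels the table binarily -- viruses of the investigated families
#' against all others -- removes profile columns with no hit in the
#' investigated families, and runs the same repeated subsampled MI scheme
#' as [mi_profile()].
#'
#' @param families character vector of family labels of interest.
#' @param table a `"signature_table"`.
#' @inheritParams mi_profile
#' @return as [mi_profile()]; the number of removed columns is recorded in
#'   attribute `"n_removed"`.
#' @export
family_shared_features <- function(families, table, reps = 100L,
                                   max_per_group = 2L, seed = 1L,
                                   display_threshold = 0.1) {
  fam <- table$taxonomy$family
  labels <- ifelse(fam %in% families, "investigated", "other")
  inv <- labels == "investigated"
  keep <- colSums(table$scores[inv, , drop = FALSE]) > 0
  sub <- signature_table(table$accessions, table$taxonomy,
                         table$scores[, keep, drop = FALSE],
                         table$locations[, keep, drop = FALSE],
                         table$gom_sigs, table$meta)
  ann <- attr(table, "annotations")
  if (!is.null(ann)) attr(sub, "annotations") <- ann[keep]
  out <- mi_profile(sub, reps = reps, max_per_group = max_per_group,
                    seed = seed, display_threshold = display_threshold,
                    labels = labels)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Categorise a profile by its gene annotation
#'
#' Case-insensitive keyword matching of the profile's concatenated member
#' descriptions into gene categories, with precedence
#' replication > capsid/gag > other non-structural > other structural:
#' \itemize{
#'   \item `nonstructural_replication`: polymerase, replicase;
#'   \item `structural_capsid_gag`: capsid, gag, coat, shell, core,
#'     nucleocapsid;
#'   \item `nonstructural_other`: reductase, kinase, T antigen, protease,
#'     helicase, "NS", non(-)structural, replication, transcription;
#'   \item `structural_other`: glycoprotein, matrix, tegument, envelope,
#'     surface, membrane, "structural" (but never via the "structural" in
#'     "non-structural");
#'   \item `unknown` otherwise.
#' }
#'
#' @param annotation free-text gene description(s).
#' @return one of the five category strings.
#' @export
categorize_profile <- function(annotation) {
  a <- tolower(annotation)
  if (!nzchar(trimws(a))) return("unknown")
  has <- function(pat) grepl(pat, a, perl = TRUE)
  if (has("polymerase|replicase")) return("nonstructural_replication")
  if (has("capsid|\\bgag\\b|\\bcoat\\b|\\bshell\\b|\\bcore\\b")) {
    return("structural_capsid_gag")
  }
  if (has(paste0("reductase|kinase|t[- ]antigen|protease|helicase|",
                 "\\bns\\d*\\b|non[- ]?structural|replication|",
                 "transcription"))) {
    return("nonstructural_other")
  }
  if (has("glycoprotein|matrix|tegument|envelope?\\b|surface|membrane") ||
      has("(?<!non-)(?<!non)structural")) {
    return("structural_other")
  }
  "unknown"
}

#' Write a mutual-information report
#' @param mi data.frame from [mi_profile()].
#' @param path output TSV path.
#' @export
write_mi_report <- function(mi, path) {
  utils::write.table(mi, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
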