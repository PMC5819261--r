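#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration weighted by cluster sizes: the closest
#' pair of clusters is merged at height `d/2`, and distances to the merged
#' cluster are the size-weighted means of the members' distances. Ties are
#' broken deterministically by the lexicographically smallest pair of
#' cluster representatives (the smallest leaf label in each cluster). The
#' result is a rooted, ultrametric binary tree.
#'
#' @param D a symmetric `"dist_matrix"` (or plain labelled matrix) with
#'   zero diagonal.
#' @return object of class `"upgma_tree"`: `merge` (hclust-style merge
#'   matrix: negative entries are leaves, positive entries earlier
#'   merges), `height` (merge heights, `d/2` units), `labels`, and
#'   optionally `support` (percent, per merge; `NA` until computed).
#' @export
upgma <- function(D) {
  M <- unclass(as.matrix(D))
  n <- nrow(M)
  if (n < 2L) stop("need at least two labels")
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("t", seq_len(n))
  }
  if (max(abs(M - t(M))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(M)
  active <- as.list(seq_len(n))          # cluster -> merge code (-leaf | +row)
  reps <- labels                          # lexicographic representative
  sizes <- rep(1L, n)
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  Dw <- M
  ut <- upper.tri(M)
  for (step in seq_len(n - 1L)) {
    U <- ifelse(ut, Dw, Inf)
    m0 <- min(U)
    cand <- which(U <= m0 + 1e-15, arr.ind = TRUE)
    # deterministic tie-break: lexicographically smallest representatives
    k1 <- pmin(reps[cand[, 1]], reps[cand[, 2]])
    k2 <- pmax(reps[cand[, 1]], reps[cand[, 2]])
    sel <- order(k1, k2)[1]
    i <- cand[sel, 1]; j <- cand[sel, 2]
    bestd <- Dw[i, j]
    merge[step, ] <- c(codes[i], codes[j])
    height[step] <- bestd / 2
    # size-weighted average linkage update, written into slot i
    ni <- sizes[i]; nj <- sizes[j]
    upd <- (ni * Dw[i, ] + nj * Dw[j, ]) / (ni + nj)
    Dw[i, ] <- upd; Dw[, i] <- upd
    Dw[i, i] <- 0
    sizes[i] <- ni + nj
    codes[i] <- step
    reps[i] <- min(reps[i], reps[j])
    Dw[j, ] <- Inf; Dw[, j] <- Inf   # retire slot j
  }
  structure(list(merge = merge, height = height, labels = labels,
                 support = rep(NA_real_, n - 1L)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.4g%s\n",
              length(x$labels), max(x$height),
              if (all(is.na(x$support))) "" else ", with clade support"))
  invisible(x)
}

# leaf labels under each merge row (list of character vectors, sorted)
tree_clades <- function(tree) {
  n1 <- nrow(tree$merge)
  out <- vector("list", n1)
  for (m in seq_len(n1)) {
    kids <- tree$merge[m, ]
    leaves <- character()
    for (k in kids) {
      leaves <- c(leaves, if (k < 0) tree$labels[-k] else out[[k]])
    }
    out[[m]] <- sort(leaves)
  }
  out
}

#' Cophenetic distance matrix of a tree
#'
#' The cophenetic distance between two leaves is twice the merge height of
#' their lowest common ancestor.
#'
#' @param tree an `"upgma_tree"`.
#' @return labelled symmetric matrix.
#' @export
cophenetic_matrix <- function(tree) {
  n <- length(tree$labels)
  C <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- vector("list", nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[m, ]
    sets <- lapply(kids, function(k) {
      if (k < 0) -k else members[[k]]
    })
    C[sets[[1]], sets[[2]]] <- 2 * tree$height[m]
    C[sets[[2]], sets[[1]]] <- 2 * tree$height[m]
    members[[m]] <- c(sets[[1]], sets[[2]])
  }
  C
}

#' Cophenetic correlation between a tree and its source distances
#'
#' Pearson correlation between the cophenetic distances implied by the
#' tree and the original pairwise distances, over all leaf pairs.
#'
#' @param tree an `"upgma_tree"`.
#' @param D the source `"dist_matrix"` (matching label set).
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, D) {
  M <- unclass(as.matrix(D))
  if (!setequal(rownames(M), tree$labels)) stop("label sets differ")
  if (length(tree$labels) < 3L) {
    stop("cophenetic correlation undefined for fewer than 3 taxa")
  }
  M <- M[tree$labels, tree$labels]
  C <- cophenetic_matrix(tree)
  lt <- lower.tri(M)
  x <- M[lt]; y <- C[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(1)
  stats::cor(x, y)
}

#' Bootstrap dendrograms by profile resampling
#'
#' Per replicate, profile indices are resampled uniformly with replacement
#' to the original database size; the signature-score and gene-location
#' columns and every GOM's columns are rebuilt from the resampled indices
#' (duplicated profiles appear multiply), the GOM signatures are
#' recomputed by distance correlation, the full CGJ distance matrix is
#' recomputed, and a UPGMA tree is built. This column resampling is
#' equivalent to re-annotating against the resampled database, because
#' each profile's score and location are independent of the other
#' profiles.
#'
#' @param table a `"signature_table"`.
#' @param goms named list of GOMs consistent with the table's columns.
#' @param n_reps number of replicates (default 100).
#' @param seed integer seed; a fixed seed reproduces the replicate set.
#' @return list of `"upgma_tree"` objects.
#' @export
bootstrap_trees <- function(table, goms, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(table, "signature_table"), n_reps >= 1)
  p <- ncol(table$scores)
  withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(p, p, replace = TRUE)
      upgma(.resampled_distance(table, goms, idx))
    })
  })
}

.resampled_distance <- function(table, goms, idx) {
  sc <- table$scores[, idx, drop = FALSE]
  lc <- table$locations[, idx, drop = FALSE]
  colnames(sc) <- colnames(lc) <- paste0("r", seq_along(idx))
  goms_r <- lapply(goms, function(g) g[, idx, drop = FALSE])
  gs <- gom_signature_matrix(lc, goms_r)
  tab_r <- signature_table(table$accessions, table$taxonomy, sc, lc, gs)
  pairwise_distance_matrix(tab_r)
}

#' Bootstrap support for the clades of a best-estimate tree
#'
#' For every internal clade of `best` (leaves and the root clade
#' excluded), the support is the percentage of replicate trees containing
#' a clade with the identical leaf set.
#'
#' @param best the best-estimate `"upgma_tree"`.
#' @param replicates list of replicate trees over the same leaf set.
#' @return data.frame (`clade`, `size`, `support`) plus the `best` tree
#'   with its `support` field filled, returned as attribute `"tree"`.
#' @export
clade_support <- function(best, replicates) {
  for (r in replicates) {
    if (!setequal(r$labels, best$labels)) stop("leaf sets differ")
  }
  clades <- tree_clades(best)
  keys <- vapply(clades, paste, character(1), collapse = "\r")
  root <- which.max(lengths(clades))
  rep_keys <- lapply(replicates, function(r) {
    vapply(tree_clades(r), paste, character(1), collapse = "\r")
  })
  supp <- vapply(seq_along(keys), function(m) {
    100 * mean(vapply(rep_keys, function(rk) keys[m] %in% rk, logical(1)))
  }, numeric(1))
  supp[root] <- NA_real_
  best$support <- supp
  out <- data.frame(
    clade = vapply(clades, paste, character(1), collapse = ";"),
    size = lengths(clades),
    support = supp,
    stringsAsFactors = FALSE)
  out <- out[-root, , drop = FALSE]
  attr(out, "tree") <- best
  out
}

#' Re-bootstrap a clade with a pruned signature table
#'
#' Restricts the table to the clade's members, drops profile columns that
#' no clade member has similarity to (all-zero score columns) and GOMs of
#' families with no member in the clade, recomputes GOM signatures, and
#' reruns the bootstrap on the pruned table. Pruning shrinks the bootstrap
#' sampling space so that replicates are less likely to draw only profiles
#' the clade's viruses lack ("empty profile sampling").
#'
#' @param table the full `"signature_table"`.
#' @param goms the full GOM set.
#' @param clade_leaves accessions of the clade to re-bootstrap (>= 2).
#' @param n_reps,seed as in [bootstrap_trees()].
#' @return list: `tree` (pruned best-estimate tree with support),
#'   `support` (support table), `n_profiles_dropped`, `n_goms_dropped`.
#' @export
pruned_rebootstrap <- function(table, goms, clade_leaves,
                               n_reps = 100L, seed = 1L) {
  if (length(clade_leaves) < 2L) stop("need at least two clade members")
  sub <- subset_signature_table(table, clade_leaves)
  keep_cols <- colSums(sub$scores) > 0
  fams <- unique(sub$taxonomy$family)
  keep_goms <- names(goms) %in% fams
  sc <- sub$scores[, keep_cols, drop = FALSE]
  lc <- sub$locations[, keep_cols, drop = FALSE]
  goms_p <- lapply(goms[keep_goms], function(g) {
    g[, keep_cols, drop = FALSE]
  })
  gs <- gom_signature_matrix(lc, goms_p)
  tab_p <- signature_table(sub$accessions, sub$taxonomy, sc, lc, gs,
                           meta = sub$meta)
  best <- upgma(pairwise_distance_matrix(tab_p))
  reps <- bootstrap_trees(tab_p, goms_p, n_reps = n_reps, seed = seed)
  supp <- clade_support(best, reps)
  list(tree = attr(supp, "tree"), support = supp,
       n_profiles_dropped = sum(!keep_cols),
       n_goms_dropped = sum(!keep_goms))
}

## ---- Newick I/O ----

#' Write / read trees in Newick format
#'
#' Branch lengths encode the ultrametric heights; bootstrap supports (when
#' present) are written as internal node labels. The round trip
#' write -> read -> write is byte-identical.
#'
#' @param tree an `"upgma_tree"`.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return `write_newick()`: the Newick string (invisibly when written to
#'   a file); `read_newick()`: an `"upgma_tree"`.
#' @export
write_newick <- function(tree, path = NULL) {
  # Heights are snapped to 10 significant digits before branch lengths are
  # derived: differences of snapped decimals are short exact decimals, so
  # the reader's height reconstruction (sums of parsed branch lengths,
  # error ~1e-17) re-snaps to identical values and write -> read -> write
  # is byte-identical.
  heights <- signif(tree$height, 10)
  fmt <- function(x) sprintf("%.12g", x)
  rec <- function(code, parent_h) {
    if (code < 0) {
      return(paste0(tree$labels[-code], ":", fmt(parent_h)))
    }
    kids <- tree$merge[code, ]
    inner <- paste(vapply(kids, rec, character(1),
                          parent_h = heights[code]), collapse = ",")
    lab <- if (!is.na(tree$support[code])) fmt(tree$support[code]) else ""
    paste0("(", inner, ")", lab, ":", fmt(parent_h - heights[code]))
  }
  root <- nrow(tree$merge)
  kids <- tree$merge[root, ]
  inner <- paste(vapply(kids, rec, character(1),
                        parent_h = heights[root]), collapse = ",")
  lab <- if (!is.na(tree$support[root])) fmt(tree$support[root]) else ""
  s <- paste0("(", inner, ")", lab, ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' @rdname write_newick
#' @param text Newick string (or `path` to read from).
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error near position 1")
  .phylo_to_upgma(phy)
}

# convert an ultrametric rooted phylo to the internal merge representation;
# node heights are rebuilt bottom-up (max path length to a descendant leaf)
# so rounding stays local to each subtree
.phylo_to_upgma <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  node_h <- numeric(nn)
  kids_of <- split(phy$edge[, 2], phy$edge[, 1])
  bl_of <- split(phy$edge.length, phy$edge[, 1])
  fill_h <- function(nd) {
    kids <- kids_of[[as.character(nd)]]
    if (is.null(kids)) return(0)
    bls <- bl_of[[as.character(nd)]]
    node_h[nd] <<- max(vapply(seq_along(kids), function(i)
      bls[i] + fill_h(kids[i]), numeric(1)))
    node_h[nd]
  }
  fill_h(n + 1L)
  internal <- (n + 1L):(n + phy$Nnode)
  ord <- internal[order(node_h[internal])]
  merge <- matrix(0L, phy$Nnode, 2L)
  height <- numeric(phy$Nnode)
  support <- rep(NA_real_, phy$Nnode)
  code_of <- integer(n + phy$Nnode)
  code_of[seq_len(n)] <- -seq_len(n)
  row <- 0L
  for (nd in ord) {
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    if (length(kids) != 2L) {
      stop("tree is not strictly binary")
    }
    row <- row + 1L
    merge[row, ] <- code_of[kids]
    height[row] <- node_h[nd]
    if (!is.null(phy$node.label)) {
      lab <- phy$node.label[nd - n]
      if (!is.na(lab) && nzchar(lab)) support[row] <- as.numeric(lab)
    }
    code_of[nd] <- row
  }
  structure(list(merge = merge, height = height,
                 labels = phy$tip.label, support = support),
            class = "upgma_tree")
}

#' Convert to an ape phylo object
#' @param tree an `"upgma_tree"`.
#' @return an [ape::read.tree()]-style `phylo`.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Write a clade support table
#' @param support data.frame from [clade_support()].
#' @param path output TSV path.
#' @export
write_support_table <- function(support, path) {
  utils::write.table(support, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Distance-matrix heat map ordered by tree leaf order
#'
#' Optional visual summary mirroring the usual presentation of the CGJ
#' distance matrix: rows and columns follow the dendrogram's leaf order.
#' Requires the `pheatmap` package.
#'
#' @param D a `"dist_matrix"`.
#' @param tree an `"upgma_tree"` over the same labels.
#' @param filename optional output file passed to `pheatmap`.
#' @export
plot_distance_heatmap <- function(D, tree = NULL, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_distance_heatmap requires the pheatmap package")
  }
  M <- unclass(as.matrix(D))
  if (!is.null(tree)) {
    ord <- .leaf_order(tree)
    M <- M[ord, ord]
  }
  pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                     filename = filename)
}

.leaf_order <- function(tree) {
  rec <- function(code) {
    if (code < 0) return(tree$labels[-code])
    c(rec(tree$merge[code, 1]), rec(tree$merge[code, 2]))
  }
  rec(nrow(tree$merge))
}
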