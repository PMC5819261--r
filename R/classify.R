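#' Fit a group-specific CGJ similarity threshold
#'
#' One-dimensional two-class maximum-margin separator with class-balanced
#' weights, fitted on the group's intra-group and inter-group CGJ
#' similarity distributions (each subsampled to at most `cap` values).
#' Candidate cuts are the midpoints between adjacent sorted values; the
#' fitted threshold minimises the class-balanced misclassification rate
#' and, among minimisers, sits in the middle of the widest separating
#' interval. For separable classes this is the midpoint of the margin
#' between the closest opposing points.
#'
#' @param intra CGJ similarities between members of the group.
#' @param inter CGJ similarities between members and non-members.
#' @param group group label stored in the model.
#' @param cap per-class subsample cap (default 10,000).
#' @param seed subsampling seed.
#' @return list with class `"threshold_model"`: `group`, `threshold`,
#'   `n_intra`, `n_inter`.
#' @export
fit_group_threshold <- function(intra, inter, group = "",
                                cap = 10000L, seed = 1L) {
  if (length(intra) == 0L) stop("no intra-group similarities")
  if (length(inter) == 0L) {
    warning("no inter-group similarities; threshold set to 0 (accept all)")
    return(structure(list(group = group, threshold = 0,
                          n_intra = length(intra), n_inter = 0L),
                     class = "threshold_model"))
  }
  withr::with_seed(seed, {
    if (length(intra) > cap) intra <- sample(intra, cap)
    if (length(inter) > cap) inter <- sample(inter, cap)
  })
  thr <- .balanced_margin_cut(intra, inter)
  structure(list(group = group, threshold = thr,
                 n_intra = length(intra), n_inter = length(inter)),
            class = "threshold_model")
}

# minimum class-balanced error cut; ties resolved toward the widest gap
.balanced_margin_cut <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  if (length(v) == 1L) return(v)
  cuts <- (v[-1] + v[-length(v)]) / 2
  widths <- diff(v)
  cuts <- c(v[1] - widths[1] / 2, cuts)      # accept-everything cut
  widths <- c(widths[1], widths)
  err <- vapply(cuts, function(t) {
    mean(pos < t) + mean(neg >= t)
  }, numeric(1))
  best <- err <= min(err) + 1e-12
  cuts[best][which.max(widths[best])]
}

#' Threshold check of a candidate assignment
#'
#' A candidate whose CGJ similarity is below the group threshold is
#' rejected ("unclassified"); a similarity equal to the threshold passes.
#'
#' @param cgj observed CGJ similarity.
#' @param model a `"threshold_model"`.
#' @return `TRUE` (pass) or `FALSE` (reject).
#' @export
threshold_check <- function(cgj, model) {
  cgj >= model$threshold
}

#' 1-nearest-neighbour candidate assignment
#'
#' The candidate group is the group of the reference virus with the
#' highest CGJ similarity to the query; ties go to the smallest reference
#' accession.
#'
#' @param similarities named numeric vector: CGJ similarity of the query
#'   to each reference virus.
#' @param ref_groups named character vector: group label per reference.
#' @return list: `candidate_group`, `best_neighbour`, `cgj`.
#' @export
nearest_neighbour <- function(similarities, ref_groups) {
  if (!length(similarities)) stop("empty reference set")
  best <- max(similarities)
  tied <- names(similarities)[similarities == best]
  nb <- sort(tied)[1]
  list(candidate_group = unname(ref_groups[nb]),
       best_neighbour = nb, cgj = unname(best))
}

#' Topological evaluation of a candidate assignment
#'
#' Examines the query's neighbourhood in a joint UPGMA dendrogram of all
#' reference viruses and queries. The candidate is accepted when (i) the
#' query's sister clade, (ii) its immediate outgroup (the sibling subtree
#' of its parent), or (iii) one of the two basal subtrees of its sister
#' clade is composed entirely of members of the candidate group.
#' Membership is evaluated over reference leaves only: co-analysed query
#' leaves carry no group label and are ignored, so a clade consisting
#' solely of other queries does not contradict the candidate (otherwise
#' several queries from one novel or under-sampled group would block each
#' other). Similarity support is the threshold check's responsibility,
#' which runs before this evaluation.
#'
#' @param tree joint `"upgma_tree"` containing the query and all
#'   references.
#' @param query query leaf label.
#' @param candidate_group proposed group.
#' @param ref_groups named character vector: group label per reference
#'   leaf.
#' @return list: `accept` (logical), `condition` (`"sister"`,
#'   `"outgroup"`, `"sister_basal"`, or `""`).
#' @export
topological_evaluate <- function(tree, query, candidate_group, ref_groups) {
  li <- match(query, tree$labels)
  if (is.na(li)) stop("query not in tree")
  clades <- tree_clades(tree)
  entire <- function(leaves) {
    refs <- leaves[leaves %in% names(ref_groups)]
    all(ref_groups[refs] == candidate_group)
  }
  subtree_leaves <- function(code) {
    if (code < 0) tree$labels[-code] else clades[[code]]
  }
  # merge where the query leaf attaches
  m1 <- which(tree$merge[, 1] == -li | tree$merge[, 2] == -li)
  sister_code <- setdiff(tree$merge[m1, ], -li)
  # (i) sister clade
  if (entire(subtree_leaves(sister_code))) {
    return(list(accept = TRUE, condition = "sister"))
  }
  # (ii) immediate outgroup: sibling subtree of the query's parent
  m2 <- which(tree$merge[, 1] == m1 | tree$merge[, 2] == m1)
  if (length(m2)) {
    out_code <- setdiff(tree$merge[m2, ], m1)
    if (entire(subtree_leaves(out_code))) {
      return(list(accept = TRUE, condition = "outgroup"))
    }
  }
  # (iii) the two basal branches of the sister clade
  if (sister_code > 0) {
    for (k in tree$merge[sister_code, ]) {
      if (entire(subtree_leaves(k))) {
        return(list(accept = TRUE, condition = "sister_basal"))
      }
    }
  }
  list(accept = FALSE, condition = "")
}

#' Build a classifier from labelled reference genomes
#'
#' Splits the references into sub-pipelines by (pooled) Baltimore group
#' and, per sub-pipeline: builds the profile database, annotates the
#' references against it (building the per-family GOMs), and fits a CGJ
#' threshold per group at the configured rank from the reference set's
#' intra- and inter-group similarity distributions. Groups with a single
#' member get the maximum inter-group similarity involving that member as
#' a conservative threshold.
#'
#' @param genomes named list of labelled [genome_record()] objects.
#' @param config a [pipeline_config()].
#' @return object of class `"virsig_classifier"`: list of sub-pipelines,
#'   each with `db`, `ref_table`, `goms`, `thresholds`, `ref_groups`,
#'   `min_lengths`.
#' @export
build_classifier <- function(genomes, config = pipeline_config()) {
  bg <- vapply(genomes, function(g)
    g$taxonomy[["baltimore_group"]], character(1))
  bg[bg %in% c("VI", "VII")] <- "VI+VII"
  bg[!nzchar(bg)] <- "unspecified"
  pipes <- list()
  for (grp in sort(unique(bg))) {
    gset <- genomes[bg == grp]
    db <- build_database(gset, config, group = grp)
    ref_table <- annotate(gset, db, goms = NULL, config = config)
    goms <- attr(ref_table, "goms")
    groups <- .rank_labels(ref_table$taxonomy, config$rank)
    names(groups) <- ref_table$accessions
    thresholds <- .fit_thresholds(ref_table, groups, config)
    lens <- vapply(gset, function(g) sum(nchar(g$segments)), numeric(1))
    min_lengths <- tapply(lens, groups[names(gset)], min)
    pipes[[grp]] <- list(group = grp, db = db, ref_table = ref_table,
                         goms = goms, thresholds = thresholds,
                         ref_groups = groups,
                         min_lengths = min_lengths)
  }
  structure(list(pipelines = pipes, config = config),
            class = "virsig_classifier")
}

.rank_labels <- function(taxonomy, rank) {
  lab <- taxonomy[[rank]]
  lab[is.na(lab)] <- ""
  lab
}

.fit_thresholds <- function(ref_table, groups, config) {
  J <- cgj_cross(ref_table)
  out <- list()
  for (g in sort(unique(groups))) {
    i <- which(groups == g)
    o <- which(groups != g)
    inter <- as.numeric(J[i, o])
    if (length(i) < 2L) {
      thr <- if (length(inter)) min(1, max(inter)) else 0
      out[[g]] <- structure(list(group = g, threshold = thr,
                                 n_intra = 0L, n_inter = length(inter)),
                            class = "threshold_model")
    } else {
      intra <- J[i, i][upper.tri(J[i, i])]
      out[[g]] <- fit_group_threshold(intra, inter, group = g,
                                      cap = config$svm_sample_cap,
                                      seed = config$seed)
    }
  }
  out
}

#' @export
print.virsig_classifier <- function(x, ...) {
  cat(sprintf("<virsig_classifier> %d sub-pipeline(s): %s\n",
              length(x$pipelines),
              paste(names(x$pipelines), collapse = ", ")))
  invisible(x)
}

#' Classify query genomes
#'
#' Runs every query through every sub-pipeline: annotation against the
#' sub-pipeline's database and GOMs, 1-nearest-neighbour candidate
#' assignment by CGJ similarity, the group-threshold check, and the
#' topological evaluation on a joint dendrogram of all references and all
#' queries. A query accepted by several sub-pipelines takes the
#' assignment with the highest CGJ similarity; a query accepted by none
#' is "unclassified".
#'
#' @param classifier a `"virsig_classifier"`.
#' @param queries named list of [genome_record()] objects (possibly
#'   empty).
#' @param config optional [pipeline_config()]; defaults to the
#'   classifier's.
#' @return data.frame: `query`, `assigned_group` (`"unclassified"` when
#'   rejected), `sub_pipeline`, `cgj`, `nearest_neighbour`, `threshold`,
#'   `threshold_pass`, `condition` (which topological condition fired).
#' @export
classify <- function(classifier, queries, config = NULL) {
  stopifnot(inherits(classifier, "virsig_classifier"))
  if (is.null(config)) config <- classifier$config
  if (!length(queries)) {
    return(data.frame(query = character(), assigned_group = character(),
                      sub_pipeline = character(), cgj = numeric(),
                      nearest_neighbour = character(), threshold = numeric(),
                      threshold_pass = logical(), condition = character(),
                      stringsAsFactors = FALSE))
  }
  qaccs <- vapply(queries, function(g) g$accession, character(1))
  cand <- list()
  for (pipe in classifier$pipelines) {
    qtab <- annotate(queries, pipe$db, goms = pipe$goms, config = config)
    J <- cgj_cross(qtab, pipe$ref_table)
    joint <- .joint_table(pipe$ref_table, qtab)
    tree <- upgma(pairwise_distance_matrix(joint))
    for (q in qaccs) {
      nn <- nearest_neighbour(J[q, ], pipe$ref_groups)
      model <- pipe$thresholds[[nn$candidate_group]]
      pass <- !is.null(model) && threshold_check(nn$cgj, model)
      topo <- list(accept = FALSE, condition = "")
      if (pass) {
        topo <- topological_evaluate(tree, q, nn$candidate_group,
                                     pipe$ref_groups)
      }
      cand[[length(cand) + 1L]] <- data.frame(
        query = q, sub_pipeline = pipe$group,
        candidate_group = nn$candidate_group,
        nearest_neighbour = nn$best_neighbour, cgj = nn$cgj,
        threshold = if (is.null(model)) NA_real_ else model$threshold,
        threshold_pass = pass,
        accepted = pass && topo$accept,
        condition = topo$condition,
        stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, cand)
  out <- lapply(qaccs, function(q) {
    rows <- cand[cand$query == q, , drop = FALSE]
    acc <- rows[rows$accepted, , drop = FALSE]
    if (nrow(acc)) {
      best <- acc[which.max(acc$cgj), , drop = FALSE]
      data.frame(query = q, assigned_group = best$candidate_group,
                 sub_pipeline = best$sub_pipeline, cgj = best$cgj,
                 nearest_neighbour = best$nearest_neighbour,
                 threshold = best$threshold, threshold_pass = TRUE,
                 condition = best$condition, stringsAsFactors = FALSE)
    } else {
      best <- rows[which.max(rows$cgj), , drop = FALSE]
      data.frame(query = q, assigned_group = "unclassified",
                 sub_pipeline = best$sub_pipeline, cgj = best$cgj,
                 nearest_neighbour = best$nearest_neighbour,
                 threshold = best$threshold,
                 threshold_pass = best$threshold_pass,
                 condition = best$condition, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

# stack reference and query signature tables (shared profile columns and
# GOM ordering)
.joint_table <- function(ref, qry) {
  stopifnot(identical(colnames(ref$scores), colnames(qry$scores)),
            identical(colnames(ref$gom_sigs), colnames(qry$gom_sigs)))
  signature_table(c(ref$accessions, qry$accessions),
                  rbind(ref$taxonomy, qry$taxonomy),
                  rbind(ref$scores, qry$scores),
                  rbind(ref$locations, qry$locations),
                  rbind(ref$gom_sigs, qry$gom_sigs),
                  meta = ref$meta)
}

#' Cross-validate the classifier on a labelled genome set
#'
#' Repeats an independent random split `config$cv_folds` times: within
#' each group at the configured rank, 67% of the genomes go to the
#' reference set and 33% to the test set; groups with fewer than three
#' genomes (and any group listed in `holdout_groups`) go entirely to the
#' test set. Per fold, a classifier is built from the reference genomes
#' and the test genomes are classified. Sensitivity is the fraction of
#' test viruses whose group is represented in the reference set that are
#' assigned to their correct group; specificity is the fraction of test
#' viruses from unrepresented groups that are labelled "unclassified".
#'
#' @param genomes named list of labelled [genome_record()] objects.
#' @param config a [pipeline_config()].
#' @param holdout_groups groups always placed in the test set.
#' @param seed split seed (defaults to `config$seed`).
#' @return data.frame with one row per fold: counts and percentages per
#'   "known"/"unknown" stratum, plus attribute `"results"` with the
#'   per-query classification of every fold.
#' @export
cross_validate <- function(genomes, config = pipeline_config(),
                           holdout_groups = character(),
                           seed = config$seed) {
  groups <- vapply(genomes, function(g)
    g$taxonomy[[config$rank]], character(1))
  folds <- withr::with_seed(seed, {
    lapply(seq_len(config$cv_folds), function(f) {
      ref <- character()
      for (g in unique(groups)) {
        members <- names(genomes)[groups == g]
        if (length(members) < 3L || g %in% holdout_groups) next
        n_ref <- max(2L, round(0.67 * length(members)))
        ref <- c(ref, sample(members, n_ref))
      }
      ref
    })
  })
  rows <- list(); all_results <- list()
  for (f in seq_along(folds)) {
    ref_ids <- folds[[f]]
    test_ids <- setdiff(names(genomes), ref_ids)
    clf <- build_classifier(genomes[ref_ids], config)
    res <- classify(clf, genomes[test_ids], config)
    truth <- groups[res$query]
    known <- truth %in% unique(groups[ref_ids])
    correct <- known & res$assigned_group == truth
    wrong <- known & res$assigned_group != "unclassified" &
      res$assigned_group != truth
    unk_ok <- !known & res$assigned_group == "unclassified"
    res$fold <- f
    res$truth <- unname(truth)
    res$stratum <- ifelse(known, "known", "unknown")
    all_results[[f]] <- res
    rows[[f]] <- data.frame(
      fold = f,
      n_known = sum(known),
      n_correct = sum(correct),
      n_wrong = sum(wrong),
      n_unclassified_known = sum(known) - sum(correct) - sum(wrong),
      sensitivity = if (sum(known)) 100 * sum(correct) / sum(known)
                    else NA_real_,
      n_unknown = sum(!known),
      n_unknown_unclassified = sum(unk_ok),
      n_unknown_assigned = sum(!known) - sum(unk_ok),
      specificity = if (sum(!known)) 100 * sum(unk_ok) / sum(!known)
                    else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- do.call(rbind, all_results)
  out
}

#' Metagenomic length filter
#'
#' Excludes query genomes shorter than the smallest reference genome of
#' their provisional group (a query exactly at the minimum is retained).
#' Queries with an empty or unrepresented provisional group are retained
#' with a warning.
#'
#' @param queries named list of query [genome_record()] objects.
#' @param provisional_groups named character vector: provisional group per
#'   query accession.
#' @param reference_genomes named list of labelled reference genomes.
#' @param rank taxonomic rank of the provisional labels.
#' @return the retained queries; excluded accessions in attribute
#'   `"excluded"`.
#' @export
metagenomic_length_filter <- function(queries, provisional_groups,
                                      reference_genomes, rank = "family") {
  ref_groups <- vapply(reference_genomes, function(g)
    g$taxonomy[[rank]], character(1))
  ref_lens <- vapply(reference_genomes, function(g)
    sum(nchar(g$segments)), numeric(1))
  min_len <- tapply(ref_lens, ref_groups, min)
  keep <- logical(length(queries))
  for (i in seq_along(queries)) {
    acc <- queries[[i]]$accession
    grp <- provisional_groups[[acc]]
    qlen <- sum(nchar(queries[[i]]$segments))
    if (is.null(grp) || is.na(grp) || !nzchar(grp) ||
        !(grp %in% names(min_len))) {
      warning("query ", acc, " has no represented provisional group; retained")
      keep[i] <- TRUE
    } else {
      keep[i] <- qlen >= min_len[[grp]]
    }
  }
  out <- queries[keep]
  attr(out, "excluded") <- vapply(queries[!keep], function(g)
    g$accession, character(1))
  out
}

#' Write a classification report
#' @param results data.frame from [classify()].
#' @param path output TSV path.
#' @export
write_classification_report <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cross-validation report
#' @param cv data.frame from [cross_validate()].
#' @param path output TSV path.
#' @export
write_cv_report <- function(cv, path) {
  utils::write.table(cv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
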