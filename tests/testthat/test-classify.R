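tiny_classifier <- function() {
  memo("tiny_clf", build_classifier(tiny_sim()$genomes, native_config()))
}

test_that("group threshold is the balanced maximum-margin cut", {
  m <- fit_group_threshold(c(0.8, 0.9), c(0.1, 0.2), group = "f")
  expect_equal(m$threshold, 0.5)

  expect_warning(m0 <- fit_group_threshold(0.9, numeric(), group = "g"),
                 "threshold set to 0")
  expect_equal(m0$threshold, 0)

  # subsample cap is honoured
  withr::with_seed(1, {
    mcap <- fit_group_threshold(runif(20000, .6, 1), runif(20000, 0, .4),
                                cap = 10000, seed = 5)
  })
  expect_equal(mcap$n_intra, 10000L)
  expect_equal(mcap$n_inter, 10000L)

  # overlapping distributions: chosen cut attains the brute-force minimum
  # of the class-balanced misclassification over a dense grid
  withr::with_seed(2, {
    pos <- rnorm(300, 0.7, 0.12); neg <- rnorm(500, 0.45, 0.12)
    pos <- pmin(pmax(pos, 0), 1); neg <- pmin(pmax(neg, 0), 1)
  })
  fit <- fit_group_threshold(pos, neg, cap = 10000, seed = 1)
  balerr <- function(t) mean(pos < t) + mean(neg >= t)
  grid <- seq(-0.01, 1.01, by = 1e-4)
  expect_lte(balerr(fit$threshold), min(vapply(grid, balerr, numeric(1))) +
               1e-9)
})

test_that("threshold check uses >= semantics", {
  m <- structure(list(group = "f", threshold = 0.5), class = "threshold_model")
  expect_false(threshold_check(0.3, m))
  expect_true(threshold_check(0.5, m))
  expect_true(threshold_check(0.9, m))
})

test_that("1-NN assignment picks the most similar reference, ties by accession", {
  groups <- c(R1 = "f", R2 = "g", R3 = "f")
  nn <- nearest_neighbour(c(R1 = 1, R2 = 0.4, R3 = 0.2), groups)
  expect_equal(nn$candidate_group, "f")
  expect_equal(nn$cgj, 1)
  tie <- nearest_neighbour(c(R3 = 0.8, R2 = 0.8, R1 = 0.1), groups)
  expect_equal(tie$best_neighbour, "R2")
  expect_equal(tie$candidate_group, "g")
  nn0 <- nearest_neighbour(c(R1 = 0, R2 = 0, R3 = 0), groups)
  expect_equal(nn0$cgj, 0)
})

test_that("topological evaluation implements the three acceptance conditions", {
  groups <- c(RF = "f", RF2 = "f", RG = "g", RG2 = "g", RH = "h",
              F1 = "f", F2 = "f", G1 = "g", G2 = "g",
              H1 = "h", H2 = "h")
  ev <- function(nwk, cand) {
    topological_evaluate(read_newick(nwk), "Q", cand, groups)
  }
  # (i) sister clade entirely the candidate group
  r <- ev("((Q:1,RF:1):1,RG:2);", "f")
  expect_true(r$accept); expect_equal(r$condition, "sister")
  # (ii) immediate outgroup entirely the candidate group
  r <- ev("((Q:1,RG:1):1,RF:2);", "f")
  expect_true(r$accept); expect_equal(r$condition, "outgroup")
  # (iii) a basal branch of the sister clade
  r <- ev(paste0("((Q:2,((F1:0.5,F2:0.5):1,(G1:0.7,G2:0.7):0.8):0.5):1,",
                 "(H1:1,H2:1):2);"), "f")
  expect_true(r$accept); expect_equal(r$condition, "sister_basal")
  # none of the conditions
  r <- ev("((Q:1,RG:1):1,(RG2:1,RH:1):1);", "f")
  expect_false(r$accept)
  # co-analysed query leaves are ignored: an all-query sister cannot block
  # the candidate (several queries of one family would otherwise block
  # each other)
  r <- topological_evaluate(read_newick("((Q:1,Q2:1):1,RF:2);"),
                            "Q", "f", groups)
  expect_true(r$accept); expect_equal(r$condition, "sister")
  # ... but a sister containing a foreign reference still rejects via (i)
  r <- topological_evaluate(read_newick("(((Q:1,RG:1):0.5,RH:1.5):1,RF:2.5);"),
                            "Q", "f", groups)
  expect_false(r$accept)
  expect_error(topological_evaluate(read_newick("((A:1,B:1):1,C:2);"),
                                    "Q", "f", groups), "not in tree")
})

test_that("references re-classify to their own group; novelties are rejected", {
  fx <- tiny_native()
  clf <- tiny_classifier()
  # a copy of a reference genome classifies to its own family with cgj ~ 1
  g <- fx$sim$genomes[[5]]
  copy <- genome_record("COPY1", g$segments, taxonomy = g$taxonomy)
  res <- classify(clf, list(COPY1 = copy))
  expect_equal(res$assigned_group, g$taxonomy[["family"]])
  expect_gt(res$cgj, 0.98)

  # held-out family with disjoint repertoire is always unclassified
  unk <- simulate_queries(fx$sim, 2, "unknown", seed = 31, acc_prefix = "U")
  res_u <- classify(clf, unk$genomes)
  expect_true(all(res_u$assigned_group == "unclassified"))
  expect_true(all(res_u$cgj == 0))

  # zero queries: empty report
  expect_equal(nrow(classify(clf, list())), 0L)
})

test_that("raising a group's threshold never turns unclassified into assigned", {
  fx <- tiny_native()
  clf <- tiny_classifier()
  q <- simulate_queries(fx$sim, 3, "mixed", seed = 33, acc_prefix = "M")
  res <- classify(clf, q$genomes)
  clf_hi <- clf
  for (g in names(clf_hi$pipelines[[1]]$thresholds)) {
    clf_hi$pipelines[[1]]$thresholds[[g]]$threshold <-
      min(1, clf_hi$pipelines[[1]]$thresholds[[g]]$threshold + 0.2)
  }
  res_hi <- classify(clf_hi, q$genomes)
  was_un <- res$assigned_group == "unclassified"
  expect_true(all(res_hi$assigned_group[was_un] == "unclassified"))
})

test_that("cross-validation puts small groups in the test set and scores folds", {
  cfg <- native_config(seed = 5)
  cfg$cv_folds <- 2L
  sim <- simulate_reference_set(simulation_config(
    n_families = 3, genomes_per_family = 4, genes_per_genome = 2,
    gene_length_range = c(110L, 150L), seed = 55))
  # add a 2-member family: always test, hence "unknown"
  extra <- simulate_reference_set(simulation_config(
    n_families = 1, genomes_per_family = 2, genes_per_genome = 2,
    gene_length_range = c(110L, 150L), seed = 56))
  small <- extra$genomes
  for (a in names(small)) {
    small[[a]]$accession <- paste0("X", a)
    small[[a]]$taxonomy[["family"]] <- "tinyfam"
  }
  names(small) <- paste0("X", names(small))
  cv <- cross_validate(c(sim$genomes, small), cfg)
  res <- attr(cv, "results")
  # both members of the 2-genome family were tested in every fold
  for (f in unique(res$fold)) {
    expect_equal(sum(res$fold == f & res$truth == "tinyfam"), 2L)
    expect_true(all(res$stratum[res$fold == f & res$truth == "tinyfam"] ==
                      "unknown"))
  }
  expect_true(all(cv$sensitivity >= 0 & cv$sensitivity <= 100))
  expect_true(all(cv$specificity >= 0 & cv$specificity <= 100))
  # counts are consistent
  expect_equal(cv$n_correct + cv$n_wrong + cv$n_unclassified_known,
               cv$n_known)
  expect_equal(cv$n_unknown_unclassified + cv$n_unknown_assigned,
               cv$n_unknown)
})

test_that("metagenomic length filter uses the group minimum with >= retention", {
  refs <- list(
    R1 = genome_record("R1", rand_dna(3000, 1),
                       taxonomy = c(family = "famA")),
    R2 = genome_record("R2", rand_dna(2500, 2),
                       taxonomy = c(family = "famA")),
    R3 = genome_record("R3", rand_dna(5000, 3),
                       taxonomy = c(family = "famB")))
  qs <- list(
    Q1 = genome_record("Q1", rand_dna(2400, 4)),   # short for famA
    Q2 = genome_record("Q2", rand_dna(2500, 5)),   # exactly at minimum
    Q3 = genome_record("Q3", rand_dna(1000, 6)))   # no known group
  prov <- c(Q1 = "famA", Q2 = "famA", Q3 = "")
  expect_warning(kept <- metagenomic_length_filter(qs, prov, refs),
                 "retained")
  expect_setequal(names(kept), c("Q2", "Q3"))
  expect_equal(attr(kept, "excluded"), c(Q1 = "Q1"))
})
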