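dm <- function(M, labels) {
  dimnames(M) <- list(labels, labels)
  structure(M, class = c("dist_matrix", "matrix"))
}

test_that("UPGMA reproduces hand-computed merges", {
  # two taxa at d = 0.6 merge at height 0.3
  t2 <- upgma(dm(matrix(c(0, .6, .6, 0), 2), c("A", "B")))
  expect_equal(t2$height, 0.3)

  # d(A,B)=2, d(A,C)=8, d(B,C)=8: (A,B) at height 1, then C at height 4
  M <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, byrow = TRUE)
  t3 <- upgma(dm(M, c("A", "B", "C")))
  expect_equal(t3$height, c(1, 4))
  cl <- virsig:::tree_clades(t3)
  expect_identical(cl[[1]], c("A", "B"))

  expect_error(upgma(dm(matrix(c(0, 1, 2, 0), 2), c("A", "B"))),
               "symmetric")
})

test_that("UPGMA agrees with average-linkage hclust on random matrices", {
  withr::with_seed(17, {
    for (r in 1:5) {
      n <- sample(5:12, 1)
      M <- matrix(0, n, n)
      M[upper.tri(M)] <- runif(n * (n - 1) / 2, 0.1, 1)
      M <- M + t(M)
      labels <- sprintf("t%02d", 1:n)
      tree <- upgma(dm(M, labels))
      hc <- hclust(as.dist(M), method = "average")
      hc$labels <- labels
      expect_equal(virsig:::cophenetic_matrix(tree)[labels, labels],
                   as.matrix(stats::cophenetic(hc))[labels, labels],
                   tolerance = 1e-12)
    }
  })
})

test_that("UPGMA heights are monotone and outputs ultrametric", {
  tab <- simulate_signature_table(n_families = 4, genomes_per_family = 3,
                                  noise_sd = 5, seed = 5)
  D <- pairwise_distance_matrix(tab)
  tree <- upgma(D)
  expect_true(all(diff(sort(tree$height)) >= 0))
  # children merge below their parent
  for (m in seq_len(nrow(tree$merge))) {
    for (k in tree$merge[m, ]) {
      if (k > 0) expect_lte(tree$height[k], tree$height[m])
    }
  }
  # the cophenetic matrix of an UPGMA tree is itself ultrametric
  C <- virsig:::cophenetic_matrix(tree)
  expect_equal(unname(diag(C)), rep(0, nrow(C)))
  # ultrametric input is reproduced exactly
  tree2 <- upgma(dm(C, rownames(C)))
  expect_equal(virsig:::cophenetic_matrix(tree2)[rownames(C), rownames(C)],
               C, tolerance = 1e-12)
})

test_that("cophenetic correlation matches the all-pairs oracle and noise ladder", {
  tab <- simulate_signature_table(n_families = 4, genomes_per_family = 4,
                                  seed = 6)
  D <- pairwise_distance_matrix(tab)
  tree <- upgma(D)
  # direct oracle: correlation over all pairs
  C <- virsig:::cophenetic_matrix(tree)[rownames(D), rownames(D)]
  lt <- lower.tri(D)
  expect_equal(cophenetic_correlation(tree, D), cor(D[lt], C[lt]))
  # exact preservation of an ultrametric matrix
  expect_equal(cophenetic_correlation(upgma(dm(C, rownames(C))),
                                      dm(C, rownames(C))), 1)
  # noise ladder: correlation decreases as distances are perturbed
  withr::with_seed(30, {
    cors <- vapply(c(0.02, 0.1, 0.3), function(sd0) {
      E <- matrix(0, nrow(C), ncol(C))
      E[upper.tri(E)] <- abs(rnorm(sum(upper.tri(E)), 0, sd0))
      E <- E + t(E)
      Dn <- dm(pmin(C + E, 1), rownames(C))
      cophenetic_correlation(upgma(Dn), Dn)
    }, numeric(1))
    expect_lt(cors[1], 1 + 1e-12)
    expect_true(all(diff(cors) < 0))
  })
  expect_error(cophenetic_correlation(upgma(dm(matrix(c(0, 1, 1, 0), 2),
                                               c("A", "B"))),
                                      dm(matrix(c(0, 1, 1, 0), 2),
                                         c("A", "B"))),
               "fewer than 3")
})

test_that("single-profile bootstrap replicates equal the best tree", {
  tab <- simulate_signature_table(n_families = 3, genomes_per_family = 3,
                                  profiles_per_family = 1, seed = 7)
  # keep only one profile so resampling is the identity
  one <- signature_table(tab$accessions, tab$taxonomy,
                         tab$scores[, 1, drop = FALSE],
                         tab$locations[, 1, drop = FALSE],
                         tab$gom_sigs)
  goms <- build_gom_set(one$locations, one$taxonomy$family)
  gs <- gom_signature_matrix(one$locations, goms)
  one <- signature_table(one$accessions, one$taxonomy, one$scores,
                         one$locations, gs)
  best <- upgma(pairwise_distance_matrix(one))
  reps <- bootstrap_trees(one, goms, n_reps = 10, seed = 1)
  supp <- clade_support(best, reps)
  expect_true(all(supp$support == 100))
})

test_that("bootstrap replicates are seed-reproducible and support counts right", {
  tab <- simulate_signature_table(n_families = 3, genomes_per_family = 3,
                                  noise_sd = 10, seed = 8)
  goms <- build_gom_set(tab$locations, tab$taxonomy$family)
  r1 <- bootstrap_trees(tab, goms, n_reps = 5, seed = 9)
  r2 <- bootstrap_trees(tab, goms, n_reps = 5, seed = 9)
  expect_identical(lapply(r1, `[[`, "merge"), lapply(r2, `[[`, "merge"))
  expect_identical(lapply(r1, `[[`, "height"), lapply(r2, `[[`, "height"))

  # direct counting: a clade present in 2 of 4 replicates scores 50%
  best <- upgma(dm(matrix(c(0, .2, .9, .9,
                            .2, 0, .9, .9,
                            .9, .9, 0, .4,
                            .9, .9, .4, 0), 4, byrow = TRUE),
                   c("A", "B", "C", "D")))
  alt <- upgma(dm(matrix(c(0, .9, .2, .9,
                           .9, 0, .9, .4,
                           .2, .9, 0, .9,
                           .9, .4, .9, 0), 4, byrow = TRUE),
                  c("A", "B", "C", "D")))
  supp <- clade_support(best, list(best, best, alt, alt))
  ab <- supp$support[supp$clade == "A;B"]
  expect_equal(ab, 50)
  # invariant to replicate order
  supp2 <- clade_support(best, list(alt, best, alt, best))
  expect_equal(supp$support, supp2$support)
})

test_that("pruned re-bootstrap drops irrelevant columns and foreign GOMs", {
  tab <- simulate_signature_table(n_families = 4, genomes_per_family = 3,
                                  profiles_per_family = 3, seed = 11)
  goms <- build_gom_set(tab$locations, tab$taxonomy$family)
  clade <- tab$accessions[tab$taxonomy$family %in% c("fam01", "fam02")]
  pr <- pruned_rebootstrap(tab, goms, clade, n_reps = 10, seed = 2)
  # two families with 3 private profiles each: 6 dropped columns, 2 GOMs
  expect_equal(pr$n_profiles_dropped, 6)
  expect_equal(pr$n_goms_dropped, 2)
  expect_setequal(pr$tree$labels, clade)

  # clade using all profiles: pruning is a no-op vs plain subtable bootstrap
  clade_all <- tab$accessions
  pr2 <- pruned_rebootstrap(tab, goms, clade_all, n_reps = 5, seed = 3)
  expect_equal(pr2$n_profiles_dropped, 0)
  sub <- tab
  best <- upgma(pairwise_distance_matrix(sub))
  reps <- bootstrap_trees(sub, goms, n_reps = 5, seed = 3)
  supp <- clade_support(best, reps)
  expect_equal(pr2$support$support, supp$support)
})

test_that("Newick round trip is byte-identical and keeps supports", {
  tab <- simulate_signature_table(n_families = 3, genomes_per_family = 3,
                                  noise_sd = 8, seed = 12)
  goms <- build_gom_set(tab$locations, tab$taxonomy$family)
  best <- upgma(pairwise_distance_matrix(tab))
  reps <- bootstrap_trees(tab, goms, n_reps = 7, seed = 13)
  best <- attr(clade_support(best, reps), "tree")
  s1 <- write_newick(best)
  t2 <- read_newick(s1)
  expect_identical(write_newick(t2), s1)
  expect_setequal(t2$labels, best$labels)
  nn <- !is.na(best$support)
  expect_equal(sum(!is.na(t2$support)), sum(nn))

  # two-leaf serialisation
  t0 <- upgma(dm(matrix(c(0, .6, .6, 0), 2), c("A", "B")))
  expect_match(write_newick(t0), "^\\(A:0\\.3,B:0\\.3\\):?;?")

  expect_error(read_newick("((A,B);"), "parse")
})
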