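edge <- function(q = "a", s = "b", bits = 100, e = 1e-10,
                 pid = 90, qc = 95, sc = 95) {
  data.frame(query_id = q, subject_id = s, bit_score = bits, e_value = e,
             pct_identity = pid, query_coverage = qc, subject_coverage = sc,
             stringsAsFactors = FALSE)
}

test_that("edge filter applies the E-value, identity and coverage cut-offs", {
  cfg <- pipeline_config()
  expect_equal(nrow(filter_edges(edge(e = 1e-5, pid = 35, qc = 80, sc = 80),
                                 cfg)), 1L)
  # high identity cannot rescue a failing E-value
  expect_equal(nrow(filter_edges(edge(e = 0.01, pid = 90, qc = 100, sc = 100),
                                 cfg)), 0L)
  expect_equal(nrow(filter_edges(edge(pid = 29), cfg)), 0L)
  expect_equal(nrow(filter_edges(edge(qc = 74), cfg)), 0L)
  expect_equal(nrow(filter_edges(edge(sc = 74), cfg)), 0L)
  # boundary values are retained
  expect_equal(nrow(filter_edges(edge(e = 1e-3, pid = 30, qc = 75, sc = 75),
                                 cfg)), 1L)
  expect_equal(nrow(filter_edges(edge()[0, ], cfg)), 0L)
  # idempotent
  e2 <- rbind(edge(), edge(e = 0.5))
  expect_identical(filter_edges(filter_edges(e2, cfg), cfg),
                   filter_edges(e2, cfg))
})

test_that("best-hit reduction keeps the best bit score per unordered pair", {
  e <- rbind(edge("a", "b", bits = 50), edge("b", "a", bits = 60))
  w <- best_hit_reduction(e)
  expect_equal(nrow(w), 1L)
  expect_equal(w$weight, 60)
  expect_identical(c(w$a, w$b), c("a", "b"))

  w1 <- best_hit_reduction(edge("x", "y", bits = 42))
  expect_equal(w1$weight, 42)

  expect_equal(nrow(best_hit_reduction(edge()[0, ])), 0L)
})

test_that("MCL recovers connected structure and partitions the nodes", {
  # two disconnected weighted pairs -> 2 clusters
  w <- data.frame(a = c("a", "c"), b = c("b", "d"), weight = c(5, 7))
  cl <- mcl_cluster(w)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, paste, character(1), collapse = ","),
                  c("a,b", "c,d"))

  # fully connected triangle plus an isolated node
  w2 <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"), weight = 50)
  cl2 <- mcl_cluster(w2, node_ids = c("a", "b", "c", "d"))
  expect_setequal(vapply(cl2, paste, character(1), collapse = ","),
                  c("a,b,c", "d"))

  # clustering is invariant to uniform weight scaling
  w3 <- w2; w3$weight <- w3$weight * 1000
  expect_identical(mcl_cluster(w3, node_ids = c("a", "b", "c", "d")), cl2)
})

test_that("MCL output is a partition refining connected components", {
  withr::with_seed(99, {
    n <- 25
    ids <- sprintf("n%02d", 1:n)
    # random sparse graph
    pairs <- t(combn(ids, 2))
    take <- runif(nrow(pairs)) < 0.12
    w <- data.frame(a = pairs[take, 1], b = pairs[take, 2],
                    weight = runif(sum(take), 10, 100))
    cl <- mcl_cluster(w, node_ids = ids)
    expect_setequal(unlist(cl), ids)
    expect_equal(anyDuplicated(unlist(cl)), 0L)
    g <- igraph::graph_from_data_frame(w[, 1:2], directed = FALSE,
                                       vertices = ids)
    ncomp <- igraph::components(g)$no
    expect_gte(length(cl), ncomp)
    expect_lte(length(cl), n)
    # each cluster lies within one component
    memb <- igraph::components(g)$membership
    for (cc in cl) expect_length(unique(memb[cc]), 1L)
  })
})

test_that("native search finds self-identity and rejects unrelated pairs", {
  cfg <- native_config()
  p <- rand_protein(150, 1)
  prot <- data.frame(id = c("p1", "p2"), sequence = c(p, p))
  e <- pairwise_protein_search(prot, cfg)
  self <- e[e$query_id != e$subject_id, ][1, ]
  expect_equal(self$pct_identity, 100)
  expect_equal(self$query_coverage, 100)
  expect_equal(self$subject_coverage, 100)

  # unrelated random proteins never pass the downstream filter
  withr::with_seed(2, {
    rnd <- data.frame(id = paste0("r", 1:6),
                      sequence = replicate(6, rand_protein(150)))
  })
  e2 <- filter_edges(pairwise_protein_search(rnd, cfg), cfg)
  expect_equal(nrow(e2), 0L)

  expect_equal(nrow(pairwise_protein_search(prot[1, , drop = FALSE], cfg)),
               0L)
})

test_that("external and native engines agree on surviving pairs", {
  # planted 3-family protein fixture: 3 variants per family
  withr::with_seed(5, {
    fams <- lapply(1:3, function(i) rand_protein(140))
    prot <- do.call(rbind, lapply(1:3, function(i) {
      data.frame(id = paste0("f", i, "_", 1:3),
                 sequence = vapply(1:3, function(k) {
                   aa <- strsplit(fams[[i]], "")[[1]]
                   idx <- sample(2:140, 14)    # 10% divergence
                   aa[idx] <- sample(c("A","C","D","E","F","G","H","I","K",
                                       "L","N","P","Q","R","S","T","V","W",
                                       "Y"), 14, TRUE)
                   paste0(aa, collapse = "")
                 }, character(1)))
    }))
  })
  cfg_ext <- pipeline_config(engine = "external")
  cfg_nat <- native_config()
  surv <- function(e, cfg) {
    w <- best_hit_reduction(filter_edges(e, cfg))
    sort(paste(w$a, w$b))
  }
  pairs_ext <- surv(pairwise_protein_search(prot, cfg_ext), cfg_ext)
  pairs_nat <- surv(pairwise_protein_search(prot, cfg_nat), cfg_nat)
  expect_identical(pairs_ext, pairs_nat)
  # exactly the within-family pairs survive
  expect_length(pairs_ext, 9L)
})

test_that("tabular search results reader computes both coverages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t95.0\t100\t1e-50\t200\t1\t100\t11\t110\t100\t200",
             path)
  e <- read_search_tsv(path)
  expect_equal(e$query_coverage, 100)
  expect_equal(e$subject_coverage, 50)
  expect_equal(e$bit_score, 200)
})
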