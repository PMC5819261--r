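test_that("cluster alignment handles singletons, duplicates and deletions", {
  cfg <- native_config()
  p <- rand_protein(60, 1)

  one <- align_cluster(data.frame(id = "a", sequence = p), cfg)
  expect_identical(unname(one), p)

  two <- align_cluster(data.frame(id = c("a", "b"), sequence = c(p, p)), cfg)
  expect_identical(unname(two), c(p, p))
  expect_false(any(grepl("-", two)))

  # one internal deletion of 4 residues: native aligner restores it as gaps
  p2 <- paste0(substr(p, 1, 30), substr(p, 35, 60))
  aln <- align_cluster(data.frame(id = c("a", "b"), sequence = c(p, p2)),
                       cfg)
  expect_equal(nchar(aln[["a"]]), 60)
  expect_equal(lengths(regmatches(aln[["b"]], gregexpr("-", aln[["b"]]))), 4)
  expect_identical(gsub("-", "", aln[["b"]]), p2)
})

test_that("external aligner returns equal-length rows in input order", {
  cfg <- pipeline_config(engine = "external")
  withr::with_seed(2, {
    base <- rand_protein(80)
    var <- function() {
      aa <- strsplit(base, "")[[1]]
      idx <- sample(2:80, 8)
      aa[idx] <- sample(c("A","L","S","G","V","E","K","T"), 8, TRUE)
      paste0(aa, collapse = "")
    }
    prot <- data.frame(id = c("x", "y", "z"),
                       sequence = c(base, var(), var()))
  })
  aln <- align_cluster(prot, cfg)
  expect_identical(names(aln), prot$id)
  expect_length(unique(nchar(aln)), 1L)
  expect_identical(gsub("-", "", aln[["y"]]), prot$sequence[2])
})

test_that("native profile scores its own consensus above mutants", {
  cfg <- native_config()
  p <- rand_protein(50, 3)
  aln <- setNames(rep(p, 4), paste0("m", 1:4))
  prof <- build_profile(aln, "p0001", "replicase", cfg)
  expect_equal(prof$length, 50)
  expect_identical(prof$annotation, "replicase")

  own <- profile_score(prof, p)
  withr::with_seed(4, {
    for (k in 1:5) {
      aa <- strsplit(p, "")[[1]]
      i <- sample(50, 1)
      aa[i] <- sample(setdiff(c("A","C","D","E","F","G","H","I","K","L","M",
                                "N","P","Q","R","S","T","V","W","Y"), aa[i]),
                      1)
      expect_lt(profile_score(prof, paste0(aa, collapse = "")), own)
    }
  })
})

test_that("profile length counts match columns and all-gap input errors", {
  cfg <- native_config()
  # 10 columns, 3 of them majority-gap
  rows <- c(a = "MKLV---AQW", b = "MKLV---AQW", c = "MKLVTTTAQW")
  prof <- build_profile(rows, "p0002", "", cfg)
  expect_equal(prof$length, 7)
  expect_error(build_profile(c(a = "---", b = "---"), "p", "", cfg),
               "all-gap")
})

test_that("hmm-based profiles score member sequences", {
  cfg <- pipeline_config(engine = "external")
  p <- rand_protein(120, 5)
  aln <- setNames(rep(p, 3), paste0("m", 1:3))
  prof <- build_profile(aln, "p0003", "capsid protein", cfg)
  expect_identical(prof$engine, "hmmer")
  expect_equal(prof$length, 120)
  expect_gt(profile_score(prof, p), 50)
})

test_that("database build recovers the planted gene families", {
  fx <- tiny_native()
  n_planted <- fx$sim$config$n_families * fx$sim$config$genes_per_genome
  expect_gte(length(fx$db$profiles), n_planted)
  # determinism: identical inputs and seed reproduce identical profiles
  db2 <- build_database(fx$sim$genomes, fx$cfg)
  expect_identical(lapply(db2$profiles, `[[`, "pssm"),
                   lapply(fx$db$profiles, `[[`, "pssm"))
})

test_that("reverse-transcribing groups share one database; others may not mix", {
  cfg <- native_config()
  sim <- simulate_reference_set(simulation_config(
    n_families = 2, genomes_per_family = 1, genes_per_genome = 2,
    gene_length_range = c(110L, 130L), seed = 91))
  g <- sim$genomes
  g[[1]]$taxonomy[["baltimore_group"]] <- "VI"
  g[[2]]$taxonomy[["baltimore_group"]] <- "VII"
  db <- build_database(g, cfg)
  expect_identical(db$group, "VI+VII")

  g[[2]]$taxonomy[["baltimore_group"]] <- "II"
  expect_error(build_database(g, cfg), "multiple Baltimore groups")
})

test_that("profile database serialisation round-trips", {
  fx <- tiny_native()
  dir <- withr::local_tempdir()
  write_profile_db(fx$db, dir)
  back <- read_profile_db(dir)
  expect_identical(length(back$profiles), length(fx$db$profiles))
  expect_identical(vapply(back$profiles, `[[`, character(1), "profile_id"),
                   vapply(fx$db$profiles, `[[`, character(1), "profile_id"))
  expect_equal(back$profiles[[1]]$pssm, fx$db$profiles[[1]]$pssm)
  expect_identical(back$group, fx$db$group)
  # scanning with the reloaded database gives identical signatures
  g <- fx$sim$genomes[[1]]
  s <- concatenate_segments(g$segments)
  h1 <- scan_genome(s, fx$db, fx$cfg)
  h2 <- scan_genome(s, back, fx$cfg)
  expect_equal(h1, h2)
})

test_that("database update with new gene families adds profiles", {
  fx <- tiny_native()
  same <- update_database(fx$sim$genomes, list(), fx$cfg)
  expect_equal(length(same$profiles), length(fx$db$profiles))

  novel <- simulate_queries(fx$sim, 2, "unknown", seed = 77, acc_prefix = "N")
  for (a in names(novel$genomes)) {   # annotations needed for db building
    prot <- novel$truth[novel$truth$accession == a, ]
    novel$genomes[[a]]$taxonomy[["baltimore_group"]] <- "I"
  }
  upd <- update_database(fx$sim$genomes, novel$genomes, fx$cfg)
  expect_gte(length(upd$profiles), length(fx$db$profiles) + 1L)

  # original references keep nonzero scores on their own gene profiles
  tab <- annotate(fx$sim$genomes, upd, NULL, fx$cfg)
  expect_true(all(rowSums(tab$scores > 0) >=
                    fx$sim$config$genes_per_genome))
})
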