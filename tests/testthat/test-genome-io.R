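test_that("segment concatenation orders largest to smallest, stably", {
  s300 <- rand_dna(300, 1); s500 <- rand_dna(500, 2); s400 <- rand_dna(400, 3)
  out <- concatenate_segments(c(s300, s500, s400))
  expect_identical(out, paste0(s500, s400, s300))

  expect_identical(concatenate_segments(s300), s300)

  # equal lengths keep input order
  a <- rand_dna(120, 4); b <- rand_dna(120, 5)
  expect_identical(concatenate_segments(c(a, b)), paste0(a, b))
  expect_identical(concatenate_segments(c(b, a)), paste0(b, a))

  # invariant to permutation up to the tie-break
  expect_identical(concatenate_segments(c(s400, s300, s500)),
                   concatenate_segments(c(s300, s500, s400)))

  expect_error(concatenate_segments(character()), "no segments")
})

test_that("six-frame translation follows the standard code", {
  fr <- six_frame_translate("ATGAAA")
  expect_identical(fr[["F1"]], "MK")
  # revcomp of ATG is CAT -> H
  expect_identical(six_frame_translate("ATG")[["R1"]], "H")
  expect_identical(six_frame_translate("TAA")[["F1"]], "*")
  expect_error(six_frame_translate("AT"), "codon")
  # trailing partial codons dropped
  expect_identical(six_frame_translate("ATGAA")[["F1"]], "M")
})

test_that("six frames of the reverse complement swap forward/reverse roles", {
  s <- rand_dna(99, 11)
  a <- six_frame_translate(s)
  b <- six_frame_translate(revcomp(s))
  expect_identical(unname(a[c("F1", "F2", "F3")]),
                   unname(b[c("R1", "R2", "R3")]))
  expect_identical(unname(a[c("R1", "R2", "R3")]),
                   unname(b[c("F1", "F2", "F3")]))
})

test_that("protein prediction keeps first-M-to-stop fragments above min_len", {
  # fragment with no methionine yields nothing
  nt_no_m <- paste(rep("GCT", 150), collapse = "")   # poly-alanine
  expect_equal(nrow(predict_proteins(nt_no_m, min_len = 10)), 0L)

  # M followed by 99 residues then a stop: length 100
  prot <- rand_protein(100, 6)
  nt <- paste0(vapply(strsplit(prot, "")[[1]], function(a) {
    c(A="GCT",C="TGT",D="GAT",E="GAA",F="TTT",G="GGT",H="CAT",I="ATT",
      K="AAA",L="CTT",M="ATG",N="AAT",P="CCT",Q="CAA",R="CGT",S="TCT",
      T="ACT",V="GTT",W="TGG",Y="TAT")[[a]]
  }, character(1)), collapse = "")
  nt <- paste0("TAA", nt, "TAA")
  got100 <- predict_proteins(nt, min_len = 100)
  expect_true(prot %in% got100$sequence)
  got101 <- predict_proteins(nt, min_len = 101)
  expect_false(prot %in% got101$sequence)

  # monotonicity: raising min_len never adds proteins
  g <- rand_dna(2000, 7)
  n_by_len <- vapply(c(10, 30, 60, 100), function(m)
    nrow(predict_proteins(g, m)), integer(1))
  expect_true(all(diff(n_by_len) <= 0))
})

test_that("protein extraction uses annotations when present", {
  ann <- data.frame(id = paste0("p", 1:5),
                    sequence = c(vapply(c(120, 150, 200, 110),
                                        rand_protein, character(1)),
                                 rand_protein(80)),
                    description = "x")
  rec <- genome_record("ACC1", rand_dna(600, 8), annotated_proteins = ann)
  got <- extract_proteins(rec, min_len = 100)
  expect_equal(nrow(got), 4L)
  expect_true(all(got$provenance == "annotated"))

  # annotated records never receive predicted ORFs on top
  expect_false(any(grepl("orf", got$id)))

  # unannotated record delegates to prediction
  rec2 <- genome_record("ACC2", rec$segments)
  got2 <- extract_proteins(rec2, min_len = 100)
  pred <- predict_proteins(concatenate_segments(rec2$segments), 100, "ACC2")
  expect_identical(got2$sequence, pred$sequence)
})

test_that("FASTA + taxonomy round trip preserves genomes and labels", {
  sim <- tiny_sim()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta"); tx <- file.path(dir, "tax.tsv")
  write_genomes_fasta(sim$genomes, fa)
  write_taxonomy(sim$genomes, tx)
  back <- read_genomes_fasta(fa, read_taxonomy(tx))
  expect_setequal(names(back), names(sim$genomes))
  g0 <- sim$genomes[[1]]; g1 <- back[[g0$accession]]
  expect_identical(g1$segments, g0$segments)
  expect_identical(g1$taxonomy[["family"]], g0$taxonomy[["family"]])
})

test_that("GenBank reader extracts sequence and CDS translations", {
  prot <- rand_protein(110, 9)
  seq <- tolower(rand_dna(120, 10))
  gb <- c(
    "LOCUS       TEST0001                 120 bp    DNA     linear   VRL",
    "ACCESSION   TEST0001",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             1..90",
    "                     /product=\"replicase polyprotein\"",
    "                     /protein_id=\"AAA0001.1\"",
    paste0("                     /translation=\"",
           substr(prot, 1, 40), ""),
    paste0("                     ", substr(prot, 41, 110), "\""),
    "ORIGIN",
    paste0("        1 ", paste(substring(seq, seq(1, 120, 10),
                                         seq(10, 120, 10)), collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  recs <- read_genbank(path)
  expect_length(recs, 1L)
  r <- recs[["TEST0001"]]
  expect_identical(r$segments, toupper(seq))
  expect_identical(r$annotated_proteins$sequence, prot)
  expect_identical(r$annotated_proteins$description, "replicase polyprotein")
})
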