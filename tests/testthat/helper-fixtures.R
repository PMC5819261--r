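# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# tiny reference simulation: 3 families x 3 genomes x 2 genes
tiny_sim <- function() {
  memo("tiny_sim", simulate_reference_set(simulation_config(
    n_families = 3, genomes_per_family = 3, genes_per_genome = 2,
    gene_length_range = c(110L, 160L), seed = 42)))
}

# native-engine config (pure R, exercised regardless of external tools)
native_config <- function(seed = 42) {
  pipeline_config(engine = "native", seed = seed)
}

# native database + annotation of the tiny simulation
tiny_native <- function() {
  memo("tiny_native", {
    sim <- tiny_sim()
    cfg <- native_config()
    db <- build_database(sim$genomes, cfg)
    tab <- annotate(sim$genomes, db, NULL, cfg)
    list(sim = sim, cfg = cfg, db = db, tab = tab,
         goms = attr(tab, "goms"))
  })
}

# brute-force distance correlation oracle: direct double centring
dcor_oracle <- function(x, gom) {
  if (is.null(dim(gom))) gom <- matrix(gom, nrow = 1)
  keep <- !(x == 0 & colSums(abs(gom)) == 0)
  x <- x[keep]
  Y <- gom[, keep, drop = FALSE]
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a[i, j] <- abs(x[i] - x[j])
      b[i, j] <- sqrt(sum((Y[, i] - Y[, j])^2))
    }
  }
  dc <- function(m) {
    out <- m
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        out[i, j] <- m[i, j] - mean(m[i, ]) - mean(m[, j]) + mean(m)
      }
    }
    out
  }
  A <- dc(a); B <- dc(b)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  dcov2 <- mean(A * B)
  if (dcov2 <= 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# random protein string
rand_protein <- function(len, seed = NULL) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  f <- function() paste0(c("M", sample(aa, len - 1, TRUE)), collapse = "")
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# random DNA string
rand_dna <- function(len, seed = NULL) {
  f <- function() paste0(sample(c("A","C","G","T"), len, TRUE), collapse = "")
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
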