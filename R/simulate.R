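#' Simulation configuration for family-structured virus genomes
#'
#' The generator emulates the structure the classification method assumes:
#' each virus family has its own gene repertoire (a set of ancestral protein
#' sequences) and a conserved gene order; genomes within a family diverge
#' from the ancestors by independent amino-acid substitutions. Defaults give
#' a dozen well-separated families of eight genomes, six genes per genome of
#' 120-250 aa, with a within-family per-site substitution probability of
#' 0.15 (so two family members differ at roughly a quarter of sites, well
#' inside profile-detection range) and fully disjoint repertoires between
#' families.
#'
#' @param n_families number of families.
#' @param genomes_per_family genomes simulated per family.
#' @param genes_per_genome genes per genome.
#' @param gene_length_range protein length range (aa), inclusive.
#' @param family_divergence per-site substitution probability applied
#'   independently to every genome relative to the family ancestor.
#' @param cross_family_shared_genes number of ancestral genes shared between
#'   consecutive family pairs (0 = fully disjoint repertoires).
#' @param segmented_fraction fraction of genomes split into two segments.
#' @param reverse_strand_fraction per-gene probability of being placed on
#'   the complementary strand.
#' @param spacer_length_range intergenic spacer length range (nt).
#' @param baltimore_group Baltimore group label given to all families, or a
#'   vector recycled across families.
#' @param annotate_proteins include the protein sequences as annotations on
#'   the records (as reference GenBank records would carry).
#' @param seed integer seed.
#'
#' @return a named list with class `"virsig_simconfig"`.
#' @export
simulation_config <- function(n_families = 12L,
                              genomes_per_family = 8L,
                              genes_per_genome = 6L,
                              gene_length_range = c(120L, 250L),
                              family_divergence = 0.15,
                              cross_family_shared_genes = 0L,
                              segmented_fraction = 0,
                              reverse_strand_fraction = 0,
                              spacer_length_range = c(20L, 60L),
                              baltimore_group = "I",
                              annotate_proteins = TRUE,
                              seed = 1L) {
  stopifnot(family_divergence >= 0, family_divergence <= 1,
            segmented_fraction >= 0, segmented_fraction <= 1,
            reverse_strand_fraction >= 0, reverse_strand_fraction <= 1,
            n_families >= 1, genomes_per_family >= 1, genes_per_genome >= 1)
  structure(list(
    n_families = as.integer(n_families),
    genomes_per_family = as.integer(genomes_per_family),
    genes_per_genome = as.integer(genes_per_genome),
    gene_length_range = as.integer(gene_length_range),
    family_divergence = family_divergence,
    cross_family_shared_genes = as.integer(cross_family_shared_genes),
    segmented_fraction = segmented_fraction,
    reverse_strand_fraction = reverse_strand_fraction,
    spacer_length_range = as.integer(spacer_length_range),
    baltimore_group = baltimore_group,
    annotate_proteins = isTRUE(annotate_proteins),
    seed = as.integer(seed)
  ), class = "virsig_simconfig")
}

# codons per amino acid under the standard code (stops excluded)
.syn_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# cycled over gene slots so profile annotations exercise gene categorisation
.GENE_NAMES <- c("RNA-dependent RNA polymerase",
                 "capsid protein",
                 "envelope glycoprotein",
                 "NS3 helicase",
                 "nucleocapsid protein",
                 "matrix protein",
                 "replicase-associated protein",
                 "coat protein")

.random_protein <- function(len) {
  paste0(c("M", sample(.AA20, len - 1L, replace = TRUE)), collapse = "")
}

.mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  aa <- strsplit(seq, "")[[1]]
  # keep the initial methionine so the ORF rule always finds the gene start
  idx <- which(stats::runif(length(aa)) < rate)
  idx <- idx[idx > 1L]
  if (length(idx)) {
    aa[idx] <- vapply(aa[idx], function(a)
      sample(setdiff(.AA20, a), 1L), character(1))
  }
  paste0(aa, collapse = "")
}

.back_translate <- function(prot) {
  aa <- strsplit(prot, "")[[1]]
  paste0(vapply(aa, function(a) {
    cods <- .syn_codons[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

.random_dna <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Draw a family's ancestral gene repertoire: a list of protein sequences
# plus the global identifiers of the gene families they found.
.draw_ancestors <- function(fam_label, n_genes, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n_genes, replace = TRUE)
  genes <- lapply(lens, .random_protein)
  names(genes) <- paste0(fam_label, "_g", seq_len(n_genes))
  genes
}

# Realise one genome from a repertoire; returns the record + truth rows.
.realise_genome <- function(acc, tax, ancestors, gene_ids, config) {
  n_genes <- length(ancestors)
  prots <- vapply(ancestors, .mutate_protein,
                  character(1), rate = config$family_divergence)
  strands <- ifelse(stats::runif(n_genes) < config$reverse_strand_fraction,
                    -1L, 1L)
  sp <- function() .random_dna(sample(seq(config$spacer_length_range[1],
                                          config$spacer_length_range[2]), 1L))
  seq <- sp()
  starts <- integer(n_genes); ends <- integer(n_genes)
  for (j in seq_len(n_genes)) {
    nt <- .back_translate(prots[[j]])
    if (strands[j] < 0L) nt <- .revcomp_chr(nt)
    starts[j] <- nchar(seq) + 1L
    seq <- paste0(seq, nt)
    ends[j] <- nchar(seq)
    seq <- paste0(seq, sp())
  }
  segments <- seq
  if (stats::runif(1) < config$segmented_fraction && n_genes >= 2L) {
    cut <- ends[ceiling(n_genes / 2)] + 1L   # split inside a spacer
    segments <- c(substring(seq, 1L, cut), substring(seq, cut + 1L))
  }
  ann <- NULL
  if (config$annotate_proteins) {
    ann <- data.frame(
      id = paste0("p", seq_len(n_genes)),
      sequence = unname(prots),
      description = .GENE_NAMES[(seq_len(n_genes) - 1L) %%
                                  length(.GENE_NAMES) + 1L],
      stringsAsFactors = FALSE)
  }
  rec <- genome_record(acc, segments, taxonomy = tax,
                       annotated_proteins = ann)
  truth <- data.frame(accession = acc, gene_family = gene_ids,
                      start = starts, end = ends, strand = strands,
                      stringsAsFactors = FALSE)
  list(record = rec, truth = truth)
}

#' Simulate a family-structured reference genome set
#'
#' Draws ancestral gene repertoires per family, realises genomes by mutating
#' each gene at the configured divergence, back-translates with uniformly
#' random synonymous codons, and assembles genomes with random intergenic
#' spacers (optionally segmented, optionally with reverse-strand genes).
#' Consecutive family pairs can share a configurable number of ancestral
#' genes to emulate cross-family homology.
#'
#' @param config a [simulation_config()].
#' @return list with class `"virsig_simulation"`: `genomes` (named list of
#'   [genome_record()]), `truth` (per-gene data.frame: accession,
#'   gene_family, start, end, strand), `ancestors` (per-family list of
#'   ancestral proteins, kept so that query genomes can be drawn from the
#'   same repertoires), and `config`.
#' @export
simulate_reference_set <- function(config = simulation_config()) {
  stopifnot(inherits(config, "virsig_simconfig"))
  withr::with_seed(config$seed, .simulate_set(config))
}

.simulate_set <- function(config, fam_prefix = "fam", acc_prefix = "V") {
  fams <- sprintf("%s%02d", fam_prefix, seq_len(config$n_families))
  groups <- rep(config$baltimore_group, length.out = config$n_families)
  ancestors <- list()
  for (i in seq_along(fams)) {
    anc <- .draw_ancestors(fams[i], config$genes_per_genome,
                           config$gene_length_range)
    k <- config$cross_family_shared_genes
    if (k > 0L && i %% 2L == 0L) {
      # even-numbered family shares its first k genes with its predecessor
      prev <- ancestors[[fams[i - 1L]]]
      k2 <- min(k, length(prev), length(anc))
      anc[seq_len(k2)] <- prev[seq_len(k2)]
      names(anc)[seq_len(k2)] <- names(prev)[seq_len(k2)]
    }
    ancestors[[fams[i]]] <- anc
  }
  genomes <- list(); truth <- list()
  idx <- 0L
  for (i in seq_along(fams)) {
    for (g in seq_len(config$genomes_per_family)) {
      idx <- idx + 1L
      acc <- sprintf("%s%04d", acc_prefix, idx)
      tax <- c(baltimore_group = groups[i], order = "simorder",
               family = fams[i], genus = paste0(fams[i], "_gen"),
               species = paste0(fams[i], "_sp", g))
      res <- .realise_genome(acc, tax, ancestors[[fams[i]]],
                             names(ancestors[[fams[i]]]), config)
      genomes[[acc]] <- res$record
      truth[[acc]] <- res$truth
    }
  }
  structure(list(genomes = genomes,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 ancestors = ancestors,
                 config = config),
            class = "virsig_simulation")
}

#' Simulate query genomes
#'
#' Known queries are fresh draws from families already present in the
#' reference simulation (their family is represented in the reference set);
#' unknown queries come from freshly drawn families with repertoires
#' disjoint from every reference family. Mixed mode draws half and half
#' (unknowns rounded up).
#'
#' @param sim a `"virsig_simulation"` from [simulate_reference_set()].
#' @param n number of query genomes.
#' @param mode `"known"`, `"unknown"` or `"mixed"`.
#' @param seed integer seed (independent of the reference seed).
#' @param acc_prefix accession prefix (keep distinct across query sets
#'   analysed together).
#' @return list with `genomes`, `truth`, and `ancestors` of any new
#'   families.
#' @export
simulate_queries <- function(sim, n, mode = c("known", "unknown", "mixed"),
                             seed = 2L, acc_prefix = "Q") {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "virsig_simulation"), n >= 1)
  config <- sim$config
  withr::with_seed(seed, {
    n_unknown <- switch(mode, known = 0L, unknown = as.integer(n),
                        mixed = as.integer(ceiling(n / 2)))
    n_known <- as.integer(n) - n_unknown
    genomes <- list(); truth <- list(); new_anc <- list()
    if (n_unknown > 0L) {
      n_newfam <- max(1L, ceiling(n_unknown / config$genomes_per_family))
      ufams <- sprintf("unkfam%02d", seq_len(n_newfam))
      for (f in ufams) {
        new_anc[[f]] <- .draw_ancestors(f, config$genes_per_genome,
                                        config$gene_length_range)
      }
    }
    for (q in seq_len(n)) {
      acc <- sprintf("%s%04d", acc_prefix, q)
      if (q <= n_known) {
        fam <- sample(names(sim$ancestors), 1L)
        anc <- sim$ancestors[[fam]]
      } else {
        fam <- names(new_anc)[(q - n_known - 1L) %% length(new_anc) + 1L]
        anc <- new_anc[[fam]]
      }
      tax <- c(baltimore_group = config$baltimore_group[1],
               order = "", family = fam, genus = "", species = "")
      res <- .realise_genome(acc, tax, anc, names(anc), config)
      # queries are unannotated, as metagenomic contigs would be
      res$record$annotated_proteins <- NULL
      genomes[[acc]] <- res$record
      truth[[acc]] <- res$truth
    }
    list(genomes = genomes,
         truth = do.call(rbind, c(truth, make.row.names = FALSE)),
         ancestors = new_anc)
  })
}

#' Simulate a signature table directly
#'
#' Bypasses the sequence level: emits a signature table whose profile-score
#' matrix is block diagonal (each family has its own block of profiles with
#' positive scores plus optional Gaussian noise everywhere) and whose gene
#' locations follow a family-conserved order. GOMs and GOM signatures are
#' computed from the emitted locations exactly as the annotation stage
#' would. Used for fast tests of the similarity, dendrogram and classifier
#' stages.
#'
#' @param n_families,genomes_per_family,profiles_per_family table shape.
#' @param score_mean mean score of a present profile.
#' @param score_sd within-block score spread.
#' @param noise_sd sd of nonnegative background noise added to the whole
#'   score matrix (0 = clean block structure).
#' @param location_jitter sd (nt) of jitter on gene midpoint locations.
#' @param seed integer seed.
#' @return a `"signature_table"` (see [annotate()]).
#' @export
simulate_signature_table <- function(n_families = 4L,
                                     genomes_per_family = 5L,
                                     profiles_per_family = 3L,
                                     score_mean = 120,
                                     score_sd = 15,
                                     noise_sd = 0,
                                     location_jitter = 0,
                                     seed = 1L) {
  withr::with_seed(seed, {
    nfam <- as.integer(n_families)
    npg <- as.integer(genomes_per_family)
    ppf <- as.integer(profiles_per_family)
    n <- nfam * npg
    p <- nfam * ppf
    fams <- sprintf("fam%02d", rep(seq_len(nfam), each = npg))
    accs <- sprintf("S%04d", seq_len(n))
    profile_ids <- sprintf("profile_%03d", seq_len(p))
    scores <- matrix(0, n, p, dimnames = list(accs, profile_ids))
    locs <- matrix(0, n, p, dimnames = list(accs, profile_ids))
    for (i in seq_len(n)) {
      f <- (i - 1L) %/% npg
      cols <- f * ppf + seq_len(ppf)
      scores[i, cols] <- pmax(1, stats::rnorm(ppf, score_mean, score_sd))
      locs[i, cols] <- pmax(1, 500 * seq_len(ppf) +
                              round(stats::rnorm(ppf, 0, location_jitter)))
    }
    if (noise_sd > 0) {
      scores <- scores + matrix(abs(stats::rnorm(n * p, 0, noise_sd)), n, p)
    }
    tax <- data.frame(accession = accs, baltimore_group = "I",
                      order = "simorder", family = fams,
                      genus = paste0(fams, "_gen"),
                      species = paste0(fams, "_sp"),
                      stringsAsFactors = FALSE)
    goms <- build_gom_set(locs, fams)
    gs <- gom_signature_matrix(locs, goms)
    signature_table(accs, tax, scores, locs, gs,
                    meta = list(source = "simulate_signature_table",
                                seed = seed))
  })
}
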