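#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one object. Defaults
#' are the operating constants of the method: proteins shorter than 100 aa
#' are discarded; protein-protein hits are kept only when E-value <= 0.001,
#' percent identity >= 30 and both query and subject coverage >= 75%;
#' profile hits are kept when the conditional E-value <= 0.001 and the score
#' is positive; dendrograms are bootstrapped 100 times; cross-validation is
#' threefold; mutual information is averaged over 100 subsampled estimates;
#' threshold fitting subsamples at most 10,000 similarity scores per class.
#'
#' @param protein_min_len minimum protein length retained (amino acids).
#' @param blast_evalue_max,blast_identity_min,blast_coverage_min hit filter:
#'   maximum E-value, minimum percent identity (0-100), minimum query and
#'   subject coverage (0-100).
#' @param cevalue_max maximum conditional E-value for a profile hit.
#' @param mcl_inflation MCL inflation parameter (> 1).
#' @param gap_open,gap_extend gap costs handed to the cluster aligner
#'   (positive penalties).
#' @param bootstrap_reps number of bootstrap replicates.
#' @param cv_folds number of cross-validation repetitions.
#' @param mi_reps,mi_max_per_group mutual-information repeats and per-group
#'   subsample cap.
#' @param svm_sample_cap per-class cap on similarity scores used when
#'   fitting a group threshold.
#' @param engine `"auto"` (use external tools when on `PATH`), `"external"`
#'   (require them) or `"native"` (pure-R fallbacks).
#' @param seed integer seed consumed by every stochastic step.
#' @param rank taxonomic rank used for classification (`"family"`).
#'
#' @return a named list with class `"virsig_config"`.
#' @export
pipeline_config <- function(protein_min_len = 100L,
                            blast_evalue_max = 1e-3,
                            blast_identity_min = 30,
                            blast_coverage_min = 75,
                            cevalue_max = 1e-3,
                            mcl_inflation = 2.0,
                            gap_open = 3.0,
                            gap_extend = 0.0,
                            bootstrap_reps = 100L,
                            cv_folds = 3L,
                            mi_reps = 100L,
                            mi_max_per_group = 2L,
                            svm_sample_cap = 10000L,
                            engine = c("auto", "external", "native"),
                            seed = 1L,
                            rank = "family") {
  engine <- match.arg(engine)
  stopifnot(protein_min_len >= 1, mcl_inflation > 1,
            blast_coverage_min >= 0, blast_coverage_min <= 100,
            bootstrap_reps >= 1, cv_folds >= 1)
  structure(list(
    protein_min_len = as.integer(protein_min_len),
    blast_evalue_max = blast_evalue_max,
    blast_identity_min = blast_identity_min,
    blast_coverage_min = blast_coverage_min,
    cevalue_max = cevalue_max,
    mcl_inflation = mcl_inflation,
    gap_open = gap_open,
    gap_extend = gap_extend,
    bootstrap_reps = as.integer(bootstrap_reps),
    cv_folds = as.integer(cv_folds),
    mi_reps = as.integer(mi_reps),
    mi_max_per_group = as.integer(mi_max_per_group),
    svm_sample_cap = as.integer(svm_sample_cap),
    engine = engine,
    seed = as.integer(seed),
    rank = rank
  ), class = "virsig_config")
}

# Resolve which engine actually runs a given stage. `tool` is the binary
# that the external adapter needs; "auto" degrades to native when absent.
resolve_engine <- function(config, tool) {
  eng <- if (is.null(config$engine)) "auto" else config$engine
  if (eng == "native") return("native")
  ok <- all(nzchar(Sys.which(tool)))
  if (ok) return("external")
  if (eng == "external") {
    stop("external engine requested but tool(s) not found: ",
         paste(tool, collapse = ", "))
  }
  "native"
}

#' @export
print.virsig_config <- function(x, ...) {
  cat("virsig pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
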