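---
title: "Classifying virus genomes by profile and organisation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying virus genomes by profile and organisation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virsig)
```

## The model

`virsig` treats a virus genome as a bag of protein families plus an
arrangement of those families along the genome. Both aspects are captured
without any multiple alignment of whole genomes:

1. **Protein profiles.** Proteins extracted from the reference genomes
   (annotated proteins where the record has them; otherwise ORFs from a
   six-frame translation, split at every stop codon and trimmed to the
   first methionine, minimum 100 aa) are compared all-vs-all. Hits are kept
   only when E ≤ 0.001, identity ≥ 30% and coverage ≥ 75% on both sides —
   deliberately conservative filters that favour specificity of homology
   detection over sensitivity. Best-hit bit scores feed Markov clustering
   (inflation 2, the cited tool's default); each cluster is aligned and
   becomes a scoring profile. One database is built per Baltimore group,
   with the two reverse-transcribing groups pooled.

2. **Signatures.** A genome (segments concatenated largest-first) is
   six-frame translated, concatenated with neutral separators, and scanned
   against the database. Hits with conditional E-value > 0.001 or
   non-positive score are discarded. The per-profile score vector is the
   *profile signature*; the signed nucleotide midpoint of each profile's
   best hit is the *gene-location vector*. Stacking the location vectors of
   a family's members gives its *genome-organisation model* (GOM); the
   vector of Székely distance correlations between a genome's locations and
   each family GOM is its *GOM signature*. Locations absent from both the
   query and the GOM are excluded from the correlation, and a constant
   (zero-variance) series is assigned correlation 0.

3. **Similarity.** Two genomes are compared by the composite generalised
   Jaccard index, the geometric mean of `Σ min / Σ max` over the two
   signature types; distance is `D = 1 − J`. Two genomes with empty
   signatures are defined to be maximally distant (`J = 0`), not identical.

The classification stage is a thresholded 1-nearest neighbour: the
candidate family is the most CGJ-similar reference; the candidate must (a)
reach the family's similarity threshold and (b) sit next to that family in
a joint UPGMA dendrogram of all references and all queries — via its sister
clade, its immediate outgroup, or one of the two basal subtrees of the
sister clade being composed entirely of candidate-family references.
Queries run through all Baltimore-group sub-pipelines; the accepted
assignment with the highest CGJ wins, and queries accepted nowhere are
"unclassified".

## Assumptions

The method assumes family membership is reflected in shared protein
repertoires and (secondarily) conserved gene order; it needs (near-)
complete genomes, since partial genomes lose repertoire signal — hence the
per-family length filter for metagenomic input, set at the smallest
reference genome of the provisional family. It assumes the reference
taxonomy itself is broadly genomically coherent; families defined purely by
morphology will not be recovered.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `protein_min_len` | 100 | aa | suppresses spurious short ORFs in unannotated sequence at a small (~5–10%) cost in true genes |
| hit filter | E ≤ 1e−3, id ≥ 30%, cov ≥ 75% | — | conservative homology detection; lower thresholds risk false homologies that distort whole-genome relatedness |
| `cevalue_max` | 1e−3 | — | per-domain significance of profile hits |
| `mcl_inflation` | 2.0 | — | cluster granularity; the clustering tool's default |
| `bootstrap_reps` | 100 | — | clade-support resolution of ~1% |
| `svm_sample_cap` | 10,000 | scores/class | bounds threshold-fitting cost for large families |
| `mi_reps`, `mi_max_per_group` | 100, 2 | — | equalises group sizes in MI estimation; means over 100 repeats tame estimator noise |
| `gap_open`, `gap_extend` | 3.0, 0.0 | score | cluster-alignment gap costs |

## Engines and numerical choices

External engines (BLASTp, MAFFT, HMMER's `hmmbuild`/`hmmscan` with the
bias filter disabled) are used when on `PATH`; each stage has a native R
fallback so the pipeline runs anywhere:

* *Native search*: Smith–Waterman under BLOSUM62 (open 11/extend 1) behind
  a shared-4-mer prefilter; bit scores by Karlin–Altschul scaling
  (λ = 0.267, K = 0.041), E = m·n·2^(−bits) without the finite-length
  correction.
* *Native aligner*: progressive profile–profile alignment over a k-mer
  UPGMA guide tree. With free gap extension the two affine gap states
  collapse into running maxima, which keeps the dynamic programme
  row-vectorised.
* *Native profiles*: match columns are those with ≤ 50% gaps; Laplace
  pseudocount 1; log-odds in bits against the pooled residue composition of
  the database's own proteins. Scoring the training composition rather than
  a fixed background keeps scores centred for queries of like composition —
  with a fixed background, composition drift alone can push long unrelated
  matches past any E-value cut. Scan significance comes from a Gumbel null
  fitted by moments on 200 seeded random background sequences, location-
  shifted by β·log(N/500) for query length N. This is a documented
  approximation to a full profile-HMM E-value, not a replacement for it.
* *Distance correlation* uses the biased V-statistic form (double-centred
  distance matrices, `dCov² = mean(A∘B)`); negative rounding of `dCov²` and
  zero variances return 0.
* *UPGMA* merges by size-weighted average linkage at height d/2; ties —
  common at D = 1 between repertoire-disjoint families — are broken by the
  lexicographically smallest pair of cluster representatives, making trees
  deterministic.
* *Thresholds*: in one dimension, a linear maximum-margin separator with
  class-balanced weights reduces to a closed form — the cut minimising
  balanced misclassification, placed at the midpoint of the widest
  separating gap — which is computed exactly instead of iteratively.
* *Mutual information*: kNN estimator (k = 3) for continuous scores,
  plug-in for ≤ 8 unique values; natural-log units (recorded in the
  output's `estimator` attribute).

Bootstrap replicates resample profile columns of the signature table and
of every GOM rather than re-scanning genomes: per-profile scores and
locations do not depend on other profiles, so column resampling is exactly
the re-annotation the resampled database would produce, at a small fraction
of the cost. Resampling perturbs profile columns only; GOM membership rows
are kept fixed.

## Design choices on open points

* **Location convention.** Positive locations are codon midpoints on the
  input strand; negative locations are minus the midpoint *on the
  complementary strand* (not mapped back to input coordinates). This is the
  only convention under which reverse-complementing a genome maps every
  location to its exact negative, making annotation — and therefore CGJ —
  strand-invariant even for mixed-strand genomes.
* **Topological vacuity.** "Composed entirely of members of the candidate
  group" is evaluated over reference leaves only, so co-analysed queries
  cannot block each other. A clade containing no reference leaf at all
  (only other queries) counts as compatible with the candidate: when
  several test viruses of one family are analysed jointly they tend to
  attach to each other before joining their family's references — their
  profile scores are systematically a little lower than the references'
  own, which makes them mutually closest — and requiring a reference in
  the sister clade would reject exactly the clearest assignments.
  Similarity support is the threshold check's job, which runs first.
* **Single-member families** have no intra-family similarity distribution;
  their threshold is the largest inter-family similarity involving the
  member — conservative in that anything less similar than the closest
  foreign virus is rejected.
* **Equal-length segments** concatenate in input order (stable sort);
  **circular genomes** are used as provided in linear form.
* **Threshold boundary**: similarity exactly at the threshold passes, and a
  metagenomic query exactly at its family's minimum length is retained.
* The distance correlation pairs observations **by profile index** (query
  location against the GOM column), the only pairing defined for a single
  query against a family matrix.

## What the synthetic data does and does not show

The generator draws per-family ancestral gene repertoires (random proteins,
120–250 aa), realises genomes by independent per-site substitutions at the
configured divergence (default 0.15 against the ancestor), back-translates
with uniform synonymous codons, and assembles genomes with random spacers —
optionally segmented, with reverse-strand genes, or with gene sharing
between designated family pairs. It emulates exactly the structure the
classifier assumes: family-specific repertoires with conserved gene order.
It does **not** emulate indels, rate heterogeneity, base composition bias,
mosaicism/recombination, or overlapping genes; passing tests therefore
demonstrate the machinery's correctness and its behaviour under the
assumed structure, not performance on real taxonomies. Test problem sizes
(chosen to keep a laptop-scale run comfortable) are 18 families × 9
genomes × 6 genes for the cross-validation and dendrogram checks, and
3 × 3 × 2 for the sequence-level unit fixtures.

## Known limitations

* The native profile scorer is gapless and reports a single best hit per
  profile; the per-profile "overall score" is that hit's score. Fine for
  compact virus genes, weaker for profiles with long indel-rich members.
* Native search E-values omit BLAST's length corrections; edge hits on
  very short proteins are slightly mis-calibrated.
* GenBank parsing covers LOCUS/ACCESSION/CDS `/translation` + ORIGIN;
  joined/spliced CDS are taken as the record's stated translation.
* No genus- or species-level criteria, and candidate novel groups are
  reported only as unassigned clades — naming them is out of scope.
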