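#' @import methods
NULL

#' ClonalArchitecture: a tumor's clonal composition model
#'
#' Represents the clonal model inferred from bulk variant-allele-fraction
#' (VAF) clustering: a set of clones related by parentage, each introducing
#' one new mutation cluster and occupying a fraction of the cell population,
#' plus a non-tumor (wild-type) fraction. Clone frequencies and the
#' non-tumor fraction must sum to one, and parentage must form a tree with
#' a single founding clone.
#'
#' @slot subject character(1), subject identifier.
#' @slot clones data.frame with columns \code{id}, \code{parent}
#'   (\code{NA} for the founding clone), \code{frequency} and
#'   \code{cluster} (the mutation cluster introduced by that clone).
#' @slot nonTumorFraction numeric(1) in [0, 1].
#'
#' @seealso [buildArchitecture()], [expectedBulkVAF()], [samlArchitectures()]
#' @export
setClass("ClonalArchitecture",
  representation(
    subject = "character",
    clones = "data.frame",
    nonTumorFraction = "numeric"
  )
)

setValidity("ClonalArchitecture", function(object) {
  cl <- object@clones
  msgs <- character()
  need <- c("id", "parent", "frequency", "cluster")
  if (!all(need %in% names(cl))) {
    return(sprintf("clones must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cl$id)) msgs <- c(msgs, "clone ids must be unique")
  if (length(object@nonTumorFraction) != 1L ||
      object@nonTumorFraction < 0 || object@nonTumorFraction > 1) {
    msgs <- c(msgs, "nonTumorFraction must be a single value in [0, 1]")
  }
  if (any(cl$frequency <= 0)) msgs <- c(msgs, "clone frequencies must be > 0")
  tot <- sum(cl$frequency) + object@nonTumorFraction
  if (abs(tot - 1) > 1e-9) {
    msgs <- c(msgs, sprintf(
      "clone frequencies plus nonTumorFraction must sum to 1 (got %.6f)", tot))
  }
  if (sum(is.na(cl$parent)) != 1L) {
    msgs <- c(msgs, "exactly one clone must have no parent (the founding clone)")
  }
  known <- !is.na(cl$parent) & !(cl$parent %in% cl$id)
  if (any(known)) {
    msgs <- c(msgs, sprintf("unknown parent id(s): %s",
                            paste(unique(cl$parent[known]), collapse = ", ")))
  }
  if (length(msgs) == 0L && nrow(cl) > 0L) {
    # walk each clone to the root; a cycle never reaches a parentless clone
    for (i in seq_len(nrow(cl))) {
      seen <- character()
      cur <- cl$id[i]
      while (!is.na(cur)) {
        if (cur %in% seen) return("clone parentage contains a cycle")
        seen <- c(seen, cur)
        cur <- cl$parent[match(cur, cl$id)]
      }
    }
    if (anyDuplicated(cl$cluster)) {
      msgs <- c(msgs, "each clone must introduce a distinct cluster")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LocusCatalog: the targeted loci assayed per subject
#'
#' The set of loci captured for targeted single-cell genotyping: validated
#' somatic SNVs labelled with their bulk VAF cluster, plus germline SNPs
#' (heterozygous or homozygous) used for benchmarking variant calling.
#'
#' @slot loci data.frame with columns \code{locus_id}, \code{subject},
#'   \code{kind} (one of \code{somatic_cluster}, \code{germline_het},
#'   \code{germline_homref}, \code{germline_homvar}) and \code{cluster}
#'   (\code{NA} for germline loci).
#'
#' @seealso [makeLocusCatalog()], [samlLocusCatalog()]
#' @export
setClass("LocusCatalog", representation(loci = "data.frame"))

.locusKinds <- c("somatic_cluster", "germline_het", "germline_homref",
                 "germline_homvar")

setValidity("LocusCatalog", function(object) {
  lo <- object@loci
  need <- c("locus_id", "subject", "kind", "cluster")
  if (!all(need %in% names(lo))) {
    return(sprintf("loci must have columns %s", paste(need, collapse = ", ")))
  }
  msgs <- character()
  if (anyDuplicated(lo$locus_id)) msgs <- c(msgs, "locus_ids must be unique")
  if (!all(lo$kind %in% .locusKinds)) {
    msgs <- c(msgs, sprintf("kind must be one of %s",
                            paste(.locusKinds, collapse = ", ")))
  }
  som <- lo$kind == "somatic_cluster"
  if (any(som & is.na(lo$cluster))) {
    msgs <- c(msgs, "somatic loci must carry a cluster label")
  }
  if (any(!som & !is.na(lo$cluster))) {
    msgs <- c(msgs, "germline loci must not carry a cluster label")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReadCountTable: reference/variant read counts per sample and locus
#'
#' The unit consumed by genotype calling and the cellularity likelihood:
#' one row per (sample, locus) with the number of reads supporting the
#' reference and the variant allele. Depth is \code{ref_reads + var_reads}.
#'
#' @slot counts data.frame with columns \code{sample_id}, \code{locus_id},
#'   \code{ref_reads}, \code{var_reads} (non-negative integers).
#'
#' @seealso [readCountsTSV()], [simulateCells()], [callMatrix()]
#' @export
setClass("ReadCountTable", representation(counts = "data.frame"))

setValidity("ReadCountTable", function(object) {
  ct <- object@counts
  need <- c("sample_id", "locus_id", "ref_reads", "var_reads")
  if (!all(need %in% names(ct))) {
    return(sprintf("counts must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(ct) && (any(ct$ref_reads < 0) || any(ct$var_reads < 0))) {
    return("read counts must be non-negative")
  }
  if (nrow(ct) && anyDuplicated(ct[c("sample_id", "locus_id")])) {
    return("duplicate (sample_id, locus_id) entries")
  }
  TRUE
})

#' GenotypeMatrix: genotype calls for cells at targeted loci
#'
#' Integer-coded calls with rows as cells (samples) and columns as loci:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous variant,
#' \code{NA} = no call (depth below the callable threshold).
#'
#' @slot calls integer matrix, cells x loci, with dimnames.
#' @slot callableThreshold numeric(1), the minimum depth for a call
#'   (default 25).
#'
#' @seealso [callMatrix()], [genotypeCalls()], [callableFraction()]
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", callableThreshold = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@calls
  if (!is.numeric(m) && !is.integer(m)) return("calls must be numeric")
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    return("calls must be 0 (hom-ref), 1 (het), 2 (hom-var) or NA (no call)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    return("calls must have cell rownames and locus colnames")
  }
  if (object@callableThreshold < 0) return("callableThreshold must be >= 0")
  TRUE
})

#' BenchmarkReport: variant-calling accuracy at loci of known genotype
#'
#' Confusion-matrix accounting of calls against truth using allele-level
#' definitions: a call is positive when at least one non-reference allele
#' is called. Sensitivity (TPR) is undefined at homozygous-reference truth
#' (no true positives exist there) and specificity at heterozygous truth;
#' the per-zygosity strata report \code{NA} accordingly.
#'
#' @slot overall data.frame with one row: TP, TN, FP, FN, TPR, FPR, FNR.
#' @slot byZygosity data.frame with one row per truth zygosity stratum.
#'
#' @seealso [benchmarkCalls()]
#' @export
setClass("BenchmarkReport",
  representation(overall = "data.frame", byZygosity = "data.frame"))

#' CellularityResult: pure-vs-mixed classification of one sorted sample
#'
#' Result of the binomial maximum-likelihood cellularity analysis: the
#' best-scoring single-clone (pure) explanation, the best two-distinct-clone
#' (mixed) explanation, the likelihood-ratio statistic, its one-sided
#' chi-square(1) p-value, and the resulting classification.
#'
#' @slot sample character(1) sample id.
#' @slot pureClone character(1), clone of the best pure hypothesis.
#' @slot pureLogLik numeric(1).
#' @slot mixedPair character(2), clones of the best mixed hypothesis.
#' @slot mixedLogLik numeric(1).
#' @slot lrt numeric(1), 2 * (mixed - pure) log-likelihood, floored at 0.
#' @slot pValue numeric(1).
#' @slot classification character(1): "pure", "mixed" or "indeterminate".
#' @slot nLoci integer(1), number of covered somatic loci used.
#'
#' @seealso [classifySample()]
#' @export
setClass("CellularityResult",
  representation(
    sample = "character", pureClone = "character", pureLogLik = "numeric",
    mixedPair = "character", mixedLogLik = "numeric",
    lrt = "numeric", pValue = "numeric", classification = "character",
    nLoci = "integer"
  )
)

setValidity("CellularityResult", function(object) {
  msgs <- character()
  if (object@classification %in% c("pure", "mixed")) {
    if (!is.na(object@lrt) && object@lrt < 0) {
      msgs <- c(msgs, "LRT statistic must be >= 0")
    }
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1)) {
      msgs <- c(msgs, "p-value must lie in [0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DistanceMatrix: pairwise genetic distances between cells
#'
#' Symmetric mismatch-fraction distances over sites callable in both cells
#' of each pair (pairwise deletion), with the number of co-callable sites
#' retained so that poorly supported pairs can be flagged.
#'
#' @slot distances symmetric numeric matrix, zero diagonal.
#' @slot sharedSites integer matrix, co-callable site counts per pair.
#' @slot minShared numeric(1), threshold below which a pair is flagged.
#'
#' @seealso [pairwiseDistance()], [neighborJoining()]
#' @export
setClass("DistanceMatrix",
  representation(distances = "matrix", sharedSites = "matrix",
                 minShared = "numeric"))

setValidity("DistanceMatrix", function(object) {
  d <- object@distances
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (any(abs(diag(d)) > 1e-12)) return("diagonal must be zero")
  if (any(abs(d - t(d)) > 1e-12)) return("distance matrix must be symmetric")
  if (any(d < 0)) return("distances must be non-negative")
  if (!identical(dim(d), dim(object@sharedSites))) {
    return("sharedSites must match the distance matrix dimensions")
  }
  TRUE
})
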