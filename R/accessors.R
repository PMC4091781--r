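#' @describeIn ClonalArchitecture-accessors clone table of an architecture
#' @export
setGeneric("clones", function(x) standardGeneric("clones"))

#' @describeIn ClonalArchitecture-accessors non-tumor (wild-type) fraction
#' @export
setGeneric("nonTumorFraction", function(x) standardGeneric("nonTumorFraction"))

#' @describeIn ClonalArchitecture-accessors subject identifier
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Accessors for ClonalArchitecture objects
#'
#' @param x a [ClonalArchitecture-class] object.
#' @return `clones()` returns the clone data.frame (id, parent, frequency,
#'   cluster); `nonTumorFraction()` and `subjectId()` return scalars.
#' @name ClonalArchitecture-accessors
#' @aliases clones nonTumorFraction subjectId
#' @examples
#' arch <- samlArchitectures()[["UPN182896"]]
#' clones(arch)
#' nonTumorFraction(arch)
NULL

#' @rdname ClonalArchitecture-accessors
#' @export
setMethod("clones", "ClonalArchitecture", function(x) x@clones)

#' @rdname ClonalArchitecture-accessors
#' @export
setMethod("nonTumorFraction", "ClonalArchitecture",
          function(x) x@nonTumorFraction)

#' @rdname ClonalArchitecture-accessors
#' @export
setMethod("subjectId", "ClonalArchitecture", function(x) x@subject)

#' Loci table of a LocusCatalog
#'
#' @param x a [LocusCatalog-class].
#' @return data.frame with columns locus_id, subject, kind, cluster.
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname loci
#' @export
setMethod("loci", "LocusCatalog", function(x) x@loci)

#' Read-count table of a ReadCountTable object
#'
#' @param x a [ReadCountTable-class].
#' @return data.frame with columns sample_id, locus_id, ref_reads, var_reads.
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname readCounts
#' @export
setMethod("readCounts", "ReadCountTable", function(x) x@counts)

#' Call matrix of a GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return integer matrix (cells x loci) with values 0/1/2 and NA for
#'   no-calls.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' Fraction of callable (non-NA) sites per cell
#'
#' @param x a [GenotypeMatrix-class].
#' @return named numeric vector, one entry per cell.
#' @export
setGeneric("callableFraction", function(x) standardGeneric("callableFraction"))

#' @rdname callableFraction
#' @export
setMethod("callableFraction", "GenotypeMatrix", function(x) {
  rowMeans(!is.na(x@calls))
})

setMethod("show", "ClonalArchitecture", function(object) {
  cl <- object@clones
  cat("ClonalArchitecture for subject", object@subject, "\n")
  cat(sprintf("  %d clones + %.0f%% non-tumor\n", nrow(cl),
              100 * object@nonTumorFraction))
  for (i in seq_len(nrow(cl))) {
    cat(sprintf("  %s (cluster %s, %.0f%%)%s\n", cl$id[i],
                as.character(cl$cluster[i]), 100 * cl$frequency[i],
                if (is.na(cl$parent[i])) " [founding]"
                else paste0(" <- ", cl$parent[i])))
  }
})

setMethod("show", "LocusCatalog", function(object) {
  lo <- object@loci
  cat("LocusCatalog:", nrow(lo), "loci,",
      length(unique(lo$subject)), "subject(s)\n")
  print(table(subject = lo$subject, kind = lo$kind))
})

setMethod("show", "ReadCountTable", function(object) {
  ct <- object@counts
  cat("ReadCountTable:", nrow(ct), "entries,",
      length(unique(ct$sample_id)), "sample(s),",
      length(unique(ct$locus_id)), "locus/loci\n")
  if (nrow(ct)) {
    print(utils::head(ct, 4L))
    if (nrow(ct) > 4L) cat("  ...\n")
  }
})

setMethod("show", "GenotypeMatrix", function(object) {
  m <- object@calls
  cat(sprintf(
    "GenotypeMatrix: %d cells x %d loci (callable threshold %gx)\n",
    nrow(m), ncol(m), object@callableThreshold))
  cat(sprintf("  callable fraction: mean %.2f (range %.2f-%.2f)\n",
              mean(!is.na(m)), min(rowMeans(!is.na(m))),
              max(rowMeans(!is.na(m)))))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat("BenchmarkReport (allele-level accounting at callable sites)\n")
  print(object@overall, row.names = FALSE)
  cat("by truth zygosity:\n")
  print(object@byZygosity, row.names = FALSE)
})

setMethod("show", "CellularityResult", function(object) {
  cat(sprintf("CellularityResult for sample %s: %s\n", object@sample,
              object@classification))
  cat(sprintf("  best pure: %s (logLik %.2f)\n", object@pureClone,
              object@pureLogLik))
  cat(sprintf("  best mixed: %s + %s (logLik %.2f)\n", object@mixedPair[1L],
              object@mixedPair[2L], object@mixedLogLik))
  cat(sprintf("  LRT %.3f, p = %.3g over %d loci\n", object@lrt,
              object@pValue, object@nLoci))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d cells (min shared sites %g)\n",
              nrow(object@distances), object@minShared))
  low <- sum(object@sharedSites[upper.tri(object@sharedSites)] <
               object@minShared)
  if (low) cat(" ", low, "pair(s) below the shared-site threshold\n")
})

#' Distance and shared-site accessors for DistanceMatrix
#'
#' @param x a [DistanceMatrix-class].
#' @return `distances()` returns the symmetric numeric distance matrix;
#'   `sharedSites()` the per-pair co-callable site counts.
#' @name DistanceMatrix-accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname DistanceMatrix-accessors
#' @export
setMethod("distances", "DistanceMatrix", function(x) x@distances)

#' @rdname DistanceMatrix-accessors
#' @export
setGeneric("sharedSites", function(x) standardGeneric("sharedSites"))

#' @rdname DistanceMatrix-accessors
#' @export
setMethod("sharedSites", "DistanceMatrix", function(x) x@sharedSites)
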