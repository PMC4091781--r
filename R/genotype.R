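# Binomial likelihood genotyping with a coverage gate, and accuracy
# accounting against known genotypes.

#' Call the genotype at one site
#'
#' Maximum-likelihood call among homozygous reference (variant-read
#' probability \code{seqError}), heterozygous (0.5) and homozygous variant
#' (\code{1 - seqError}) under a binomial read model. Sites below
#' \code{minDepth} coverage are not called; a non-reference call
#' additionally requires at least \code{minVarReads} variant reads, which
#' keeps the false-positive budget small at high depth. Likelihood ties
#' break toward the reference (non-reference calls should be conservative).
#'
#' @param refReads,varReads non-negative read counts.
#' @param minDepth callable-site coverage gate (default 25).
#' @param seqError per-read miscall probability (default 0.01).
#' @param minVarReads variant-read floor for a non-reference call
#'   (default 3).
#' @return integer: 0 (hom-ref), 1 (het), 2 (hom-var) or \code{NA}
#'   (no call).
#' @examples
#' callSite(50, 0)    # hom-ref
#' callSite(15, 5)    # NA: depth 20 below the 25x gate
#' callSite(30, 28)   # het
#' @export
callSite <- function(refReads, varReads, minDepth = 25, seqError = 0.01,
                     minVarReads = 3) {
  stopifnot(refReads >= 0, varReads >= 0)
  n <- refReads + varReads
  if (n < minDepth) return(NA_integer_)
  if (varReads < minVarReads) return(0L)
  ll <- c(stats::dbinom(varReads, n, seqError, log = TRUE),
          stats::dbinom(varReads, n, 0.5, log = TRUE),
          stats::dbinom(varReads, n, 1 - seqError, log = TRUE))
  best <- max(ll)
  # ties break toward the smaller genotype code, i.e. toward reference
  as.integer(which(ll >= best - 1e-12)[1L] - 1L)
}

#' Call genotypes for every sample and locus of a read-count table
#'
#' Applies [callSite()] elementwise and assembles the calls into a
#' cells x loci [GenotypeMatrix-class]. Loci a sample has no row for are
#' treated as zero coverage (no call).
#'
#' @param counts a [ReadCountTable-class]; must be non-empty.
#' @param minDepth,seqError,minVarReads passed to [callSite()].
#' @return a [GenotypeMatrix-class].
#' @export
callMatrix <- function(counts, minDepth = 25, seqError = 0.01,
                       minVarReads = 3) {
  ct <- readCounts(counts)
  if (nrow(ct) == 0L) stop("empty read-count table")
  samples <- unique(ct$sample_id)
  locusIds <- unique(ct$locus_id)
  calls <- matrix(NA_integer_, length(samples), length(locusIds),
                  dimnames = list(samples, locusIds))
  n <- ct$ref_reads + ct$var_reads
  callable <- n >= minDepth
  idx <- cbind(match(ct$sample_id, samples), match(ct$locus_id, locusIds))
  # vectorized ML genotype for the callable subset
  if (any(callable)) {
    k <- ct$var_reads[callable]
    nn <- n[callable]
    ll0 <- stats::dbinom(k, nn, seqError, log = TRUE)
    ll1 <- stats::dbinom(k, nn, 0.5, log = TRUE)
    ll2 <- stats::dbinom(k, nn, 1 - seqError, log = TRUE)
    g <- max.col(cbind(ll0 + 1e-12, ll1, ll2), ties.method = "first") - 1L
    g[k < minVarReads] <- 0L
    calls[idx[callable, , drop = FALSE]] <- g
  }
  new("GenotypeMatrix", calls = calls, callableThreshold = minDepth)
}

#' Benchmark genotype calls against known truth
#'
#' Allele-level confusion accounting at callable sites: a call is
#' "positive" when at least one non-reference allele is called (het or
#' hom-var); truth is positive when the known genotype carries a
#' non-reference allele. TPR = TP/(TP+FN), FPR = FP/(FP+TN),
#' FNR = 1 - TPR. Strata by truth zygosity report sensitivity as
#' \code{NA} at homozygous-reference truth (there are no true positives)
#' and FPR as \code{NA} where no true negatives exist.
#'
#' @param calls a [GenotypeMatrix-class].
#' @param truth integer matrix of known genotypes (0/1/2) with the same
#'   dimnames as \code{calls}; every called locus must be present.
#' @return a [BenchmarkReport-class].
#' @export
benchmarkCalls <- function(calls, truth) {
  m <- genotypeCalls(calls)
  if (!all(rownames(m) %in% rownames(truth))) {
    stop("cells in calls missing from truth")
  }
  if (!all(colnames(m) %in% colnames(truth))) {
    stop("loci in calls missing from truth: ",
         paste(utils::head(setdiff(colnames(m), colnames(truth))),
               collapse = ", "))
  }
  tr <- truth[rownames(m), colnames(m), drop = FALSE]
  ok <- !is.na(m) & !is.na(tr)
  callPos <- m[ok] > 0L
  truthPos <- tr[ok] > 0L
  zyg <- c("0" = "hom-ref", "1" = "het", "2" = "hom-var")[as.character(tr[ok])]

  tally <- function(cp, tp) {
    TP <- sum(cp & tp); FN <- sum(!cp & tp)
    FP <- sum(cp & !tp); TN <- sum(!cp & !tp)
    TPR <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    FPR <- if (FP + TN > 0) FP / (FP + TN) else NA_real_
    data.frame(TP = TP, TN = TN, FP = FP, FN = FN, TPR = TPR, FPR = FPR,
               FNR = if (is.na(TPR)) NA_real_ else 1 - TPR)
  }
  overall <- tally(callPos, truthPos)
  strata <- lapply(c("hom-ref", "het", "hom-var"), function(z) {
    sel <- zyg == z
    cbind(zygosity = z, tally(callPos[sel], truthPos[sel]))
  })
  new("BenchmarkReport", overall = overall,
      byZygosity = do.call(rbind, strata))
}

#' Test symmetry of allelic dropout
#'
#' At loci known to be heterozygous, erroneous homozygous calls are either
#' hom-ref (variant allele lost) or hom-var (reference allele lost). Under
#' allelic dropout the two directions occur at equal rates; a two-sided
#' exact binomial test against 0.5 checks this.
#'
#' @param calls a [GenotypeMatrix-class].
#' @param truthHetLoci character vector of loci known heterozygous in
#'   every cell.
#' @return list with \code{nHomRef}, \code{nHomVar}, \code{pValue} and
#'   \code{degenerate} (TRUE when no homozygous errors were observed, in
#'   which case p = 1).
#' @export
adoSymmetryTest <- function(calls, truthHetLoci) {
  m <- genotypeCalls(calls)
  miss <- setdiff(truthHetLoci, colnames(m))
  if (length(miss)) stop("unknown loci: ", paste(utils::head(miss),
                                                 collapse = ", "))
  sub <- m[, truthHetLoci, drop = FALSE]
  nHomRef <- sum(sub == 0L, na.rm = TRUE)
  nHomVar <- sum(sub == 2L, na.rm = TRUE)
  tot <- nHomRef + nHomVar
  if (tot == 0L) {
    return(list(nHomRef = 0L, nHomVar = 0L, pValue = 1, degenerate = TRUE))
  }
  p <- stats::binom.test(nHomRef, tot, p = 0.5,
                         alternative = "two.sided")$p.value
  list(nHomRef = nHomRef, nHomVar = nHomVar, pValue = p, degenerate = FALSE)
}

#' Concordance of per-locus dropout rates between subject groups
#'
#' Compares the per-locus false-negative (dropout) rate at heterozygous
#' sites shared between groups of cells (e.g. subjects). Squared Pearson
#' correlations near zero indicate dropout is stochastic rather than
#' locus-driven; shared site-specific effects raise them.
#'
#' @param fnrByLocus named list of numeric vectors, one per group: the
#'   per-locus dropout rate, named by locus, over that group's cells.
#' @return data.frame with one row per group pair: \code{group1},
#'   \code{group2}, \code{nShared}, \code{r2}.
#' @export
locusDropoutConcordance <- function(fnrByLocus) {
  stopifnot(is.list(fnrByLocus), length(fnrByLocus) >= 2L)
  groups <- names(fnrByLocus)
  if (is.null(groups)) groups <- as.character(seq_along(fnrByLocus))
  pairs <- utils::combn(seq_along(fnrByLocus), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- fnrByLocus[[pairs[1L, j]]]
    b <- fnrByLocus[[pairs[2L, j]]]
    shared <- intersect(names(a), names(b))
    if (length(shared) < 3L) {
      stop("fewer than 3 shared het loci between groups ",
           groups[pairs[1L, j]], " and ", groups[pairs[2L, j]])
    }
    r <- stats::cor(a[shared], b[shared])
    data.frame(group1 = groups[pairs[1L, j]], group2 = groups[pairs[2L, j]],
               nShared = length(shared), r2 = r^2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-locus dropout rates at known het loci
#'
#' Convenience summary feeding [locusDropoutConcordance()]: for each locus
#' known heterozygous, the fraction of callable cells in which it was
#' erroneously called homozygous (either direction).
#'
#' @param calls a [GenotypeMatrix-class].
#' @param truthHetLoci loci known heterozygous in every cell.
#' @return named numeric vector of per-locus dropout rates (NA where no
#'   cell was callable).
#' @export
perLocusDropoutRate <- function(calls, truthHetLoci) {
  m <- genotypeCalls(calls)[, truthHetLoci, drop = FALSE]
  called <- colSums(!is.na(m))
  dropped <- colSums(m == 0L | m == 2L, na.rm = TRUE)
  ifelse(called > 0, dropped / called, NA_real_)
}
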