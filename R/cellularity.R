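# Maximum-likelihood classification of sorted samples as clonally pure
# (one cell, or two cells of the same clone) or heterogeneous (a mixture
# of two distinct clones), from variant read counts at clustered somatic
# loci.

#' Estimate per-cluster cumulative error rates from control cells
#'
#' Somatic SNVs are private to a subject, so single cells from the other
#' subjects are expected to be reference at these loci; any variant reads
#' they show measure the cumulative error intrinsic to amplification,
#' library preparation and sequencing. The estimate pools reads across
#' control cells per cluster: e = variant reads / total depth, clipped to
#' [1e-6, 0.5).
#'
#' @param controlCounts a [ReadCountTable-class] of cells from other
#'   subjects, covering this subject's somatic loci.
#' @param catalog a [LocusCatalog-class].
#' @param subject the subject whose clusters are being profiled.
#' @return named numeric vector: error rate per cluster label.
#' @export
estimateErrorProfile <- function(controlCounts, catalog, subject) {
  lo <- loci(catalog)
  lo <- lo[lo$subject == subject & lo$kind == "somatic_cluster", ,
           drop = FALSE]
  ct <- readCounts(controlCounts)
  ct <- ct[ct$locus_id %in% lo$locus_id, , drop = FALSE]
  depth <- ct$ref_reads + ct$var_reads
  ct <- ct[depth > 0, , drop = FALSE]
  if (nrow(ct) == 0L) stop("no covered control loci for subject ", subject)
  cluster <- lo$cluster[match(ct$locus_id, lo$locus_id)]
  varTot <- tapply(ct$var_reads, cluster, sum)
  depthTot <- tapply(ct$ref_reads + ct$var_reads, cluster, sum)
  e <- as.numeric(varTot / depthTot)
  names(e) <- names(varTot)
  out <- stats::setNames(rep(NA_real_, length(unique(lo$cluster))),
                         sort(unique(lo$cluster)))
  out[names(e)] <- e
  if (anyNA(out)) stop("no covered control loci for cluster(s) ",
                       paste(names(out)[is.na(out)], collapse = ", "))
  pmin(pmax(out, 1e-6), 0.5 - 1e-6)
}

#' Success probability of a variant read at a site
#'
#' The probability that a read carries the variant allele when the
#' sampled population has true variant allele fraction \code{f} and the
#' cumulative error rate is \code{e}: \code{f (1 - e) + (1 - f) e}. Note
#' that \code{f = 0.5} maps to 0.5 for every error rate, which is why the
#' single-cell het VAF center is insensitive to e.
#'
#' @param f true variant allele fraction in [0, 1].
#' @param e cumulative error rate in [0, 1].
#' @return probability in [0, 1]; vectorized over both arguments.
#' @examples
#' siteSuccessProb(0.5, 0.02)   # 0.5
#' siteSuccessProb(0.25, 0.02)  # 0.26
#' @export
siteSuccessProb <- function(f, e) {
  if (any(f < 0 | f > 1) || any(e < 0 | e > 1)) {
    stop("f and e must lie in [0, 1]")
  }
  f * (1 - e) + (1 - f) * e
}

# implied per-cluster source VAF for a pair of sources (clones or
# "non-tumor"): 0.5 where both carry the cluster, 0.25 where exactly one
# does, 0 where neither does
.pairClusterVAF <- function(arch, sourceA, sourceB) {
  clusters <- arch@clones$cluster
  carA <- clusters %in% .cloneClusters(arch, sourceA)
  carB <- clusters %in% .cloneClusters(arch, sourceB)
  stats::setNames((carA + carB) / 4, clusters)
}

#' Log-likelihood of observed counts under one mixture hypothesis
#'
#' Sums, over covered somatic cluster loci, the log binomial probability
#' of the observed variant read count given the hypothesis' per-cluster
#' source VAF and the cluster's error rate. Zero-depth loci contribute
#' nothing; an empty locus set gives log-likelihood 0.
#'
#' @param varReads,depth integer vectors over loci.
#' @param cluster cluster label per locus.
#' @param fByCluster named vector of source VAFs per cluster (from the
#'   hypothesis).
#' @param errorProfile named vector of per-cluster error rates.
#' @return scalar log-likelihood.
#' @export
hypothesisLogLik <- function(varReads, depth, cluster, fByCluster,
                             errorProfile) {
  keep <- depth > 0
  if (!any(keep)) return(0)
  k <- varReads[keep]
  n <- depth[keep]
  cl <- as.character(cluster[keep])
  p <- siteSuccessProb(fByCluster[cl], errorProfile[cl])
  sum(stats::dbinom(k, n, p, log = TRUE))
}

#' Classify one sorted sample as clonally pure or mixed
#'
#' Enumerates every unordered pair of sources drawn from the
#' architecture's clones plus a non-tumor source. Identical pairs are the
#' pure hypotheses (the model cannot distinguish one cell from two cells
#' of the same clone); distinct pairs are the mixed hypotheses, implying
#' per-cluster source VAFs of 0.5 / 0.25 / 0. The likelihood-ratio
#' statistic 2 (best mixed - best pure), floored at zero, is referred to
#' a one-sided chi-square distribution with one degree of freedom; the
#' sample is called mixed when p < alpha.
#'
#' @param counts a [ReadCountTable-class] containing the sample.
#' @param sampleId which sample to classify.
#' @param arch the subject's [ClonalArchitecture-class].
#' @param catalog the [LocusCatalog-class]; only the subject's somatic
#'   cluster loci enter the likelihood (germline het loci are 0.5 under
#'   every hypothesis and carry no signal).
#' @param errorProfile per-cluster error rates from
#'   [estimateErrorProfile()].
#' @param alpha significance level for the mixed call (default 0.05).
#' @return a [CellularityResult-class]; samples with no covered somatic
#'   loci are classified \code{"indeterminate"}.
#' @export
classifySample <- function(counts, sampleId, arch, catalog, errorProfile,
                           alpha = 0.05) {
  lo <- loci(catalog)
  lo <- lo[lo$subject == arch@subject & lo$kind == "somatic_cluster", ,
           drop = FALSE]
  ct <- readCounts(counts)
  ct <- ct[ct$sample_id == sampleId & ct$locus_id %in% lo$locus_id, ,
           drop = FALSE]
  depth <- ct$ref_reads + ct$var_reads
  ct <- ct[depth > 0, , drop = FALSE]
  if (nrow(ct) == 0L) {
    return(new("CellularityResult", sample = sampleId,
               pureClone = NA_character_, pureLogLik = NA_real_,
               mixedPair = c(NA_character_, NA_character_),
               mixedLogLik = NA_real_, lrt = NA_real_, pValue = NA_real_,
               classification = "indeterminate", nLoci = 0L))
  }
  cluster <- lo$cluster[match(ct$locus_id, lo$locus_id)]
  missing <- setdiff(unique(cluster), names(errorProfile))
  if (length(missing)) stop("errorProfile missing cluster(s) ",
                            paste(missing, collapse = ", "))
  sources <- c(arch@clones$id, "non-tumor")
  ll <- function(a, b) {
    hypothesisLogLik(ct$var_reads, ct$ref_reads + ct$var_reads, cluster,
                     .pairClusterVAF(arch, a, b), errorProfile)
  }
  bestPure <- NULL
  bestMixed <- NULL
  for (i in seq_along(sources)) {
    for (j in i:length(sources)) {
      l <- ll(sources[i], sources[j])
      if (i == j) {
        if (is.null(bestPure) || l > bestPure$l) {
          bestPure <- list(pair = sources[c(i, j)], l = l)
        }
      } else if (is.null(bestMixed) || l > bestMixed$l) {
        bestMixed <- list(pair = sources[c(i, j)], l = l)
      }
    }
  }
  lrt <- max(0, 2 * (bestMixed$l - bestPure$l))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  new("CellularityResult", sample = sampleId,
      pureClone = bestPure$pair[1L], pureLogLik = bestPure$l,
      mixedPair = bestMixed$pair, mixedLogLik = bestMixed$l,
      lrt = lrt, pValue = p,
      classification = if (p < alpha) "mixed" else "pure",
      nLoci = nrow(ct))
}

#' Cellularity classification for every sample in a table
#'
#' Runs [classifySample()] on each sample and assembles a summary table
#' (sample, best pure source, best mixed pair, log-likelihoods, LRT,
#' p-value, classification).
#'
#' @inheritParams classifySample
#' @return data.frame with one row per sample.
#' @export
cellularityTable <- function(counts, arch, catalog, errorProfile,
                             alpha = 0.05) {
  samples <- unique(readCounts(counts)$sample_id)
  rows <- lapply(samples, function(s) {
    r <- classifySample(counts, s, arch, catalog, errorProfile, alpha)
    data.frame(sample = r@sample, best_pure = r@pureClone,
               pure_loglik = r@pureLogLik,
               best_mixed = paste(r@mixedPair, collapse = "+"),
               mixed_loglik = r@mixedLogLik, lrt = r@lrt,
               p_value = r@pValue, classification = r@classification,
               n_loci = r@nLoci, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
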