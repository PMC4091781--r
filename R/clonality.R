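# Mapping single-cell genotype profiles onto bulk-predicted cluster
# models: clone assignment, ADO-vs-substructure discrimination, branch
# detection, outlier rescue and clone-frequency concordance.

# cluster labels ordered by lineage depth, with each cluster's ancestor
# clusters, derived from the clone tree
.clusterAncestry <- function(arch) {
  cl <- arch@clones
  lapply(stats::setNames(cl$cluster, cl$cluster), function(cc) {
    carried <- .cloneClusters(arch, cl$id[match(cc, cl$cluster)])
    setdiff(carried, cc)
  })
}

#' Assign cells to clones from their genotype profiles
#'
#' A cluster is "observed" in a cell when the detection fraction (variant
#' calls / callable sites within the cluster) reaches \code{tauDetect}
#' with at least \code{minCallable} callable sites. Each cell is assigned
#' the clone introducing the deepest observed cluster whose ancestor
#' clusters are all observed; cells observing no cluster are non-tumor.
#' Cells with a lineage gap (a descendant cluster observed while an
#' ancestor is not) are flagged inconsistent rather than force-assigned,
#' since such profiles reflect either dropout or cryptic substructure.
#'
#' @param calls a [GenotypeMatrix-class].
#' @param catalog a [LocusCatalog-class].
#' @param arch the subject's [ClonalArchitecture-class].
#' @param tauDetect detection-fraction threshold (default 0.5; with an
#'   ADO-driven false-negative rate near 0.12 a majority rule separates
#'   presence from dropout cleanly).
#' @param minCallable minimum callable sites for a cluster to be
#'   evaluable in a cell (default 3).
#' @return list with \code{assignments} (data.frame: cell_id, clone,
#'   inconsistent), \code{detection} (cells x clusters detection-fraction
#'   matrix) and \code{callable} (matching callable-site counts).
#' @export
assignCells <- function(calls, catalog, arch, tauDetect = 0.5,
                        minCallable = 3L) {
  m <- genotypeCalls(calls)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty genotype matrix")
  lo <- loci(catalog)
  lo <- lo[lo$subject == arch@subject & lo$kind == "somatic_cluster" &
             lo$locus_id %in% colnames(m), , drop = FALSE]
  clusters <- arch@clones$cluster
  det <- callable <- matrix(NA_real_, nrow(m), length(clusters),
                            dimnames = list(rownames(m), clusters))
  for (cc in clusters) {
    ids <- lo$locus_id[lo$cluster == cc]
    sub <- m[, ids, drop = FALSE]
    nCall <- rowSums(!is.na(sub))
    nVar <- rowSums(sub > 0L, na.rm = TRUE)
    callable[, cc] <- nCall
    det[, cc] <- ifelse(nCall > 0, nVar / nCall, NA_real_)
  }
  observed <- det >= tauDetect & callable >= minCallable
  observed[is.na(observed)] <- FALSE

  ancestry <- .clusterAncestry(arch)
  depth <- vapply(ancestry, length, integer(1))
  cl <- arch@clones
  assignOne <- function(obs) {
    if (!any(obs)) return(list(clone = "non-tumor", inconsistent = FALSE))
    consistent <- vapply(clusters, function(cc) {
      obs[cc] && all(obs[ancestry[[cc]]])
    }, logical(1))
    gap <- any(obs & !consistent)
    if (!any(consistent)) {
      return(list(clone = "non-tumor", inconsistent = TRUE))
    }
    deepest <- clusters[consistent][which.max(depth[clusters[consistent]])]
    list(clone = cl$id[match(deepest, cl$cluster)], inconsistent = gap)
  }
  res <- lapply(seq_len(nrow(m)), function(i) assignOne(observed[i, ]))
  assignments <- data.frame(
    cell_id = rownames(m),
    clone = vapply(res, `[[`, character(1), "clone"),
    inconsistent = vapply(res, `[[`, logical(1), "inconsistent"),
    stringsAsFactors = FALSE)
  list(assignments = assignments, detection = det, callable = callable)
}

#' Test whether reference calls exceed the ADO expectation
#'
#' Reference calls at loci a cell's clone is expected to carry are either
#' stochastic dropout or cryptic substructure. Per cell, the observed
#' reference-call count within expected-variant clusters is tested
#' against the germline-estimated false-negative rate (one-sided exact
#' binomial, excess direction). Per locus, the reference-call count
#' across carrier cells is tested the same way with Bonferroni
#' correction; flagged loci that share an identical reference-cell
#' pattern in a cluster (>= 2 loci, >= 2 cells) are reported as candidate
#' substructure, whereas scattered flagged loci are consistent with ADO.
#'
#' @param calls a [GenotypeMatrix-class].
#' @param assignments the \code{assignments} data.frame from
#'   [assignCells()].
#' @param catalog a [LocusCatalog-class].
#' @param arch the subject's [ClonalArchitecture-class].
#' @param fnrEst false-negative rate estimate at het sites (e.g. from
#'   [benchmarkCalls()] on germline het loci).
#' @param alpha significance level (default 0.05).
#' @return list with \code{perCell}, \code{perLocus} data.frames and
#'   \code{substructure} (data.frame of flagged locus blocks).
#' @export
referenceCallExcess <- function(calls, assignments, catalog, arch, fnrEst,
                                alpha = 0.05) {
  m <- genotypeCalls(calls)
  lo <- loci(catalog)
  lo <- lo[lo$subject == arch@subject & lo$kind == "somatic_cluster" &
             lo$locus_id %in% colnames(m), , drop = FALSE]
  carried <- lapply(stats::setNames(assignments$clone, assignments$cell_id),
                    function(cid) .cloneClusters(arch, cid))

  perCell <- do.call(rbind, lapply(seq_len(nrow(assignments)), function(i) {
    cell <- assignments$cell_id[i]
    ids <- lo$locus_id[lo$cluster %in% carried[[cell]]]
    g <- m[cell, ids]
    n <- sum(!is.na(g))
    r <- sum(g == 0L, na.rm = TRUE)
    p <- if (n > 0) stats::pbinom(r - 1L, n, fnrEst, lower.tail = FALSE)
         else NA_real_
    data.frame(cell_id = cell, n_callable = n, n_reference = r,
               rate = if (n > 0) r / n else NA_real_, p_value = p,
               excess = !is.na(p) && p < alpha, stringsAsFactors = FALSE)
  }))

  carriers <- lapply(stats::setNames(lo$locus_id, lo$locus_id), function(id) {
    cc <- lo$cluster[match(id, lo$locus_id)]
    assignments$cell_id[vapply(assignments$cell_id,
                               function(cell) cc %in% carried[[cell]],
                               logical(1))]
  })
  perLocus <- do.call(rbind, lapply(lo$locus_id, function(id) {
    cells <- carriers[[id]]
    g <- m[cells, id]
    n <- sum(!is.na(g))
    r <- sum(g == 0L, na.rm = TRUE)
    p <- if (n > 0) stats::pbinom(r - 1L, n, fnrEst, lower.tail = FALSE)
         else NA_real_
    refCells <- cells[!is.na(g) & g == 0L]
    data.frame(locus_id = id, cluster = lo$cluster[match(id, lo$locus_id)],
               n_callable = n, n_reference = r, p_value = p,
               pattern = paste(sort(refCells), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  nTest <- sum(!is.na(perLocus$p_value))
  perLocus$flagged <- !is.na(perLocus$p_value) &
    perLocus$p_value * nTest < alpha

  fl <- perLocus[perLocus$flagged & perLocus$n_reference >= 2L, ,
                 drop = FALSE]
  blocks <- NULL
  if (nrow(fl)) {
    key <- paste(fl$cluster, fl$pattern, sep = "|")
    for (k in unique(key)) {
      sel <- fl[key == k, , drop = FALSE]
      nCells <- length(strsplit(sel$pattern[1L], ",")[[1L]])
      if (nrow(sel) >= 2L && nCells >= 2L) {
        blocks <- rbind(blocks, data.frame(
          cluster = sel$cluster[1L], n_loci = nrow(sel),
          n_cells = nCells,
          loci = paste(sel$locus_id, collapse = ","),
          cells = sel$pattern[1L], stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(blocks)) {
    blocks <- data.frame(cluster = character(), n_loci = integer(),
                         n_cells = integer(), loci = character(),
                         cells = character(), stringsAsFactors = FALSE)
  }
  list(perCell = perCell, perLocus = perLocus, substructure = blocks)
}

#' Detect mutually exclusive variant sets (evolutionary branch points)
#'
#' Seeds candidate branch configurations from SNVs sharing identical
#' variant-cell patterns, yielding pairs of disjoint tumor-cell sets
#' (S_A, S_B). Exclusivity is judged against the given (null) cluster
#' model: a reference call only constitutes evidence where the cell's
#' assigned clone carries the locus's cluster, since a descendant
#' cluster is genuinely absent from ancestor-only cells under linear
#' nesting. A locus is "A-exclusive" when it is variant in at least one
#' S_A cell, expected variant and callable in at least one S_B cell,
#' and reference at every such entry (and symmetrically for B). Under
#' the no-branching null each locus becomes exclusive only through
#' dropout of all its cross-side expected-variant entries, with
#' probability \code{fnrEst} per entry; the count of exclusive loci per
#' side is compared against its dropout-expected Poisson rate. The two
#' sides' tail probabilities are multiplied and Bonferroni-corrected
#' over the \code{3^cells} possible disjoint cell-set pairs, pricing
#' the data-driven selection of the candidate sets. Pairs passing
#' \code{alpha} with at least \code{minCells} supporting cells per side
#' are reported, with the maximal exclusive SNV sets as the two sides.
#' Running the detector with a collapsed cluster model (e.g. one bulk
#' cluster that may hide substructure) is how within-cluster splits
#' such as 5A/5B are discovered.
#'
#' @param calls a [GenotypeMatrix-class].
#' @param assignments assignments data.frame from [assignCells()]; only
#'   cells not assigned non-tumor are used.
#' @param catalog a [LocusCatalog-class] mapping loci to clusters.
#' @param arch the subject's [ClonalArchitecture-class] (the null model
#'   without the candidate branches).
#' @param fnrEst het-site false-negative rate estimate.
#' @param minCells minimum supporting cells per side (default 2).
#' @param alpha family-wise significance level (default 0.05).
#' @param lociUse optional character vector restricting the SNV columns
#'   examined (e.g. one cluster's loci).
#' @return data.frame with one row per reported branch: the two SNV
#'   sides, their supporting cells, the exclusive-locus counts and
#'   dropout expectations, and the adjusted significance.
#' @export
detectBranches <- function(calls, assignments, catalog, arch, fnrEst,
                           minCells = 2L, alpha = 0.05, lociUse = NULL) {
  m <- genotypeCalls(calls)
  tumor <- assignments$cell_id[assignments$clone != "non-tumor"]
  if (length(tumor) < 2L) stop("need at least 2 tumor cells")
  m <- m[tumor, , drop = FALSE]
  lo <- loci(catalog)
  lo <- lo[lo$subject == arch@subject & lo$kind == "somatic_cluster", ,
           drop = FALSE]
  keep <- intersect(colnames(m), lo$locus_id)
  if (!is.null(lociUse)) keep <- intersect(keep, lociUse)
  m <- m[, keep, drop = FALSE]
  lociCluster <- lo$cluster[match(colnames(m), lo$locus_id)]
  # expected-variant mask: cell's assigned clone carries the cluster
  carried <- lapply(stats::setNames(
    assignments$clone[match(tumor, assignments$cell_id)], tumor),
    function(cid) .cloneClusters(arch, cid))
  expectedVar <- vapply(seq_along(lociCluster), function(j) {
    vapply(tumor, function(cell) lociCluster[j] %in% carried[[cell]],
           logical(1))
  }, logical(length(tumor)))
  dimnames(expectedVar) <- dimnames(m)
  nCells <- nrow(m)
  emptyReport <- data.frame(
    side_a = character(), side_b = character(), cells_a = character(),
    cells_b = character(), n_cells_a = integer(), n_cells_b = integer(),
    n_loci_a = integer(), n_loci_b = integer(), expected_a = numeric(),
    expected_b = numeric(), p_value = numeric(), p_adjusted = numeric(),
    stringsAsFactors = FALSE)

  varSets <- apply(m, 2L, function(g) {
    paste(sort(rownames(m)[!is.na(g) & g > 0L]), collapse = ",")
  })
  patterns <- unique(varSets[varSets != ""])
  if (length(patterns) < 2L) return(emptyReport)
  cellsOf <- lapply(patterns, function(s) strsplit(s, ",")[[1L]])

  # exclusive-side evaluation for one direction: loci variant within
  # `inside`, expected variant and callable in >= 1 `outside` cell, and
  # reference at every such entry; the Poisson rate sums each candidate
  # locus's probability of full cross-side dropout
  sideEval <- function(inside, outside) {
    sub <- m[outside, , drop = FALSE]
    informative <- !is.na(sub) & expectedVar[outside, , drop = FALSE]
    mCross <- colSums(informative)
    refAll <- colSums(informative & sub == 0L) == mCross
    varIn <- colSums(m[inside, , drop = FALSE] > 0L, na.rm = TRUE) > 0L
    trials <- mCross > 0L
    sel <- trials & refAll & varIn
    list(loci = colnames(m)[sel], n = sum(sel),
         lambda = sum(fnrEst^mCross[trials]))
  }

  out <- NULL
  seen <- character()
  cand <- utils::combn(length(patterns), 2L)
  for (j in seq_len(ncol(cand))) {
    cellsA <- cellsOf[[cand[1L, j]]]
    cellsB <- cellsOf[[cand[2L, j]]]
    if (length(intersect(cellsA, cellsB))) next
    key <- paste(paste(cellsA, collapse = ","),
                 paste(cellsB, collapse = ","), sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    a <- sideEval(cellsA, cellsB)
    b <- sideEval(cellsB, cellsA)
    if (a$n == 0L || b$n == 0L) next
    pA <- stats::ppois(a$n - 1L, a$lambda, lower.tail = FALSE)
    pB <- stats::ppois(b$n - 1L, b$lambda, lower.tail = FALSE)
    p <- pA * pB
    supA <- rownames(m)[rowSums(m[, a$loci, drop = FALSE] > 0L,
                                na.rm = TRUE) > 0L]
    supB <- rownames(m)[rowSums(m[, b$loci, drop = FALSE] > 0L,
                                na.rm = TRUE) > 0L]
    out <- rbind(out, data.frame(
      side_a = paste(a$loci, collapse = ","),
      side_b = paste(b$loci, collapse = ","),
      cells_a = paste(sort(supA), collapse = ","),
      cells_b = paste(sort(supB), collapse = ","),
      n_cells_a = length(supA), n_cells_b = length(supB),
      n_loci_a = a$n, n_loci_b = b$n,
      expected_a = a$lambda, expected_b = b$lambda,
      p_value = p, stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(emptyReport)
  out$p_adjusted <- pmin(1, out$p_value * 3^nCells)
  out <- out[out$n_cells_a >= minCells & out$n_cells_b >= minCells &
               out$p_adjusted < alpha, , drop = FALSE]
  # drop dominated duplicates: keep the most significant row per side pair
  if (nrow(out) > 1L) {
    out <- out[order(out$p_adjusted), , drop = FALSE]
    out <- out[!duplicated(paste(out$side_a, out$side_b)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Rescue outlier SNVs by pattern matching against clusters
#'
#' An outlier SNV (one that could not be clustered from bulk VAFs) is
#' assigned to a cluster when its cell-level presence/absence pattern
#' matches the cluster's carrier cells in an ADO-tolerant way: a variant
#' call in a cell whose clone does not carry the candidate cluster is
#' disqualifying (false positives are not ADO-explainable), and reference
#' calls in carrier cells are tolerated up to
#' \code{ceiling(fnrEst * carriers)}. SNVs callable in fewer than
#' \code{minInformativeCells} cells, spanning fewer than 2 clones, with
#' no variant call, or matching more than one cluster are left
#' unassigned.
#'
#' @param calls a [GenotypeMatrix-class] containing the outlier columns.
#' @param assignments assignments data.frame from [assignCells()].
#' @param outlierSnvs character vector of outlier locus ids.
#' @param arch the subject's [ClonalArchitecture-class].
#' @param fnrEst het-site false-negative rate estimate.
#' @param minInformativeCells minimum callable cells (default 4).
#' @return data.frame: snv_id, assigned cluster (NA when unassigned),
#'   reason, number of matching clusters, mismatch count for the winner.
#' @export
rescueOutliers <- function(calls, assignments, outlierSnvs, arch, fnrEst,
                           minInformativeCells = 4L) {
  m <- genotypeCalls(calls)
  clusters <- arch@clones$cluster
  carried <- lapply(stats::setNames(assignments$clone, assignments$cell_id),
                    function(cid) .cloneClusters(arch, cid))
  rows <- lapply(outlierSnvs, function(snv) {
    g <- m[assignments$cell_id, snv]
    names(g) <- assignments$cell_id
    callable <- names(g)[!is.na(g)]
    res <- data.frame(snv_id = snv, cluster = NA_character_,
                      reason = "", n_matches = 0L,
                      mismatches = NA_integer_, stringsAsFactors = FALSE)
    if (length(callable) < minInformativeCells ||
        length(unique(assignments$clone[match(callable,
                                              assignments$cell_id)])) < 2L) {
      res$reason <- "insufficient_information"
      return(res)
    }
    if (!any(g[callable] > 0L)) {
      res$reason <- "no_variant_call"
      return(res)
    }
    matches <- list()
    for (cc in clusters) {
      isCarrier <- vapply(callable, function(cell) cc %in% carried[[cell]],
                          logical(1))
      # hard constraint: a variant call outside the carrier set cannot be ADO
      if (any(g[callable][!isCarrier] > 0L)) next
      mism <- sum(g[callable][isCarrier] == 0L)
      if (sum(isCarrier) == 0L) next
      if (mism <= ceiling(fnrEst * sum(isCarrier))) {
        matches[[cc]] <- mism
      }
    }
    res$n_matches <- length(matches)
    if (length(matches) == 1L) {
      res$cluster <- names(matches)
      res$reason <- "assigned"
      res$mismatches <- matches[[1L]]
    } else if (length(matches) == 0L) {
      res$reason <- "no_match"
    } else {
      res$reason <- "ambiguous"
    }
    res
  })
  do.call(rbind, rows)
}

#' Concordance between single-cell clone frequencies and bulk predictions
#'
#' Compares the frequency of each clone among assigned single cells with
#' the bulk prediction (the mean VAF of the clone's defining cluster, the
#' frequency proxy used when clone frequency is read off unfractionated
#' data). Returns the squared Pearson correlation over matched points.
#'
#' @param scFreq named numeric vector of single-cell clone frequencies
#'   (cells assigned / total cells), named by clone (optionally
#'   subject-qualified).
#' @param bulkVAF named numeric vector of bulk cluster mean VAFs with
#'   matching names.
#' @return list with \code{r2}, \code{n} and \code{table} (the matched
#'   pairs).
#' @export
cloneFrequencyConcordance <- function(scFreq, bulkVAF) {
  shared <- intersect(names(scFreq), names(bulkVAF))
  if (length(shared) < 3L) stop("need at least 3 matched clones")
  x <- bulkVAF[shared]
  y <- scFreq[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  list(r2 = r^2, n = length(shared),
       table = data.frame(clone = shared, bulk_vaf = as.numeric(x),
                          sc_freq = as.numeric(y),
                          stringsAsFactors = FALSE))
}

#' Clone frequencies from an assignment table
#'
#' @param assignments assignments data.frame from [assignCells()].
#' @return named numeric vector over clones (including non-tumor),
#'   summing to 1.
#' @export
cloneFrequencies <- function(assignments) {
  tab <- table(assignments$clone)
  stats::setNames(as.numeric(tab) / nrow(assignments), names(tab))
}
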