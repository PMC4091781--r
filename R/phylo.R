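# Cell phylogenies from genotype matrices: missing-data-aware binary
# distances, neighbor joining with a deterministic tie-break, bootstrap
# branch support, and a two-state pruning likelihood for fixed trees.

#' Pairwise genetic distances between cells
#'
#' Binary-state mismatch fraction over sites callable in both cells of a
#' pair (pairwise deletion): hom-ref is one state, het/hom-var (variant
#' present) the other. Pairs sharing fewer than \code{minShared} callable
#' sites are flagged; a pair with no co-callable site at all is an error.
#'
#' @param calls a [GenotypeMatrix-class] with at least 3 cells.
#' @param minShared flag threshold on co-callable sites (default 20).
#' @return a [DistanceMatrix-class].
#' @export
pairwiseDistance <- function(calls, minShared = 20) {
  m <- genotypeCalls(calls)
  if (nrow(m) < 3L) stop("need at least 3 cells")
  present <- (m > 0L) * 1L        # NA propagates
  obs <- !is.na(present)
  pres0 <- present
  pres0[!obs] <- 0L
  # co-callable counts and mismatch counts via cross products
  shared <- obs %*% t(obs)
  agree11 <- pres0 %*% t(pres0)
  refObs <- (1L - pres0) * obs
  agree00 <- refObs %*% t(refObs)
  mismatch <- shared - agree11 - agree00
  if (any(shared[upper.tri(shared)] == 0L)) {
    idx <- which(shared == 0L & upper.tri(shared), arr.ind = TRUE)[1L, ]
    stop(sprintf("cells %s and %s share no callable sites",
                 rownames(m)[idx[1L]], rownames(m)[idx[2L]]))
  }
  d <- mismatch / shared
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  new("DistanceMatrix", distances = d,
      sharedSites = matrix(as.integer(shared), nrow(m),
                           dimnames = dimnames(d)),
      minShared = minShared)
}

# newick token for a branch length
.bl <- function(x) sprintf("%.10g", max(0, x))

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining (Saitou-Nei Q-criterion).
#' Negative branch-length estimates are clamped to zero; ties in Q are
#' broken by the lexicographically smallest pair of subtree labels (the
#' smallest leaf label each subtree contains), making the output
#' deterministic and invariant to input row order.
#'
#' @param dist a [DistanceMatrix-class] or a symmetric numeric matrix
#'   with dimnames; all entries must be finite.
#' @return an unrooted \code{ape::phylo} tree over the cells.
#' @export
neighborJoining <- function(dist) {
  D <- if (is(dist, "DistanceMatrix")) distances(dist) else dist
  if (!all(is.finite(D))) stop("non-finite distance entries")
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  nwk <- labels          # growing newick fragment per active node
  reps <- labels         # smallest leaf label per active node
  active <- seq_len(n)
  while (length(active) > 3L) {
    N <- length(active)
    Ds <- D[active, active, drop = FALSE]
    r <- rowSums(Ds)
    Q <- (N - 2) * Ds - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    ties <- ties[ties[, 1L] < ties[, 2L], , drop = FALSE]
    keyOf <- function(i, j) {
      pr <- sort(c(reps[active[i]], reps[active[j]]))
      paste(pr, collapse = "\r")
    }
    keys <- vapply(seq_len(nrow(ties)),
                   function(t) keyOf(ties[t, 1L], ties[t, 2L]),
                   character(1))
    pick <- ties[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- Ds[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- dij - li
    ai <- active[i]; aj <- active[j]
    newD <- (D[ai, active] + D[aj, active] - dij) / 2
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    D[u, active] <- newD
    D[active, u] <- newD
    D[u, u] <- 0
    nwk <- c(nwk, sprintf("(%s:%s,%s:%s)", nwk[ai], .bl(li),
                          nwk[aj], .bl(lj)))
    reps <- c(reps, min(reps[ai], reps[aj]))
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[a], .bl(la), nwk[b], .bl(lb),
                 nwk[c3], .bl(lc))
  ape::read.tree(text = txt)
}

#' Bootstrap branch support for the neighbor-joining cell tree
#'
#' Builds the tree from the full genotype matrix, then resamples loci
#' with replacement \code{nIter} times, rebuilding the tree each time,
#' and reports for every internal edge the percentage of replicates
#' containing the same bipartition. Edges at or above
#' \code{strongThreshold} are flagged strongly supported. Replicates
#' whose resampled loci leave some cell pair with no co-callable site
#' are dropped (the support denominator is the number of successful
#' replicates). Deterministic given \code{seed}.
#'
#' @param calls a [GenotypeMatrix-class] with at least 4 cells.
#' @param nIter number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param minShared passed to [pairwiseDistance()].
#' @param strongThreshold percent support considered strong (default 75).
#' @return list with \code{tree} (an \code{ape::phylo} whose node labels
#'   carry the support percentages; the root label is \code{NA}),
#'   \code{support} (numeric per internal node), \code{strong} (logical)
#'   and \code{nReplicates}.
#' @export
bootstrapSupport <- function(calls, nIter = 1000L, seed, minShared = 20,
                             strongThreshold = 75) {
  if (nIter <= 0L) stop("nIter must be a positive integer")
  m <- genotypeCalls(calls)
  if (nrow(m) < 4L) stop("need at least 4 cells")
  base <- neighborJoining(pairwiseDistance(calls, minShared))
  set.seed(seed)
  reps <- vector("list", nIter)
  ok <- 0L
  for (b in seq_len(nIter)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mb <- m[, idx, drop = FALSE]
    colnames(mb) <- sprintf("bs%06d", seq_len(ncol(mb)))
    gm <- new("GenotypeMatrix", calls = mb,
              callableThreshold = calls@callableThreshold)
    tr <- tryCatch(neighborJoining(pairwiseDistance(gm, minShared)),
                   error = function(e) NULL)
    if (!is.null(tr)) {
      ok <- ok + 1L
      reps[[ok]] <- tr
    }
  }
  if (ok == 0L) stop("no bootstrap replicate produced a valid tree")
  reps <- reps[seq_len(ok)]
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(base, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- 100 * cnt / ok
  support[1L] <- NA_real_   # root of the unrooted tree: trivial bipartition
  base$node.label <- ifelse(is.na(support), "",
                            sprintf("%.0f", support))
  list(tree = base, support = support,
       strong = !is.na(support) & support >= strongThreshold,
       nReplicates = ok)
}

#' Two-state likelihood of a genotype matrix on a fixed tree
#'
#' Felsenstein pruning under a symmetric two-state model (variant absent
#' / present) with stationary frequencies (0.5, 0.5) and branch
#' transition probability \code{(1 - exp(-2 rate t)) / 2}. No-call
#' entries are marginalized (partial likelihood 1 for both states), so an
#' all-missing matrix scores 0. Intended for comparing fixed candidate
#' topologies; no optimization is performed.
#'
#' @param calls a [GenotypeMatrix-class]; cells must match the tree's
#'   tips.
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param rate substitution rate (> 0).
#' @return total log-likelihood summed over loci.
#' @export
twoStateLogLik <- function(calls, tree, rate = 1) {
  stopifnot(rate > 0)
  m <- genotypeCalls(calls)
  if (!setequal(rownames(m), tree$tip.label)) {
    stop("tree tips must match the cells of the matrix")
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  state <- (m > 0L) * 1L   # 0 = reference state, 1 = variant present
  nSites <- ncol(m)
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  tre <- stats::reorder(tree, "postorder")
  # partial likelihoods: one (nSites x 2) matrix per node
  part <- vector("list", nTip + nNode)
  for (i in seq_len(nTip)) {
    s <- state[tre$tip.label[i], ]
    L <- matrix(1, nSites, 2L)
    L[which(s == 1L), 1L] <- 0
    L[which(s == 0L), 2L] <- 0
    part[[i]] <- L
  }
  for (nd in (nTip + 1L):(nTip + nNode)) part[[nd]] <- matrix(1, nSites, 2L)
  for (e in seq_len(nrow(tre$edge))) {
    parent <- tre$edge[e, 1L]
    child <- tre$edge[e, 2L]
    q <- (1 - exp(-2 * rate * tre$edge.length[e])) / 2
    Lc <- part[[child]]
    towards <- cbind((1 - q) * Lc[, 1L] + q * Lc[, 2L],
                     q * Lc[, 1L] + (1 - q) * Lc[, 2L])
    part[[parent]] <- part[[parent]] * towards
  }
  root <- part[[nTip + 1L]]
  sum(log(0.5 * root[, 1L] + 0.5 * root[, 2L]))
}
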