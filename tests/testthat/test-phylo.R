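test_that("pairwise distances are mismatch fractions with pairwise deletion", {
  m <- rbind(a = c(0L, 0L, 1L, 1L, 2L),
             b = c(0L, 0L, 1L, 1L, 2L),
             c = c(1L, 0L, 0L, 1L, 0L))
  colnames(m) <- sprintf("L%d", 1:5)
  d <- distances(pairwiseDistance(gmOf(m), minShared = 3))
  expect_equal(d["a", "b"], 0)             # identical rows
  expect_equal(d["a", "c"], 3 / 5)         # states differ at L1, L3, L5
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  # het and hom-var are the same (variant-present) state
  m2 <- rbind(a = c(1L, 1L), b = c(2L, 2L), c = c(0L, 0L))
  colnames(m2) <- c("L1", "L2")
  d2 <- distances(pairwiseDistance(gmOf(m2), minShared = 1))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)

  # 5 mismatches over 50 co-callable sites
  set.seed(3)
  base <- sample(0:1, 50, TRUE)
  m3 <- rbind(a = as.integer(base), b = as.integer(base),
              c = rep(0L, 50))
  m3["b", 1:5] <- 1L - m3["b", 1:5]
  colnames(m3) <- sprintf("L%02d", 1:50)
  expect_equal(distances(pairwiseDistance(gmOf(m3)))["a", "b"], 0.1)

  # a pair with no co-callable sites is an error naming the pair
  m4 <- rbind(a = c(1L, NA), b = c(NA, 1L), c = c(1L, 1L))
  colnames(m4) <- c("L1", "L2")
  expect_error(pairwiseDistance(gmOf(m4), minShared = 1),
               "a and b share no callable sites")
  expect_error(pairwiseDistance(gmOf(m[1:2, , drop = FALSE])),
               "at least 3")
})

test_that("neighbor joining recovers a known quartet exactly", {
  # tree ((a:2,b:3):1,(c:4,d:5)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 5
  D["a", "c"] <- D["c", "a"] <- 7
  D["a", "d"] <- D["d", "a"] <- 8
  D["b", "c"] <- D["c", "b"] <- 8
  D["b", "d"] <- D["d", "b"] <- 9
  D["c", "d"] <- D["d", "c"] <- 9
  tr <- neighborJoining(D)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), letters[1:4])
  # the tree reproduces the input distances exactly (additivity)
  coph <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(coph, D, tolerance = 1e-9)
  # brute-force oracle: of the 3 quartet topologies, only ab|cd fits
  expect_true(ape::is.monophyletic(ape::root(tr, "a"), c("c", "d")))

  # 3 taxa: closed-form three-point lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighborJoining(D3)
  expect_equal(ape::cophenetic.phylo(t3)[c("x", "y", "z"), c("x", "y", "z")],
               D3, tolerance = 1e-9)
  expect_error(neighborJoining(matrix(c(0, Inf, Inf, 0), 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "finite|at least 3")
})

test_that("neighbor joining exactly recovers random additive trees up to 8 leaves", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (n in c(5, 6, 8)) {
    for (rep in 1:4) {
      true <- ape::rtree(n, rooted = FALSE,
                         br = function(k) runif(k, 0.5, 2))
      D <- ape::cophenetic.phylo(true)
      D <- D[sort(rownames(D)), sort(rownames(D))]
      got <- neighborJoining(D)
      expect_equal(ape::dist.topo(ape::unroot(true), got), 0,
                   ignore_attr = TRUE)
      expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)],
                   D, tolerance = 1e-8)
      # independent oracle: ape's own NJ finds the same topology
      expect_equal(ape::dist.topo(ape::nj(as.dist(D)), got), 0,
                   ignore_attr = TRUE)
    }
  }
  # exhaustive least-squares search over all topologies for one 6-leaf case
  true <- ape::rtree(6, rooted = FALSE, br = function(k) runif(k, 0.5, 2))
  D <- ape::cophenetic.phylo(true)
  lab <- sort(rownames(D))
  D <- D[lab, lab]
  fitRSS <- function(topo) {
    topo$edge.length <- rep(1, nrow(topo$edge))
    paths <- matrix(0, choose(6, 2), nrow(topo$edge))
    y <- numeric(choose(6, 2))
    r <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      r <- r + 1
      y[r] <- D[lab[i], lab[j]]
      p <- ape::nodepath(topo, match(lab[i], topo$tip.label),
                         match(lab[j], topo$tip.label))
      for (k in seq_len(length(p) - 1)) {
        e <- which(topo$edge[, 1] %in% p[c(k, k + 1)] &
                     topo$edge[, 2] %in% p[c(k, k + 1)])
        paths[r, e] <- 1
      }
    }
    fit <- lm.fit(paths, y)
    sum(fit$residuals^2)
  }
  all6 <- phangorn::allTrees(6, rooted = FALSE, tip.label = lab)
  rss <- vapply(all6, fitRSS, numeric(1))
  best <- all6[[which.min(rss)]]
  expect_equal(ape::dist.topo(best, neighborJoining(D)), 0,
               ignore_attr = TRUE)
})

test_that("neighbor joining is deterministic and label-stable under row permutation", {
  set.seed(29)
  true <- ape::rtree(7, rooted = FALSE, br = function(k) runif(k, 0.5, 2))
  D <- ape::cophenetic.phylo(true)
  perm <- sample(rownames(D))
  t1 <- neighborJoining(D)
  t2 <- neighborJoining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  # an equidistant (fully tied) matrix resolves deterministically
  E <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(E) <- 0
  e1 <- neighborJoining(E)
  e2 <- neighborJoining(E[c(3, 1, 5, 2, 4), c(3, 1, 5, 2, 4)])
  expect_equal(ape::dist.topo(e1, e2), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports are reproducible and high for clean splits", {
  arch <- twoCloneArch("S1", f1 = 0.5, f2 = 0.4, nonTumor = 0.1)
  cat <- smallCatalog("S1", c("1" = 40L, "2" = 40L), 0L, 0L, 0L)
  sim <- simulateCells(arch, cat, cleanNoise(seqError = 0), nCells = 10,
                       seed = 61)
  # need both clones present for a split to exist
  expect_gte(sum(sim$clone == "clone2"), 2L)
  gm <- callMatrix(sim$counts)
  bs1 <- bootstrapSupport(gm, nIter = 100, seed = 5)
  bs2 <- bootstrapSupport(gm, nIter = 100, seed = 5)
  expect_identical(bs1$support, bs2$support)
  expect_identical(ape::write.tree(bs1$tree), ape::write.tree(bs2$tree))
  # the clone-1 vs clone-2 bipartition is strongly supported
  expect_true(any(bs1$strong))
  expect_gt(max(bs1$support, na.rm = TRUE), 90)

  # cell-order invariance up to relabeling
  m <- genotypeCalls(gm)
  permuted <- gmOf(m[rev(rownames(m)), ])
  bs3 <- bootstrapSupport(permuted, nIter = 100, seed = 5)
  expect_equal(ape::dist.topo(bs1$tree, bs3$tree), 0, ignore_attr = TRUE)
  expect_equal(sort(bs1$support), sort(bs3$support))

  expect_error(bootstrapSupport(gm, nIter = 0, seed = 1), "positive")
})

test_that("random-genotype matrices yield mostly weak bootstrap support", {
  set.seed(71)
  m <- matrix(sample(c(0L, 1L), 10 * 80, TRUE), 10, 80,
              dimnames = list(sprintf("c%02d", 1:10),
                              sprintf("L%03d", 1:80)))
  bs <- bootstrapSupport(gmOf(m), nIter = 100, seed = 2)
  expect_lt(mean(bs$strong), 0.5)
})

test_that("the two-state pruning likelihood matches closed forms", {
  # zero-length star tree, identical rows: stationary prior only
  m <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), 3), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), sprintf("L%d", 1:5)))
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  expect_equal(twoStateLogLik(gmOf(m), star), 5 * log(0.5))

  # two leaves, one site, same state: lik = 0.5((1-q)^2 + q^2)
  m2 <- matrix(c(0L, 0L), 2, 1, dimnames = list(c("a", "b"), "L1"))
  for (t in c(0.1, 1, 5)) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t / 2, t / 2))
    q <- (1 - exp(-2 * (t / 2))) / 2
    # closed form: 0.5[(1-q)^2 + q^2] summed over the two root states
    expect_equal(twoStateLogLik(gmOf(m2), tr),
                 log(0.5 * ((1 - q)^2 + q^2)))
  }
  # infinitely long branches: states independent, lik -> 1/4 per site
  trInf <- ape::read.tree(text = "(a:50,b:50);")
  expect_equal(twoStateLogLik(gmOf(m2), trInf), log(0.25),
               tolerance = 1e-8)

  # an all-missing matrix is fully marginalized
  m3 <- matrix(NA_integer_, 3, 4,
               dimnames = list(c("a", "b", "c"), sprintf("L%d", 1:4)))
  tr3 <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_equal(twoStateLogLik(gmOf(m3), tr3), 0)
  expect_error(twoStateLogLik(gmOf(m), ape::read.tree(text = "(a:1,x:1,c:1);")),
               "match")
})

test_that("the pruning likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(83)
  tr <- ape::rtree(5, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  m <- matrix(sample(c(0L, 1L), 5 * 30, TRUE), 5, 30,
              dimnames = list(tr$tip.label, sprintf("L%02d", 1:30)))
  states <- matrix(as.character(m), 5, dimnames = dimnames(m))
  dat <- phangorn::phyDat(states, type = "USER", levels = c("0", "1"))
  fit <- phangorn::pml(tr, dat)
  expect_equal(twoStateLogLik(gmOf(m), tr), as.numeric(fit$logLik),
               tolerance = 1e-6)
})
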