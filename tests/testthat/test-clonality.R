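# five-cluster linear architecture for constructed-profile tests
fiveClusterArch <- function() {
  buildArchitecture("S5",
    data.frame(id = paste0("clone", 1:5), parent = c(NA, paste0("clone", 1:4)),
               frequency = c(0.06, 0.04, 0.33, 0.33, 0.14),
               cluster = as.character(1:5)),
    nonTumorFraction = 0.10)
}

fiveClusterCatalog <- function(perCluster = 4L) {
  makeLocusCatalog("S5", setNames(rep(perCluster, 5), as.character(1:5)))
}

# constructed genotype matrix: each cell carries clusters 1..k at the
# given detection level
profileMatrix <- function(cat, carried, detect = 1) {
  lo <- loci(cat)
  cells <- names(carried)
  m <- matrix(0L, length(cells), nrow(lo),
              dimnames = list(cells, lo$locus_id))
  for (cell in cells) {
    for (cc in carried[[cell]]) {
      ids <- lo$locus_id[lo$cluster == cc]
      nVar <- round(detect * length(ids))
      if (nVar > 0) m[cell, ids[seq_len(nVar)]] <- 1L
    }
  }
  m
}

test_that("cells are assigned the deepest consistently observed cluster", {
  arch <- fiveClusterArch()
  cat <- fiveClusterCatalog()
  m <- profileMatrix(cat, list(
    cellA = as.character(1:3),     # clusters 1-3 -> clone 3
    cellB = as.character(1:5),     # everything -> clone 5
    cellC = character()            # no variant calls -> non-tumor
  ), detect = 0.8)
  res <- assignCells(gmOf(m), cat, arch)
  asn <- res$assignments
  expect_equal(asn$clone[asn$cell_id == "cellA"], "clone3")
  expect_equal(asn$clone[asn$cell_id == "cellB"], "clone5")
  expect_equal(asn$clone[asn$cell_id == "cellC"], "non-tumor")
  expect_false(any(asn$inconsistent))

  # a lineage gap (cluster 3 without cluster 2) is flagged, not forced
  gap <- profileMatrix(cat, list(cellG = c("1", "3")), detect = 1)
  resGap <- assignCells(gmOf(gap), cat, arch)
  expect_true(resGap$assignments$inconsistent)
  expect_equal(resGap$assignments$clone, "clone1")
  expect_error(assignCells(gmOf(matrix(integer(), 0, 0)), cat, arch))
})

test_that("assignment recovers every true clone on noise-free simulations", {
  arch <- twoCloneArch("S1")
  cat <- smallCatalog("S1")
  sim <- simulateCells(arch, cat, cleanNoise(seqError = 0), nCells = 15,
                       seed = 33)
  res <- assignCells(callMatrix(sim$counts), cat, arch)
  expect_identical(setNames(res$assignments$clone,
                            res$assignments$cell_id), sim$clone)
  # clone frequencies from assignments sum to one
  expect_equal(sum(cloneFrequencies(res$assignments)), 1)
})

test_that("clone recovery tolerates study-level allelic dropout", {
  arch <- fiveClusterArch()
  cat <- makeLocusCatalog("S5", setNames(rep(30L, 5), as.character(1:5)))
  noise <- deepNoise(adoProb = 0.24, seqError = 0.01)
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    sim <- simulateCells(arch, cat, noise, nCells = 8, seed = 400 + s)
    res <- assignCells(callMatrix(sim$counts), cat, arch)
    got <- setNames(res$assignments$clone, res$assignments$cell_id)
    hits <- hits + sum(got == sim$clone)
    total <- total + length(got)
  }
  expect_gt(hits / total, 0.9)
})

test_that("reference-call excess separates substructure blocks from scattered ADO", {
  arch <- fiveClusterArch()
  cat <- makeLocusCatalog("S5", c("1" = 10L, "2" = 10L, "3" = 10L,
                                  "4" = 20L, "5" = 10L))
  lo <- loci(cat)
  cells <- sprintf("c%02d", 1:10)
  # all cells are clone 4 carriers (clusters 1-4 variant)...
  m <- matrix(0L, 10, nrow(lo), dimnames = list(cells, lo$locus_id))
  m[, lo$locus_id[lo$cluster %in% as.character(1:4)]] <- 1L
  # ...but a 5-SNV block in cluster 4 is reference in cells 1-6, far
  # beyond what stochastic dropout at FNR 0.12 explains
  block <- lo$locus_id[lo$cluster == "4"][1:5]
  m[1:6, block] <- 0L
  res0 <- assignCells(gmOf(m), cat, arch)
  rep <- referenceCallExcess(gmOf(m), res0$assignments, cat, arch,
                             fnrEst = 0.12)
  expect_gte(nrow(rep$substructure), 1L)
  expect_equal(rep$substructure$cluster[1], "4")
  expect_equal(rep$substructure$n_loci[1], 5L)

  # a matrix whose reference calls sit exactly at the FNR is not flagged
  set.seed(8)
  m2 <- matrix(0L, 10, nrow(lo), dimnames = list(cells, lo$locus_id))
  carrier <- lo$locus_id[lo$cluster %in% as.character(1:4)]
  m2[, carrier] <- 1L
  drop <- matrix(runif(10 * length(carrier)) < 0.12, 10)
  m2[, carrier][drop] <- 0L
  res2 <- assignCells(gmOf(m2), cat, arch)
  rep2 <- referenceCallExcess(gmOf(m2), res2$assignments, cat, arch,
                              fnrEst = 0.12)
  expect_equal(nrow(rep2$substructure), 0L)
  # per-cell tests are uncorrected, so allow the occasional 5% flag
  expect_lte(sum(rep2$perCell$excess), 1L)

  # per-cell p-value is the exact upper binomial tail
  pc <- rep2$perCell[1, ]
  expect_equal(pc$p_value,
               pbinom(pc$n_reference - 1, pc$n_callable, 0.12,
                      lower.tail = FALSE))
})

test_that("reference-rate comparison uses the exact binomial tail", {
  # observed 0.15 vs FNR 0.12 at n = 200 sites
  p <- pbinom(30 - 1, 200, 0.12, lower.tail = FALSE)
  expect_equal(p, sum(dbinom(30:200, 200, 0.12)))
  expect_gt(p, 0.05)   # not an excess at this sample size
})

test_that("mutually exclusive variant sets are detected as branch points", {
  # one bulk cluster ("2") hides an exclusive 4/4 SNV split across cells
  arch <- twoCloneArch("S1")
  cat <- smallCatalog("S1", c("1" = 6L, "2" = 8L), 0L, 0L, 0L)
  lo <- loci(cat)
  cells <- sprintf("c%02d", 1:4)
  m <- matrix(0L, 4, nrow(lo), dimnames = list(cells, lo$locus_id))
  m[, lo$locus_id[lo$cluster == "1"]] <- 1L
  c2 <- lo$locus_id[lo$cluster == "2"]
  sideA <- c2[1:4]
  sideB <- c2[5:8]
  m[1:2, sideA] <- 1L
  m[3:4, sideB] <- 1L
  asn <- assignCells(gmOf(m), cat, arch)$assignments
  expect_true(all(asn$clone == "clone2"))   # every cell carries cluster 2
  br <- detectBranches(gmOf(m), asn, cat, arch, fnrEst = 0.12,
                       lociUse = c2)
  expect_equal(nrow(br), 1L)
  expect_setequal(strsplit(br$cells_a[1], ",")[[1]], c("c01", "c02"))
  expect_setequal(strsplit(br$cells_b[1], ",")[[1]], c("c03", "c04"))
  expect_setequal(strsplit(br$side_a[1], ",")[[1]], sideA)
  expect_setequal(strsplit(br$side_b[1], ",")[[1]], sideB)

  # one supporting cell per side fails the min-cells rule
  m1 <- m
  m1[2, sideA] <- 0L
  m1[4, sideB] <- 0L
  asn1 <- assignCells(gmOf(m1), cat, arch)$assignments
  br1 <- detectBranches(gmOf(m1), asn1, cat, arch, fnrEst = 0.4,
                        lociUse = c2)
  expect_equal(nrow(br1), 0L)
})

test_that("branch detection recovers a simulated branching architecture", {
  # truth branches (2a vs 2b) but the analysis model collapses them into
  # one bulk cluster "2": the detector must rediscover the split
  truthArch <- branchedArch("SB")
  truthCat <- makeLocusCatalog("SB", c("1" = 10L, "2a" = 10L, "2b" = 10L))
  sim <- simulateCells(truthArch, truthCat, cleanNoise(seqError = 0),
                       nCells = 14, seed = 55)
  # seed chosen so both branch sides carry multiple cells
  expect_gte(sum(sim$clone == "clone2a"), 2L)
  expect_gte(sum(sim$clone == "clone2b"), 2L)

  nullArch <- twoCloneArch("SB", f1 = 0.2, f2 = 0.7, nonTumor = 0.1)
  lo <- loci(truthCat)
  lo$cluster[lo$cluster %in% c("2a", "2b")] <- "2"
  nullCat <- new("LocusCatalog", loci = lo)

  gm <- callMatrix(sim$counts)
  asn <- assignCells(gm, nullCat, nullArch)
  br <- detectBranches(gm, asn$assignments, nullCat, nullArch,
                       fnrEst = 0.12,
                       lociUse = lo$locus_id[lo$cluster == "2"])
  expect_gte(nrow(br), 1L)
  sides <- c(br$side_a[1], br$side_b[1])
  trueLo <- loci(truthCat)
  clustersOf <- function(s) unique(trueLo$cluster[match(
    strsplit(s, ",")[[1]], trueLo$locus_id)])
  expect_setequal(unlist(lapply(sides, clustersOf)), c("2a", "2b"))
})

test_that("outlier SNVs are rescued only on unambiguous ADO-tolerant matches", {
  arch <- fiveClusterArch()
  cat <- fiveClusterCatalog()
  lo <- loci(cat)
  cells <- sprintf("c%02d", 1:8)
  carried <- setNames(lapply(c(1, 2, 3, 3, 4, 4, 5, 5),
                             function(k) as.character(seq_len(k))), cells)
  m <- profileMatrix(cat, carried, detect = 1)
  asn <- assignCells(gmOf(m), cat, arch)$assignments

  addCol <- function(m, id, values) {
    m2 <- cbind(m, values)
    colnames(m2)[ncol(m2)] <- id
    m2
  }
  # outlier variant exactly in cluster-4 carriers -> assigned cluster 4
  inClust4 <- vapply(cells, function(cl) "4" %in% carried[[cl]], logical(1))
  m1 <- addCol(m, "out1", ifelse(inClust4, 1L, 0L))
  r1 <- rescueOutliers(gmOf(m1), asn, "out1", arch, fnrEst = 0.12)
  expect_equal(r1$cluster, "4")
  expect_equal(r1$reason, "assigned")

  # callable in only 2 cells: insufficient information
  v <- rep(NA_integer_, 8); v[7:8] <- 1L
  m2 <- addCol(m, "out2", v)
  r2 <- rescueOutliers(gmOf(m2), asn, "out2", arch, fnrEst = 0.12)
  expect_true(is.na(r2$cluster))
  expect_equal(r2$reason, "insufficient_information")

  # no informative cell separates clusters 4 and 5 -> ambiguous
  asn45 <- asn[asn$clone %in% c("clone3", "clone5"), ]
  m3 <- m[asn45$cell_id, ]
  in5 <- asn45$clone == "clone5"
  m3 <- addCol(m3, "out3", ifelse(in5, 1L, 0L))
  # mask cluster-4-only cells so nothing separates 4 from 5
  r3 <- rescueOutliers(gmOf(m3), asn45, "out3", arch, fnrEst = 0.12)
  expect_equal(r3$reason, "ambiguous")
  expect_true(is.na(r3$cluster))

  # hard constraint: a variant call in a non-carrier cell disqualifies
  bad <- ifelse(inClust4, 1L, 0L)
  bad[1] <- 1L    # clone-1 cell shows the variant
  m4 <- addCol(m, "out4", bad)
  r4 <- rescueOutliers(gmOf(m4), asn, "out4", arch, fnrEst = 0.9)
  expect_false(identical(r4$cluster, "4"))
})

test_that("clone frequency concordance computes matched R squared", {
  x <- c(a = 0.4, b = 0.25, c = 0.1)
  expect_equal(cloneFrequencyConcordance(2 * x, x)$r2, 1)
  expect_error(cloneFrequencyConcordance(x[1:2], x[1:2]), "at least 3")
  expect_error(cloneFrequencyConcordance(c(a = 1, b = 1, c = 1), x),
               "zero variance")
  got <- cloneFrequencyConcordance(c(a = 0.5, b = 0.3, c = 0.05, zzz = 1),
                                   x)
  expect_equal(got$n, 3L)
  expect_equal(got$r2, cor(c(0.5, 0.3, 0.05), c(0.4, 0.25, 0.1))^2)
})
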