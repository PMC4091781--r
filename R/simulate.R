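# Simulation of clonal architectures and single-cell targeted sequencing
# with whole-genome-amplification (WGA) artifacts: allelic dropout (ADO),
# locus dropout, overdispersed coverage and sequencing miscalls.

#' WgaNoiseModel: the single-cell amplification/sequencing noise model
#'
#' Parameters of the WGA artifact model used by [simulateCells()] and
#' [simulateMultiplet()]. Allelic dropout removes one allele of a
#' heterozygous pair before read sampling (whole-allele loss, so a het
#' site can appear homozygous); coverage is drawn from a zero-inflated
#' negative binomial; reads are then miscalled at a fixed per-read rate.
#'
#' @slot adoProb per-(cell, locus) probability that one allele of a het
#'   pair drops out; default 0.24 so that about half of dropouts silence
#'   the variant allele, giving a het-site false-negative rate near 0.12.
#' @slot seqError per-read miscall probability; default 0.01.
#' @slot depthMean mean on-target coverage; default 113.
#' @slot depthDispersion negative-binomial size parameter; default 0.45,
#'   chosen with the default locus dropout so ~55% of loci reach 25x.
#' @slot locusDropoutProb probability a locus yields zero coverage in a
#'   cell (failed amplification); default 0.10.
#' @slot locusEffectSD standard deviation (log scale) of an optional
#'   per-locus ADO multiplier shared across cells; default 0 (dropout
#'   i.i.d. per cell and locus).
#' @export
setClass("WgaNoiseModel",
  representation(
    adoProb = "numeric", seqError = "numeric", depthMean = "numeric",
    depthDispersion = "numeric", locusDropoutProb = "numeric",
    locusEffectSD = "numeric"
  )
)

setValidity("WgaNoiseModel", function(object) {
  pr <- c(ado = object@adoProb, seq = object@seqError,
          locus = object@locusDropoutProb)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@depthMean <= 0) return("depthMean must be > 0")
  if (object@depthDispersion <= 0) return("depthDispersion must be > 0")
  if (object@locusEffectSD < 0) return("locusEffectSD must be >= 0")
  TRUE
})

#' Construct a WGA noise model
#'
#' @param adoProb,seqError,depthMean,depthDispersion,locusDropoutProb,locusEffectSD
#'   see [WgaNoiseModel-class] for meanings and defaults.
#' @return a validated [WgaNoiseModel-class] object.
#' @examples
#' wgaNoiseModel()                       # study-like defaults
#' wgaNoiseModel(adoProb = 0, seqError = 0)  # noise-free
#' @export
wgaNoiseModel <- function(adoProb = 0.24, seqError = 0.01, depthMean = 113,
                          depthDispersion = 0.45, locusDropoutProb = 0.10,
                          locusEffectSD = 0) {
  new("WgaNoiseModel", adoProb = adoProb, seqError = seqError,
      depthMean = depthMean, depthDispersion = depthDispersion,
      locusDropoutProb = locusDropoutProb, locusEffectSD = locusEffectSD)
}

#' Build and validate a clonal architecture
#'
#' @param subject subject identifier.
#' @param clones data.frame (or coercible) with columns \code{id},
#'   \code{parent} (NA for the founding clone), \code{frequency},
#'   \code{cluster}.
#' @param nonTumorFraction fraction of non-tumor (wild-type) cells.
#' @return a validated [ClonalArchitecture-class]; invalid specifications
#'   (frequency sums away from 1, cyclic parentage, multiple roots) are
#'   rejected with an error.
#' @examples
#' buildArchitecture("UPN182896",
#'   data.frame(id = c("clone1", "clone2"), parent = c(NA, "clone1"),
#'              frequency = c(0.13, 0.52), cluster = c("1", "2")),
#'   nonTumorFraction = 0.35)
#' @export
buildArchitecture <- function(subject, clones, nonTumorFraction) {
  clones <- as.data.frame(clones, stringsAsFactors = FALSE)
  clones$id <- as.character(clones$id)
  clones$parent <- as.character(clones$parent)
  clones$cluster <- as.character(clones$cluster)
  new("ClonalArchitecture", subject = as.character(subject), clones = clones,
      nonTumorFraction = as.numeric(nonTumorFraction))
}

# root-to-clone path of clone ids
.cloneLineage <- function(arch, cloneId) {
  cl <- arch@clones
  if (!cloneId %in% cl$id) stop("unknown clone: ", cloneId)
  path <- character()
  cur <- cloneId
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- cl$parent[match(cur, cl$id)]
  }
  path
}

# clusters carried by a clone (its own plus all ancestors')
.cloneClusters <- function(arch, cloneId) {
  if (identical(cloneId, "non-tumor")) return(character())
  cl <- arch@clones
  cl$cluster[match(.cloneLineage(arch, cloneId), cl$id)]
}

# clone introducing a cluster, plus all its descendants
.clusterCarriers <- function(arch, cluster) {
  cl <- arch@clones
  intro <- cl$id[match(as.character(cluster), cl$cluster)]
  if (is.na(intro)) stop("unknown cluster: ", cluster)
  carriers <- intro
  repeat {
    kids <- cl$id[!is.na(cl$parent) & cl$parent %in% carriers &
                    !(cl$id %in% carriers)]
    if (!length(kids)) break
    carriers <- c(carriers, kids)
  }
  carriers
}

#' Cumulative prevalence of a mutation cluster
#'
#' The fraction of all cells carrying a cluster's variants: the summed
#' frequency of the clone that introduced the cluster and all of its
#' descendants. Non-increasing from ancestor to descendant clusters.
#'
#' @param arch a [ClonalArchitecture-class].
#' @param cluster cluster label.
#' @return fraction in [0, 1].
#' @export
clusterPrevalence <- function(arch, cluster) {
  cl <- arch@clones
  sum(cl$frequency[cl$id %in% .clusterCarriers(arch, cluster)])
}

#' Expected bulk variant allele fraction of a cluster
#'
#' Under the heterozygous-diploid convention (every somatic SNV is het in
#' the cells that carry it), the expected VAF of a cluster in unsorted
#' material is half its cumulative prevalence.
#'
#' @inheritParams clusterPrevalence
#' @return expected VAF in [0, 0.5].
#' @examples
#' arch <- samlArchitectures()[["UPN182896"]]
#' expectedBulkVAF(arch, "1")  # (0.13 + 0.52) / 2
#' expectedBulkVAF(arch, "2")  # 0.52 / 2
#' @export
expectedBulkVAF <- function(arch, cluster) {
  clusterPrevalence(arch, cluster) / 2
}

#' The three secondary-AML architectures used throughout the package
#'
#' The bulk-predicted clonal models for the three study subjects: subject
#' UPN461282 with five nested subclones (6/4/33/33/14% of cells, clusters
#' 1-5) plus 10% non-tumor; UPN182896 with two subclones (13/52%, clusters
#' 1-2) plus 35% non-tumor; UPN288033 with two subclones (62/31%) plus 7%
#' non-tumor. Cluster-5 descent from clone 4 follows the single-cell
#' resolution of the originally ambiguous branch.
#'
#' @return named list of three [ClonalArchitecture-class] objects.
#' @export
samlArchitectures <- function() {
  list(
    UPN461282 = buildArchitecture("UPN461282",
      data.frame(
        id = paste0("clone", 1:5),
        parent = c(NA, paste0("clone", 1:4)),
        frequency = c(0.06, 0.04, 0.33, 0.33, 0.14),
        cluster = as.character(1:5)),
      nonTumorFraction = 0.10),
    UPN182896 = buildArchitecture("UPN182896",
      data.frame(id = c("clone1", "clone2"), parent = c(NA, "clone1"),
                 frequency = c(0.13, 0.52), cluster = c("1", "2")),
      nonTumorFraction = 0.35),
    UPN288033 = buildArchitecture("UPN288033",
      data.frame(id = c("clone1", "clone2"), parent = c(NA, "clone1"),
                 frequency = c(0.62, 0.31), cluster = c("1", "2")),
      nonTumorFraction = 0.07)
  )
}

#' Build a locus catalog for one subject
#'
#' @param subject subject identifier.
#' @param clusterSizes named integer vector: number of somatic SNVs per
#'   cluster label.
#' @param nGermlineHet,nGermlineHomRef,nGermlineHomVar numbers of germline
#'   SNP loci of each zygosity to include.
#' @param prefix prefix for locus ids (default the subject id).
#' @return a [LocusCatalog-class].
#' @export
makeLocusCatalog <- function(subject, clusterSizes, nGermlineHet = 0L,
                             nGermlineHomRef = 0L, nGermlineHomVar = 0L,
                             prefix = subject) {
  som <- data.frame(
    locus_id = character(), subject = character(), kind = character(),
    cluster = character(), stringsAsFactors = FALSE)
  if (length(clusterSizes)) {
    cluster <- rep(names(clusterSizes), clusterSizes)
    som <- data.frame(
      locus_id = sprintf("%s_c%s_s%03d", prefix, cluster,
                         unlist(lapply(clusterSizes, seq_len))),
      subject = subject, kind = "somatic_cluster", cluster = cluster,
      stringsAsFactors = FALSE)
  }
  germ <- function(kind, n, tag) {
    if (n == 0L) return(NULL)
    data.frame(locus_id = sprintf("%s_%s_%03d", prefix, tag, seq_len(n)),
               subject = subject, kind = kind, cluster = NA_character_,
               stringsAsFactors = FALSE)
  }
  lo <- rbind(som,
              germ("germline_het", nGermlineHet, "ghet"),
              germ("germline_homref", nGermlineHomRef, "gref"),
              germ("germline_homvar", nGermlineHomVar, "gvar"))
  new("LocusCatalog", loci = lo)
}

#' The study-shaped locus catalog
#'
#' Targeted loci matching the study's capture design: 1,953 validated
#' somatic SNVs split 872 / 777 / 304 across the three subjects, with
#' cluster 5 of UPN461282 held at its 60 targeted variants and remaining
#' loci divided evenly among each subject's other clusters. Germline SNP
#' counts per subject default to 200 heterozygous, 200 homozygous
#' reference and 50 homozygous variant loci for benchmarking.
#'
#' @param nGermlineHet,nGermlineHomRef,nGermlineHomVar germline SNP counts
#'   per subject.
#' @return a [LocusCatalog-class] covering all three subjects.
#' @examples
#' cat <- samlLocusCatalog()
#' sum(loci(cat)$kind == "somatic_cluster")  # 1953
#' @export
samlLocusCatalog <- function(nGermlineHet = 200L, nGermlineHomRef = 200L,
                             nGermlineHomVar = 50L) {
  sizes <- list(
    UPN461282 = c("1" = 203L, "2" = 203L, "3" = 203L, "4" = 203L, "5" = 60L),
    UPN182896 = c("1" = 389L, "2" = 388L),
    UPN288033 = c("1" = 152L, "2" = 152L)
  )
  parts <- lapply(names(sizes), function(s) {
    loci(makeLocusCatalog(s, sizes[[s]], nGermlineHet, nGermlineHomRef,
                          nGermlineHomVar))
  })
  new("LocusCatalog", loci = do.call(rbind, parts))
}

# truth genotype codes for one clone over a catalog (0/1/2)
.truthForClone <- function(arch, catalog, cloneId) {
  lo <- loci(catalog)
  carried <- .cloneClusters(arch, cloneId)
  g <- integer(nrow(lo))
  som <- lo$kind == "somatic_cluster" & lo$subject == arch@subject
  g[som & lo$cluster %in% carried] <- 1L
  g[lo$kind == "germline_het"] <- 1L
  g[lo$kind == "germline_homvar"] <- 2L
  names(g) <- lo$locus_id
  g
}

# post-ADO template state: het (1) drops to ref-only (0) or var-only (2)
# with probability d, the lost allele chosen uniformly
.applyAdo <- function(truth, adoProbs) {
  het <- which(truth == 1L)
  if (!length(het)) return(truth)
  drop <- stats::runif(length(het)) < adoProbs[het]
  lost <- het[drop]
  truth[lost] <- sample(c(0L, 2L), length(lost), replace = TRUE)
  truth
}

# zero-inflated negative-binomial depth draw
.drawDepth <- function(n, noise) {
  d <- stats::rnbinom(n, size = noise@depthDispersion, mu = noise@depthMean)
  d[stats::runif(n) < noise@locusDropoutProb] <- 0L
  d
}

# reads from a template allele state (f = state/2) with miscalls
.drawReads <- function(state, depth, seqError) {
  f <- state / 2
  p <- f * (1 - seqError) + (1 - f) * seqError
  k <- stats::rbinom(length(depth), depth, p)
  cbind(ref = depth - k, var = k)
}

# per-locus ADO probabilities, optionally modulated by shared factors
.locusAdoProbs <- function(noise, locusIds, locusFactors) {
  d <- rep(noise@adoProb, length(locusIds))
  names(d) <- locusIds
  if (!is.null(locusFactors)) {
    idx <- match(locusIds, names(locusFactors))
    fac <- ifelse(is.na(idx), 1, locusFactors[idx])
    d <- pmin(1, d * fac)
  }
  d
}

#' Simulate single cells with WGA artifacts
#'
#' Draws each cell's clone from the architecture's clone and non-tumor
#' frequencies, derives its truth genotype over the catalog (a somatic
#' locus is het iff the cell's clone lineage includes the cluster's
#' introducing clone; germline loci follow their zygosity), then applies
#' allelic dropout at het loci, draws coverage from the zero-inflated
#' negative-binomial depth model, and miscalls reads at the sequencing
#' error rate. Deterministic given \code{seed}.
#'
#' @param arch a [ClonalArchitecture-class].
#' @param catalog a [LocusCatalog-class]; every subject's somatic loci
#'   are simulated (other subjects' SNVs are reference in these cells,
#'   providing mutual error controls), plus this subject's germline loci.
#' @param noise a [WgaNoiseModel-class].
#' @param nCells number of cells to simulate (>= 1).
#' @param seed integer seed.
#' @param cellIds optional character vector of cell ids.
#' @param locusFactors optional named per-locus ADO multipliers (shared
#'   locus effects); loci absent from the vector keep the base rate.
#' @return list with elements \code{truth} (integer matrix cells x loci,
#'   codes 0/1/2, pre-dropout), \code{clone} (assigned clone per cell,
#'   \code{"non-tumor"} for wild-type cells) and \code{counts}
#'   (a [ReadCountTable-class]).
#' @examples
#' arch <- samlArchitectures()[["UPN288033"]]
#' cat <- makeLocusCatalog("UPN288033", c("1" = 40, "2" = 40),
#'                         nGermlineHet = 20)
#' sim <- simulateCells(arch, cat, wgaNoiseModel(), nCells = 4, seed = 7)
#' table(sim$clone)
#' @export
simulateCells <- function(arch, catalog, noise = wgaNoiseModel(), nCells,
                          seed, cellIds = NULL, locusFactors = NULL) {
  stopifnot(nCells >= 1)
  lo <- loci(catalog)
  # the capture panel spans all subjects' somatic loci; other subjects'
  # SNVs are reference in these cells (they serve as mutual controls).
  # germline SNP loci are subject-specific.
  keep <- lo$kind == "somatic_cluster" | lo$subject == arch@subject
  lo <- lo[keep, , drop = FALSE]
  sub <- new("LocusCatalog", loci = lo)
  if (is.null(cellIds)) {
    cellIds <- sprintf("%s_cell%02d", arch@subject, seq_len(nCells))
  }
  stopifnot(length(cellIds) == nCells)

  seeds <- .childSeeds(seed, 3L)
  cl <- arch@clones
  pool <- c(cl$id, "non-tumor")
  probs <- c(cl$frequency, arch@nonTumorFraction)

  set.seed(seeds[1L])
  assigned <- sample(pool, nCells, replace = TRUE, prob = probs)

  if (noise@locusEffectSD > 0 && is.null(locusFactors)) {
    set.seed(seeds[2L])
    locusFactors <- stats::setNames(
      exp(stats::rnorm(nrow(lo), -noise@locusEffectSD^2 / 2,
                       noise@locusEffectSD)),
      lo$locus_id)
  }
  adoProbs <- .locusAdoProbs(noise, lo$locus_id, locusFactors)

  truth <- matrix(NA_integer_, nCells, nrow(lo),
                  dimnames = list(cellIds, lo$locus_id))
  rows <- vector("list", nCells)
  set.seed(seeds[3L])
  for (i in seq_len(nCells)) {
    g <- .truthForClone(arch, sub, assigned[i])
    truth[i, ] <- g
    state <- .applyAdo(g, adoProbs)
    depth <- .drawDepth(length(g), noise)
    reads <- .drawReads(state, depth, noise@seqError)
    rows[[i]] <- data.frame(
      sample_id = cellIds[i], locus_id = lo$locus_id,
      ref_reads = reads[, "ref"], var_reads = reads[, "var"],
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(truth = truth, clone = stats::setNames(assigned, cellIds),
       counts = new("ReadCountTable", counts = counts))
}

#' Simulate bulk (unsorted) read counts
#'
#' Variant reads at each locus are binomially sampled around the
#' architecture's expected bulk VAF, perturbed by the per-read error
#' rate; germline loci use their zygosity VAF (0, 0.5, or 1).
#'
#' @inheritParams simulateCells
#' @param depth read depth applied to every locus (0 yields (0, 0)
#'   entries).
#' @param seqError per-read miscall rate.
#' @param sampleId sample identifier in the output table.
#' @return a [ReadCountTable-class] with one row per locus.
#' @export
simulateBulkCounts <- function(arch, catalog, depth, seed, seqError = 0.01,
                               sampleId = paste0(arch@subject, "_bulk")) {
  stopifnot(depth >= 0)
  lo <- loci(catalog)
  keep <- lo$kind != "somatic_cluster" | lo$subject == arch@subject
  lo <- lo[keep, , drop = FALSE]
  f <- numeric(nrow(lo))
  som <- lo$kind == "somatic_cluster"
  if (any(som)) {
    f[som] <- vapply(lo$cluster[som], function(cc) expectedBulkVAF(arch, cc),
                     numeric(1))
  }
  f[lo$kind == "germline_het"] <- 0.5
  f[lo$kind == "germline_homvar"] <- 1
  p <- f * (1 - seqError) + (1 - f) * seqError
  set.seed(seed)
  k <- stats::rbinom(nrow(lo), depth, p)
  new("ReadCountTable", counts = data.frame(
    sample_id = sampleId, locus_id = lo$locus_id,
    ref_reads = depth - k, var_reads = k, stringsAsFactors = FALSE))
}

#' Simulate a two-cell (doublet) sample
#'
#' Pools the allele templates of two cells (four alleles per locus) and
#' amplifies them with the same WGA noise model. With equal amplification
#' weights, loci heterozygous in exactly one of the two cells have
#' expected VAF 0.25 (the two-cell dilution), loci het in both stay at
#' 0.5, and loci variant in neither stay near the error rate.
#'
#' @param truthA,truthB named integer truth vectors (codes 0/1/2) over the
#'   same loci, e.g. rows of the \code{truth} matrix from
#'   [simulateCells()].
#' @param noise a [WgaNoiseModel-class].
#' @param seed integer seed.
#' @param weightA amplification weight of cell A (default 0.5, equal
#'   amplification).
#' @param sampleId sample identifier.
#' @param locusFactors optional shared per-locus ADO multipliers.
#' @return a [ReadCountTable-class] with one row per locus.
#' @export
simulateMultiplet <- function(truthA, truthB, noise = wgaNoiseModel(), seed,
                              weightA = 0.5, sampleId = "twocell",
                              locusFactors = NULL) {
  stopifnot(identical(names(truthA), names(truthB)),
            weightA >= 0, weightA <= 1)
  adoProbs <- .locusAdoProbs(noise, names(truthA), locusFactors)
  set.seed(seed)
  stateA <- .applyAdo(truthA, adoProbs)
  stateB <- .applyAdo(truthB, adoProbs)
  f <- weightA * stateA / 2 + (1 - weightA) * stateB / 2
  p <- f * (1 - noise@seqError) + (1 - f) * noise@seqError
  depth <- .drawDepth(length(f), noise)
  k <- stats::rbinom(length(f), depth, p)
  new("ReadCountTable", counts = data.frame(
    sample_id = sampleId, locus_id = names(truthA),
    ref_reads = depth - k, var_reads = k, stringsAsFactors = FALSE,
    row.names = NULL))
}
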