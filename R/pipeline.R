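# End-to-end driver: simulate -> call -> cellularity -> clonality ->
# phylogeny for each subject, with a reproducible manifest.

.configDefaults <- function() {
  list(
    seed = 1L,
    subjects = c("UPN461282", "UPN182896", "UPN288033"),
    simulate = list(nCells = 12L, nDoublets = 2L, adoProb = 0.24,
                    seqError = 0.01, depthMean = 113,
                    depthDispersion = 0.45, locusDropoutProb = 0.10,
                    locusEffectSD = 0, bulkDepth = 500L,
                    nGermlineHet = 200L, nGermlineHomRef = 200L,
                    nGermlineHomVar = 50L),
    call = list(minDepth = 25, seqError = 0.01, minVarReads = 3L),
    cellularity = list(alpha = 0.05),
    clonality = list(tauDetect = 0.5, minCallable = 3L, alpha = 0.05,
                     minBranchCells = 2L),
    phylo = list(bootstrapIter = 200L, minShared = 20)
  )
}

#' Build a validated pipeline run configuration
#'
#' Merges the supplied values over the defaults; unknown keys at either
#' level are rejected so that typos never silently fall back to a
#' default. The configuration round-trips losslessly through JSON.
#'
#' @param ... named top-level entries (\code{seed}, \code{subjects}) or
#'   named lists for the per-stage blocks \code{simulate}, \code{call},
#'   \code{cellularity}, \code{clonality}, \code{phylo}.
#' @return a named list of class \code{clonalRunConfig}.
#' @examples
#' cfg <- runConfig(seed = 7, simulate = list(nCells = 6))
#' cfg$simulate$nCells
#' @export
runConfig <- function(...) {
  user <- list(...)
  cfg <- .configDefaults()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(cfg[[key]])) {
      bad <- setdiff(names(user[[key]]), names(cfg[[key]]))
      if (length(bad)) stop("unknown key(s) in block '", key, "': ",
                            paste(bad, collapse = ", "))
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  if (cfg$simulate$nCells < 1) stop("simulate$nCells must be >= 1")
  if (cfg$phylo$bootstrapIter < 1) stop("phylo$bootstrapIter must be >= 1")
  structure(cfg, class = "clonalRunConfig")
}

#' Read / write a run configuration as JSON
#'
#' @param path file path.
#' @return [readRunConfigJSON()] returns a validated configuration;
#'   unknown keys in the file are rejected.
#' @export
readRunConfigJSON <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(runConfig, raw)
}

#' @rdname readRunConfigJSON
#' @param config a configuration from [runConfig()].
#' @export
writeRunConfigJSON <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeRunConfigJSON(config, tmp)
  unname(tools::md5sum(tmp))
}

# FNR at germline het sites from a benchmark report, with a floor so a
# zero estimate never collapses the branch-point null
.hetFNR <- function(report, floor = 0.01) {
  byz <- report@byZygosity
  fnr <- byz$FNR[byz$zygosity == "het"]
  if (length(fnr) != 1L || is.na(fnr)) fnr <- 0.12
  max(fnr, floor)
}

#' Run the full single-cell clonality validation pipeline
#'
#' For every configured subject: simulates single cells and intentionally
#' cross-contaminated two-cell samples under the WGA noise model, calls
#' genotypes with the coverage gate, benchmarks calls at germline SNPs,
#' classifies every sample's cellularity with the binomial
#' likelihood-ratio test (error rates estimated from the other subjects'
#' cells), assigns cells to clones, screens for reference-call excess and
#' mutually exclusive branch points, and reconstructs the cell phylogeny
#' with bootstrap support. Finally compares single-cell clone frequencies
#' with the simulated bulk cluster VAFs across subjects. All randomness
#' descends deterministically from \code{config$seed}; identical
#' configurations give identical outputs.
#'
#' @param config a configuration from [runConfig()].
#' @param outDir output directory; created if absent. On any stage
#'   failure the partial outputs written by this run are removed and the
#'   error is re-thrown with the stage name.
#' @return invisibly, a list with per-subject results
#'   (\code{benchmark}, \code{cellularity}, \code{assignments},
#'   \code{branches}, \code{tree}, ...), the cross-subject
#'   \code{concordance} and the \code{manifest}.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "clonalRunConfig"))
  created <- !dir.exists(outDir)
  if (created) dir.create(outDir, recursive = TRUE)
  written <- character()
  emit <- function(path) {
    written[[length(written) + 1L]] <<- path
    path
  }
  stage <- "setup"
  result <- tryCatch({
    archs <- samlArchitectures()[config$subjects]
    if (anyNA(names(archs))) stop("unknown subject(s) in roster")
    simcfg <- config$simulate
    catalog <- samlLocusCatalog(simcfg$nGermlineHet, simcfg$nGermlineHomRef,
                                simcfg$nGermlineHomVar)
    noise <- wgaNoiseModel(simcfg$adoProb, simcfg$seqError, simcfg$depthMean,
                           simcfg$depthDispersion, simcfg$locusDropoutProb,
                           simcfg$locusEffectSD)
    seeds <- matrix(.childSeeds(config$seed, 6L * length(archs)),
                    nrow = length(archs))
    rownames(seeds) <- names(archs)

    stage <- "simulate"
    sims <- list()
    for (s in names(archs)) {
      sim <- simulateCells(archs[[s]], catalog, noise, simcfg$nCells,
                           seed = seeds[s, 1L])
      doublets <- list()
      if (simcfg$nDoublets > 0L) {
        dseeds <- .childSeeds(seeds[s, 2L], 2L * simcfg$nDoublets)
        for (k in seq_len(simcfg$nDoublets)) {
          pair <- simulateCells(archs[[s]], catalog, noise, 2L,
                                seed = dseeds[2L * k - 1L],
                                cellIds = paste0(s, c("_dA", "_dB")))
          doublets[[k]] <- simulateMultiplet(
            pair$truth[1L, ], pair$truth[2L, ], noise,
            seed = dseeds[2L * k],
            sampleId = sprintf("%s_twocell%d", s, k))
        }
      }
      bulk <- simulateBulkCounts(archs[[s]], catalog, simcfg$bulkDepth,
                                 seed = seeds[s, 3L],
                                 seqError = simcfg$seqError)
      sims[[s]] <- list(cells = sim, doublets = doublets, bulk = bulk)
      writeCountsTSV(sim$counts, emit(file.path(outDir,
        sprintf("%s_cell_counts.tsv", s))))
    }

    stage <- "genotype"
    calls <- list()
    benchmarks <- list()
    for (s in names(archs)) {
      combined <- rbind(readCounts(sims[[s]]$cells$counts),
                        do.call(rbind, lapply(sims[[s]]$doublets,
                                              readCounts)))
      gm <- callMatrix(new("ReadCountTable", counts = combined),
                       config$call$minDepth, config$call$seqError,
                       config$call$minVarReads)
      singles <- rownames(sims[[s]]$cells$truth)
      gmCells <- new("GenotypeMatrix",
                     calls = genotypeCalls(gm)[singles, , drop = FALSE],
                     callableThreshold = gm@callableThreshold)
      calls[[s]] <- list(all = gm, cells = gmCells)
      benchmarks[[s]] <- benchmarkCalls(gmCells, sims[[s]]$cells$truth)
      writeGenotypeTSV(gmCells, emit(file.path(outDir,
        sprintf("%s_genotypes.tsv", s))))
    }

    stage <- "cellularity"
    cellularity <- list()
    for (s in names(archs)) {
      others <- setdiff(names(archs), s)
      controls <- do.call(rbind, lapply(others, function(o) {
        readCounts(sims[[o]]$cells$counts)
      }))
      err <- estimateErrorProfile(
        new("ReadCountTable", counts = controls), catalog, s)
      allCounts <- rbind(readCounts(sims[[s]]$cells$counts),
                         do.call(rbind, lapply(sims[[s]]$doublets,
                                               readCounts)))
      tab <- cellularityTable(new("ReadCountTable", counts = allCounts),
                              archs[[s]], catalog, err,
                              config$cellularity$alpha)
      cellularity[[s]] <- list(errorProfile = err, table = tab)
      utils::write.table(tab, emit(file.path(outDir,
        sprintf("%s_cellularity.tsv", s))), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }

    stage <- "clonality"
    clonality <- list()
    for (s in names(archs)) {
      asn <- assignCells(calls[[s]]$cells, catalog, archs[[s]],
                         config$clonality$tauDetect,
                         config$clonality$minCallable)
      fnr <- .hetFNR(benchmarks[[s]])
      excess <- referenceCallExcess(calls[[s]]$cells, asn$assignments,
                                    catalog, archs[[s]], fnr,
                                    config$clonality$alpha)
      lo <- loci(catalog)
      somatic <- lo$locus_id[lo$subject == s &
                               lo$kind == "somatic_cluster"]
      branches <- detectBranches(calls[[s]]$cells, asn$assignments,
                                 catalog, archs[[s]], fnr,
                                 config$clonality$minBranchCells,
                                 config$clonality$alpha,
                                 lociUse = somatic)
      clonality[[s]] <- list(assignments = asn, fnr = fnr,
                             excess = excess, branches = branches)
      utils::write.table(asn$assignments, emit(file.path(outDir,
        sprintf("%s_assignments.tsv", s))), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(branches, emit(file.path(outDir,
        sprintf("%s_branches.tsv", s))), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }

    stage <- "phylo"
    trees <- list()
    for (s in names(archs)) {
      lo <- loci(catalog)
      somatic <- lo$locus_id[lo$subject == s &
                               lo$kind == "somatic_cluster"]
      m <- genotypeCalls(calls[[s]]$cells)
      gmSom <- new("GenotypeMatrix",
                   calls = m[, intersect(colnames(m), somatic),
                             drop = FALSE],
                   callableThreshold = calls[[s]]$cells@callableThreshold)
      bs <- bootstrapSupport(gmSom, config$phylo$bootstrapIter,
                             seed = seeds[s, 4L],
                             minShared = config$phylo$minShared)
      trees[[s]] <- bs
      ape::write.tree(bs$tree, emit(file.path(outDir,
        sprintf("%s_tree.nwk", s))))
    }

    stage <- "concordance"
    scFreq <- numeric()
    bulkVAF <- numeric()
    for (s in names(archs)) {
      cl <- clones(archs[[s]])
      freqs <- cloneFrequencies(clonality[[s]]$assignments$assignments)
      bulkCt <- readCounts(sims[[s]]$bulk)
      lo <- loci(catalog)
      lo <- lo[lo$subject == s & lo$kind == "somatic_cluster", ]
      vafs <- .vaf(bulkCt)[match(lo$locus_id, bulkCt$locus_id)]
      for (i in seq_len(nrow(cl))) {
        key <- paste(s, cl$id[i], sep = ":")
        scFreq[key] <- if (cl$id[i] %in% names(freqs)) freqs[[cl$id[i]]]
                       else 0
        bulkVAF[key] <- mean(vafs[lo$cluster == cl$cluster[i]],
                             na.rm = TRUE)
      }
    }
    concordance <- cloneFrequencyConcordance(scFreq, bulkVAF)
    utils::write.table(concordance$table, emit(file.path(outDir,
      "concordance.tsv")), sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    manifest <- list(
      seed = config$seed,
      config_hash = .configHash(config),
      package_version = as.character(utils::packageVersion("scClonality")),
      subjects = names(archs),
      concordance_r2 = concordance$r2,
      outputs = basename(unlist(written)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(sims = sims, calls = calls, benchmarks = benchmarks,
         cellularity = cellularity, clonality = clonality, trees = trees,
         concordance = concordance, manifest = manifest)
  }, error = function(e) {
    unlink(unlist(written))
    if (created) unlink(outDir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
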