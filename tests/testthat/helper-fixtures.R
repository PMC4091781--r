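# Shared fixtures: tiny architectures, catalogs and noise models used
# across the suite. Everything is generated in code.

# linear two-clone model (the biclonal subjects' shape)
twoCloneArch <- function(subject = "S1", f1 = 0.62, f2 = 0.31,
                         nonTumor = 0.07) {
  buildArchitecture(subject,
    data.frame(id = c("clone1", "clone2"), parent = c(NA, "clone1"),
               frequency = c(f1, f2), cluster = c("1", "2")),
    nonTumorFraction = nonTumor)
}

# branching model: clusters 2a and 2b both descend from cluster 1
branchedArch <- function(subject = "S1") {
  buildArchitecture(subject,
    data.frame(id = c("clone1", "clone2a", "clone2b"),
               parent = c(NA, "clone1", "clone1"),
               frequency = c(0.2, 0.35, 0.35),
               cluster = c("1", "2a", "2b")),
    nonTumorFraction = 0.10)
}

smallCatalog <- function(subject = "S1", sizes = c("1" = 30L, "2" = 30L),
                         nHet = 20L, nHomRef = 20L, nHomVar = 5L) {
  makeLocusCatalog(subject, sizes, nGermlineHet = nHet,
                   nGermlineHomRef = nHomRef, nGermlineHomVar = nHomVar)
}

# effectively noise-free sequencing: no dropout of any kind, deep and
# tight coverage so every site clears the 25x gate
cleanNoise <- function(depthMean = 500, seqError = 0) {
  wgaNoiseModel(adoProb = 0, seqError = seqError, depthMean = depthMean,
                depthDispersion = 100, locusDropoutProb = 0)
}

# study-like noise but without locus dropout (keeps sites callable)
deepNoise <- function(adoProb = 0.24, seqError = 0.01) {
  wgaNoiseModel(adoProb = adoProb, seqError = seqError, depthMean = 100,
                depthDispersion = 20, locusDropoutProb = 0)
}

# GenotypeMatrix from a plain integer matrix (codes 0/1/2, NA = no call)
gmOf <- function(m, threshold = 25) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("cell%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("L%03d", seq_len(ncol(m)))
  new("GenotypeMatrix", calls = m, callableThreshold = threshold)
}

# ReadCountTable from vectors
rctOf <- function(sample_id, locus_id, ref_reads, var_reads) {
  new("ReadCountTable", counts = data.frame(
    sample_id = sample_id, locus_id = locus_id,
    ref_reads = as.integer(ref_reads), var_reads = as.integer(var_reads),
    stringsAsFactors = FALSE))
}

# naive majority genotyper: the oracle for noise-free recovery
naiveGenotype <- function(counts, minDepth = 25) {
  ct <- readCounts(counts)
  depth <- ct$ref_reads + ct$var_reads
  vaf <- ifelse(depth > 0, ct$var_reads / depth, NA_real_)
  g <- ifelse(depth < minDepth, NA_integer_,
              ifelse(vaf > 0.75, 2L, ifelse(vaf >= 0.25, 1L, 0L)))
  samples <- unique(ct$sample_id)
  locusIds <- unique(ct$locus_id)
  m <- matrix(NA_integer_, length(samples), length(locusIds),
              dimnames = list(samples, locusIds))
  m[cbind(match(ct$sample_id, samples), match(ct$locus_id, locusIds))] <- g
  m
}

# mean VAF over a set of loci for one sample of a ReadCountTable
meanVAF <- function(counts, sampleId, lociIds) {
  ct <- readCounts(counts)
  ct <- ct[ct$sample_id == sampleId & ct$locus_id %in% lociIds, ]
  depth <- ct$ref_reads + ct$var_reads
  mean(ct$var_reads[depth > 0] / depth[depth > 0])
}
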