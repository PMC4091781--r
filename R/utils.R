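# derive n reproducible child seeds from one master seed, so that stages
# consuming randomness in different orders do not perturb one another
.childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# VAF per row of a read-count data.frame; NA where depth is zero
.vaf <- function(counts) {
  depth <- counts$ref_reads + counts$var_reads
  ifelse(depth > 0, counts$var_reads / depth, NA_real_)
}
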