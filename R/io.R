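# Plain-text interchange: TSV read-count tables, genotype matrices with
# {., 0, 1, 2} codes, and JSON architecture specifications.

#' Read a read-count table from TSV
#'
#' The file must carry the exact header \code{sample_id, locus_id,
#' ref_reads, var_reads}; counts must parse as non-negative integers.
#' Malformed rows are reported with their line number.
#'
#' @param path file path.
#' @return a [ReadCountTable-class].
#' @export
readCountsTSV <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  expected <- c("sample_id", "locus_id", "ref_reads", "var_reads")
  if (!identical(header, expected)) {
    stop("header must be exactly: ", paste(expected, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(new("ReadCountTable", counts = data.frame(
      sample_id = character(), locus_id = character(),
      ref_reads = integer(), var_reads = integer(),
      stringsAsFactors = FALSE)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    lineNo <- i + 1L
    if (length(f) != 4L) {
      stop(sprintf("line %d: expected 4 fields, found %d", lineNo,
                   length(f)))
    }
    counts <- suppressWarnings(as.integer(f[3:4]))
    if (anyNA(counts) || any(counts < 0) ||
        any(as.numeric(f[3:4]) != counts)) {
      stop(sprintf("line %d: counts must be non-negative integers", lineNo))
    }
  }
  ct <- data.frame(
    sample_id = vapply(fields, `[[`, character(1), 1L),
    locus_id = vapply(fields, `[[`, character(1), 2L),
    ref_reads = as.integer(vapply(fields, `[[`, character(1), 3L)),
    var_reads = as.integer(vapply(fields, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  new("ReadCountTable", counts = ct)
}

#' Write a read-count table to TSV
#'
#' @param counts a [ReadCountTable-class].
#' @param path file path.
#' @return invisibly, the path. Round-trips losslessly through
#'   [readCountsTSV()].
#' @export
writeCountsTSV <- function(counts, path) {
  utils::write.table(readCounts(counts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix to TSV
#'
#' Rows are cells, columns loci; codes are \code{.} (no call), \code{0}
#' (hom-ref), \code{1} (het), \code{2} (hom-var). The first column holds
#' the cell id under the header \code{cell_id}.
#'
#' @param calls a [GenotypeMatrix-class].
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeGenotypeTSV <- function(calls, path) {
  m <- genotypeCalls(calls)
  chr <- matrix(as.character(m), nrow(m), dimnames = dimnames(m))
  chr[is.na(chr)] <- "."
  df <- data.frame(cell_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' @param path file written by [writeGenotypeTSV()].
#' @param callableThreshold recorded threshold (default 25).
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeTSV <- function(path, callableThreshold = 25) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  cells <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !(m %in% c(".", "0", "1", "2"))
  if (any(bad)) stop("invalid genotype codes: ",
                     paste(unique(m[bad]), collapse = ", "))
  m[m == "."] <- NA_character_
  storage.mode(m) <- "integer"
  rownames(m) <- cells
  new("GenotypeMatrix", calls = m, callableThreshold = callableThreshold)
}

#' Read a clonal architecture from JSON
#'
#' Expected keys: \code{subject}, \code{non_tumor_fraction},
#' \code{clones} (array of objects with \code{id}, \code{parent} --
#' null for the founding clone -- \code{frequency}, \code{cluster}).
#'
#' @param path file path.
#' @return a validated [ClonalArchitecture-class].
#' @export
readArchitectureJSON <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("subject", "non_tumor_fraction", "clones")
  if (!all(need %in% names(spec))) {
    stop("architecture JSON must contain keys: ",
         paste(need, collapse = ", "))
  }
  cl <- as.data.frame(spec$clones, stringsAsFactors = FALSE)
  if (is.null(cl$parent)) cl$parent <- NA_character_
  cl$parent[cl$parent %in% c("", "null")] <- NA_character_
  buildArchitecture(spec$subject, cl, spec$non_tumor_fraction)
}

#' Write a clonal architecture to JSON
#'
#' @param arch a [ClonalArchitecture-class].
#' @param path file path.
#' @return invisibly, the path. Round-trips through
#'   [readArchitectureJSON()].
#' @export
writeArchitectureJSON <- function(arch, path) {
  jsonlite::write_json(
    list(subject = arch@subject,
         non_tumor_fraction = arch@nonTumorFraction,
         clones = arch@clones),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
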