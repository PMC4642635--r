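## File formats: relationship matrices (square and long TSV), genotype
## matrices, phased haplotype tables, phased VCF and interval weights.

.fmt <- function(x, digits = 17) sprintf(paste0("%.", digits, "g"), x)

#' Read / write relationship matrices as TSV
#'
#' Square format: an id header row, then one row per individual with
#' the id in the first column.  Long format: three columns
#' `id1<TAB>id2<TAB>value`, upper triangle including the diagonal.
#' Values are written with 17 significant digits by default so that
#' file round trips preserve exact identities.
#'
#' @param x a [RelationshipMatrix] (or plain matrix).
#' @param path file path.
#' @param format `"square"` or `"long"`.
#' @param digits significant digits written.
#' @return `readRelationshipMatrix` returns a [RelationshipMatrix].
#' @export
writeRelationshipMatrix <- function(x, path, format = c("square", "long"),
                                    digits = 17) {
  format <- match.arg(format)
  v <- if (is(x, "RelationshipMatrix")) x@values else as.matrix(x)
  ids <- rownames(v)
  if (format == "square") {
    lines <- c(paste(c("id", ids), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                 paste(c(ids[i], .fmt(v[i, ], digits)), collapse = "\t"), ""))
  } else {
    iu <- which(upper.tri(v, diag = TRUE), arr.ind = TRUE)
    lines <- c("id1\tid2\tvalue",
               paste(ids[iu[, 1L]], ids[iu[, 2L]],
                     .fmt(v[iu], digits), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRelationshipMatrix
#' @param kind kind tag given to the matrix read back.
#' @export
readRelationshipMatrix <- function(path, kind = "custom") {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (identical(first[1:3], c("id1", "id2", "value"))) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric"))
    ids <- unique(c(d$id1, d$id2))
    v <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
    v[cbind(d$id1, d$id2)] <- d$value
    v[cbind(d$id2, d$id1)] <- d$value
    if (anyNA(v)) stop("long-format matrix in ", path, " is incomplete")
  } else {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = 1L)
    v <- as.matrix(d)
    rownames(v) <- as.character(rownames(d))
  }
  RelationshipMatrix(v, kind = kind)
}

#' Read a genotype matrix TSV
#'
#' Rows are individuals (first column the id), columns are markers,
#' values in \{0, 1, 2\}.
#'
#' @param path file path.
#' @return numeric matrix with individual ids as rownames.
#' @export
readGenotypeMatrix <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, row.names = 1L)
  M <- as.matrix(d)
  if (!is.numeric(M)) stop("genotype matrix in ", path, " is not numeric")
  if (!all(M %in% c(0, 1, 2)))
    stop("genotype values outside {0,1,2} in ", path)
  M
}

#' Read / write a phased haplotype table
#'
#' TSV with an `id` first column and one column per marker; two rows
#' per individual (its two haplotypes), values are allele symbols.
#'
#' @param path file path.
#' @return `readHaplotypeTable` returns a character matrix with 2 rows
#'   per individual, rownames the individual ids.
#' @export
readHaplotypeTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, colClasses = "character")
  if (ncol(d) < 2L) stop("haplotype table ", path,
                         " needs an id column plus marker columns")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}

#' @rdname readHaplotypeTable
#' @param haplotypes character matrix as returned by
#'   [readHaplotypeTable()] (2 rows per individual, rownames = ids).
#' @export
writeHaplotypeTable <- function(haplotypes, path) {
  markers <- colnames(haplotypes)
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(haplotypes)))
  lines <- c(paste(c("id", markers), collapse = "\t"),
             vapply(seq_len(nrow(haplotypes)), function(i)
               paste(c(rownames(haplotypes)[i], haplotypes[i, ]),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Haplotype table from genomes
#'
#' Writes each genome's two haplotypes as rows of allele symbols by
#' looking the segments up in the generating APFA.
#'
#' @param genomes list of [Genome]s.
#' @param apfa the generating [Apfa].
#' @return character matrix, 2 rows per individual.
#' @export
genomesToHaplotypeTable <- function(genomes, apfa) {
  al <- stats::setNames(apfa@edges$allele, apfa@edges$id)
  rows <- lapply(genomes, function(g)
    rbind(unname(al[g@hap1]), unname(al[g@hap2])))
  m <- do.call(rbind, rows)
  rownames(m) <- rep(vapply(genomes, function(g) g@id, ""), each = 2L)
  colnames(m) <- paste0("m", seq_len(ncol(m)))
  m
}

#' Read phased haplotypes from a VCF
#'
#' Requires the vcfR package.  All genotypes must be phased (`|`
#' separator) and complete; each sample contributes two haplotype rows
#' of allele indices ("0", "1", ...).  One contig is treated as one
#' interval sequence, in file order.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return character matrix with 2 rows per sample, suitable for
#'   [haplotypesToGenomes()].
#' @export
readPhasedVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) stop("VCF ", path, " has missing genotypes")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("VCF ", path, " has unphased genotypes; phased '|' GT required")
  samples <- colnames(gt)
  out <- matrix(NA_character_, 2L * length(samples), nrow(gt))
  rn <- character(2L * length(samples))
  for (j in seq_along(samples)) {
    sp <- strsplit(gt[, j], "|", fixed = TRUE)
    if (any(lengths(sp) != 2L))
      stop("VCF ", path, ": sample ", samples[j], " is not diploid phased")
    out[2L * j - 1L, ] <- vapply(sp, `[`, "", 1L)
    out[2L * j, ] <- vapply(sp, `[`, "", 2L)
    rn[c(2L * j - 1L, 2L * j)] <- samples[j]
  }
  rownames(out) <- rn
  colnames(out) <- rownames(gt)
  out
}

#' Read interval weights
#'
#' One non-negative number per line; the weights must sum to 1 within
#' 1e-9.
#'
#' @param path file path.
#' @param p expected number of intervals.
#' @return numeric vector of length p.
#' @export
readIntervalWeights <- function(path, p) {
  w <- suppressWarnings(as.numeric(readLines(path)))
  if (anyNA(w)) stop("non-numeric weight in ", path)
  .checkWeights(w, p)
}
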