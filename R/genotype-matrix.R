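#' Construct a GenotypeMatrix
#'
#' @param genotypes numeric matrix, individuals x loci, values 0/1/2/NA
#'   (alternate-allele counts).
#' @param sampleInfo optional data.frame of per-sample metadata; rownames (or
#'   an `id` column) give sample ids. If omitted, ids are taken from
#'   `rownames(genotypes)`.
#' @param lociInfo optional data.frame of per-locus metadata; rownames give
#'   locus ids.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(genotypes, sampleInfo = NULL, lociInfo = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes)) && nrow(genotypes))
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)) && ncol(genotypes))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  if (is.null(sampleInfo)) {
    sampleInfo <- data.frame(row.names = rownames(genotypes))
  } else {
    sampleInfo <- as.data.frame(sampleInfo)
    if (!is.null(sampleInfo$id) && is.null(rownames(sampleInfo)))
      rownames(sampleInfo) <- sampleInfo$id
    sampleInfo <- sampleInfo[rownames(genotypes), , drop = FALSE]
    rownames(sampleInfo) <- rownames(genotypes)
  }
  if (is.null(lociInfo)) {
    lociInfo <- data.frame(row.names = colnames(genotypes))
  } else {
    lociInfo <- as.data.frame(lociInfo)
    rownames(lociInfo) <- colnames(genotypes)
  }
  new("GenotypeMatrix", genotypes = genotypes,
      sampleInfo = sampleInfo, lociInfo = lociInfo)
}

#' @describeIn GenotypeMatrix genotype code matrix (individuals x loci)
#' @param x,object a GenotypeMatrix
#' @export
genotypes <- function(x) x@genotypes

#' @describeIn GenotypeMatrix sample identifiers
#' @export
sampleIds <- function(x) rownames(x@genotypes)

#' @describeIn GenotypeMatrix locus identifiers
#' @export
lociIds <- function(x) colnames(x@genotypes)

#' @describeIn GenotypeMatrix number of individuals
#' @export
nSamples <- function(x) nrow(x@genotypes)

#' @describeIn GenotypeMatrix number of loci
#' @export
nLoci <- function(x) ncol(x@genotypes)

#' @describeIn GenotypeMatrix per-sample metadata data.frame
#' @export
sampleInfo <- function(x) x@sampleInfo

#' @describeIn GenotypeMatrix per-locus metadata data.frame
#' @export
lociInfo <- function(x) x@lociInfo

#' @describeIn GenotypeMatrix population labels (the `pop` metadata column),
#'   or NULL
#' @export
popLabels <- function(x) {
  if ("pop" %in% names(x@sampleInfo)) as.character(x@sampleInfo$pop) else NULL
}

#' Subset a GenotypeMatrix by individuals and/or loci
#'
#' @param x a GenotypeMatrix
#' @param i,j individual / locus indices (integer, logical or character)
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  GenotypeMatrix(x@genotypes[i, j, drop = FALSE],
                 sampleInfo = x@sampleInfo[i, , drop = FALSE],
                 lociInfo   = x@lociInfo[j, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@genotypes
  miss <- mean(is.na(g))
  cat("GenotypeMatrix:", nrow(g), "individuals x", ncol(g), "loci\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  if (!is.null(popLabels(object))) {
    tab <- table(popLabels(object))
    cat("  populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
})

#' Per-individual missing-call fraction
#' @param x a GenotypeMatrix
#' @return named numeric vector
#' @export
missingRateByIndividual <- function(x) rowMeans(is.na(genotypes(x)))

#' Alternate-allele frequency per locus
#'
#' Computed over non-missing genotypes; loci with no calls return NA.
#' @param x a GenotypeMatrix
#' @export
alleleFrequencies <- function(x) colMeans(genotypes(x), na.rm = TRUE) / 2

#' Read/write a plain genotype table
#'
#' CSV layout: first column `id`, remaining columns one per locus with codes
#' 0/1/2 and empty cells for missing.
#' @param x a GenotypeMatrix
#' @param path file path
#' @export
writeGenotypeCsv <- function(x, path) {
  df <- data.frame(id = sampleIds(x), genotypes(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeGenotypeCsv
#' @export
readGenotypeCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot("id" %in% names(df))
  g <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  mode(g) <- "numeric"
  rownames(g) <- df$id
  GenotypeMatrix(g)
}

#' Read sample metadata CSV
#'
#' Expected columns: `id`, projected `x`, `y` in metres, `location` label,
#' ISO-8601 `date`. Extra columns pass through.
#' @param path file path
#' @return data.frame with rownames = id
#' @export
readSampleMetadata <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(meta))
  rownames(meta) <- meta$id
  if ("date" %in% names(meta)) meta$date <- as.Date(meta$date)
  meta
}
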