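#' Locate optional real-data fixtures
#'
#' Some checks can only be reproduced against the study's deposited SNP
#' table and sample sheet, which are not distributed with the package.
#' This helper looks for them locally (a genotype CSV and a sample-metadata
#' CSV) and reports whether the gated analyses can run. With the files
#' absent it returns `available = FALSE` and the package's test-suite
#' exercises the gating logic only; synthetic data cover everything else.
#'
#' @param dir directory to search; default the `HEDGESCAPE_DATA` environment
#'   variable, falling back to `~/hedgescape-data`.
#' @param genotypeFile,metadataFile file names expected inside `dir`.
#' @return list with `available` (logical), and when TRUE, `genotypes`
#'   (a [GenotypeMatrix-class]) and `metadata` (data.frame).
#' @export
loadGatedSnpData <- function(dir = Sys.getenv("HEDGESCAPE_DATA",
                                              "~/hedgescape-data"),
                             genotypeFile = "snp_genotypes.csv",
                             metadataFile = "sample_metadata.csv") {
  gPath <- file.path(path.expand(dir), genotypeFile)
  mPath <- file.path(path.expand(dir), metadataFile)
  if (!file.exists(gPath) || !file.exists(mPath))
    return(list(available = FALSE, dir = dir))
  list(available = TRUE,
       genotypes = readGenotypeCsv(gPath),
       metadata = readSampleMetadata(mPath))
}
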