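#' Group samples into populations by spatial proximity
#'
#' Single-linkage clustering on projected coordinates: two samples share a
#' label iff they are connected by a chain of pairwise distances at or below
#' `radius`. This mirrors grouping carcass-collection sites into candidate
#' populations when samples lie within a nightly movement range of one
#' another.
#'
#' @param metadata data.frame with columns `x`, `y` in metres (rownames or
#'   an `id` column give sample ids).
#' @param radius linkage distance in metres; default 1000.
#' @return character vector of population labels (`"loc1"`, `"loc2"`, ...)
#'   named by sample id; samples with missing coordinates get NA with a
#'   warning.
#' @export
groupByLocation <- function(metadata, radius = 1000) {
  ids <- if (!is.null(metadata$id)) as.character(metadata$id)
         else rownames(metadata)
  ok <- is.finite(metadata$x) & is.finite(metadata$y)
  if (any(!ok))
    warning("samples without coordinates left unlabelled: ",
            paste(ids[!ok], collapse = ", "))
  labels <- rep(NA_character_, length(ids))
  xy <- metadata[ok, c("x", "y"), drop = FALSE]
  if (nrow(xy) == 1L) {
    labels[ok] <- "loc1"
  } else if (nrow(xy) > 1L) {
    hc <- hclust(dist(xy), method = "single")
    grp <- cutree(hc, h = radius)
    # relabel in order of first appearance for stable names
    grp <- match(grp, unique(grp))
    labels[ok] <- paste0("loc", grp)
  }
  setNames(labels, ids)
}

#' Subset an over-sampled site
#'
#' Greedy curation of a location that dominates the dataset: candidates at
#' the site are visited in descending collection date; a candidate is
#' skipped if its relatedness to any already-kept sample reaches the
#' first-degree threshold; at most `nKeep` samples are retained. Samples
#' from all other sites pass through untouched.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param metadata data.frame with `location` and `date` columns, rownames =
#'   sample ids (see [readSampleMetadata()]).
#' @param relatedness symmetric QG relatedness matrix over the samples (see
#'   [qgRelatedness()]).
#' @param site location label to curate.
#' @param nKeep maximum samples kept at the site; default 5.
#' @param firstDegreeThreshold QG relatedness at or above which a pair is
#'   treated as first-degree; default 0.35.
#' @return list with `genotypes` (curated matrix) and `kept`, `dropped`
#'   (ids at the site).
#' @export
subsetOversampledSite <- function(gm, metadata, relatedness, site,
                                  nKeep = 5, firstDegreeThreshold = 0.35) {
  ids <- sampleIds(gm)
  meta <- metadata[ids, , drop = FALSE]
  if (!site %in% meta$location)
    stop("site label '", site, "' not present in metadata")
  atSite <- ids[!is.na(meta$location) & meta$location == site]
  if (anyNA(meta[atSite, "date"]))
    stop("collection dates required for all samples at '", site, "'")
  ord <- atSite[order(meta[atSite, "date"], decreasing = TRUE)]
  kept <- character()
  for (cand in ord) {
    if (length(kept) >= nKeep) break
    if (length(kept)) {
      r <- relatedness[cand, kept]
      if (any(!is.na(r) & r >= firstDegreeThreshold)) next
    }
    kept <- c(kept, cand)
  }
  keepAll <- ids[!(ids %in% setdiff(atSite, kept))]
  list(genotypes = gm[keepAll, ], kept = kept,
       dropped = setdiff(atSite, kept))
}

#' Flag individuals with unusually high heterozygosity
#'
#' Optional curation rule: computes each individual's heterozygous-site
#' proportion and flags those whose z-score exceeds `k`. Off by default in
#' the pipeline; exposed for explicit use.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param k z-score cutoff; default 3.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flagExcessHeterozygosity <- function(gm, k = 3) {
  g <- genotypes(gm)
  prop <- rowSums(g == 1, na.rm = TRUE) / rowSums(!is.na(g))
  z <- (prop - mean(prop)) / sd(prop)
  sampleIds(gm)[!is.na(z) & z > k]
}
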