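#' VariantTable: site-level variant records with per-genotype depths
#'
#' The substrate of the post-variant-calling filter chain. Sites are columns;
#' individuals are rows of the genotype and depth matrices.
#'
#' @slot chrom,ref,alt per-site character vectors (`alt` may be a
#'   comma-separated list for multiallelic sites).
#' @slot pos 1-based positions.
#' @slot qual phred-like site quality (QUAL).
#' @slot mq site mapping quality (INFO MQ).
#' @slot locus UCE-region identifier per site (for one-SNP-per-locus
#'   thinning); may be NA.
#' @slot gt genotype codes (alternate-allele count 0/1/2, NA missing),
#'   individuals x sites.
#' @slot dp per-genotype read depths, individuals x sites.
#' @export
setClass("VariantTable",
  representation(
    chrom = "character", pos = "integer", ref = "character",
    alt = "character", qual = "numeric", mq = "numeric", locus = "character",
    gt = "matrix", dp = "matrix"
  )
)

setValidity("VariantTable", function(object) {
  msg <- character()
  nSite <- length(object@pos)
  if (any(object@pos < 1L)) msg <- c(msg, "pos must be >= 1")
  if (any(!nzchar(object@ref)) || any(!nzchar(object@alt)))
    msg <- c(msg, "alleles must be non-empty")
  for (sl in c("chrom", "ref", "alt", "qual", "mq", "locus"))
    if (length(slot(object, sl)) != nSite)
      msg <- c(msg, paste0(sl, " length must match number of sites"))
  if (ncol(object@gt) != nSite || !identical(dim(object@gt), dim(object@dp)))
    msg <- c(msg, "gt/dp must be individuals x sites")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable:", nrow(object@gt), "individuals x",
      length(object@pos), "sites\n")
  invisible(object)
})

#' @describeIn VariantTable-class number of sites
#' @param x a VariantTable
#' @export
nSites <- function(x) length(x@pos)

#' Subset a VariantTable by sites
#' @param x a VariantTable
#' @param i individual indices
#' @param j site indices
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "VariantTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@gt))
  if (missing(j)) j <- seq_len(nSites(x))
  new("VariantTable", chrom = x@chrom[j], pos = x@pos[j], ref = x@ref[j],
      alt = x@alt[j], qual = x@qual[j], mq = x@mq[j], locus = x@locus[j],
      gt = x@gt[i, j, drop = FALSE], dp = x@dp[i, j, drop = FALSE])
})

#' Degrade a clean genotype matrix into VCF-like variant records
#'
#' Adds the annotations the filter chain consumes: per-genotype simulated
#' read depths (Poisson around a site mean), site QUAL and mapping quality,
#' and randomly dropped genotype calls. Sites can be forced to specific mean
#' depths / qualities to construct filter fixtures.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param missingRate fraction of genotype calls set missing, in [0, 1).
#'   May be a vector of per-individual rates.
#' @param depthModel list with elements `meanDepth` (default 30), `qual`
#'   (default 60), `mq` (default 60), and optional per-site overrides
#'   `siteMeanDepth`, `siteQual`, `siteMq` (named by locus id or indexed
#'   vectors with NA for no override). An overridden site mean depth is
#'   applied as a constant depth for every genotype at the site.
#' @param seed integer seed.
#' @return A [VariantTable-class].
#' @export
degradeToVcfRecords <- function(gm, missingRate = 0.05,
                                depthModel = list(), seed = 1L) {
  if (any(missingRate < 0) || any(missingRate >= 1))
    stop("missingRate must lie in [0, 1)")
  dm <- modifyList(list(meanDepth = 30, qual = 60, mq = 60,
                        siteMeanDepth = NULL, siteQual = NULL, siteMq = NULL),
                   depthModel)
  set.seed(seed)
  g <- genotypes(gm)
  n <- nrow(g); L <- ncol(g)
  siteDepth <- rep(dm$meanDepth, L)
  forced <- rep(FALSE, L)
  ov <- expandSiteOverride(dm$siteMeanDepth, colnames(g), L)
  forced[!is.na(ov)] <- TRUE
  siteDepth[!is.na(ov)] <- ov[!is.na(ov)]
  dp <- matrix(rpois(n * L, rep(siteDepth, each = n)), n, L)
  dp[, forced] <- rep(siteDepth[forced], each = n)

  qual <- pmax(1, rnorm(L, dm$qual, 5))
  ovq <- expandSiteOverride(dm$siteQual, colnames(g), L)
  qual[!is.na(ovq)] <- ovq[!is.na(ovq)]
  mq <- pmax(1, rnorm(L, dm$mq, 3))
  ovm <- expandSiteOverride(dm$siteMq, colnames(g), L)
  mq[!is.na(ovm)] <- mq[!is.na(ovm)] * 0 + ovm[!is.na(ovm)]

  gt <- g
  rates <- rep_len(missingRate, n)
  drop <- matrix(runif(n * L) < rates, n, L)
  gt[drop] <- NA

  info <- lociInfo(gm)
  chrom <- if ("chrom" %in% names(info)) as.character(info$chrom)
           else rep("chr1", L)
  pos <- if ("pos" %in% names(info)) as.integer(info$pos)
         else seq_len(L) * 100L
  locus <- if ("locus" %in% names(info)) as.character(info$locus)
           else paste0("uce-", seq_len(L))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  dimnames(dp) <- dimnames(gt)
  new("VariantTable", chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      qual = qual, mq = mq, locus = locus, gt = gt, dp = dp)
}

expandSiteOverride <- function(ov, ids, L) {
  out <- rep(NA_real_, L)
  if (is.null(ov)) return(out)
  if (!is.null(names(ov))) {
    idx <- match(names(ov), ids)
    out[idx[!is.na(idx)]] <- ov[!is.na(idx)]
  } else {
    out[seq_along(ov)] <- ov
  }
  out
}

#' Read variant records from a VCF file
#'
#' Parses diploid GT and per-genotype DP, site QUAL, and INFO `MQ` and
#' `LOCUS` tags (the latter carrying the UCE-region assignment). Non-diploid
#' GT entries are rejected.
#'
#' @param path VCF file (plain or gzipped).
#' @return A [VariantTable-class].
#' @export
readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gtRaw <- v@gt
  samples <- colnames(gtRaw)[-1]
  fmt <- strsplit(gtRaw[, "FORMAT"], ":")
  gtField <- vapply(fmt, function(f) match("GT", f), integer(1))
  dpField <- vapply(fmt, function(f) match("DP", f), integer(1))
  nSite <- nrow(fix); n <- length(samples)
  gt <- matrix(NA_real_, n, nSite, dimnames = list(samples, fix[, "ID"]))
  dp <- matrix(NA_real_, n, nSite, dimnames = list(samples, fix[, "ID"]))
  for (j in seq_len(nSite)) {
    cells <- strsplit(gtRaw[j, -1], ":")
    gts <- vapply(cells, `[`, character(1), gtField[j])
    alleles <- strsplit(gts, "[/|]")
    nAll <- lengths(alleles)
    if (any(nAll != 2L))
      stop("non-diploid GT at ", fix[j, "CHROM"], ":", fix[j, "POS"],
           " (record ", j, ")")
    code <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(as.integer(a) > 0L)
    }, numeric(1))
    gt[, j] <- code
    if (!is.na(dpField[j]))
      dp[, j] <- suppressWarnings(as.numeric(
        vapply(cells, `[`, character(1), dpField[j])))
  }
  info <- fix[, "INFO"]
  getTag <- function(tag) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]+"), info))
    out <- rep(NA_character_, nSite)
    hit <- grepl(paste0(tag, "="), info)
    out[hit] <- sub(paste0(".*", tag, "="), "", m)
    out
  }
  mq <- suppressWarnings(as.numeric(getTag("MQ")))
  locus <- getTag("LOCUS")
  new("VariantTable",
      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      ref = fix[, "REF"], alt = fix[, "ALT"],
      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
      mq = mq, locus = locus, gt = gt, dp = dp)
}

#' Write variant records to VCF
#'
#' Emits VCF 4.2 with GT:DP genotypes, site QUAL, and INFO `DP` (summed
#' depth), `MQ` and `LOCUS` tags. Output is gzip-compressed (a `.vcf.gz`
#' suffix is conventional); [readGenotypeVcf()] round-trips it losslessly.
#'
#' @param vt a [VariantTable-class].
#' @param path output path.
#' @export
writeGenotypeVcf <- function(vt, path) {
  nSite <- nSites(vt); n <- nrow(vt@gt)
  codeToGt <- function(code) {
    out <- rep("./.", length(code))
    out[!is.na(code) & code == 0] <- "0/0"
    out[!is.na(code) & code == 1] <- "0/1"
    out[!is.na(code) & code == 2] <- "1/1"
    out
  }
  gtCols <- matrix("", n, nSite)
  for (j in seq_len(nSite)) {
    dpj <- vt@dp[, j]
    dpj <- ifelse(is.na(dpj), ".", as.character(round(dpj)))
    gtCols[, j] <- paste(codeToGt(vt@gt[, j]), dpj, sep = ":")
  }
  info <- sprintf("DP=%d;MQ=%.2f;LOCUS=%s",
                  round(colSums(vt@dp, na.rm = TRUE)), vt@mq, vt@locus)
  ids <- colnames(vt@gt)
  if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(nSite))
  fix <- cbind(CHROM = vt@chrom, POS = as.character(vt@pos), ID = ids,
               REF = vt@ref, ALT = vt@alt,
               QUAL = sprintf("%.2f", vt@qual), FILTER = "PASS", INFO = info)
  gt <- cbind(FORMAT = rep("GT:DP", nSite), t(gtCols))
  colnames(gt) <- c("FORMAT", rownames(vt@gt))
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
            "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
            "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"UCE region\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  out <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Convert a VariantTable to a GenotypeMatrix
#'
#' @param vt a [VariantTable-class].
#' @return A [GenotypeMatrix-class] with chrom/pos/locus in `lociInfo`.
#' @export
asGenotypeMatrix <- function(vt) {
  g <- vt@gt
  if (is.null(colnames(g))) colnames(g) <- sprintf("snp%05d", seq_len(ncol(g)))
  GenotypeMatrix(g, lociInfo = data.frame(
    chrom = vt@chrom, pos = vt@pos, locus = vt@locus,
    row.names = colnames(g)))
}
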