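#' @import methods
#' @importClassesFrom vcfR vcfR
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t solve Cholesky
#'   tcrossprod determinant
#' @importFrom stats rbinom rbeta runif rnorm rpois qlogis plogis dist hclust
#'   cutree optimize prcomp wilcox.test p.adjust pnorm lm coef resid median
#'   sd var quantile setNames cor na.omit
#' @importFrom utils read.csv write.csv write.table modifyList combn
NULL

#' GenotypeMatrix: individuals by biallelic loci
#'
#' Genotypes are coded as the count of the alternate allele (0, 1, 2) with
#' `NA` for missing calls. Rows are individuals, columns are loci. Optional
#' per-sample metadata (population label, projected coordinates, collection
#' date) and per-locus metadata (chromosome, position, UCE-style locus id)
#' travel with the matrix.
#'
#' @slot genotypes integer matrix, individuals x loci, values in {0,1,2,NA}.
#' @slot sampleInfo data.frame with rownames = sample ids; may carry columns
#'   `pop`, `x`, `y`, `location`, `date`.
#' @slot lociInfo data.frame with rownames = locus ids; may carry columns
#'   `chrom`, `pos`, `locus` (the UCE region a SNP belongs to).
#' @export
setClass("GenotypeMatrix",
  representation(
    genotypes  = "matrix",
    sampleInfo = "data.frame",
    lociInfo   = "data.frame"
  )
)

setValidity("GenotypeMatrix", function(object) {
  g <- object@genotypes
  msg <- character()
  if (!is.numeric(g)) msg <- c(msg, "genotypes must be numeric")
  bad <- g[!is.na(g)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(g))) msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(colnames(g))) msg <- c(msg, "locus ids must be unique")
  if (nrow(object@sampleInfo) != nrow(g))
    msg <- c(msg, "sampleInfo rows must match individuals")
  if (nrow(object@lociInfo) != ncol(g))
    msg <- c(msg, "lociInfo rows must match loci")
  if (length(msg)) msg else TRUE
})

#' LandcoverRaster: categorical landcover on a regular grid
#'
#' Integer class codes on a regular grid of square cells. The origin is the
#' projected (x, y) of the *top-left corner* of the grid; the centre of cell
#' (row r, col c), 1-based, is at
#' `origin + (c - 0.5, -(r - 0.5)) * resolution`. The legend maps every code
#' occurring in the grid to a class name and always contains an explicit
#' `"Unclassified"` entry.
#'
#' @slot codes integer matrix of class codes.
#' @slot resolution cell edge length in metres.
#' @slot origin numeric length-2: projected x, y of the top-left corner.
#' @slot legend named character: names are codes (as character), values are
#'   class names.
#' @export
setClass("LandcoverRaster",
  representation(
    codes      = "matrix",
    resolution = "numeric",
    origin     = "numeric",
    legend     = "character"
  )
)

setValidity("LandcoverRaster", function(object) {
  msg <- character()
  if (length(object@resolution) != 1L || object@resolution <= 0)
    msg <- c(msg, "resolution must be a single positive number (metres)")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be length-2 (x, y of top-left corner)")
  if (is.null(names(object@legend)))
    msg <- c(msg, "legend must be a named character vector (code -> class)")
  codes <- unique(as.vector(object@codes))
  codes <- codes[!is.na(codes)]
  if (!all(as.character(codes) %in% names(object@legend)))
    msg <- c(msg, "every code in the grid must have a legend entry")
  if (!"Unclassified" %in% object@legend)
    msg <- c(msg, "legend must contain an 'Unclassified' class")
  if (length(msg)) msg else TRUE
})

#' ResistanceHypothesis: class-to-resistance mapping under a named hypothesis
#'
#' Finite resistances are costs per cell (>= 1); classes in the barrier set
#' are absolute barriers (non-traversable).
#'
#' @slot name hypothesis label, e.g. "NULL", "EMP", "RAILCOR".
#' @slot resistances named numeric, class name -> finite resistance >= 1.
#' @slot barriers character vector of class names treated as absolute
#'   barriers.
#' @export
setClass("ResistanceHypothesis",
  representation(
    name        = "character",
    resistances = "numeric",
    barriers    = "character"
  )
)

setValidity("ResistanceHypothesis", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@resistances) && any(object@resistances < 1))
    msg <- c(msg, "finite resistances must be >= 1")
  if (length(intersect(names(object@resistances), object@barriers)))
    msg <- c(msg, "barrier classes must not also carry a finite resistance")
  if (length(msg)) msg else TRUE
})

#' ResistanceSurface: per-cell movement cost on a regular grid
#'
#' Finite values are resistances (>= 1); `NA` marks absolute-barrier
#' (non-traversable) cells. Grid geometry follows [LandcoverRaster-class].
#'
#' @slot resistance numeric matrix; `NA` = barrier.
#' @slot hypothesis name of the generating [ResistanceHypothesis-class].
#' @slot resolution cell size in metres.
#' @slot origin projected x, y of the top-left corner.
#' @export
setClass("ResistanceSurface",
  representation(
    resistance = "matrix",
    hypothesis = "character",
    resolution = "numeric",
    origin     = "numeric"
  )
)

setValidity("ResistanceSurface", function(object) {
  msg <- character()
  r <- object@resistance
  fin <- r[!is.na(r)]
  if (!length(fin)) msg <- c(msg, "surface must have at least one traversable cell")
  if (length(fin) && any(fin < 1)) msg <- c(msg, "resistances must be >= 1")
  if (length(object@resolution) != 1L || object@resolution <= 0)
    msg <- c(msg, "resolution must be positive")
  if (length(msg)) msg else TRUE
})

#' TransitionGraph: movement graph over traversable raster cells
#'
#' One node per traversable cell; undirected weighted edges between
#' 8-neighbours (or 4, by configuration) with conductance
#' `mean(1/r_i, 1/r_j) / d` where `d` is the centre-to-centre distance.
#'
#' @slot conductance symmetric sparse matrix (dgCMatrix) over traversable
#'   cells; entry (i, j) > 0 iff an edge joins nodes i and j.
#' @slot cellIndex integer vector mapping node index -> linear cell index of
#'   the source grid (column-major).
#' @slot dims integer length-2: grid rows, cols.
#' @slot resolution cell size in metres.
#' @slot origin projected x, y of the top-left grid corner.
#' @slot epsilon conductance added between all adjacent traversable cells
#'   (connectivity repair for commute computations); 0 if none.
#' @export
setClass("TransitionGraph",
  representation(
    conductance = "Matrix",
    cellIndex   = "integer",
    dims        = "integer",
    resolution  = "numeric",
    origin      = "numeric",
    epsilon     = "numeric"
  )
)

setValidity("TransitionGraph", function(object) {
  msg <- character()
  if (nrow(object@conductance) != length(object@cellIndex))
    msg <- c(msg, "conductance dimension must match number of traversable cells")
  if (length(object@dims) != 2L) msg <- c(msg, "dims must be length 2")
  if (length(msg)) msg else TRUE
})

#' PairwiseDistanceMatrix: symmetric individual-by-individual distances
#'
#' @slot values symmetric numeric matrix, zero diagonal; `Inf` flags
#'   disconnected pairs (lcp kind only), `NA` flags undefined pairs.
#' @slot kind one of "genetic", "euclidean", "lcp", "commute".
#' @slot units free-text unit label.
#' @export
setClass("PairwiseDistanceMatrix",
  representation(
    values = "matrix",
    kind   = "character",
    units  = "character"
  )
)

setValidity("PairwiseDistanceMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (!object@kind %in% c("genetic", "euclidean", "lcp", "commute"))
    msg <- c(msg, "kind must be genetic|euclidean|lcp|commute")
  if (nrow(v) && any(abs(diag(v)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal must be zero")
  fin <- v[is.finite(v)]
  if (length(fin) && any(fin < -1e-9)) msg <- c(msg, "distances must be nonnegative")
  if (nrow(v) && !isTRUE(all.equal(v, t(v), tolerance = 1e-8)))
    msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' MLPEFit: fitted maximum-likelihood-population-effects model
#'
#' Pairwise regression `y_ab = X beta + u_a + u_b + e_ab` with one Gaussian
#' random effect per individual (variance tau2) shared by all pairs the
#' individual belongs to, and residual variance sigma2. Fitted by maximum
#' likelihood; the implied correlation between pairs sharing exactly one
#' individual is `rho = tau2 / (2 tau2 + sigma2)`.
#'
#' @slot beta named fixed-effect estimates.
#' @slot tau2,sigma2 variance components (>= 0).
#' @slot rho derived pair correlation, in [0, 0.5).
#' @slot logLik maximised log-likelihood.
#' @slot k number of estimated parameters (fixed effects + 2 variances).
#' @slot n number of pairs used.
#' @slot AICc,BIC information criteria.
#' @slot R2 squared Pearson correlation of fixed-effect predictions with the
#'   response.
#' @slot fitted fixed-effect predictions.
#' @slot predictors names of predictor columns used.
#' @export
setClass("MLPEFit",
  representation(
    beta       = "numeric",
    tau2       = "numeric",
    sigma2     = "numeric",
    rho        = "numeric",
    logLik     = "numeric",
    k          = "numeric",
    n          = "numeric",
    AICc       = "numeric",
    BIC        = "numeric",
    R2         = "numeric",
    fitted     = "numeric",
    predictors = "character"
  )
)

setValidity("MLPEFit", function(object) {
  msg <- character()
  if (object@tau2 < 0 || object@sigma2 < 0)
    msg <- c(msg, "variance components must be nonnegative")
  if (object@rho < 0 || object@rho >= 0.5)
    msg <- c(msg, "rho must lie in [0, 0.5)")
  if (is.finite(object@AICc) && object@AICc < -2 * object@logLik + 2 * object@k - 1e-8)
    msg <- c(msg, "AICc must be >= AIC")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: full parameterisation of a generated dataset
#'
#' Bundles every knob of the synthetic-data generators so a dataset can be
#' regenerated bit-identically from (scenario, seed).
#'
#' @slot seed integer master seed.
#' @slot nPops number of demes (island model) or spatial clusters.
#' @slot nPerPop individuals per deme.
#' @slot nLoci number of biallelic SNPs.
#' @slot fstTarget Balding-Nichols differentiation target in [0, 1).
#' @slot ibrPhi range parameter of the spatial covariance, in commute-distance
#'   units.
#' @slot ibrSigma2 logit-frequency variance of the spatial model.
#' @slot missingRate fraction of genotype calls dropped when degrading to VCF.
#' @slot landscape list: grid dims, resolution, class specifications.
#' @export
setClass("SyntheticScenario",
  representation(
    seed        = "integer",
    nPops       = "integer",
    nPerPop     = "integer",
    nLoci       = "integer",
    fstTarget   = "numeric",
    ibrPhi      = "numeric",
    ibrSigma2   = "numeric",
    missingRate = "numeric",
    landscape   = "list"
  )
)

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (any(c(object@nPops, object@nPerPop, object@nLoci) < 1))
    msg <- c(msg, "counts must be >= 1")
  if (object@fstTarget < 0 || object@fstTarget >= 1)
    msg <- c(msg, "fstTarget must lie in [0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
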