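#' Canonical landcover classes and precedence order
#'
#' The class list used by the packaged movement hypotheses, in descending
#' precedence: when class masks overlap (a pond inside a park), the class
#' higher in this list wins the cell.
#'
#' @return character vector of class names, highest precedence first.
#' @export
canonicalPrecedence <- function() {
  c("Buildings", "Path", "Waterbodies", "Railways", "Small street",
    "Highways", "Large street", "Linear Water", "Wetland", "Impervious",
    "Woodland", "Lawn", "Amenity", "Parks and Playspace", "Cemeteries",
    "Allotments", "Farmland", "Private Garden", "Unclassified")
}

# empirical per-class resistances for urban hedgehog movement
# (radiotracking-derived literature values); NA = absolute barrier
empResistances <- function() {
  c("Buildings" = NA, "Path" = 14, "Waterbodies" = NA, "Railways" = 100,
    "Small street" = 8, "Highways" = 100, "Large street" = 100,
    "Linear Water" = 100, "Wetland" = 100, "Impervious" = 13,
    "Woodland" = 100, "Lawn" = 5, "Amenity" = 6,
    "Parks and Playspace" = 1, "Cemeteries" = 1, "Allotments" = 1,
    "Farmland" = 100, "Private Garden" = 1, "Unclassified" = 15)
}

# focal class groups for the single-landcover hypotheses
hypothesisGroups <- function() {
  list(
    RAILBAR  = list(focal = "Railways", focalValue = 100),
    RAILCOR  = list(focal = "Railways", focalValue = 1),
    ROADBAR  = list(focal = c("Small street", "Large street", "Highways"),
                    focalValue = 100),
    GREENCOR = list(focal = c("Parks and Playspace", "Cemeteries",
                              "Allotments", "Private Garden", "Lawn",
                              "Amenity", "Woodland"), focalValue = 1),
    FARMBAR  = list(focal = "Farmland", focalValue = 100),
    FARMCOR  = list(focal = "Farmland", focalValue = 1),
    WATERBAR = list(focal = c("Linear Water", "Wetland"), focalValue = 100))
}

#' Construct a movement hypothesis
#'
#' Either retrieve one of the packaged hedgehog hypotheses by name over the
#' canonical class list, or build a custom one from explicit resistances.
#'
#' Packaged hypotheses: `NULL` (isolation by distance: every traversable
#' class has resistance 1), `EMP` (empirical literature-derived per-class
#' resistances), and single-landcover hypotheses `RAILBAR`, `RAILCOR`,
#' `ROADBAR`, `GREENCOR`, `FARMBAR`, `FARMCOR`, `WATERBAR` in which the
#' focal class group takes resistance 1 or 100 and all other classes the
#' opposite value. Buildings and waterbodies are absolute barriers in every
#' packaged hypothesis.
#'
#' @param name hypothesis name.
#' @param resistances named numeric (class -> resistance >= 1) for a custom
#'   hypothesis; ignored for packaged names.
#' @param barriers character vector of absolute-barrier classes for a custom
#'   hypothesis.
#' @param classes class list for packaged hypotheses; default
#'   [canonicalPrecedence()].
#' @return A [ResistanceHypothesis-class].
#' @export
resistanceHypothesis <- function(name, resistances = NULL, barriers = character(),
                                 classes = canonicalPrecedence()) {
  if (!is.null(resistances)) {
    return(new("ResistanceHypothesis", name = name,
               resistances = resistances, barriers = barriers))
  }
  alwaysBarrier <- intersect(c("Buildings", "Waterbodies"), classes)
  if (name == "NULL") {
    r <- setNames(rep(1, length(classes)), classes)
    r <- r[setdiff(classes, alwaysBarrier)]
    return(new("ResistanceHypothesis", name = "NULL", resistances = r,
               barriers = alwaysBarrier))
  }
  if (name == "EMP") {
    emp <- empResistances()
    missing <- setdiff(classes, names(emp))
    if (length(missing))
      stop("EMP has no value for class(es): ", paste(missing, collapse = ", "))
    emp <- emp[classes]
    return(new("ResistanceHypothesis", name = "EMP",
               resistances = emp[!is.na(emp)],
               barriers = names(emp)[is.na(emp)]))
  }
  groups <- hypothesisGroups()
  if (!name %in% names(groups))
    stop("unknown hypothesis '", name, "'")
  spec <- groups[[name]]
  other <- if (spec$focalValue == 1) 100 else 1
  r <- setNames(rep(other, length(classes)), classes)
  r[intersect(spec$focal, classes)] <- spec$focalValue
  r <- r[setdiff(names(r), alwaysBarrier)]
  new("ResistanceHypothesis", name = name, resistances = r,
      barriers = alwaysBarrier)
}

setMethod("show", "ResistanceHypothesis", function(object) {
  cat("ResistanceHypothesis '", object@name, "': ",
      length(object@resistances), " classes, ",
      length(object@barriers), " barrier class(es)\n", sep = "")
  invisible(object)
})

#' Mosaic binary class masks with precedence
#'
#' Each mask is a 0/1 (or logical) matrix on a shared grid; every cell takes
#' the highest-precedence class whose mask covers it, and cells covered by
#' no mask become `Unclassified`. The result is idempotent and independent
#' of the order in which masks are supplied.
#'
#' @param masks named list of matrices (names = class names).
#' @param precedence character vector, highest priority first; default
#'   [canonicalPrecedence()]. Every mask name must appear in it.
#' @param resolution,origin grid geometry; defaults 5 m and c(0, 0).
#' @return A [LandcoverRaster-class].
#' @export
mosaicWithPrecedence <- function(masks, precedence = canonicalPrecedence(),
                                 resolution = 5, origin = c(0, 0)) {
  stopifnot(length(masks) >= 1, !is.null(names(masks)))
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all masks must share the same grid geometry")
  unknown <- setdiff(names(masks), precedence)
  if (length(unknown))
    stop("mask class(es) missing from the precedence table: ",
         paste(unknown, collapse = ", "))
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  classNames <- c("Unclassified",
                  intersect(precedence, names(masks)))
  codes <- matrix(0L, nr, nc)
  # paint lowest precedence first so higher precedence overwrites
  for (cl in rev(intersect(precedence, names(masks)))) {
    hit <- masks[[cl]] > 0
    codes[hit] <- match(cl, classNames) - 1L
  }
  legend <- setNames(classNames, as.character(seq_along(classNames) - 1L))
  new("LandcoverRaster", codes = codes, resolution = resolution,
      origin = as.numeric(origin), legend = legend)
}

#' Buffer (dilate) a linear-feature mask
#'
#' Morphological dilation by `ceil(buffer_m / resolution)` cells in the
#' chessboard metric, so thin rasterised lines are not lost in downstream
#' mosaicking.
#'
#' @param mask 0/1 or logical matrix.
#' @param bufferM buffer radius in metres (>= 0).
#' @param resolution cell size in metres; default 5.
#' @return logical matrix, a superset of the input.
#' @export
bufferLinearClass <- function(mask, bufferM, resolution = 5) {
  if (bufferM < 0) stop("buffer must be nonnegative")
  cells <- ceiling(bufferM / resolution)
  out <- mask > 0
  if (cells == 0) return(out)
  nr <- nrow(out); nc <- ncol(out)
  res <- out
  for (dr in -cells:cells) {
    for (dc in -cells:cells) {
      if (dr == 0 && dc == 0) next
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      rsSrc <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      csSrc <- max(1, 1 - dc):min(nc, nc - dc)
      res[rs, cs] <- res[rs, cs] | out[rsSrc, csSrc]
    }
  }
  res
}

#' Build a resistance surface from landcover under a hypothesis
#'
#' Cell-wise lookup of each landcover class in the hypothesis: classes in
#' the barrier set become non-traversable (`NA`), all others take their
#' finite resistance. A legend class mapped by neither is an error naming
#' the class.
#'
#' @param lc a [LandcoverRaster-class].
#' @param hyp a [ResistanceHypothesis-class], or a packaged hypothesis name
#'   (passed to [resistanceHypothesis()] with the raster's legend classes).
#' @param barrierResistance optional finite value to substitute for
#'   barriers (sensitivity checks); default NA keeps them non-traversable.
#' @return A [ResistanceSurface-class].
#' @export
buildResistanceSurface <- function(lc, hyp, barrierResistance = NA) {
  if (is.character(hyp))
    hyp <- resistanceHypothesis(hyp, classes = unname(lc@legend))
  present <- unique(as.vector(lc@codes))
  classes <- unname(lc@legend[as.character(present)])
  unmapped <- setdiff(classes, c(names(hyp@resistances), hyp@barriers))
  if (length(unmapped))
    stop("hypothesis '", hyp@name, "' does not map class(es): ",
         paste(unmapped, collapse = ", "))
  lookup <- c(hyp@resistances,
              setNames(rep(if (is.na(barrierResistance)) NA_real_
                           else barrierResistance,
                           length(hyp@barriers)), hyp@barriers))
  classOfCell <- lc@legend[as.character(lc@codes)]
  r <- matrix(lookup[classOfCell], nrow(lc@codes), ncol(lc@codes))
  new("ResistanceSurface", resistance = r, hypothesis = hyp@name,
      resolution = lc@resolution, origin = lc@origin)
}

#' @describeIn buildResistanceSurface resistance matrix (NA = barrier)
#' @param x a ResistanceSurface
#' @export
resistanceValues <- function(x) x@resistance

setMethod("show", "ResistanceSurface", function(object) {
  r <- object@resistance
  cat("ResistanceSurface '", object@hypothesis, "': ", nrow(r), "x", ncol(r),
      " cells @ ", object@resolution, "m; ", sum(is.na(r)),
      " barrier cells\n", sep = "")
  invisible(object)
})

#' Proportion of urban landcover around a point
#'
#' Fraction of cells whose centre lies within `radiusM` of the point that
#' carry an urban class. Buffers clipped at the raster edge use in-bounds
#' cells only.
#'
#' @param lc a [LandcoverRaster-class].
#' @param point numeric length-2 projected x, y (must be within the raster).
#' @param radiusM buffer radius in metres.
#' @param urbanClasses class names counted as urban; default buildings, the
#'   street types, railways and impervious cover.
#' @return fraction in [0, 1].
#' @export
urbanProportion <- function(lc, point, radiusM,
                            urbanClasses = c("Buildings", "Small street",
                                             "Large street", "Highways",
                                             "Railways", "Impervious")) {
  nr <- nrow(lc@codes); nc <- ncol(lc@codes)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ctr <- cellCentres(lc, as.vector(rows), as.vector(cols))
  inBuf <- (ctr[, 1] - point[1])^2 + (ctr[, 2] - point[2])^2 <= radiusM^2
  if (!any(inBuf)) stop("no cell centres within the buffer; point may be ",
                        "outside the raster or the radius too small")
  classOfCell <- lc@legend[as.character(as.vector(lc@codes))]
  mean(classOfCell[inBuf] %in% urbanClasses)
}

#' Resample a landcover raster to a coarser resolution (majority rule)
#'
#' Aggregates blocks of `factor x factor` cells into one cell carrying the
#' modal class (ties to the highest-precedence class among the tied ones).
#'
#' @param lc a [LandcoverRaster-class].
#' @param factor integer aggregation factor (>= 1).
#' @param precedence tie-break order; default [canonicalPrecedence()].
#' @return A [LandcoverRaster-class] at `resolution * factor`.
#' @export
resampleLandcover <- function(lc, factor, precedence = canonicalPrecedence()) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(lc)
  nr <- nrow(lc@codes) %/% factor
  nc <- ncol(lc@codes) %/% factor
  if (nr < 1 || nc < 1) stop("factor larger than the grid")
  out <- matrix(0L, nr, nc)
  prRank <- function(code) {
    cl <- lc@legend[as.character(code)]
    r <- match(cl, precedence)
    ifelse(is.na(r), length(precedence) + 1L, r)
  }
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- lc@codes[((i - 1) * factor + 1):(i * factor),
                        ((j - 1) * factor + 1):(j * factor)]
      tab <- table(as.vector(block))
      top <- as.integer(names(tab)[tab == max(tab)])
      out[i, j] <- top[which.min(prRank(top))]
    }
  }
  new("LandcoverRaster", codes = out, resolution = lc@resolution * factor,
      origin = lc@origin, legend = lc@legend)
}

#' Clip a landcover raster to a rectangle around points
#'
#' @param lc a [LandcoverRaster-class].
#' @param points 2-column matrix of projected x, y.
#' @param marginM margin in metres around the points' bounding box.
#' @return A clipped [LandcoverRaster-class].
#' @export
clipLandcover <- function(lc, points, marginM = 3000) {
  points <- rbind(points)
  cells <- cellAt(lc, cbind(
    pmin(pmax(points[, 1], lc@origin[1]), lc@origin[1] +
           ncol(lc@codes) * lc@resolution - 1e-9),
    pmin(pmax(points[, 2], lc@origin[2] -
                nrow(lc@codes) * lc@resolution + 1e-9), lc@origin[2])))
  m <- ceiling(marginM / lc@resolution)
  r1 <- max(1L, min(cells[, 1]) - m); r2 <- min(nrow(lc@codes), max(cells[, 1]) + m)
  c1 <- max(1L, min(cells[, 2]) - m); c2 <- min(ncol(lc@codes), max(cells[, 2]) + m)
  new("LandcoverRaster", codes = lc@codes[r1:r2, c1:c2, drop = FALSE],
      resolution = lc@resolution,
      origin = c(lc@origin[1] + (c1 - 1) * lc@resolution,
                 lc@origin[2] - (r1 - 1) * lc@resolution),
      legend = lc@legend)
}
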