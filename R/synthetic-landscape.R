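#' Generate a categorical synthetic landscape
#'
#' Produces a [LandcoverRaster-class] from a landscape specification:
#' patch-type classes are laid down by thresholded smoothed Gaussian noise
#' (weights control expected coverage), then linear-feature classes (roads,
#' railways, rivers) are drawn as straight or wandering strips at least one
#' cell wide that span the full grid, overwriting patch classes. Every cell
#' receives exactly one class; the output is a pure function of
#' `(spec, seed)`.
#'
#' @param spec list with elements:
#'   \describe{
#'     \item{nrow, ncol}{grid dimensions (>= 8 each when linear features are
#'       requested; >= 1 otherwise)}
#'     \item{resolution}{cell size in metres (> 0); default 5}
#'     \item{origin}{projected x,y of the top-left corner; default c(0, 0)}
#'     \item{classes}{list of class specs, each a list with `name`, and
#'       either `weight` (> 0, patch class) or `type` one of
#'       `"vstrip"`, `"hstrip"`, `"wander"` with optional `width` (cells,
#'       default 1) and `at` (column/row index for straight strips)}
#'   }
#' @param seed integer seed.
#' @return A [LandcoverRaster-class]; legend codes are assigned in class
#'   order, plus an `Unclassified` code 0 (unused unless no patch class is
#'   given).
#' @export
generateLandscape <- function(spec, seed) {
  stopifnot(is.list(spec), !is.null(spec$nrow), !is.null(spec$ncol))
  nr <- as.integer(spec$nrow); nc <- as.integer(spec$ncol)
  res <- if (is.null(spec$resolution)) 5 else spec$resolution
  if (res <= 0) stop("resolution must be positive")
  origin <- if (is.null(spec$origin)) c(0, 0) else spec$origin
  classes <- spec$classes
  if (is.null(classes) || !length(classes)) stop("class list must not be empty")
  isLinear <- vapply(classes, function(cl)
    !is.null(cl$type) && cl$type %in% c("vstrip", "hstrip", "wander"), logical(1))
  if (any(isLinear) && (nr < 8 || nc < 8))
    stop("grids with linear features must be at least 8x8")
  patch <- classes[!isLinear]
  linear <- classes[isLinear]
  if (length(patch)) {
    w <- vapply(patch, function(cl) if (is.null(cl$weight)) 1 else cl$weight,
                numeric(1))
    if (sum(w) <= 0) stop("patch class weights must sum to > 0")
  }

  set.seed(seed)
  codes <- matrix(0L, nr, nc)
  names <- "Unclassified"
  codeOf <- c(Unclassified = 0L)
  nextCode <- 1L
  for (cl in classes) {
    codeOf[[cl$name]] <- nextCode
    names <- c(names, cl$name)
    nextCode <- nextCode + 1L
  }

  if (length(patch) == 1L) {
    codes[] <- codeOf[[patch[[1L]]$name]]
  } else if (length(patch) > 1L) {
    # one smoothed noise field per patch class; cell takes the argmax of
    # field + log(weight) so heavier classes claim more ground
    fields <- lapply(patch, function(cl) {
      f <- matrix(rnorm(nr * nc), nr, nc)
      smoothField(f, span = max(2L, round(min(nr, nc) / 8)))
    })
    w <- vapply(patch, function(cl) if (is.null(cl$weight)) 1 else cl$weight,
                numeric(1))
    stacked <- vapply(seq_along(fields),
                      function(k) as.vector(fields[[k]]) + log(w[k]),
                      numeric(nr * nc))
    pick <- max.col(stacked, ties.method = "first")
    codes[] <- vapply(patch, function(cl) codeOf[[cl$name]], integer(1))[pick]
  }

  for (cl in linear) {
    width <- if (is.null(cl$width)) 1L else as.integer(cl$width)
    code <- codeOf[[cl$name]]
    if (cl$type == "vstrip") {
      at <- if (is.null(cl$at)) sample.int(nc, 1L) else as.integer(cl$at)
      colsHit <- pmax(1L, pmin(nc, at + seq_len(width) - 1L))
      codes[, colsHit] <- code
    } else if (cl$type == "hstrip") {
      at <- if (is.null(cl$at)) sample.int(nr, 1L) else as.integer(cl$at)
      rowsHit <- pmax(1L, pmin(nr, at + seq_len(width) - 1L))
      codes[rowsHit, ] <- code
    } else { # wander: random-walk column per row, spans top to bottom
      col <- if (is.null(cl$at)) sample.int(nc, 1L) else as.integer(cl$at)
      for (r in seq_len(nr)) {
        col <- min(nc, max(1L, col + sample(c(-1L, 0L, 1L), 1L)))
        hit <- pmax(1L, pmin(nc, col + seq_len(width) - 1L))
        codes[r, hit] <- code
      }
    }
  }

  # legend: code 0 = Unclassified, then one code per class in spec order
  legend <- setNames(names, as.character(seq_along(names) - 1L))
  new("LandcoverRaster", codes = codes, resolution = res,
      origin = as.numeric(origin), legend = legend)
}

# separable box smoothing with reflecting edges, standardised to unit
# variance so class weights act as comparable log-odds shifts
smoothField <- function(f, span) {
  out <- smoothFieldRaw(f, span)
  (out - mean(out)) / max(sd(out), .Machine$double.eps)
}

smoothFieldRaw <- function(f, span) {
  k <- 2L * span + 1L
  pad <- function(m) {
    top <- m[rev(seq_len(span)), , drop = FALSE]
    bot <- m[nrow(m) - seq_len(span) + 1L, , drop = FALSE]
    rbind(top, m, bot)
  }
  sm1 <- function(m) {
    p <- pad(m)
    cs <- apply(p, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(k + 1L):nrow(cs), , drop = FALSE] -
       cs[seq_len(nrow(cs) - k), , drop = FALSE]) / k
  }
  t(sm1(t(sm1(f))))
}

#' @describeIn generateLandscape class-code matrix of a LandcoverRaster
#' @param x a LandcoverRaster
#' @export
landcoverCodes <- function(x) x@codes

#' @describeIn generateLandscape legend (code -> class name)
#' @export
landcoverLegend <- function(x) x@legend

#' @describeIn generateLandscape cell resolution in metres
#' @export
resolution <- function(x) x@resolution

setMethod("show", "LandcoverRaster", function(object) {
  cat("LandcoverRaster:", nrow(object@codes), "x", ncol(object@codes),
      "cells @", object@resolution, "m\n")
  tab <- table(factor(as.vector(object@codes),
                      levels = names(object@legend), labels = object@legend))
  tab <- tab[tab > 0]
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(object)
})

#' Projected coordinates of cell centres
#'
#' @param x a LandcoverRaster or ResistanceSurface
#' @param rows,cols 1-based cell indices (vectorised)
#' @return matrix with columns x, y
#' @export
cellCentres <- function(x, rows, cols) {
  cbind(x = x@origin[1] + (cols - 0.5) * x@resolution,
        y = x@origin[2] - (rows - 0.5) * x@resolution)
}

#' Locate the cell containing a projected point
#' @param x a LandcoverRaster or ResistanceSurface
#' @param xy numeric length-2 or 2-column matrix of projected coordinates
#' @return matrix with columns row, col (NA if out of bounds)
#' @export
cellAt <- function(x, xy) {
  xy <- rbind(xy)
  dims <- dim(if (is(x, "LandcoverRaster")) x@codes else x@resistance)
  col <- floor((xy[, 1] - x@origin[1]) / x@resolution) + 1L
  row <- floor((x@origin[2] - xy[, 2]) / x@resolution) + 1L
  bad <- row < 1L | row > dims[1] | col < 1L | col > dims[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Write / read a landcover raster as an ESRI ASCII grid with a JSON legend
#'
#' The grid goes to `<path>` in ESRI ASCII (.asc) format and the legend to
#' `<path>.legend.json`. Plain-text, georeferenced, square cells.
#' @param x a LandcoverRaster
#' @param path output path (conventionally ending .asc)
#' @export
writeLandcover <- function(x, path) {
  writeAsciiGrid(x@codes, path, x@resolution, x@origin)
  jsonlite::write_json(as.list(x@legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLandcover
#' @export
readLandcover <- function(path) {
  g <- readAsciiGrid(path)
  legendPath <- paste0(path, ".legend.json")
  legend <- if (file.exists(legendPath)) {
    l <- jsonlite::read_json(legendPath)
    setNames(unlist(l), names(l))
  } else {
    codes <- sort(unique(as.vector(g$values)))
    setNames(paste0("class", codes), as.character(codes))
  }
  if (!"Unclassified" %in% legend)
    legend <- c(legend, setNames("Unclassified",
                                 as.character(max(as.integer(names(legend))) + 1L)))
  m <- g$values
  mode(m) <- "integer"
  new("LandcoverRaster", codes = m, resolution = g$resolution,
      origin = g$origin, legend = legend)
}

# ESRI ASCII grid primitives (text raster format; cellsize in metres,
# corner registration). origin here is the TOP-left corner.
writeAsciiGrid <- function(values, path, resolution, origin, naValue = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  xll <- origin[1]
  yll <- origin[2] - nr * resolution
  v <- values
  v[is.na(v)] <- naValue
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(resolution, scientific = FALSE)),
    paste("NODATA_value", naValue)), con)
  for (r in seq_len(nr))
    writeLines(paste(v[r, ], collapse = " "), con)
  invisible(path)
}

readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  nr <- hdr$nrows; nc <- hdr$ncols
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  stopifnot(length(vals) == nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  list(values = m, resolution = hdr$cellsize, origin = origin)
}
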