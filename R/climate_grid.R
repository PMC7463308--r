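# Lightweight raster container for multi-variable climate grids, with
# plain-text (ESRI ASCII grid) input/output. Cells are regular, addressed by
# the vectors of cell-centre coordinates; one value matrix per variable
# (rows = y descending, cols = x ascending); a shared NA mask.

#' Climate grid
#'
#' @param x,y vectors of regularly spaced cell-centre coordinates (x
#'   ascending, y ascending).
#' @param values named list of `length(y) x length(x)` matrices, one per
#'   bioclimatic variable.
#' @param epoch `"current"` or `"future"`.
#' @param mask optional logical matrix (TRUE = cell used); defaults to cells
#'   with complete data across variables.
#' @return A `climate_grid` object.
#' @export
climate_grid <- function(x, y, values, epoch = "current", mask = NULL) {
  stopifnot(is.list(values), length(values) >= 1, !is.null(names(values)))
  for (v in values)
    if (!all(dim(v) == c(length(y), length(x))))
      stop("each value matrix must be length(y) x length(x)")
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(values, function(v) is.finite(v)))
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), values = values,
                 epoch = epoch, mask = mask),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid (%s): %d x %d cells, %d variables (%s), %d masked\n",
              x$epoch, length(x$x), length(x$y), length(x$values),
              paste(names(x$values), collapse = ", "), sum(!x$mask)))
  invisible(x)
}

grid_vars <- function(grid) names(grid$values)

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y)) &&
    identical(dim(a$mask), dim(b$mask)) && all(a$mask == b$mask)
}

# cells x variables matrix over unmasked cells (row order: column-major over
# the mask), with cell coordinates attached
grid_cells <- function(grid) {
  idx <- which(grid$mask)
  vals <- vapply(grid$values, function(v) v[idx], numeric(length(idx)))
  vals <- matrix(vals, nrow = length(idx),
                 dimnames = list(NULL, names(grid$values)))
  rc <- arrayInd(idx, dim(grid$mask))
  attr(vals, "coords") <- data.frame(lon = grid$x[rc[, 2]],
                                     lat = grid$y[rc[, 1]])
  attr(vals, "index") <- idx
  vals
}

#' Extract grid values at site coordinates
#'
#' Nearest-cell lookup of every variable at each site.
#'
#' @param grid a [climate_grid()].
#' @param coords data frame with `lon`, `lat`.
#' @return Data frame of per-site predictor values.
#' @export
extract_sites <- function(grid, coords) {
  ix <- vapply(coords$lon, function(v) which.min(abs(grid$x - v)), integer(1))
  iy <- vapply(coords$lat, function(v) which.min(abs(grid$y - v)), integer(1))
  out <- lapply(grid$values, function(m) m[cbind(iy, ix)])
  as.data.frame(out)
}

#' Write one grid variable as an ESRI ASCII grid
#'
#' @param grid a [climate_grid()].
#' @param var variable name.
#' @param path output file.
#' @export
write_ascii_grid <- function(grid, var, path) {
  m <- grid$values[[var]]
  if (is.null(m)) stop("unknown variable ", var)
  m[!grid$mask] <- NA
  cs <- if (length(grid$x) > 1) diff(grid$x[1:2]) else 1
  hdr <- c(paste("ncols", length(grid$x)),
           paste("nrows", length(grid$y)),
           paste("xllcorner", grid$x[1] - cs / 2),
           paste("yllcorner", grid$y[1] - cs / 2),
           paste("cellsize", cs),
           "NODATA_value -9999")
  m2 <- m[rev(seq_along(grid$y)), , drop = FALSE]  # top row first
  m2[is.na(m2)] <- -9999
  lines <- apply(m2, 1, paste, collapse = " ")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read ESRI ASCII grids into a climate grid
#'
#' @param paths named character vector, one file per variable.
#' @param epoch epoch tag.
#' @return A [climate_grid()].
#' @export
read_ascii_grid <- function(paths, epoch = "current") {
  vals <- list()
  geom <- NULL
  for (v in names(paths)) {
    ln <- readLines(paths[[v]])
    hdr <- strsplit(trimws(ln[1:6]), "\\s+")
    hv <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                   tolower(vapply(hdr, `[`, "", 1)))
    body <- do.call(rbind, lapply(ln[-(1:6)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    body[body == hv[["nodata_value"]]] <- NA
    m <- body[rev(seq_len(nrow(body))), , drop = FALSE]  # back to y ascending
    vals[[v]] <- m
    geom <- hv
  }
  cs <- geom[["cellsize"]]
  x <- geom[["xllcorner"]] + cs / 2 + cs * (seq_len(geom[["ncols"]]) - 1)
  y <- geom[["yllcorner"]] + cs / 2 + cs * (seq_len(geom[["nrows"]]) - 1)
  climate_grid(x, y, vals, epoch = epoch)
}
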