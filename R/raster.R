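# Plain-text grid container and nearest-cell point extraction.
#
# The grid format mirrors the ESRI ASCII header (ncols/nrows/xllcorner/
# yllcorner/cellsize/nodata_value) followed by nrows lines of ncols values,
# first line = northernmost row. Cells are half-open [x, x + dx) so that
# categorical rasters (e.g. soil class) are never interpolated.

#' Construct an in-memory grid
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length (same units as the coordinates), > 0.
#' @param nodata Sentinel value marking missing cells.
#' @param crs Free-text coordinate reference label.
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                       crs = "WGS84") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), cellsize > 0,
            is.finite(xll), is.finite(yll))
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat("<ascii_grid> ", nrow(x$values), "x", ncol(x$values),
      " cells, cellsize ", x$cellsize, ", origin (", x$xll, ", ", x$yll,
      "), crs ", x$crs, "\n", sep = "")
  invisible(x)
}

#' Read a plain-text grid file
#'
#' @param path Path to a text grid (ESRI-ASCII-style header + rows).
#' @return An `ascii_grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- kv[2]
    i <- i + 1
  }
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  nodata <- as.numeric(hdr$nodata_value %||% -9999)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == ncols * nrows)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  ascii_grid(m, xll = as.numeric(hdr$xllcorner %||% hdr$xll),
             yll = as.numeric(hdr$yllcorner %||% hdr$yll),
             cellsize = as.numeric(hdr$cellsize), nodata = nodata,
             crs = hdr$crs %||% "WGS84")
}

#' Write a plain-text grid file
#'
#' @param grid An `ascii_grid`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid$values)),
    paste("nrows", nrow(grid$values)),
    paste("xllcorner", format(grid$xll, digits = 15)),
    paste("yllcorner", format(grid$yll, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("nodata_value", format(grid$nodata, digits = 15)),
    paste("crs", grid$crs)), con)
  apply(grid$values, 1, function(r) {
    writeLines(paste(format(r, digits = 15, trim = TRUE), collapse = " "), con)
  })
  invisible(path)
}

#' Extract point values from a grid by nearest cell
#'
#' Looks up the grid cell containing each point under the half-open cell
#' convention `[x, x + dx)`, `[y, y + dy)` and returns the cell value under
#' `name_out`, ready to merge onto a weather table by `env_id`. Values
#' equal to the grid's nodata sentinel are returned as `NA` (flagged, never
#' silently numeric).
#'
#' @param points Data frame with columns `env_id`, `lat`, `lon`.
#' @param raster An `ascii_grid` (x = longitude, y = latitude).
#' @param name_out Name of the value column in the result.
#' @return Tibble with columns `env_id` and `name_out`.
#' @export
extract_gis <- function(points, raster, name_out = "value") {
  stopifnot(inherits(raster, "ascii_grid"),
            all(c("env_id", "lat", "lon") %in% names(points)))
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  dx <- raster$cellsize
  xmax <- raster$xll + nc * dx
  ymax <- raster$yll + nr * dx
  col <- floor((points$lon - raster$xll) / dx) + 1L
  # row index counted from the bottom, matrix stored top-down
  row_bottom <- floor((points$lat - raster$yll) / dx) + 1L
  outside <- points$lon < raster$xll | points$lon >= xmax |
    points$lat < raster$yll | points$lat >= ymax
  if (any(outside)) {
    stop("point(s) outside raster extent: ",
         paste(points$env_id[outside], collapse = ", "), call. = FALSE)
  }
  row_top <- nr - row_bottom + 1L
  vals <- raster$values[cbind(row_top, col)]
  vals[vals == raster$nodata] <- NA_real_
  out <- tibble::tibble(env_id = points$env_id, value = vals)
  names(out)[2] <- name_out
  out
}
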