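#' Co-registered stack of environmental predictor rasters
#'
#' Layers are plain numeric matrices sharing dimensions and a minimal
#' geotransform: cell-center registration, row 1 = northernmost row,
#' `xmin`/`ymax` the outer edge of the top-left cell, square cells of size
#' `cellsize` (map units). `NA` cells are missing and propagate through
#' extraction, prediction and overlays.
#'
#' @param layers named list of numeric matrices with identical dimensions.
#' @param xmin,ymax coordinates of the top-left corner of the grid.
#' @param cellsize cell edge length in map units.
#' @return A `predictor_stack`.
#' @export
predictor_stack <- function(layers, xmin = 0, ymax = NULL, cellsize = 1) {
  stopifnot(is.list(layers), length(layers) > 0L)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop("layers must be named")
  }
  dims <- lapply(layers, dim)
  if (any(vapply(layers, function(m) !is.matrix(m), TRUE))) {
    stop("every layer must be a matrix")
  }
  d1 <- dims[[1L]]
  if (!all(vapply(dims, identical, TRUE, d1))) {
    stop("all layers must share the same dimensions")
  }
  if (is.null(ymax)) ymax <- d1[1L] * cellsize
  structure(list(layers = layers, nrow = d1[1L], ncol = d1[2L],
                 xmin = xmin, ymax = ymax, cellsize = cellsize),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat("Predictor stack:", length(x$layers), "layer(s),",
      x$nrow, "x", x$ncol, "cells, cellsize", x$cellsize, "\n")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  miss <- sum(Reduce(`|`, lapply(x$layers, is.na)))
  cat("  masked cells (missing in any layer):", miss, "\n")
  invisible(x)
}

# combined missing mask: TRUE where any layer is NA
stack_mask <- function(stack) {
  Reduce(`|`, lapply(stack$layers, is.na))
}

#' Extract predictor values at station coordinates
#'
#' Nearest-cell rule (no interpolation): each station maps to the cell whose
#' center is nearest to its coordinates; coordinates outside the grid are an
#' error.
#'
#' @param stack a `predictor_stack`.
#' @param x,y station coordinates in map units.
#' @return matrix (stations x predictors) of extracted values; `NA` for
#'   masked cells.
#' @export
extract_stations <- function(stack, x, y) {
  stopifnot(inherits(stack, "predictor_stack"), length(x) == length(y))
  col <- floor((x - stack$xmin) / stack$cellsize) + 1L
  row <- floor((stack$ymax - y) / stack$cellsize) + 1L
  # a coordinate exactly on the outer max edge belongs to the last cell
  col[x == stack$xmin + stack$ncol * stack$cellsize] <- stack$ncol
  row[y == stack$ymax - stack$nrow * stack$cellsize] <- stack$nrow
  if (any(col < 1L | col > stack$ncol | row < 1L | row > stack$nrow)) {
    stop("station coordinates fall outside the raster grid")
  }
  out <- vapply(stack$layers,
                function(m) m[cbind(row, col)],
                numeric(length(x)))
  if (length(x) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, names(stack$layers)))
  out
}

# cell-index helper used by the synthetic generator
cell_center_xy <- function(stack, row, col) {
  list(x = stack$xmin + (col - 0.5) * stack$cellsize,
       y = stack$ymax - (row - 0.5) * stack$cellsize)
}

#' Read / write a raster layer as an ESRI ASCII grid
#'
#' Plain-text grid exchange format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by rows from north to south).
#'
#' @param m numeric matrix (row 1 = northernmost row).
#' @param path file path (`.asc`).
#' @param xmin,ymax,cellsize geotransform as in [predictor_stack()].
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(m, path, xmin = 0, ymax = nrow(m),
                             cellsize = 1, nodata = -9999) {
  stopifnot(is.matrix(m))
  yll <- ymax - nrow(m) * cellsize
  hdr <- c(paste("ncols", ncol(m)),
           paste("nrows", nrow(m)),
           paste("xllcorner", xmin),
           paste("yllcorner", yll),
           paste("cellsize", cellsize),
           paste("NODATA_value", nodata))
  body <- apply(m, 1L, function(r) {
    r[is.na(r)] <- nodata
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid()`: list with `matrix`, `xmin`, `ymax`,
#'   `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "[[:space:]]+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]])
  }))
  m[m == vals[["nodata_value"]]] <- NA_real_
  list(matrix = m,
       xmin = vals[["xllcorner"]],
       ymax = vals[["yllcorner"]] + vals[["nrows"]] * vals[["cellsize"]],
       cellsize = vals[["cellsize"]])
}

#' Write / read all layers of a stack as ASCII grids in a directory
#'
#' @param stack a `predictor_stack`.
#' @param dir directory; one `<layer>.asc` per layer.
#' @export
write_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     xmin = stack$xmin, ymax = stack$ymax,
                     cellsize = stack$cellsize)
  }
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0L) stop("no .asc layers in ", dir)
  grids <- lapply(files, read_ascii_grid)
  g1 <- grids[[1L]]
  layers <- lapply(grids, `[[`, "matrix")
  names(layers) <- sub("\\.asc$", "", basename(files))
  predictor_stack(layers, xmin = g1$xmin, ymax = g1$ymax,
                  cellsize = g1$cellsize)
}
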