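#' Bivariate hotspot overlay of two index rasters
#'
#' Compares where two index surfaces (e.g. bioirrigation vs bioturbation
#' potential) are relatively high. Each raster is reduced to within-raster
#' quantile ranks over its unmasked cells (midranks for ties, scaled to
#' (0, 1]), which makes the overlay invariant to any monotone rescaling of
#' either input — log vs linear scale is irrelevant. A cell is classed
#'
#' * `a_higher`  if rank_A - rank_B >  `delta_quantile`,
#' * `b_higher`  if rank_A - rank_B < -`delta_quantile`,
#' * `both_hot`  if both ranks >= `hot_quantile` and the rank difference is
#'   within `delta_quantile`,
#' * `neither`   otherwise.
#'
#' The "hotspot" rule is a documented operationalization with exposed
#' thresholds, not a published definition. Cells masked in either raster
#' stay masked.
#'
#' @param raster_a,raster_b co-registered numeric matrices.
#' @param hot_quantile rank both rasters must reach for `both_hot`
#'   (default 0.75).
#' @param delta_quantile rank difference treated as disagreement
#'   (default 0.10).
#' @return An `overlay_raster`: integer `class` matrix coded by `legend`
#'   (1 = a_higher, 2 = b_higher, 3 = both_hot, 4 = neither), the rank
#'   matrices, and the thresholds used.
#' @export
overlay_hotspots <- function(raster_a, raster_b, hot_quantile = 0.75,
                             delta_quantile = 0.10) {
  stopifnot(is.matrix(raster_a), is.matrix(raster_b))
  if (!identical(dim(raster_a), dim(raster_b))) {
    stop("rasters are not co-registered: dimensions differ")
  }
  stopifnot(hot_quantile > 0, hot_quantile <= 1,
            delta_quantile >= 0, delta_quantile < 1)
  mask <- is.na(raster_a) | is.na(raster_b)
  ra <- quantile_ranks(raster_a, mask)
  rb <- quantile_ranks(raster_b, mask)
  d <- ra - rb
  cls <- matrix(NA_integer_, nrow(raster_a), ncol(raster_a))
  cls[!mask] <- 4L
  cls[!mask & d > delta_quantile] <- 1L
  cls[!mask & d < -delta_quantile] <- 2L
  cls[!mask & abs(d) <= delta_quantile &
        ra >= hot_quantile & rb >= hot_quantile] <- 3L
  structure(list(class = cls,
                 legend = c(a_higher = 1L, b_higher = 2L, both_hot = 3L,
                            neither = 4L),
                 rank_a = ra, rank_b = rb,
                 hot_quantile = hot_quantile,
                 delta_quantile = delta_quantile),
            class = "overlay_raster")
}

# within-raster quantile ranks on unmasked cells: midranks / n, in (0, 1]
quantile_ranks <- function(m, mask) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  v <- m[!mask]
  if (length(v) > 0L) out[!mask] <- rank(v, ties.method = "average") / length(v)
  out
}

#' @export
print.overlay_raster <- function(x, ...) {
  cat("Bivariate hotspot overlay (hot >=", x$hot_quantile,
      ", delta >", x$delta_quantile, ")\n")
  tab <- table(factor(x$class, levels = x$legend,
                      labels = names(x$legend)))
  print(tab)
  cat("masked cells:", sum(is.na(x$class)), "\n")
  invisible(x)
}

#' Write an overlay raster with its class legend
#'
#' The class grid goes to an ASCII grid file and the legend to a plain-text
#' sidecar (`<path>.legend.txt`).
#'
#' @param overlay an `overlay_raster`.
#' @param path output `.asc` path.
#' @inheritParams write_ascii_grid
#' @export
write_overlay <- function(overlay, path, xmin = 0,
                          ymax = nrow(overlay$class), cellsize = 1) {
  write_ascii_grid(overlay$class + 0, path, xmin = xmin, ymax = ymax,
                   cellsize = cellsize)
  legend_path <- paste0(path, ".legend.txt")
  writeLines(c(sprintf("%d = %s", overlay$legend, names(overlay$legend)),
               sprintf("hot_quantile = %g", overlay$hot_quantile),
               sprintf("delta_quantile = %g", overlay$delta_quantile)),
             legend_path)
  invisible(path)
}
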