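#' Five-number summaries of index values per station
#'
#' Boxplot statistics (min, Q1, median, Q3, max; linear-interpolation
#' quantiles) of the index per station, for temporal-variability displays.
#'
#' @param values numeric index values.
#' @param stations station label per value.
#' @param station_order optional explicit ordering of stations (e.g. by
#'   system then descending salinity); default is first appearance.
#' @return data.frame: station, n, min, q1, median, q3, max.
#' @export
station_boxstats <- function(values, stations, station_order = NULL) {
  stopifnot(length(values) == length(stations))
  stations <- as.character(stations)
  ord <- if (is.null(station_order)) unique(stations) else station_order
  rows <- lapply(ord, function(st) {
    v <- values[stations == st]
    if (length(v) == 0L) stop("no values for station ", st)
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    data.frame(station = st, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Index values are transformed (default log10(x+1), matching the transform
#' applied to the right-skewed index elsewhere in the pipeline), submitted
#' to a one-way ANOVA, and all pairwise group differences are tested with
#' Tukey's honestly-significant-difference procedure (Tukey-Kramer for
#' unequal group sizes, via [stats::TukeyHSD()]). Letters are assigned by
#' the insert-and-absorb algorithm so that two groups share a letter if and
#' only if their adjusted p-value is at or above `alpha`.
#'
#' If every group has zero within-group variance the comparison is exact:
#' groups with identical means share letters, all others are separated.
#'
#' @param values numeric response values.
#' @param groups group label per value (>= 2 groups).
#' @param alpha significance level (default 0.05).
#' @param transform monotone transform applied before the ANOVA; use
#'   `identity` to analyse the raw scale.
#' @return A `bip_cld`: `means` (transformed scale, by group), `pairs`
#'   (data.frame group1, group2, diff, p_adj), `letters` (named character),
#'   `alpha`, `transform` label.
#' @export
tukey_letters <- function(values, groups, alpha = 0.05,
                          transform = function(x) log10(x + 1)) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least two groups")
  if (any(table(groups) < 1L)) stop("empty group")
  y <- transform(values)
  g <- factor(groups, levels = lev)
  means <- tapply(y, g, mean)

  within_ss <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (within_ss <= .Machine$double.eps * sum(y^2 + 1)) {
    # degenerate: no residual variance; equal means are indistinguishable,
    # unequal means are exactly separated
    cmb <- utils::combn(lev, 2L)
    pairs <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
                        diff = means[cmb[2L, ]] - means[cmb[1L, ]],
                        p_adj = as.numeric(means[cmb[1L, ]] == means[cmb[2L, ]]),
                        stringsAsFactors = FALSE)
  } else {
    fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    # index rows by constructed pair names (group labels may contain "-")
    cmb <- utils::combn(lev, 2L)
    rn <- paste(cmb[2L, ], cmb[1L, ], sep = "-")
    stopifnot(all(rn %in% rownames(tk)))
    pairs <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
                        diff = unname(tk[rn, "diff"]),
                        p_adj = unname(tk[rn, "p adj"]),
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  letters <- cld_insert_absorb(lev[order(-means[lev])], pairs, alpha)
  structure(list(means = means, pairs = pairs, letters = letters[lev],
                 alpha = alpha,
                 transform = deparse1(substitute(transform))),
            class = "bip_cld")
}

# Insert-and-absorb compact letter display. `ordered_groups` fixes the
# letter order (typically by descending mean). Guarantees: significant
# pairs never share a letter; non-significant pairs share at least one.
cld_insert_absorb <- function(ordered_groups, pairs, alpha) {
  cols <- list(ordered_groups)
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    a <- sig$group1[k]; b <- sig$group2[k]
    new_cols <- list()
    for (col in cols) {
      if (all(c(a, b) %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop duplicates and columns contained in another column
    new_cols <- unique(lapply(new_cols, sort))
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            length(new_cols[[i]]) < length(new_cols[[j]]) &&
            all(new_cols[[i]] %in% new_cols[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the position of their first group, assign letters
  pos <- vapply(cols, function(col)
    min(match(col, ordered_groups)), numeric(1))
  cols <- cols[order(pos)]
  out <- stats::setNames(rep("", length(ordered_groups)), ordered_groups)
  for (i in seq_along(cols)) {
    ltr <- letters[i]
    for (gp in cols[[i]]) out[gp] <- paste0(out[gp], ltr)
  }
  # sort letters within each group for a stable display
  vapply(out, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
}

#' @export
print.bip_cld <- function(x, ...) {
  df <- data.frame(group = names(x$means),
                   mean = as.numeric(x$means),
                   letters = unname(x$letters[names(x$means)]))
  cat("Tukey HSD compact letter display (alpha =", x$alpha, ")\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Advective / diffusive contrast of mean index values
#'
#' Ratio of arithmetic means of the untransformed index between the two
#' sediment systems, with the Tukey HSD adjusted p-value of the
#' system factor (computed on the `transform` scale).
#'
#' @param values numeric index values.
#' @param systems `"diffusive"` / `"advective"` label per value; both must
#'   be present.
#' @param by_station optional station label per value; when given, the
#'   ratio is computed on station means rather than pooled samples.
#' @param transform transform for the significance test (default
#'   log10(x+1)).
#' @return list: `ratio` (advective/diffusive), `mean_advective`,
#'   `mean_diffusive`, `tukey_p`.
#' @export
system_contrast <- function(values, systems,
                            by_station = NULL,
                            transform = function(x) log10(x + 1)) {
  systems <- as.character(systems)
  stopifnot(length(values) == length(systems))
  if (!all(c("diffusive", "advective") %in% systems)) {
    stop("both systems must be represented")
  }
  if (!is.null(by_station)) {
    st_mean <- tapply(values, by_station, mean)
    st_sys <- tapply(systems, by_station, function(s) s[1L])
    values <- as.numeric(st_mean)
    systems <- as.character(st_sys)
  }
  m_adv <- mean(values[systems == "advective"])
  m_dif <- mean(values[systems == "diffusive"])
  cmp <- tukey_letters(values, systems, transform = transform)
  list(ratio = m_adv / m_dif,
       mean_advective = m_adv,
       mean_diffusive = m_dif,
       tukey_p = cmp$pairs$p_adj[1L])
}
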