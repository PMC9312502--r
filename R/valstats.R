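#' Pairwise correlation matrix with significance levels
#'
#' Spearman (midranks for ties) or Pearson correlations between all column
#' pairs, with two-sided p-values, handling missing values pairwise-complete.
#' For Spearman and Kendall with n <= 9 untied observations the p-value is
#' exact (the full permutation distribution, via [stats::cor.test()]);
#' otherwise the t (Spearman/Pearson) or normal (Kendall) approximation is
#' used. Pairs with fewer than 3 complete observations, or involving a
#' constant variable, get `NA` coefficients rather than a value.
#'
#' @param data data.frame or matrix of numeric variables (columns).
#' @param method `"spearman"`, `"pearson"` or `"kendall"`.
#' @param exact_max_n largest pair n for which the exact rank-permutation
#'   p-value is used (default 9; set 0 to always approximate).
#' @return A `bip_corr`: `r`, `p`, `n` matrices, `method`.
#' @export
corr_matrix <- function(data, method = c("spearman", "pearson", "kendall"),
                        exact_max_n = 9L) {
  method <- match.arg(method)
  X <- as.data.frame(data)
  k <- ncol(X)
  stopifnot(k >= 2L)
  nm <- colnames(X)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  diag(p) <- 0
  diag(n) <- colSums(!is.na(X))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- stats::complete.cases(X[[i]], X[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      ct <- cor_pair(X[[i]][ok], X[[j]][ok], method, exact_max_n)
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p
    }
  }
  structure(list(r = r, p = p, n = n, method = method),
            class = "bip_corr")
}

cor_pair <- function(x, y, method, exact_max_n) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  exact <- if (method == "pearson") NULL else {
    ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    n <= exact_max_n && !ties
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = exact))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.bip_corr <- function(x, digits = 3, ...) {
  cat("Correlation matrix (", x$method,
      "); coefficients above the diagonal, p-values below\n", sep = "")
  k <- ncol(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) out[i, j] <- format(round(x$r[i, j], digits))
      if (i > j) out[i, j] <- format(round(x$p[i, j], digits))
    }
  }
  print(out, quote = FALSE)
  invisible(x)
}

#' Write a correlation matrix in mixed layout
#'
#' CSV with coefficients above the diagonal and p-values below it.
#'
#' @param cm a `bip_corr`.
#' @param path output path.
#' @export
write_corr_matrix <- function(cm, path) {
  k <- ncol(cm$r)
  out <- matrix(NA_real_, k, k, dimnames = dimnames(cm$r))
  out[upper.tri(out)] <- cm$r[upper.tri(cm$r)]
  out[lower.tri(out)] <- cm$p[lower.tri(cm$p)]
  df <- data.frame(variable = rownames(out), out, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ordinary least-squares R-squared
#'
#' @param x predictor (must not be constant).
#' @param y response.
#' @return list: `r2`, `slope`, `intercept`, `n`.
#' @export
linear_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(r2 = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(x))
}

#' Per-analyte rank correlation of index values with solute fluxes
#'
#' Matches stations between an index table and a flux measurement table and
#' reports Spearman's rho, p and n per analyte. Repeated visits per station
#' can be aggregated by mean or max before correlating; analytes with fewer
#' than 3 matched stations are skipped with a warning.
#'
#' @param index data.frame with columns `station` and `index` (one row per
#'   station, or repeated stations which are then aggregated with `aggregate`
#'   as well).
#' @param fluxes data.frame with columns `station`, `analyte`, `value`.
#' @param aggregate `"none"`, `"mean"` or `"max"` across repeated rows per
#'   station.
#' @param exact_max_n see [corr_matrix()].
#' @return data.frame: analyte, rho, p, n, significant (p < 0.05).
#' @export
flux_association <- function(index, fluxes,
                             aggregate = c("none", "mean", "max"),
                             exact_max_n = 9L) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("station", "index") %in% names(index)),
            all(c("station", "analyte", "value") %in% names(fluxes)))
  agg_fun <- switch(aggregate, none = NULL, mean = mean, max = max)
  if (!is.null(agg_fun)) {
    index <- stats::aggregate(index["index"], index["station"], agg_fun)
    fluxes <- stats::aggregate(fluxes["value"],
                               fluxes[c("station", "analyte")], agg_fun)
  }
  rows <- list()
  for (an in unique(fluxes$analyte)) {
    fx <- fluxes[fluxes$analyte == an, , drop = FALSE]
    m <- merge(index, fx, by = "station")
    if (nrow(m) < 3L) {
      warning("analyte '", an, "' skipped: fewer than 3 matched stations")
      next
    }
    ct <- cor_pair(m$index, m$value, "spearman", exact_max_n)
    rows[[an]] <- data.frame(analyte = an, rho = ct$r, p = ct$p,
                             n = nrow(m),
                             significant = !is.na(ct$p) && ct$p < 0.05,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(analyte = character(), rho = numeric(), p = numeric(),
               n = integer(), significant = logical())
  rownames(out) <- NULL
  out
}
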