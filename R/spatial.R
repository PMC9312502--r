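#' Collinearity screen for environmental predictors
#'
#' Iteratively removes one member of every highly collinear predictor pair
#' (|Pearson r| above `r_threshold` with p below `alpha`): the member with
#' the lower univariate predictive power, defined as the smaller absolute
#' Spearman correlation with the response (a simple, deterministic
#' operationalization). Constant predictors are dropped first with a
#' warning, their correlations being undefined.
#'
#' @param predictors numeric matrix or data.frame (stations x predictors),
#'   named columns.
#' @param response numeric response used to rank pair members.
#' @param r_threshold absolute Pearson correlation above which a pair is
#'   collinear (default 0.90).
#' @param alpha required significance of the pair correlation (default
#'   0.05).
#' @return list: `retained` (column names), `dropped` (data.frame with
#'   `dropped`, `kept`, `r` per removal; constants have `kept = NA`).
#' @export
collinearity_screen <- function(predictors, response, r_threshold = 0.90,
                                alpha = 0.05) {
  X <- as.data.frame(predictors)
  stopifnot(ncol(X) >= 2L, nrow(X) >= 3L, nrow(X) == length(response))
  drops <- data.frame(dropped = character(), kept = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  const <- vapply(X, function(v) stats::var(v) == 0, TRUE)
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(names(X)[const], collapse = ", "))
    drops <- rbind(drops, data.frame(dropped = names(X)[const],
                                     kept = NA_character_, r = NA_real_))
    X <- X[, !const, drop = FALSE]
  }
  power <- vapply(X, function(v)
    abs(stats::cor(v, response, method = "spearman")), numeric(1))
  repeat {
    if (ncol(X) < 2L) break
    cm <- stats::cor(as.matrix(X))
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1L, ]
    r <- cm[worst[1L], worst[2L]]
    if (abs(r) <= r_threshold) break
    ct <- stats::cor.test(X[[worst[1L]]], X[[worst[2L]]])
    if (ct$p.value >= alpha) break
    pair <- colnames(cm)[worst]
    # drop the member with lower |Spearman| vs response; alphabetical
    # tie-break for determinism
    pw <- power[pair]
    drop_nm <- if (pw[1L] < pw[2L]) pair[1L]
    else if (pw[2L] < pw[1L]) pair[2L]
    else sort(pair)[2L]
    keep_nm <- setdiff(pair, drop_nm)
    drops <- rbind(drops, data.frame(dropped = drop_nm, kept = keep_nm,
                                     r = r))
    X <- X[, setdiff(colnames(X), drop_nm), drop = FALSE]
  }
  list(retained = colnames(X), dropped = drops)
}

#' Random-forest spatial model of the (log-transformed) index
#'
#' Fits random-forest regressions of log10(index + 1) on the screened
#' predictors over a grid of variables-per-node settings and keeps the one
#' with the highest out-of-bag percent variance explained. Defaults follow
#' the protocol used for mapping BIPc (1000 trees, 1 to 5 variables per
#' node); the reference BPc mapping uses 500 trees with 3 variables per
#' node (`ntree = 500, mtry_range = 3`). Permutation importance (%IncMSE)
#' is computed out-of-bag with `nperm` shuffles per tree; predictive skill
#' is summarised as Kendall's tau between out-of-bag predictions and the
#' observed transformed values.
#'
#' @param values non-negative index values per station.
#' @param predictors matrix/data.frame of station predictor values.
#' @param ntree number of trees (default 1000).
#' @param mtry_range candidate variables-per-node settings (default 1:5,
#'   clipped to the number of retained predictors).
#' @param screen apply [collinearity_screen()] first (default TRUE).
#' @param r_threshold collinearity cutoff passed to the screen.
#' @param nperm out-of-bag permutations per tree for %IncMSE (default 10).
#' @param seed integer seed; recorded in the report, makes refits
#'   reproducible.
#' @return A `bip_fit`: the selected `model` (randomForest), `retained`,
#'   `dropped`, `mtry`, `var_explained_pct` (OOB), `importance` (%IncMSE,
#'   descending), `kendall_tau`, `kendall_p`, `oob_predicted`,
#'   `observed_transformed`, `ntree`, `seed`.
#' @export
fit_bip_map <- function(values, predictors, ntree = 1000,
                        mtry_range = 1:5, screen = TRUE,
                        r_threshold = 0.90, nperm = 10, seed = 1L) {
  X <- as.data.frame(predictors)
  stopifnot(nrow(X) == length(values))
  if (any(values < 0)) stop("index values must be non-negative")
  if (nrow(X) < 10L) stop("need at least 10 stations")
  if (ncol(X) < 1L) stop("need at least one predictor")
  dropped <- data.frame(dropped = character(), kept = character(),
                        r = numeric())
  if (screen && ncol(X) >= 2L) {
    sc <- collinearity_screen(X, values, r_threshold = r_threshold)
    dropped <- sc$dropped
    X <- X[, sc$retained, drop = FALSE]
  }
  y <- log10(values + 1)
  mtry_range <- mtry_range[mtry_range >= 1 & mtry_range <= ncol(X)]
  if (length(mtry_range) == 0L) mtry_range <- min(5L, ncol(X))
  fits <- vector("list", length(mtry_range))
  for (i in seq_along(mtry_range)) {
    set.seed(seed + mtry_range[i])
    fits[[i]] <- randomForest::randomForest(
      x = X, y = y, ntree = ntree, mtry = mtry_range[i],
      importance = TRUE, nPerm = nperm)
  }
  oob_var <- vapply(fits, function(f) 100 * f$rsq[length(f$rsq)], numeric(1))
  best <- which.max(oob_var)
  model <- fits[[best]]
  imp <- randomForest::importance(model, type = 1, scale = TRUE)[, 1L]
  imp <- sort(imp, decreasing = TRUE)
  kd <- kendall_validate(model$predicted, y)
  structure(list(model = model,
                 retained = colnames(X),
                 dropped = dropped,
                 mtry = mtry_range[best],
                 mtry_tested = stats::setNames(oob_var, mtry_range),
                 var_explained_pct = oob_var[best],
                 importance = imp,
                 kendall_tau = kd$tau,
                 kendall_p = kd$p,
                 oob_predicted = model$predicted,
                 observed_transformed = y,
                 ntree = ntree,
                 seed = seed),
            class = "bip_fit")
}

#' @export
print.bip_fit <- function(x, ...) {
  cat("Random-forest index map fit\n")
  cat(sprintf("  trees: %d  variables/node: %d (tested %s)\n",
              x$ntree, x$mtry, paste(names(x$mtry_tested), collapse = ",")))
  cat(sprintf("  OOB variance explained: %.2f%%\n", x$var_explained_pct))
  cat(sprintf("  Kendall tau (OOB vs observed): %.3f (p = %.3g)\n",
              x$kendall_tau, x$kendall_p))
  cat("  predictors retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0L) {
    cat("  dropped collinear/constant:",
        paste(x$dropped$dropped, collapse = ", "), "\n")
  }
  cat("  importance (%IncMSE):\n")
  print(round(x$importance, 2))
  invisible(x)
}

#' Permutation importance of a fitted map
#'
#' @param fit a `bip_fit`.
#' @return named numeric vector of %IncMSE values, descending.
#' @export
bip_importance <- function(fit) {
  stopifnot(inherits(fit, "bip_fit"))
  fit$importance
}

#' Rank-correlation validation of modelled vs observed values
#'
#' Kendall's tau (two-sided test) between predictions and observations;
#' constant predictions make tau undefined and are reported as `NA`.
#'
#' @param predicted,observed numeric vectors (>= 3 values).
#' @return list with `tau`, `p`, `n`.
#' @export
kendall_validate <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3L)
  if (stats::var(predicted) == 0 || stats::var(observed) == 0) {
    return(list(tau = NA_real_, p = NA_real_, n = length(predicted)))
  }
  ct <- suppressWarnings(
    stats::cor.test(predicted, observed, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value, n = length(predicted))
}

#' Predict the index surface over a raster stack
#'
#' Cell-wise model prediction over the stack; cells missing in any required
#' layer stay missing. The primary product is on the log10(x+1) scale the
#' model was fitted on; the back-transformed surface 10^y - 1 (no bias
#' correction) is returned alongside.
#'
#' @param fit a `bip_fit`.
#' @param stack a `predictor_stack` containing every retained predictor.
#' @return list: `log_raster`, `raster` (back-transformed), both matrices
#'   with the stack's geometry.
#' @export
predict_bip_raster <- function(fit, stack) {
  stopifnot(inherits(fit, "bip_fit"), inherits(stack, "predictor_stack"))
  miss <- setdiff(fit$retained, names(stack$layers))
  if (length(miss) > 0L) {
    stop("stack is missing predictor layer(s): ",
         paste(miss, collapse = ", "))
  }
  mask <- Reduce(`|`, lapply(stack$layers[fit$retained], is.na))
  cells <- which(!mask)
  newdata <- as.data.frame(lapply(stack$layers[fit$retained],
                                  function(m) m[cells]))
  out <- matrix(NA_real_, stack$nrow, stack$ncol)
  if (length(cells) > 0L) {
    out[cells] <- stats::predict(fit$model, newdata)
  }
  list(log_raster = out, raster = 10^out - 1)
}

#' Univariate variance explained (distance-based redundancy reduction)
#'
#' For a single Euclidean-distance response variable, distance-based
#' redundancy analysis reduces to ordinary least squares on the variable
#' itself, so the variance explained by one predictor is 100 * R^2 of the
#' OLS fit.
#'
#' @param predictor,response numeric vectors (n >= 3).
#' @return percent of response variance explained.
#' @export
variance_explained <- function(predictor, response) {
  100 * linear_r2(predictor, response)$r2
}
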