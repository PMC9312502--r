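#' Community bioirrigation potential (BIPc) of a sample
#'
#' For each taxon i the mean individual biomass Bi/Ai (AFDW g m^-2 over
#' ind m^-2) is multiplied by the feeding-type, burrow-type and depth scores
#' of the sediment system in force and weighted back by abundance:
#'
#'   BIPc = sum_i (Bi/Ai) * Ai * FTi * BTi * Li
#'
#' A zero in any score removes the taxon's contribution (epifauna and other
#' traits irrelevant to solute exchange). Taxa absent from the score table
#' contribute nothing and are reported in `unscored_taxa`; the coverage
#' diagnostics quantify the abundance/biomass share the scored taxa carry.
#' Records with zero abundance (necessarily zero biomass) contribute zero
#' without evaluating 0/0.
#'
#' The reference community bioturbation potential is computed alongside:
#' BPc = sum_i sqrt(Bi/Ai) * Ai * Mi * Ri, with a single score set (no
#' system switching).
#'
#' @param sample a `community_sample`.
#' @param scores a `bip_scores` table.
#' @param system `"diffusive"` or `"advective"`.
#' @return A `bip_result`: sample ids, system used, `bipc`, `bpc`, named
#'   per-taxon `contributions` (BIPc) and `contributions_bpc`,
#'   `coverage_abundance_pct`, `coverage_biomass_pct`, `unscored_taxa`.
#' @seealso [bpc()], [layer_index()], [depth_profile()], [coverage()]
#' @export
bipc <- function(sample, scores, system) {
  stopifnot(inherits(sample, "community_sample"),
            inherits(scores, "bip_scores"))
  if (!system %in% c("diffusive", "advective")) {
    stop("unknown system label: ", system)
  }
  rec <- sample$records
  idx <- match(normalize_taxon(rec$taxon), normalize_taxon(scores$taxon))
  scored <- !is.na(idx)

  contrib <- index_contributions(rec, scores, idx, system)
  contrib_bpc <- bpc_contributions(rec, scores, idx)

  tot_a <- sum(rec$abundance)
  tot_b <- sum(rec$biomass_afdw)
  cov_a <- if (tot_a > 0) 100 * sum(rec$abundance[scored]) / tot_a else NA_real_
  cov_b <- if (tot_b > 0) 100 * sum(rec$biomass_afdw[scored]) / tot_b else NA_real_

  if (nrow(rec) > 0L && !any(scored)) {
    warning("no taxon of sample ", sample$station_id, "/", sample$date,
            " is in the score table; index is 0")
  }

  structure(list(station_id = sample$station_id,
                 date = sample$date,
                 system = system,
                 bipc = sum(contrib),
                 bpc = sum(contrib_bpc),
                 contributions = contrib,
                 contributions_bpc = contrib_bpc,
                 coverage_abundance_pct = cov_a,
                 coverage_biomass_pct = cov_b,
                 unscored_taxa = rec$taxon[!scored]),
            class = "bip_result")
}

# vectorized engine shared by bipc(), layer_index() and depth_profile():
# per-scored-taxon BIPc contributions, named by taxon
index_contributions <- function(rec, scores, idx, system) {
  scored <- !is.na(idx)
  if (!any(scored)) return(stats::setNames(numeric(0), character(0)))
  a <- rec$abundance[scored]
  b <- rec$biomass_afdw[scored]
  s <- scores[idx[scored], , drop = FALSE]
  if (system == "diffusive") {
    prod <- s$ft_diff * s$bt_diff * s$l_diff
  } else {
    prod <- s$ft_adv * s$bt_adv * s$l_adv
  }
  mib <- ifelse(a > 0, b / a, 0)
  stats::setNames(mib * a * prod, rec$taxon[scored])
}

bpc_contributions <- function(rec, scores, idx) {
  scored <- !is.na(idx)
  if (!any(scored)) return(stats::setNames(numeric(0), character(0)))
  a <- rec$abundance[scored]
  b <- rec$biomass_afdw[scored]
  s <- scores[idx[scored], , drop = FALSE]
  mib <- ifelse(a > 0, b / a, 0)
  stats::setNames(sqrt(mib) * a * s$m_bpc * s$r_bpc, rec$taxon[scored])
}

#' Community bioturbation potential (BPc) of a sample
#'
#' BPc = sum_i sqrt(Bi/Ai) * Ai * Mi * Ri with mobility and reworking
#' scores; one score set for all sediment systems.
#'
#' @inheritParams bipc
#' @return list with `value` and named per-taxon `contributions`.
#' @export
bpc <- function(sample, scores) {
  stopifnot(inherits(sample, "community_sample"),
            inherits(scores, "bip_scores"))
  rec <- sample$records
  idx <- match(normalize_taxon(rec$taxon), normalize_taxon(scores$taxon))
  contrib <- bpc_contributions(rec, scores, idx)
  list(value = sum(contrib), contributions = contrib)
}

#' @export
print.bip_result <- function(x, ...) {
  cat("BIPc result: station", x$station_id, "on", x$date,
      "(", x$system, "system )\n")
  cat(sprintf("  BIPc = %.4g   BPc = %.4g\n", x$bipc, x$bpc))
  cat(sprintf("  coverage: %.1f%% of abundance, %.1f%% of AFDW biomass\n",
              x$coverage_abundance_pct, x$coverage_biomass_pct))
  if (length(x$unscored_taxa) > 0L) {
    cat("  unscored taxa:", paste(x$unscored_taxa, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate score-coverage diagnostics
#'
#' Share of total abundance and total AFDW biomass (summed across samples)
#' carried by taxa present in the score table. Scored and unscored shares
#' always total 100; a zero total (e.g. no biomass at all) makes the
#' corresponding coverage undefined (NA), never 0.
#'
#' @param samples list of `community_sample` objects.
#' @param scores a `bip_scores` table.
#' @return list with `coverage_abundance_pct`, `coverage_biomass_pct`,
#'   `unscored_taxa` (unique, across samples).
#' @export
coverage <- function(samples, scores) {
  stopifnot(length(samples) > 0L)
  key <- normalize_taxon(scores$taxon)
  tot_a <- tot_b <- sc_a <- sc_b <- 0
  unscored <- character(0)
  for (s in samples) {
    rec <- s$records
    scored <- normalize_taxon(rec$taxon) %in% key
    tot_a <- tot_a + sum(rec$abundance)
    tot_b <- tot_b + sum(rec$biomass_afdw)
    sc_a <- sc_a + sum(rec$abundance[scored])
    sc_b <- sc_b + sum(rec$biomass_afdw[scored])
    unscored <- union(unscored, rec$taxon[!scored])
  }
  list(coverage_abundance_pct = if (tot_a > 0) 100 * sc_a / tot_a else NA_real_,
       coverage_biomass_pct = if (tot_b > 0) 100 * sc_b / tot_b else NA_real_,
       unscored_taxa = unscored)
}

#' Key species: ranked contribution shares to summed BIPc
#'
#' Within each group (e.g. sediment class, or `"overall"`), the share of a
#' taxon is its summed BIPc contribution divided by the group's summed BIPc,
#' in percent; shares sum to 100 per group. Ties are broken alphabetically.
#' A group with zero total BIPc yields an empty ranking.
#'
#' @param samples list of `community_sample` objects.
#' @param scores a `bip_scores` table.
#' @param systems character vector (length 1 or `length(samples)`) of system
#'   labels used per sample.
#' @param groups optional character vector of group labels per sample
#'   (e.g. "mud", "fine sand"); the pooled "overall" group is always
#'   reported.
#' @param top optional integer, keep only the top taxa per group.
#' @return data.frame with columns `group`, `taxon`, `contribution`,
#'   `share_pct`, ordered by group then descending share.
#' @export
key_species <- function(samples, scores, systems, groups = NULL,
                        top = NULL) {
  n <- length(samples)
  systems <- rep_len(systems, n)
  labels <- if (is.null(groups)) rep("overall", n) else {
    stopifnot(length(groups) == n)
    as.character(groups)
  }
  sums <- new.env(parent = emptyenv())
  add_contrib <- function(group, contrib) {
    if (length(contrib) == 0L) return()
    cur <- if (exists(group, envir = sums)) get(group, envir = sums) else
      numeric(0)
    for (tx in names(contrib)) {
      cur[tx] <- (if (tx %in% names(cur)) cur[[tx]] else 0) + contrib[[tx]]
    }
    assign(group, cur, envir = sums)
  }
  for (i in seq_len(n)) {
    res <- suppressWarnings(bipc(samples[[i]], scores, systems[i]))
    add_contrib("overall", res$contributions)
    if (!is.null(groups)) add_contrib(labels[i], res$contributions)
  }
  out <- list()
  for (group in sort(ls(sums))) {
    cur <- get(group, envir = sums)
    total <- sum(cur)
    if (total <= 0) next
    ord <- order(-cur, names(cur))
    cur <- cur[ord]
    if (!is.null(top)) cur <- utils::head(cur, top)
    out[[group]] <- data.frame(group = group, taxon = names(cur),
                               contribution = unname(cur),
                               share_pct = unname(100 * cur / total),
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(group = character(), taxon = character(),
                      contribution = numeric(), share_pct = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Index restricted to a sediment depth layer
#'
#' Only records whose measured depth of occurrence falls in
#' `[top, bottom)` cm contribute (closed lower, open upper bound); the
#' computation is otherwise identical to [bipc()].
#'
#' @inheritParams bipc
#' @param layer numeric length-2, `c(top, bottom)` in cm.
#' @return A `bip_result` for the layer-restricted community.
#' @export
layer_index <- function(sample, scores, system, layer) {
  stopifnot(length(layer) == 2L, layer[1] < layer[2])
  rec <- sample$records
  if (nrow(rec) > 0L && all(is.na(rec$depth_measured))) {
    stop("no measured depths in sample ", sample$station_id,
         "; use the whole-core index instead")
  }
  keep <- !is.na(rec$depth_measured) &
    rec$depth_measured >= layer[1] & rec$depth_measured < layer[2]
  sub <- sample
  sub$records <- rec[keep, , drop = FALSE]
  res <- suppressWarnings(bipc(sub, scores, system))
  res$layer <- layer
  res
}

#' Vertical BIPc profile of a sample
#'
#' Distributes each taxon's whole contribution into the depth slice
#' containing its depth of occurrence. Slices are `slice_cm` thick,
#' half-open `[top, bottom)` from the sediment-water interface, with the
#' final slice closed. In `"measured"` mode the observed mid-depth of the
#' slice of occurrence is used; in `"theoretical"` mode the literature
#' burrow/penetration depth (`lit_depth_cm` column of the score table),
#' which anticipates the maximum penetration depth of the taxon. Taxa
#' lacking a depth in the requested mode are excluded from the profile but
#' retained in the whole-core value and listed in `excluded`.
#'
#' @inheritParams bipc
#' @param slice_cm slice thickness in cm (default 2).
#' @param mode `"measured"` or `"theoretical"`.
#' @return A `bip_profile`: data.frame `slices` (top, bottom, bipc),
#'   `whole_core` BIPc, `mode`, `excluded` (taxa without depth) and their
#'   summed `excluded_contribution`.
#' @export
depth_profile <- function(sample, scores, system, slice_cm = 2,
                          mode = c("measured", "theoretical")) {
  mode <- match.arg(mode)
  stopifnot(slice_cm > 0)
  rec <- sample$records
  idx <- match(normalize_taxon(rec$taxon), normalize_taxon(scores$taxon))
  contrib_all <- index_contributions(rec, scores, idx, system)
  whole <- sum(contrib_all)

  scored <- which(!is.na(idx))
  if (mode == "measured") {
    depth <- rec$depth_measured[scored]
    if (length(scored) > 0L && all(is.na(depth))) {
      stop("mode 'measured' requires depth_measured; ",
           "consider mode = 'theoretical'")
    }
  } else {
    if (!"lit_depth_cm" %in% names(scores)) {
      stop("mode 'theoretical' requires a lit_depth_cm score column")
    }
    depth <- scores$lit_depth_cm[idx[scored]]
  }
  has_depth <- !is.na(depth)
  contrib <- contrib_all[has_depth]
  depth <- depth[has_depth]
  excluded <- rec$taxon[scored][!has_depth]

  max_d <- if (length(depth) > 0L) max(depth) else slice_cm
  n_slices <- max(1L, ceiling(max_d / slice_cm))
  top <- (seq_len(n_slices) - 1L) * slice_cm
  vals <- numeric(n_slices)
  if (length(depth) > 0L) {
    k <- pmin(floor(depth / slice_cm) + 1L, n_slices)  # final slice closed
    for (i in seq_along(k)) vals[k[i]] <- vals[k[i]] + contrib[i]
  }
  structure(list(slices = data.frame(top = top, bottom = top + slice_cm,
                                     bipc = vals),
                 whole_core = whole,
                 mode = mode,
                 excluded = excluded,
                 excluded_contribution = whole - sum(vals)),
            class = "bip_profile")
}

#' @export
print.bip_profile <- function(x, ...) {
  cat("Vertical BIPc profile (", x$mode, "depths ), whole core =",
      signif(x$whole_core, 5), "\n")
  print(x$slices, row.names = FALSE)
  if (length(x$excluded) > 0L) {
    cat("excluded (no depth):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
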