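#' Construct a community sample
#'
#' One macrofauna sample at a station and date: per-taxon abundance
#' (ind m^-2), ash-free dry-weight biomass (g m^-2) and, optionally, the
#' mid-depth of the sediment slice of occurrence. Sediment metadata (median
#' grain size, an explicit system label) drives the diffusive/advective
#' attribution.
#'
#' @param station_id station identifier.
#' @param date sample date (character or Date).
#' @param records data.frame with columns `taxon`, `abundance`,
#'   `biomass_afdw` and optionally `depth_measured` (cm below the
#'   sediment-water interface).
#' @param median_grain_um optional sediment median grain size (um).
#' @param system_override optional explicit label, `"diffusive"` or
#'   `"advective"`.
#' @return A `community_sample` object.
#' @export
community_sample <- function(station_id, date, records,
                             median_grain_um = NA_real_,
                             system_override = NA_character_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0L) {
    need <- c("taxon", "abundance", "biomass_afdw")
    miss <- setdiff(need, names(records))
    if (length(miss) > 0L) {
      stop("records are missing column(s): ", paste(miss, collapse = ", "))
    }
  } else {
    records <- data.frame(taxon = character(), abundance = numeric(),
                          biomass_afdw = numeric(),
                          depth_measured = numeric(),
                          stringsAsFactors = FALSE)
  }
  if (!"depth_measured" %in% names(records)) {
    records$depth_measured <- NA_real_
  }
  records$taxon <- as.character(records$taxon)
  records$abundance <- as.numeric(records$abundance)
  records$biomass_afdw <- as.numeric(records$biomass_afdw)
  records$depth_measured <- as.numeric(records$depth_measured)
  validate_records(records, station_id, date)
  if (!is.na(median_grain_um) && median_grain_um <= 0) {
    stop("median_grain_um must be > 0 (station ", station_id, ")")
  }
  if (!is.na(system_override)) {
    system_override <- match.arg(system_override,
                                 c("diffusive", "advective"))
  }
  structure(list(station_id = as.character(station_id),
                 date = as.character(date),
                 records = records,
                 median_grain_um = as.numeric(median_grain_um),
                 system_override = system_override),
            class = "community_sample")
}

validate_records <- function(records, station_id, date) {
  where <- paste0(" (station ", station_id, ", date ", date, ")")
  if (anyNA(records$abundance) || anyNA(records$biomass_afdw)) {
    stop("missing abundance or biomass", where)
  }
  if (any(records$abundance < 0)) stop("negative abundance", where)
  if (any(records$biomass_afdw < 0)) stop("negative biomass", where)
  bad <- records$biomass_afdw > 0 & records$abundance == 0
  if (any(bad)) {
    stop("biomass > 0 with abundance = 0 for taxon ",
         records$taxon[which(bad)[1L]], where)
  }
  key <- normalize_taxon(records$taxon)
  if (anyDuplicated(key)) {
    stop("duplicate taxon within sample: ",
         records$taxon[which(duplicated(key))[1L]], where)
  }
  invisible(TRUE)
}

#' @export
print.community_sample <- function(x, ...) {
  cat("Community sample: station", x$station_id, "on", x$date, "\n")
  cat("  taxa:", nrow(x$records),
      " total abundance:", sum(x$records$abundance), "ind/m^2",
      " total AFDW:", signif(sum(x$records$biomass_afdw), 4), "g/m^2\n")
  if (!is.na(x$median_grain_um)) {
    cat("  median grain size:", x$median_grain_um, "um\n")
  }
  if (!is.na(x$system_override)) {
    cat("  explicit system label:", x$system_override, "\n")
  }
  invisible(x)
}

#' Read community samples from a long-format delimited table
#'
#' Expected columns: `station`, `date`, `taxon`, `abundance_ind_m2`,
#' `biomass_afdw_g_m2`, optionally `depth_cm`, `median_grain_um`, `system`
#' and (for `pooling = "replicates"`) `replicate`. Rows are grouped by
#' (station, date) into one sample each.
#'
#' Field samples are commonly taken as replicate grabs (e.g. three 0.1 m^2
#' van Veen grabs per station). Two pooling modes are supported and the mode
#' is always explicit, never inferred: `"pooled"` expects rows already in
#' per-m^2 units; `"replicates"` expects per-grab counts/masses with a
#' `replicate` column, converts each grab by `1 / grab_area_m2` and averages
#' across the grabs of a station-date (a taxon absent from a grab counts as
#' zero there).
#'
#' @param path delimited file (comma default, tab accepted).
#' @param pooling `"pooled"` (default) or `"replicates"`.
#' @param grab_area_m2 sampled area of one grab, used only for
#'   `pooling = "replicates"`.
#' @return list of `community_sample` objects, ordered by station then date.
#' @export
read_community_table <- function(path, pooling = c("pooled", "replicates"),
                                 grab_area_m2 = 0.1) {
  pooling <- match.arg(pooling)
  df <- read_delim_auto(path)
  need <- c("station", "date", "taxon", "abundance_ind_m2",
            "biomass_afdw_g_m2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("community table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (pooling == "replicates") {
    if (!"replicate" %in% names(df)) {
      stop("pooling = 'replicates' requires a 'replicate' column")
    }
    if (grab_area_m2 <= 0) stop("grab_area_m2 must be > 0")
  }
  df$abundance_ind_m2 <- as.numeric(df$abundance_ind_m2)
  df$biomass_afdw_g_m2 <- as.numeric(df$biomass_afdw_g_m2)
  keys <- unique(df[, c("station", "date")])
  keys <- keys[order(keys$station, keys$date), , drop = FALSE]
  samples <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sub <- df[df$station == keys$station[k] & df$date == keys$date[k], ,
              drop = FALSE]
    grain <- first_value(sub, "median_grain_um")
    syslab <- first_value(sub, "system")
    if (!is.na(syslab)) syslab <- as.character(syslab)
    # a station-date row with empty taxon marks a sample with no fauna
    sub <- sub[!is.na(sub$taxon) & nzchar(trimws(sub$taxon)), , drop = FALSE]
    if (pooling == "replicates" && nrow(sub) > 0L) {
      recs <- pool_replicates(sub, grab_area_m2)
    } else {
      recs <- data.frame(taxon = sub$taxon,
                         abundance = sub$abundance_ind_m2,
                         biomass_afdw = sub$biomass_afdw_g_m2,
                         depth_measured = if ("depth_cm" %in% names(sub))
                           as.numeric(sub$depth_cm)
                         else rep(NA_real_, nrow(sub)),
                         stringsAsFactors = FALSE)
    }
    samples[[k]] <- community_sample(
      keys$station[k], keys$date[k], recs,
      median_grain_um = if (is.na(grain)) NA_real_ else as.numeric(grain),
      system_override = if (is.na(syslab)) NA_character_ else syslab)
  }
  samples
}

first_value <- function(df, col) {
  if (!col %in% names(df)) return(NA)
  v <- df[[col]][!is.na(df[[col]])]
  if (length(v) == 0L) NA else v[1L]
}

pool_replicates <- function(sub, grab_area_m2) {
  reps <- unique(sub$replicate)
  n_rep <- length(reps)
  taxa <- unique(sub$taxon)
  ab <- bm <- numeric(length(taxa))
  dep <- rep(NA_real_, length(taxa))
  for (i in seq_along(taxa)) {
    rows <- sub[sub$taxon == taxa[i], , drop = FALSE]
    if (anyDuplicated(rows$replicate)) {
      stop("duplicate taxon within replicate: ", taxa[i])
    }
    # absent-from-grab counts as zero: divide summed per-grab values by the
    # number of grabs, then convert to per-m^2
    ab[i] <- sum(rows$abundance_ind_m2) / n_rep / grab_area_m2
    bm[i] <- sum(rows$biomass_afdw_g_m2) / n_rep / grab_area_m2
    if ("depth_cm" %in% names(rows)) {
      d <- rows$depth_cm[!is.na(rows$depth_cm)]
      if (length(d) > 0L) dep[i] <- mean(d)
    }
  }
  data.frame(taxon = taxa, abundance = ab, biomass_afdw = bm,
             depth_measured = dep, stringsAsFactors = FALSE)
}

#' Read a measurement table (tracer/flux observations)
#'
#' Columns: `core_id`, `quantity`, `value`, optionally `layer_top_cm`,
#' `layer_bottom_cm` for depth-layer-resolved measurements.
#'
#' @param path delimited file.
#' @return data.frame of measurement records.
#' @export
read_measurement_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("core_id", "quantity", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("measurement table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  if (all(c("layer_top_cm", "layer_bottom_cm") %in% names(df))) {
    has <- !is.na(df$layer_top_cm) & !is.na(df$layer_bottom_cm)
    if (any(has & df$layer_top_cm >= df$layer_bottom_cm)) {
      stop("layer_top_cm must be below layer_bottom_cm")
    }
  }
  df
}

#' Write per-sample index results to CSV
#'
#' One row per sample: station, date, system, BIPc, BPc and coverage
#' diagnostics. `read_index_table()` reads the file back.
#'
#' @param results list of `bip_result` objects (see [bipc()]).
#' @param path output CSV path.
#' @export
write_index_table <- function(results, path) {
  rows <- lapply(results, function(r) {
    data.frame(station = r$station_id, date = r$date, system = r$system,
               bipc = r$bipc, bpc = r$bpc,
               coverage_abundance_pct = r$coverage_abundance_pct,
               coverage_biomass_pct = r$coverage_biomass_pct,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(station = character(), date = character(),
               system = character(), bipc = numeric(), bpc = numeric(),
               coverage_abundance_pct = numeric(),
               coverage_biomass_pct = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  read_delim_auto(path)
}
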