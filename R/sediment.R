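#' Sediment-system classification rule
#'
#' The bioirrigation score set to apply depends on the dominant pore-water
#' transport regime: advection in permeable medium-and-coarser sands,
#' molecular diffusion in very fine / fine sands and muds. The default
#' grain-size cutoff is 177 um (2.5 phi), the conventional fine/medium-sand
#' boundary. Station overrides carry expert knowledge (e.g. fine-sand sites
#' known to behave diffusively despite a somewhat higher median grain size)
#' and always win over the grain-size rule.
#'
#' @param advective_min_grain_um median grain size (um) at or above which a
#'   sample is classed advective.
#' @param overrides named character vector, station id -> `"diffusive"` or
#'   `"advective"`.
#' @return A `system_rule` object.
#' @export
system_rule <- function(advective_min_grain_um = 177, overrides = NULL) {
  if (advective_min_grain_um <= 0) stop("threshold must be > 0")
  if (!is.null(overrides)) {
    bad <- !overrides %in% c("diffusive", "advective")
    if (any(bad)) {
      stop("override must be 'diffusive' or 'advective', got: ",
           overrides[which(bad)[1L]])
    }
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("overrides must be named by station id")
    }
  }
  structure(list(advective_min_grain_um = advective_min_grain_um,
                 overrides = overrides),
            class = "system_rule")
}

#' Classify a sample as diffusive or advective
#'
#' Precedence: rule override for the station, then the sample's explicit
#' system label, then the grain-size threshold (grain >= threshold is
#' advective). A sample with none of the three is an error — there is no
#' silent default system.
#'
#' @param sample a `community_sample`.
#' @param rule a `system_rule` (default rule if omitted).
#' @return `"diffusive"` or `"advective"`.
#' @export
classify_system <- function(sample, rule = system_rule()) {
  stopifnot(inherits(rule, "system_rule"))
  ov <- rule$overrides
  if (!is.null(ov) && sample$station_id %in% names(ov)) {
    return(unname(ov[[sample$station_id]]))
  }
  if (!is.na(sample$system_override)) {
    return(sample$system_override)
  }
  g <- sample$median_grain_um
  if (is.na(g)) {
    stop("sample ", sample$station_id, "/", sample$date,
         " has no grain size, no override and no explicit system label")
  }
  if (g >= rule$advective_min_grain_um) "advective" else "diffusive"
}
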