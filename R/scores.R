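#' Trait-score tables for bioirrigation and bioturbation indices
#'
#' A score table assigns each taxon the multiplicative trait scores used by
#' the community bioirrigation potential (BIPc) — feeding type (FT), burrow
#' type (BT) and burrowing depth (L) — separately for diffusion-dominated and
#' advection-dominated sediment systems, plus the mobility (M) and sediment
#' reworking (R) scores of the reference community bioturbation potential
#' (BPc). A score of zero in any factor encodes a trait irrelevant to solute
#' exchange (e.g. epifauna) and forces a zero contribution.
#'
#' @param x data.frame with columns `taxon`, `ft_diff`, `bt_diff`, `l_diff`,
#'   `ft_adv`, `bt_adv`, `l_adv`, `m_bpc`, `r_bpc` and optionally
#'   `lit_depth_cm` (literature burrow/penetration depth used by
#'   "theoretical" vertical profiles).
#' @return A validated `bip_scores` data.frame.
#' @export
bip_scores <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("taxon", score_columns())
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("score table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x$taxon <- as.character(x$taxon)
  for (col in score_columns()) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v) && !all(is.na(x[[col]]) == is.na(v))) {
      stop("unparseable value in score column '", col, "'")
    }
    if (anyNA(v)) stop("missing value in score column '", col, "'")
    if (any(v < 0)) {
      stop("negative score in column '", col, "' for taxon ",
           x$taxon[which(v < 0)[1L]])
    }
    x[[col]] <- v
  }
  key <- normalize_taxon(x$taxon)
  if (anyDuplicated(key)) {
    stop("duplicate taxon in score table: ",
         x$taxon[which(duplicated(key))[1L]])
  }
  if ("lit_depth_cm" %in% names(x)) {
    x$lit_depth_cm <- suppressWarnings(as.numeric(x$lit_depth_cm))
    if (any(!is.na(x$lit_depth_cm) & x$lit_depth_cm < 0)) {
      stop("negative lit_depth_cm")
    }
  }
  rownames(x) <- NULL
  class(x) <- c("bip_scores", "data.frame")
  x
}

score_columns <- function() {
  c("ft_diff", "bt_diff", "l_diff", "ft_adv", "bt_adv", "l_adv",
    "m_bpc", "r_bpc")
}

#' Normalize a taxon name for matching
#'
#' Matching between community records and the score table is exact after
#' trimming, internal-whitespace squeezing and case folding; no fuzzy
#' matching is attempted (unmatched taxa flow to coverage diagnostics).
#'
#' @param x character vector of taxon names.
#' @return normalized character vector.
#' @export
normalize_taxon <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Read a trait-score table from a delimited file
#'
#' @param path CSV (default) or TSV file; delimiter is sniffed from the
#'   header line (comma unless the header contains a tab). Decimal point
#'   only.
#' @return A `bip_scores` data.frame.
#' @export
read_score_table <- function(path) {
  bip_scores(read_delim_auto(path))
}

#' Write a trait-score table
#'
#' @param scores a `bip_scores` table.
#' @param path output CSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Delimiter sniffing: comma default, tab accepted.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = TRUE,
                    comment.char = "", quote = "\"")
}
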