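#' Round half-up
#'
#' Deterministic half-up rounding (0.05 at one decimal always rounds away from
#' zero), unlike [base::round()]'s round-half-even. All percentages and ratios
#' reported by the package go through this convention: it reproduces every
#' printed percentage of the reference panel-coverage table and the
#' strains-per-sample ratio.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(90.625, 1) # 90.6
#' round_half_up(0.25, 1)   # 0.3 (base round() would give 0.2)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small guard absorbs binary representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# percentage of count over total under the package rounding convention
pct_of <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}

#' Canonical medium ordering
#'
#' Orders medium codes with the standard panel (CH, DG, DR, SY) first, any
#' additional media alphabetically after. Used for deterministic panel
#' enumeration and tie-breaking.
#'
#' @param media character vector of medium codes.
#' @return the same codes in canonical order.
#' @export
canonical_media <- function(media) {
  media <- unique(as.character(media))
  c(DEFAULT_MEDIA[DEFAULT_MEDIA %in% media],
    sort(setdiff(media, DEFAULT_MEDIA)))
}

#' Panel labels
#'
#' A panel (subset of media) is labelled `"CH + DR"` in canonical medium
#' order; `parse_panel()` inverts the labelling.
#'
#' @param panel character vector of medium codes.
#' @return single label string.
#' @export
panel_label <- function(panel) {
  paste(canonical_media(panel), collapse = " + ")
}

#' @rdname panel_label
#' @param label a panel label such as `"CH + DR"`.
#' @export
parse_panel <- function(label) {
  strsplit(trimws(label), "\\s*\\+\\s*")[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
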