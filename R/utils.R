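#' @importFrom rlang %||% abort warn
#' @importFrom dplyr across all_of arrange bind_rows desc filter group_by
#'   left_join mutate n pull rename row_number select summarise ungroup
#' @importFrom tibble tibble as_tibble
NULL

# marker identifiers -----------------------------------------------------

MARKER_CLASSES <- c("mutation", "cnv_amp", "cnv_del", "cnv_any")

#' Compose and split marker names
#'
#' A marker is a gene symbol paired with an event class
#' (`mutation`, `cnv_amp`, `cnv_del` or `cnv_any`); its canonical string form
#' is `"GENE|class"`, used as column names of a marker matrix.
#'
#' @param gene Character vector of gene symbols.
#' @param event_class Character vector of event classes.
#' @return `marker_name()` returns a character vector; `split_marker_name()`
#'   a tibble with columns `marker`, `gene`, `event_class`.
#' @examples
#' marker_name("SP8", "mutation")
#' split_marker_name("GAGE2C|cnv_del")
#' @export
marker_name <- function(gene, event_class) {
  if (!all(event_class %in% MARKER_CLASSES)) {
    abort(paste0("event_class must be one of: ",
                 paste(MARKER_CLASSES, collapse = ", ")))
  }
  paste0(gene, "|", event_class)
}

#' @rdname marker_name
#' @param marker Character vector of `"GENE|class"` marker names.
#' @export
split_marker_name <- function(marker) {
  parts <- stringr::str_split_fixed(marker, stringr::fixed("|"), 2)
  tibble(marker = marker, gene = parts[, 1], event_class = parts[, 2])
}

# report formatting ------------------------------------------------------

#' Format percentages and p-values for report tables
#'
#' Shared formatters used by every report writer: percentages to one decimal
#' place with a trailing `%`, p-values to three decimal places.
#'
#' @param x Numeric vector; for `format_percent()` a fraction in \[0, 1\]
#'   (`NA` allowed and rendered as `"NA"`).
#' @return Character vector.
#' @examples
#' format_percent(4 / 7) # "57.1%"
#' format_pvalue(0.019231) # "0.019"
#' @export
format_percent <- function(x) {
  out <- sprintf("%.1f%%", .round_half_up(100 * x, 1))
  out[is.na(x)] <- "NA"
  out
}

#' @rdname format_percent
#' @export
format_pvalue <- function(x) sprintf("%.3f", .round_half_up(x, 3))

# report convention: exact halves round away from zero (9/16 -> "56.3%"),
# unlike base round()'s round-half-even
.round_half_up <- function(x, digits) {
  trunc(x * 10^digits + 0.5) / 10^digits
}

# internal: group label from response ------------------------------------

RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD")

response_group <- function(response) {
  ifelse(response %in% c("CR", "PR"), "sensitive", "resistant")
}
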