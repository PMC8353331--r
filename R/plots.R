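#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_point
#'   facet_grid labs theme_minimal theme element_text scale_fill_manual
#'   scale_y_continuous
#' @export
ggplot2::autoplot

SUBSTITUTION_COLORS <- c(
  "C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
  "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4"
)

#' Plot a 96-channel mutation spectrum
#'
#' Standard signature-style bar chart: one bar per trinucleotide channel,
#' panelled by substitution class with the conventional class colours.
#'
#' @param object A `spectrum96` from [build_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrum96 <- function(object, ...) {
  df <- as_tibble(object)
  df$context <- paste0(df$five_prime, ".", df$three_prime)
  ggplot(df, aes(x = .data$context, y = .data$count,
                 fill = .data$substitution)) +
    geom_col(show.legend = FALSE) +
    facet_grid(~ .data$substitution, scales = "free_x") +
    scale_fill_manual(values = SUBSTITUTION_COLORS) +
    labs(x = "trinucleotide context (5'.3')", y = "mutations") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Plot fitted signature exposures
#'
#' @param object A `signature_fit` from [fit_exposures()].
#' @param min_exposure Smallest exposure shown (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_fit <- function(object, min_exposure = 0.01, ...) {
  df <- filter(object$exposures, .data$exposure >= min_exposure)
  df$signature <- stats::reorder(df$signature, df$exposure)
  ggplot(df, aes(x = .data$exposure, y = .data$signature)) +
    geom_col(fill = "#4477AA") +
    labs(x = "exposure fraction", y = NULL,
         title = object$patient_id) +
    theme_minimal()
}

#' Plot a combination search result
#'
#' Sensitivity against specificity for every enumerated panel, sized by
#' panel size; perfect classifiers sit in the top-right corner.
#'
#' @param object A `combo_search` from [search_combinations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.combo_search <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$specificity, y = .data$sensitivity,
             size = factor(.data$size))) +
    geom_point(alpha = 0.4, colour = "#4477AA") +
    labs(x = "specificity", y = "sensitivity", size = "panel size") +
    theme_minimal()
}

#' Marker-matrix heatmap
#'
#' Patients (rows, grouped by response) against markers (columns), the usual
#' oncoprint-style presence/absence view.
#'
#' @param matrix Marker-matrix tibble.
#' @param cohort Cohort tibble with `patient_id` and `group`.
#' @return A ggplot object.
#' @export
plot_marker_matrix <- function(matrix, cohort) {
  long <- tidyr::pivot_longer(matrix, -"patient_id",
                              names_to = "marker", values_to = "present")
  long <- left_join(long, select(cohort, "patient_id", "group"),
                    by = "patient_id")
  long$patient_id <- factor(long$patient_id,
                            levels = cohort$patient_id[order(cohort$group)])
  ggplot(long, aes(x = .data$marker, y = .data$patient_id,
                   fill = factor(.data$present))) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = c(`0` = "grey90", `1` = "#CC3311"),
                      name = "event") +
    facet_grid(.data$group ~ ., scales = "free_y", space = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
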