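#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy summaries of a signature fit
#'
#' `tidy()` returns one row per signature with its fitted exposure;
#' `glance()` a one-row fit summary.
#'
#' @param x A `signature_fit` from [fit_exposures()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.signature_fit <- function(x, ...) {
  mutate(x$exposures, patient_id = x$patient_id,
         .before = 1)
}

#' @rdname tidy.signature_fit
#' @export
glance.signature_fit <- function(x, ...) {
  tibble(patient_id = x$patient_id, n_total = x$n_total,
         residual = x$residual, low_confidence = x$low_confidence)
}

#' Tidy summaries of a classifier evaluation
#'
#' `tidy()` strips the class and returns the evaluation row(s) as a plain
#' tibble; `glance()` keeps only the headline performance columns.
#'
#' @param x A `classifier_eval` from [evaluate_classifier()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.classifier_eval <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.classifier_eval
#' @export
glance.classifier_eval <- function(x, ...) {
  as_tibble(unclass(x))[, c("markers", "sensitivity", "specificity",
                            "p_value")]
}
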