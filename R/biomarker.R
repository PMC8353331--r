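.group_sizes <- function(cohort) {
  n_res <- sum(cohort$group == "resistant")
  n_sen <- sum(cohort$group == "sensitive")
  if (n_res == 0 || n_sen == 0) {
    abort("both the resistant and the sensitive group must be non-empty")
  }
  c(resistant = n_res, sensitive = n_sen)
}

.marker_logical <- function(matrix, markers) {
  missing <- setdiff(markers, names(matrix))
  if (length(missing) > 0) {
    abort(paste0("unknown marker(s): ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(matrix[markers]) > 0
  rownames(m) <- matrix$patient_id
  m
}

#' Screen markers that differ between response groups
#'
#' For every marker column of the matrix, builds the 2x2 table of group
#' (resistant/sensitive) by marker positivity, tests it with the two-sided
#' Fisher exact test, and keeps markers with `p < alpha`. Output is sorted by
#' p-value then marker name.
#'
#' @param matrix Marker-matrix tibble (`patient_id` + 0/1 marker columns).
#' @param cohort Cohort tibble with `patient_id` and `group` columns; every
#'   matrix patient must appear in it.
#' @param alpha Significance threshold (default 0.05).
#' @return A tibble with columns `marker`, `gene`, `event_class`,
#'   `count_resistant`, `count_sensitive`, `p_value`, `direction`
#'   (`"higher_in_resistant"` or `"higher_in_sensitive"`, from group-wise
#'   positivity rates).
#' @export
screen_markers <- function(matrix, cohort, alpha = 0.05) {
  sizes <- .group_sizes(cohort)
  grp <- cohort$group[match(matrix$patient_id, cohort$patient_id)]
  if (anyNA(grp)) abort("matrix contains patients absent from the cohort")
  markers <- setdiff(names(matrix), "patient_id")
  res <- purrr::map_dfr(markers, function(mk) {
    pos <- matrix[[mk]] > 0
    cr <- sum(pos & grp == "resistant")
    cs <- sum(pos & grp == "sensitive")
    ht <- fisher_exact_two_sided(cr, sizes[["resistant"]] - cr,
                                 cs, sizes[["sensitive"]] - cs)
    tibble(marker = mk, count_resistant = cr, count_sensitive = cs,
           p_value = ht$p.value,
           direction = ifelse(cr / sizes[["resistant"]] >=
                                cs / sizes[["sensitive"]],
                              "higher_in_resistant", "higher_in_sensitive"))
  })
  res <- filter(res, .data$p_value < alpha)
  res <- left_join(res, split_marker_name(res$marker), by = "marker")
  res <- arrange(res, .data$p_value, .data$marker)
  res[, c("marker", "gene", "event_class", "count_resistant",
          "count_sensitive", "p_value", "direction")]
}

#' Evaluate a (composite) marker classifier
#'
#' Under the `any_positive` (OR) rule a patient is test-positive when at least
#' one marker of the panel is present; under `all_positive` (AND) when every
#' marker is. Confusion counts are taken against the clinical grouping:
#' TP/FN over the `positive_class` patients, FP/TN over the complement.
#' Sensitivity is `tp / (tp + fn)`, specificity `tn / (tn + fp)` (`NA` when
#' the denominator is 0), and the p-value is the two-sided Fisher exact test
#' of the resulting 2x2 table. `any_positive` is the rule used throughout the
#' analysis; `all_positive` is provided for exploration only.
#'
#' @param matrix Marker-matrix tibble.
#' @param markers Character vector of marker names (`"GENE|class"`), length
#'   1 or more.
#' @param cohort Cohort tibble with `patient_id` and `group`.
#' @param positive_class `"resistant"` (default) or `"sensitive"`.
#' @param rule `"any_positive"` (default) or `"all_positive"`.
#' @return A one-row tibble of class `classifier_eval`: `markers` (sorted,
#'   `+`-joined), `size`, `rule`, `positive_class`, `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity`, `p_value`.
#' @export
evaluate_classifier <- function(matrix, markers, cohort,
                                positive_class = c("resistant", "sensitive"),
                                rule = c("any_positive", "all_positive")) {
  positive_class <- match.arg(positive_class)
  rule <- match.arg(rule)
  if (length(markers) == 0) abort("markers must be non-empty")
  .group_sizes(cohort)
  m <- .marker_logical(matrix, markers)
  test_pos <- if (rule == "any_positive") rowSums(m) > 0 else
    rowSums(m) == ncol(m)
  grp <- cohort$group[match(matrix$patient_id, cohort$patient_id)]
  if (anyNA(grp)) abort("matrix contains patients absent from the cohort")
  is_pos <- grp == positive_class
  tp <- sum(test_pos & is_pos)
  fn <- sum(!test_pos & is_pos)
  fp <- sum(test_pos & !is_pos)
  tn <- sum(!test_pos & !is_pos)
  ht <- fisher_exact_two_sided(tp, fn, fp, tn)
  panel_size <- length(markers)
  out <- tibble(
    markers = paste(sort(markers), collapse = "+"),
    size = panel_size,
    rule = rule,
    positive_class = positive_class,
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    p_value = ht$p.value
  )
  class(out) <- c("classifier_eval", class(out))
  out
}

#' Exhaustive OR-rule combination search
#'
#' Enumerates every subset of `candidates` of size 1 to `max_size`, evaluates
#' each under the `any_positive` rule with [evaluate_classifier()], and
#' returns the complete list ranked by: sensitivity (descending), specificity
#' (descending), p-value (ascending), panel size (smaller first), then
#' lexicographic marker names. The ranking is deterministic and invariant to
#' the input order of `candidates`.
#'
#' @param matrix Marker-matrix tibble.
#' @param candidates Character vector of candidate marker names.
#' @param cohort Cohort tibble.
#' @param positive_class `"resistant"` or `"sensitive"`.
#' @param max_size Largest panel size (default 3).
#' @param guard Maximum number of subsets to enumerate (default 1e6); larger
#'   candidate sets should be pre-screened with [screen_markers()].
#' @return A `combo_search` tibble: `rank` plus the [evaluate_classifier()]
#'   columns for every enumerated subset.
#' @export
search_combinations <- function(matrix, candidates, cohort,
                                positive_class = c("resistant", "sensitive"),
                                max_size = 3, guard = 1e6) {
  positive_class <- match.arg(positive_class)
  candidates <- sort(unique(candidates))
  if (max_size < 1 || max_size > length(candidates)) {
    abort("require 1 <= max_size <= number of candidates")
  }
  n_subsets <- sum(choose(length(candidates), seq_len(max_size)))
  if (n_subsets > guard) {
    abort(sprintf(
      "%.3g subsets exceed the enumeration guard (%g); pre-screen candidates first",
      n_subsets, guard
    ))
  }
  subsets <- purrr::list_flatten(purrr::map(seq_len(max_size), function(k) {
    apply(utils::combn(candidates, k), 2, identity, simplify = FALSE)
  }))
  res <- purrr::map_dfr(subsets, function(mk) {
    evaluate_classifier(matrix, mk, cohort, positive_class = positive_class)
  })
  res <- arrange(res, desc(.data$sensitivity), desc(.data$specificity),
                 .data$p_value, .data$size, .data$markers)
  res <- mutate(res, rank = row_number())
  res <- res[, c("rank", setdiff(names(res), "rank"))]
  class(res) <- c("combo_search", "tbl_df", "tbl", "data.frame")
  res
}
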