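#!/usr/bin/env Rscript
# Audit script: re-derives a 16-patient binary marker matrix consistent with
# the frozen constraint set (fixture_constraints()) by backtracking search,
# then checks that the packaged fixture satisfies the same constraints.
# Any consistent completion yields identical classifier tables; the packaged
# fixture is simply one frozen solution.
#
# Usage: Rscript scripts/fixture_search.R

suppressPackageStartupMessages(library(combimark))

cons <- fixture_constraints()
single <- cons$single
combos <- cons$combos

groups <- list(resistant = 7L, sensitive = 9L)

# Search marker membership over the positive-class group, one marker at a
# time; negative-class memberships have no union interplay beyond their
# fixed counts, so they are assigned deterministically afterwards.
search_side <- function(side) {
  rows <- single[single$positive_class == side, ]
  n <- groups[[side]]
  crel <- combos[combos$positive_class == side, ]
  crel$parts <- lapply(strsplit(crel$markers, "+", fixed = TRUE), identity)

  sets <- vector("list", nrow(rows))
  names(sets) <- rows$marker

  consistent <- function(upto) {
    assigned <- names(sets)[seq_len(upto)]
    for (i in seq_len(nrow(crel))) {
      parts <- crel$parts[[i]]
      if (!all(parts %in% assigned)) next
      got <- length(Reduce(union, sets[parts]))
      if (got != crel$tp[i]) return(FALSE)
    }
    TRUE
  }

  recurse <- function(i) {
    if (i > nrow(rows)) return(TRUE)
    k <- rows$tp[i]
    for (members in utils::combn(n, k, simplify = FALSE)) {
      sets[[i]] <<- members
      if (consistent(i) && recurse(i + 1)) return(TRUE)
    }
    sets[[i]] <<- NULL
    FALSE
  }
  if (!recurse(1)) stop("no consistent completion found for side ", side)
  sets
}

res_sets <- search_side("resistant")
sen_sets <- search_side("sensitive")

# assemble the matrix: positives in the marker's own class group from the
# search, plus the first `fp` patients of the opposite group
sens_ids <- sprintf("S%02d", 1:9)
res_ids <- sprintf("R%02d", 1:7)
matrix <- tibble::tibble(patient_id = c(sens_ids, res_ids))
for (i in seq_len(nrow(single))) {
  mk <- single$marker[i]
  side <- single$positive_class[i]
  pos <- if (side == "resistant") {
    c(res_ids[res_sets[[mk]]], sens_ids[seq_len(single$fp[i])])
  } else {
    c(sens_ids[sen_sets[[mk]]], res_ids[seq_len(single$fp[i])])
  }
  matrix[[mk]] <- as.integer(matrix$patient_id %in% pos)
}

cohort <- tibble::tibble(
  patient_id = c(sens_ids, res_ids),
  group = c(rep("sensitive", 9), rep("resistant", 7))
)

# NOTE: the opposite-group assignment above is only valid because every
# combo's FP count is implied by the component FP sets being nested
# (all FP=1 markers share one sensitive patient); verify to be sure.
verify_fixture(matrix, cohort)
cat("backtracking search found a consistent matrix; constraints verified\n")

fx <- build_fixture_cohort()
verify_fixture(fx$matrix, fx$cohort)
cat("packaged fixture verified against the same constraint set\n")
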