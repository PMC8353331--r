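COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  paste(rev(COMPLEMENT[stringr::str_split_1(toupper(x), "")]), collapse = "")
}

# reference accessor: named character vector or Biostrings::DNAStringSet
.ref_subseq <- function(reference, chrom, start1, end1) {
  if (methods::is(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference)) return(NA_character_)
    sq <- reference[[chrom]]
    if (start1 < 1 || end1 > length(sq)) return(NA_character_)
    return(as.character(Biostrings::subseq(sq, start1, end1)))
  }
  if (!chrom %in% names(reference)) return(NA_character_)
  sq <- reference[[chrom]]
  if (start1 < 1 || end1 > nchar(sq)) return(NA_character_)
  toupper(substr(sq, start1, end1))
}

#' Build a 96-channel trinucleotide mutation spectrum
#'
#' Tallies single-nucleotide substitutions into the 96 channels of
#' [spectrum_channels()], using the pyrimidine convention: substitutions whose
#' reference base is a purine are reverse-complemented (a `G>A` call with
#' reference context `TGC` is counted as `C>T` in context `GCA`). Indel
#' records are skipped and counted, as are records at contig edges where no
#' trinucleotide flank exists.
#'
#' @param snvs Tibble of SNV records (`chrom`, `pos` 1-based, `ref`, `alt`).
#' @param reference Reference sequences: a named character vector or a
#'   `Biostrings::DNAStringSet`, names matching `chrom`.
#' @return A `spectrum96` object: the 96-row channel tibble with a `count`
#'   column, plus attributes `n_total` (counted substitutions), `n_indels`
#'   and `n_skipped` (edge/invalid records).
#' @export
build_spectrum <- function(snvs, reference) {
  ch <- spectrum_channels()
  counts <- stats::setNames(rep(0L, 96), ch$channel)
  n_indels <- 0L
  n_skipped <- 0L
  for (i in seq_len(NROW(snvs))) {
    ref <- toupper(snvs$ref[i])
    alt <- toupper(snvs$alt[i])
    if (nchar(ref) != 1 || nchar(alt) != 1) {
      n_indels <- n_indels + 1L
      next
    }
    tri <- .ref_subseq(reference, snvs$chrom[i], snvs$pos[i] - 1L,
                       snvs$pos[i] + 1L)
    if (is.na(tri) || nchar(tri) != 3 ||
        !all(stringr::str_split_1(tri, "") %in% c("A", "C", "G", "T")) ||
        !alt %in% c("A", "C", "G", "T") || ref == alt) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (ref %in% c("G", "A")) {
      tri <- .revcomp(tri)
      ref <- COMPLEMENT[[ref]]
      alt <- COMPLEMENT[[alt]]
    }
    channel <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                      substr(tri, 3, 3))
    counts[channel] <- counts[channel] + 1L
  }
  spectrum <- mutate(ch, count = unname(counts))
  structure(spectrum,
            n_total = sum(counts), n_indels = n_indels, n_skipped = n_skipped,
            class = c("spectrum96", class(spectrum)))
}

#' Collapse a 96-channel spectrum to six substitution classes
#'
#' Sums the 16 context channels of each substitution class and returns the
#' class fractions (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`), which sum to 1.
#'
#' @param spectrum A `spectrum96` object with at least one counted mutation.
#' @return Named numeric vector of 6 fractions.
#' @export
collapse_to_six <- function(spectrum) {
  n <- sum(spectrum$count)
  if (n == 0) abort("cannot collapse an empty spectrum (n_total = 0)")
  cls <- spectrum |>
    group_by(.data$substitution) |>
    summarise(count = sum(.data$count), .groups = "drop")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  stats::setNames(cls$count[match(subs, cls$substitution)] / n, subs)
}

#' Fit signature exposures by non-negative least squares
#'
#' Decomposes a normalised 96-channel spectrum as a non-negative mixture of
#' reference signatures (exposure refitting). The NNLS solution is
#' renormalised to sum to 1; the residual is the Euclidean norm of the fit
#' residual before renormalisation. Samples with fewer than `min_mutations`
#' counted substitutions are fitted but flagged low-confidence, since
#' refitting on tiny catalogs is noise-dominated.
#'
#' @param spectrum A `spectrum96` with `n_total > 0`.
#' @param reference A `signature_reference`.
#' @param patient_id Optional identifier carried on the result.
#' @param min_mutations Low-confidence threshold (default 20).
#' @return A `signature_fit` object: list with `patient_id`, `exposures`
#'   (tibble `signature`, `exposure`), `residual`, `n_total`,
#'   `low_confidence`. Use [generics::tidy()] / [generics::glance()] to
#'   extract tidy summaries.
#' @export
fit_exposures <- function(spectrum, reference, patient_id = NA_character_,
                          min_mutations = 20) {
  n <- sum(spectrum$count)
  if (n == 0) abort("cannot fit exposures for an empty spectrum (n_total = 0)")
  b <- spectrum$count / n
  A <- t(reference$matrix) # 96 x k
  fit <- pracma::lsqnonneg(A, b)
  x <- fit$x
  residual <- sqrt(sum((A %*% x - b)^2))
  exposures <- if (sum(x) > 0) x / sum(x) else x
  structure(
    list(
      patient_id = patient_id,
      exposures = tibble(signature = reference$names,
                         exposure = as.numeric(exposures)),
      residual = residual,
      n_total = n,
      low_confidence = n < min_mutations
    ),
    class = "signature_fit"
  )
}

#' @export
print.signature_fit <- function(x, ...) {
  top <- dplyr::slice_max(x$exposures, .data$exposure, n = 3)
  cat(sprintf(
    "<signature_fit%s: n = %d substitutions, residual %.4g%s>\n",
    if (is.na(x$patient_id)) "" else paste0(" ", x$patient_id),
    x$n_total, x$residual,
    if (x$low_confidence) ", LOW CONFIDENCE" else ""
  ))
  cat(paste(sprintf("  %s: %.1f%%", top$signature, 100 * top$exposure),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Compare signature exposures between two groups
#'
#' Runs the package's two-sided Mann-Whitney U test per signature on the
#' exposure fractions of two groups of fitted samples.
#'
#' @param group_a,group_b Non-empty lists of `signature_fit` objects.
#' @return A tibble with one row per signature: `signature`, `median_a`,
#'   `median_b`, `statistic` (U for group A) and `p_value`.
#' @export
compare_exposures <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  expo <- function(fits) {
    vapply(fits, function(f) f$exposures$exposure,
           numeric(nrow(group_a[[1]]$exposures)))
  }
  ea <- expo(group_a)
  eb <- expo(group_b)
  sigs <- group_a[[1]]$exposures$signature
  purrr::map_dfr(seq_along(sigs), function(i) {
    ht <- mann_whitney_u(ea[i, ], eb[i, ])
    tibble(
      signature = sigs[i],
      median_a = stats::median(ea[i, ]),
      median_b = stats::median(eb[i, ]),
      statistic = unname(ht$statistic),
      p_value = ht$p.value
    )
  })
}
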