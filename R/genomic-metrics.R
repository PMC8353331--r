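#' Tumor mutational burden
#'
#' TMB is the count of somatic non-synonymous mutations divided by the size of
#' the captured target region in megabases. The denominator is configurable
#' because capture kits differ; 50 Mb is the usual whole-exome convention.
#'
#' @param snvs Tibble of SNV/indel records with an `effect` column.
#' @param target_size_mb Captured target size in Mb (> 0). Default 50.
#' @return Mutations per megabase (non-negative double).
#' @examples
#' snvs <- tibble::tibble(effect = rep("non_synonymous", 165))
#' compute_tmb(snvs, 50) # 3.3
#' @export
compute_tmb <- function(snvs, target_size_mb = 50) {
  if (target_size_mb <= 0) abort("target_size_mb must be positive")
  n <- if (is.null(snvs) || nrow(snvs) == 0) 0L else
    sum(snvs$effect == "non_synonymous")
  n / target_size_mb
}

#' Classify microsatellite sites as stable or unstable
#'
#' A site is *valid* when both the tumor and the matched-normal repeat-length
#' read histograms reach `min_depth` total reads. A valid site is *unstable*
#' when the total-variation distance between the depth-normalised tumor and
#' normal length distributions exceeds `shift_threshold`. Degenerate
#' histograms (zero depth) simply yield an invalid site, never an error.
#'
#' @param evidence Tibble with list columns `tumor_lengths` and
#'   `normal_lengths`, each element a named numeric vector mapping repeat
#'   count to read count (as produced by [generate_msi_evidence()]).
#' @param min_depth Minimum total reads per histogram for a valid site.
#' @param shift_threshold Total-variation distance above which a valid site is
#'   called unstable. Default 0.3.
#' @return The input with logical columns `valid` and `unstable` and a
#'   numeric `tv_distance` column (`NA` when invalid).
#' @export
classify_site_stability <- function(evidence, min_depth = 20,
                                    shift_threshold = 0.3) {
  res <- purrr::map2(evidence$tumor_lengths, evidence$normal_lengths,
                     function(tu, no) {
    dt <- sum(tu)
    dn <- sum(no)
    if (any(c(tu, no) < 0)) abort("read counts must be non-negative")
    valid <- dt >= min_depth && dn >= min_depth && dt > 0 && dn > 0
    if (!valid) return(list(valid = FALSE, unstable = FALSE, tv = NA_real_))
    lens <- union(names(tu), names(no))
    p <- stats::setNames(rep(0, length(lens)), lens)
    q <- p
    p[names(tu)] <- tu / dt
    q[names(no)] <- no / dn
    tv <- sum(abs(p - q)) / 2
    list(valid = TRUE, unstable = tv > shift_threshold, tv = tv)
  })
  mutate(evidence,
    valid = purrr::map_lgl(res, "valid"),
    unstable = purrr::map_lgl(res, "unstable"),
    tv_distance = purrr::map_dbl(res, "tv")
  )
}

#' Microsatellite instability score
#'
#' The MSI score is the number of unstable microsatellite sites divided by the
#' number of valid sites. With no valid sites the score is 0 and a warning is
#' emitted.
#'
#' @param sites Tibble with logical `valid` and `unstable` columns, as
#'   returned by [classify_site_stability()].
#' @return Fraction in \[0, 1\].
#' @export
msi_score <- function(sites) {
  n_valid <- sum(sites$valid)
  if (n_valid == 0) {
    warn("no valid microsatellite sites; MSI score reported as 0")
    return(0)
  }
  sum(sites$unstable) / n_valid
}

#' Exome-wide amplification and deletion fractions
#'
#' Each exon is assigned to the copy-number segment containing its midpoint
#' (first covering segment in `(chrom, start)` order); the exon counts as
#' amplified when that segment's copy number is at least `2 * ploidy` and as
#' deleted when it is at most `0.5 * ploidy`. Exons covered by no segment are
#' neutral. Midpoint membership avoids fractional-overlap bookkeeping.
#'
#' @param exons Tibble of non-overlapping exon intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param segments Tibble of CNV segments (columns `chrom`, `start`, `end`,
#'   `copy_number`), as from [read_cnv_segments()].
#' @param ploidy Average ploidy of the sample (> 0).
#' @return A list with `amp_fraction` and `del_fraction`, each in \[0, 1\].
#' @export
cnv_burden <- function(exons, segments, ploidy = 2) {
  if (is.null(exons) || nrow(exons) == 0) abort("exon list must be non-empty")
  if (ploidy <= 0) abort("ploidy must be positive")
  seg <- if (is.null(segments) || nrow(segments) == 0) {
    tibble(chrom = character(), start = double(), end = double(),
           copy_number = double())
  } else {
    arrange(segments, .data$chrom, .data$start)
  }
  mid <- floor((exons$start + exons$end) / 2)
  cn <- purrr::map_dbl(seq_len(nrow(exons)), function(i) {
    hit <- which(seg$chrom == exons$chrom[i] & seg$start <= mid[i] &
                   mid[i] < seg$end)
    if (length(hit) == 0) NA_real_ else seg$copy_number[hit[1]]
  })
  list(
    amp_fraction = mean(!is.na(cn) & cn >= 2 * ploidy),
    del_fraction = mean(!is.na(cn) & cn <= 0.5 * ploidy)
  )
}
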