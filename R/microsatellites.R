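#' Scan a sequence for microsatellite tracts
#'
#' Finds maximal perfect tandem repeats with motif length 1 to `max_motif`
#' and at least `min_repeats` complete units, the usual short-tandem-repeat
#' definition for MSI scoring. For each genomic run the shortest (primitive)
#' motif is reported — a poly-A run is motif `"A"`, never `"AA"` — and a
#' tract of a longer motif that lies wholly inside a shorter-motif tract is
#' suppressed. Trailing partial units are trimmed, so
#' `end - start == nchar(motif) * n_repeats`. Runs containing `N` are never
#' part of a tract.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @param min_repeats Minimum number of complete motif units (default 5).
#' @param max_motif Maximum motif length in bp (default 5).
#' @return A tibble with columns `start`, `end` (0-based half-open), `motif`,
#'   `n_repeats`, sorted by `start` then motif length.
#' @examples
#' find_microsatellites("GGAAAAATT") # one poly-A tract
#' @export
find_microsatellites <- function(sequence, min_repeats = 5, max_motif = 5) {
  s <- toupper(sequence)
  chars <- stringr::str_split_1(s, "")
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence may contain only A, C, G, T, N")
  }
  L <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")

  tracts <- list()
  for (m in seq_len(min(max_motif, max(0, L - 1)))) {
    # eq[k] TRUE when position k matches position k+m and both are ACGT
    k <- seq_len(L - m)
    eq <- chars[k] == chars[k + m] & valid[k] & valid[k + m]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      run_len <- r$lengths[j] # matched pairs; repeated region spans run_len + m
      n_units <- (run_len + m) %/% m
      if (n_units < min_repeats) next
      i0 <- starts[j] - 1L # 0-based tract start
      motif <- paste(chars[(i0 + 1):(i0 + m)], collapse = "")
      if (!.is_primitive_motif(motif)) next
      tracts[[length(tracts) + 1]] <- tibble(
        start = i0, end = i0 + m * n_units,
        motif = motif, n_repeats = n_units
      )
    }
  }
  if (length(tracts) == 0) {
    return(tibble(start = integer(), end = integer(),
                  motif = character(), n_repeats = integer()))
  }
  out <- bind_rows(tracts) |>
    mutate(motif_len = nchar(.data$motif)) |>
    arrange(.data$start, .data$motif_len)
  # suppress tracts wholly explained by a shorter-motif tract
  keep <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
    !any(out$motif_len < out$motif_len[i] &
           out$start <= out$start[i] & out$end >= out$end[i])
  })
  out[keep, c("start", "end", "motif", "n_repeats")]
}

# a motif is primitive when it is not a whole-number power of a shorter motif
.is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1) return(TRUE)
  for (d in seq_len(m - 1)) {
    if (m %% d == 0 &&
        motif == strrep(substr(motif, 1, d), m / d)) {
      return(FALSE)
    }
  }
  TRUE
}
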