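#' The 96 trinucleotide substitution channels
#'
#' Canonical channel order used throughout the package: substitution-major
#' (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`), then the 5' base in
#' `A`, `C`, `G`, `T` order, then the 3' base in the same order. Substitutions
#' follow the pyrimidine convention (the mutated reference base is `C` or
#' `T`; purine-reference calls are reverse-complemented).
#'
#' @return A 96-row tibble with columns `channel` (e.g. `"A[C>A]A"`),
#'   `substitution`, `five_prime`, `ref`, `alt`, `three_prime`.
#' @export
spectrum_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- tidyr::expand_grid(substitution = subs, five_prime = bases,
                             three_prime = bases)
  mutate(grid,
    ref = substr(.data$substitution, 1, 1),
    alt = substr(.data$substitution, 3, 3),
    channel = paste0(.data$five_prime, "[", .data$substitution, "]",
                     .data$three_prime)
  )[, c("channel", "substitution", "five_prime", "ref", "alt", "three_prime")]
}

.new_signature_reference <- function(mat) {
  ch <- spectrum_channels()$channel
  stopifnot(ncol(mat) == 96)
  colnames(mat) <- ch
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-6)) {
    abort("every signature row must sum to 1 (tolerance 1e-6)")
  }
  if (any(mat < 0)) abort("signature entries must be non-negative")
  structure(list(names = rownames(mat), matrix = mat),
            class = "signature_reference")
}

#' @export
print.signature_reference <- function(x, ...) {
  cat(sprintf("<signature_reference: %d signatures x 96 channels>\n",
              length(x$names)))
  invisible(x)
}

#' Deterministic synthetic signature reference (COSMIC v2 layout)
#'
#' Builds a synthetic, row-stochastic 30 x 96 signature matrix laid out like
#' the COSMIC v2 catalog (30 signatures, 96 pyrimidine-convention channels).
#' Each signature concentrates three quarters of its mass on six
#' signature-specific peak channels (drawn under a fixed internal seed, with
#' the caller's RNG state untouched) over a low uniform background, so the
#' matrix is well conditioned for exposure refitting and identical on every
#' call. **These are not the empirical COSMIC signatures**; they exist so
#' the decomposition machinery can be exercised and validated without the
#' external catalog. Substitute the real matrix with
#' [read_signature_reference()] for production use.
#'
#' @param n_signatures Number of signatures (default 30).
#' @return A `signature_reference` object.
#' @export
synthetic_signature_reference <- function(n_signatures = 30) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(9661)
  mat <- matrix(0, nrow = n_signatures, ncol = 96)
  peak_w <- c(0.30, 0.22, 0.16, 0.12, 0.10, 0.10)
  for (i in seq_len(n_signatures)) {
    peaks <- sample.int(96, length(peak_w))
    prof <- rep(0.25 / 96, 96)
    prof[peaks] <- prof[peaks] + 0.75 * peak_w
    mat[i, ] <- prof / sum(prof)
  }
  rownames(mat) <- paste0("Signature.", seq_len(n_signatures))
  .new_signature_reference(mat)
}

#' Read and write a signature reference TSV
#'
#' The TSV may be laid out either as signatures-in-rows (a `signature` column
#' followed by 96 channel columns) or channels-in-rows (a `channel` column
#' followed by one column per signature); the orientation is auto-detected
#' from the header. Rows of the resulting matrix must each sum to 1 within
#' 1e-6. Any row-stochastic matrix can stand in for the COSMIC v2 catalog.
#'
#' @param path Path to the TSV.
#' @return `read_signature_reference()` returns a `signature_reference`;
#'   `write_signature_reference()` returns `path` invisibly (signatures in
#'   rows).
#' @export
read_signature_reference <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  ch <- spectrum_channels()$channel
  if (all(ch %in% names(tab))) { # signatures in rows
    mat <- as.matrix(tab[, ch])
    rownames(mat) <- tab[[1]]
  } else if (all(ch %in% tab[[1]])) { # channels in rows
    mat <- t(as.matrix(tab[-1]))
    colnames(mat) <- tab[[1]]
    mat <- mat[, ch, drop = FALSE]
  } else {
    abort("cannot detect signature TSV orientation: no complete channel set found")
  }
  .new_signature_reference(mat)
}

#' @rdname read_signature_reference
#' @param reference A `signature_reference` object.
#' @export
write_signature_reference <- function(reference, path) {
  tab <- dplyr::bind_cols(tibble(signature = reference$names),
                          as_tibble(reference$matrix))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
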