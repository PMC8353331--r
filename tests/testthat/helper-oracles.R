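# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately avoid the code paths they check.

# Two-sided Fisher p by explicit enumeration of every table with the observed
# margins, probabilities via direct binomial-coefficient arithmetic.
fisher_oracle <- function(a, b, c, d, tie_tol = 1e-7) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + tie_tol)]))
}

# Microsatellite tract enumeration: every (start, motif-length) pair is
# tested for >= min_repeats full units of a primitive motif. A candidate is
# the head of its periodic run when period-m matching already fails at
# start - 1, which collapses shifted alignments of one run to the leftmost
# while keeping distinct adjacent runs of the same period. Tracts wholly
# inside a shorter-period tract are suppressed.
microsat_oracle <- function(seq, min_repeats = 5, max_motif = 5) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  found <- list()
  for (m in 1:max_motif) {
    hits <- list()
    for (s in seq_len(max(0, L - m * min_repeats + 1))) {
      motif <- paste(chars[s:(s + m - 1)], collapse = "")
      if (grepl("[^ACGT]", motif)) next
      # primitive?
      prim <- TRUE
      for (d in seq_len(m - 1)) {
        if (m %% d == 0 &&
            motif == strrep(substr(motif, 1, d), m / d)) prim <- FALSE
      }
      if (!prim) next
      # head of the periodic run?
      if (s > 1 && valid[s - 1] && valid[s - 1 + m] &&
          chars[s - 1] == chars[s - 1 + m]) next
      # count full units
      k <- 1
      while (s + (k + 1) * m - 1 <= L &&
             paste(chars[(s + k * m):(s + (k + 1) * m - 1)],
                   collapse = "") == motif) {
        k <- k + 1
      }
      if (k < min_repeats) next
      hits[[length(hits) + 1]] <-
        data.frame(start = s - 1, end = s - 1 + k * m, motif = motif,
                   n_repeats = k)
    }
    if (length(hits) > 0) found[[m]] <- do.call(rbind, hits)
  }
  out <- do.call(rbind, found)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), n_repeats = integer()))
  }
  out$mlen <- nchar(out$motif)
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$mlen < out$mlen[i] & out$start <= out$start[i] &
           out$end >= out$end[i])
  }, logical(1))
  out <- out[keep, c("start", "end", "motif", "n_repeats")]
  out <- out[order(out$start, nchar(out$motif)), ]
  rownames(out) <- NULL
  out
}

# Per-exon brute-force CNV burden check
cnv_burden_oracle <- function(exons, segments, ploidy) {
  amp <- 0
  del <- 0
  for (i in seq_len(nrow(exons))) {
    mid <- floor((exons$start[i] + exons$end[i]) / 2)
    cn <- NA_real_
    segs <- segments[order(segments$chrom, segments$start), ]
    for (j in seq_len(nrow(segs))) {
      if (segs$chrom[j] == exons$chrom[i] && segs$start[j] <= mid &&
          mid < segs$end[j]) {
        cn <- segs$copy_number[j]
        break
      }
    }
    if (!is.na(cn) && cn >= 2 * ploidy) amp <- amp + 1
    if (!is.na(cn) && cn <= 0.5 * ploidy) del <- del + 1
  }
  list(amp_fraction = amp / nrow(exons), del_fraction = del / nrow(exons))
}

# Draw a random multinomial 96-spectrum and wrap it as a spectrum96
random_spectrum <- function(p96, n) {
  counts <- as.integer(stats::rmultinom(1, n, p96))
  sp <- dplyr::mutate(combimark::spectrum_channels(), count = counts)
  attr(sp, "n_total") <- n
  class(sp) <- c("spectrum96", class(sp))
  sp
}

# Tiny two-patient cohort used across io tests
tiny_cohort <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    response = c("PR", "PD", "PD"),
    group = c("sensitive", "resistant", "resistant")
  )
}

write_tiny_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    lines
  ), path)
  path
}
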