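#' Generate a signature-mixture SNV catalog on a synthetic reference
#'
#' Draws a random reference sequence, samples `n_mutations` substitution
#' channels from the mixture `t(reference$matrix) %*% exposures`, and places
#' each mutation at a distinct position whose trinucleotide context matches
#' the sampled channel on either strand (pyrimidine-convention contexts are
#' matched on the reverse complement where the genomic base is a purine).
#' The truth exposures are returned so signature-refitting accuracy can be
#' measured end to end.
#'
#' @param exposures Numeric vector of mixture weights, one per reference
#'   signature, non-negative and summing to 1 (within 1e-6).
#' @param n_mutations Number of substitutions to sample.
#' @param reference Signatures to mix, a `signature_reference`.
#' @param reference_length Length in bp of the synthetic reference contig.
#' @param seed Integer seed; identical seeds give identical output.
#' @param dir Optional directory; when given, `reference.fa` and
#'   `catalog.vcf` are written there.
#' @return A list with `sequence` (named character vector, one contig),
#'   `snvs` (tibble as from [read_snv_calls()]), `truth` (tibble
#'   `signature`, `exposure`) and, when `dir` is given, `paths`.
#' @export
generate_snv_catalog <- function(exposures, n_mutations, reference,
                                 reference_length = 2e5, seed = 1,
                                 dir = NULL) {
  if (length(exposures) != length(reference$names)) {
    abort("exposures must have one weight per reference signature")
  }
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-6) {
    abort("exposures must be non-negative and sum to 1")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, reference_length, replace = TRUE)
  seq_str <- paste(chars, collapse = "")

  ch <- spectrum_channels()
  p96 <- as.numeric(exposures %*% reference$matrix)
  drawn <- if (n_mutations > 0) {
    tabulate(sample.int(96, n_mutations, replace = TRUE, prob = p96), 96)
  } else {
    rep(0L, 96)
  }

  # pyrimidine-strand context of every interior position
  mid <- chars[2:(reference_length - 1)]
  five <- chars[1:(reference_length - 2)]
  three <- chars[3:reference_length]
  pyr <- mid %in% c("C", "T")
  ctx_five <- ifelse(pyr, five, COMPLEMENT[three])
  ctx_ref <- ifelse(pyr, mid, COMPLEMENT[mid])
  ctx_three <- ifelse(pyr, three, COMPLEMENT[five])
  ctx_key <- paste0(ctx_five, ctx_ref, ctx_three)

  ch_key <- paste0(ch$five_prime, ch$ref, ch$three_prime)
  pos_by_ctx <- split(2:(reference_length - 1), ctx_key)

  records <- list()
  for (ctx in unique(ch_key)) {
    idx <- which(ch_key == ctx)
    need <- drawn[idx]
    avail <- pos_by_ctx[[ctx]] %||% integer()
    if (sum(need) > length(avail)) {
      abort(sprintf(
        "reference too short: context %s needs %d positions, %d available",
        ctx, sum(need), length(avail)
      ))
    }
    if (sum(need) == 0) next
    chosen <- sample(avail, sum(need))
    alts <- rep(ch$alt[idx], need)
    records[[length(records) + 1]] <- tibble(pos = chosen, alt_pyr = alts)
  }
  snvs <- if (length(records) == 0) {
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), gene = character(), effect = character(),
           patient_id = character())
  } else {
    recs <- bind_rows(records)
    genomic_ref <- chars[recs$pos]
    on_pyr <- genomic_ref %in% c("C", "T")
    tibble(
      chrom = "synth1",
      pos = as.integer(recs$pos),
      ref = genomic_ref,
      alt = ifelse(on_pyr, recs$alt_pyr,
                   unname(COMPLEMENT[recs$alt_pyr])),
      gene = "",
      effect = "non_synonymous",
      patient_id = "SIM"
    ) |> arrange(.data$pos)
  }
  out <- list(
    sequence = stats::setNames(seq_str, "synth1"),
    snvs = snvs,
    truth = tibble(signature = reference$names,
                   exposure = as.numeric(exposures))
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "reference.fa")
    dna <- Biostrings::DNAStringSet(out$sequence)
    Biostrings::writeXStringSet(dna, fa)
    vcf <- file.path(dir, "catalog.vcf")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tEFFECT=non_synonymous",
                    snvs$chrom, snvs$pos, snvs$ref, snvs$alt)
    readr::write_lines(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Functional effect\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body
    ), vcf)
    out$paths <- list(reference_fasta = fa, vcf = vcf)
  }
  out
}

#' Generate microsatellite read-length evidence
#'
#' Simulates tumor/normal repeat-length read histograms for `n_sites` loci.
#' Each locus gets a base repeat count between 8 and 15; the normal histogram
#' is a multinomial draw of `depth` reads over lengths (base - 1, base,
#' base + 1) with probabilities (0.2, 0.6, 0.2). Stable sites draw the tumor
#' histogram from the same distribution; unstable sites (a seeded sample of
#' `round(frac_unstable * n_sites)` loci) shift the tumor distribution down
#' by 2 repeat units, well past the default instability threshold.
#'
#' @param n_sites Number of loci.
#' @param frac_unstable Fraction of loci made unstable, in \[0, 1\].
#' @param depth Reads per histogram; a value below `min_depth` warns (all
#'   sites will be invalid under the default classifier).
#' @param seed Integer seed.
#' @param min_depth Depth used only for the warning check (default 20).
#' @return A tibble with columns `site`, `motif`, `n_repeats`,
#'   `truth_unstable`, and list columns `tumor_lengths`, `normal_lengths`
#'   (named read-count vectors), ready for [classify_site_stability()].
#' @export
generate_msi_evidence <- function(n_sites, frac_unstable, depth, seed = 1,
                                  min_depth = 20) {
  if (frac_unstable < 0 || frac_unstable > 1) {
    abort("frac_unstable must lie in [0, 1]")
  }
  if (depth < min_depth) {
    warn(sprintf("depth %d is below min_depth %d: all sites will be invalid",
                 depth, min_depth))
  }
  set.seed(seed)
  n_unstable <- round(frac_unstable * n_sites)
  unstable_at <- sample(n_sites, n_unstable)
  hist_at <- function(center, depth) {
    lens <- center + (-1):1
    counts <- as.integer(stats::rmultinom(1, depth, c(0.2, 0.6, 0.2)))
    stats::setNames(counts, lens)
  }
  purrr::map_dfr(seq_len(n_sites), function(i) {
    base <- sample(8:15, 1)
    shifted <- i %in% unstable_at
    tibble(
      site = sprintf("site_%04d", i),
      motif = "A",
      n_repeats = base,
      truth_unstable = shifted,
      tumor_lengths = list(hist_at(if (shifted) base - 2 else base, depth)),
      normal_lengths = list(hist_at(base, depth))
    )
  })
}

#' Read and write site-evidence TSVs
#'
#' One row per microsatellite locus with `tumor` and `normal` histograms
#' serialised as comma-separated `length:count` pairs.
#'
#' @param evidence Evidence tibble with `tumor_lengths` / `normal_lengths`
#'   list columns.
#' @param path File path.
#' @return `write_msi_evidence()` returns `path` invisibly;
#'   `read_msi_evidence()` the evidence tibble.
#' @export
write_msi_evidence <- function(evidence, path) {
  ser <- function(h) {
    paste(sprintf("%s:%d", names(h), as.integer(h)), collapse = ",")
  }
  tab <- tibble(
    site = evidence$site,
    motif = evidence$motif,
    n_repeats = evidence$n_repeats,
    tumor = purrr::map_chr(evidence$tumor_lengths, ser),
    normal = purrr::map_chr(evidence$normal_lengths, ser)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_msi_evidence
#' @export
read_msi_evidence <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    site = readr::col_character(), motif = readr::col_character(),
    n_repeats = readr::col_integer(), tumor = readr::col_character(),
    normal = readr::col_character()
  ), progress = FALSE)
  de <- function(s) {
    if (is.na(s) || !nzchar(s)) return(stats::setNames(integer(), character()))
    parts <- stringr::str_split_fixed(stringr::str_split_1(s, ","), ":", 2)
    stats::setNames(as.integer(parts[, 2]), parts[, 1])
  }
  tibble(
    site = tab$site, motif = tab$motif, n_repeats = tab$n_repeats,
    tumor_lengths = purrr::map(tab$tumor, de),
    normal_lengths = purrr::map(tab$normal, de)
  )
}
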