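#' Read a cohort sample sheet
#'
#' The sample sheet is a UTF-8, tab-delimited file with a mandatory header.
#' Required columns: `patient_id` and `response` (one of `CR`, `PR`, `SD`,
#' `PD`). Optional columns are carried through unchanged: prior-therapy flags
#' (`prior_surgery`, `prior_radiotherapy`, `prior_chemotherapy`,
#' `prior_endocrine`, coded 0/1), `psa_baseline` and `fpsa_baseline` (ng/ml),
#' `age` (years), and `ploidy` (per-patient average ploidy used for CNV
#' thresholds; defaults to 2 downstream when absent).
#'
#' A `group` column is derived: `"sensitive"` for complete or partial response
#' (CR/PR), `"resistant"` for stable or progressive disease (SD/PD). Row order
#' is preserved.
#'
#' @param path Path to the sample-sheet TSV.
#' @return A tibble with one row per patient, including the derived `group`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    response = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("patient_id", "response")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    abort(paste0("sample sheet is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!sheet$response %in% RESPONSE_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown response label '%s' in row %d (patient '%s'); expected CR, PR, SD or PD",
      sheet$response[bad[1]], bad[1], sheet$patient_id[bad[1]]
    ))
  }
  dup <- sheet$patient_id[duplicated(sheet$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate patient_id: ", paste(unique(dup), collapse = ", ")))
  }
  dplyr::mutate(sheet, group = response_group(.data$response))
}

#' Read annotated somatic SNV/indel calls from a VCF
#'
#' Parses a VCF 4.x file and returns one record per ALT allele (multi-allelic
#' sites are split). Gene symbol and functional effect are taken from INFO
#' keys (defaults `GENE` and `EFFECT`); the effect string is normalised to
#' `non_synonymous`, `synonymous` or `other`. Records with no gene annotation
#' are retained with `gene = ""` (marker building skips them). Positions are
#' 1-based, as in the VCF.
#'
#' @param path Path to the VCF file.
#' @param patient_id Patient identifier attached to every record.
#' @param gene_key,effect_key INFO keys holding the gene symbol and effect.
#' @param nonsyn_effects Effect strings (lower-cased) treated as
#'   non-synonymous coding changes.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `effect`, `patient_id`.
#' @export
read_snv_calls <- function(path, patient_id,
                           gene_key = "GENE", effect_key = "EFFECT",
                           nonsyn_effects = c("non_synonymous",
                                              "nonsynonymous", "missense",
                                              "stopgain", "stoploss",
                                              "frameshift",
                                              "nonframeshift")) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  .validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene = character(), effect = character(),
                  patient_id = character()))
  }
  fix <- as_tibble(fix)
  info_field <- function(info, key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    dplyr::coalesce(m, "")
  }
  recs <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_field(fix$INFO, gene_key),
    effect = .normalise_effect(info_field(fix$INFO, effect_key),
                               nonsyn_effects)
  )
  recs <- tidyr::separate_rows(recs, "alt", sep = ",")
  recs <- filter(recs, .data$ref != .data$alt)
  mutate(recs, patient_id = patient_id)
}

# hard-errors with a line number on structurally broken body lines
.validate_vcf_lines <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(stringr::str_split(lines[body], "\t"))
  bad <- body[nfield < 8]
  if (length(bad) > 0) {
    abort(sprintf("malformed VCF line %d in %s: fewer than 8 tab-separated fields",
                  bad[1], path))
  }
  invisible(TRUE)
}

.normalise_effect <- function(effect, nonsyn_effects) {
  e <- tolower(effect)
  dplyr::case_when(
    e %in% tolower(nonsyn_effects) ~ "non_synonymous",
    e == "synonymous" ~ "synonymous",
    TRUE ~ "other"
  )
}

#' Read copy-number segments from a SEG-like TSV
#'
#' Expected columns: `chrom`, `start`, `end`, `copy_number`, `genes`
#' (semicolon-separated symbols; may be empty). Coordinates are 0-based
#' half-open, the package's convention for all intervals. Lines starting with
#' `#` are skipped. Segments are validated and returned sorted by
#' `(chrom, start)`.
#'
#' @param path Path to the segment TSV.
#' @param patient_id Patient identifier attached to every segment.
#' @return A tibble with columns `chrom`, `start`, `end`, `copy_number`,
#'   `genes` (list column of character vectors), `patient_id`.
#' @export
read_cnv_segments <- function(path, patient_id) {
  seg <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    copy_number = readr::col_double(),
    genes = readr::col_character()
  ), progress = FALSE)
  bad <- which(seg$start >= seg$end)
  if (length(bad) > 0) {
    abort(sprintf("segment row %d has start >= end (%g >= %g)",
                  bad[1], seg$start[bad[1]], seg$end[bad[1]]))
  }
  if (any(seg$copy_number < 0)) {
    abort("negative copy_number in segment file")
  }
  seg$genes[is.na(seg$genes)] <- ""
  seg <- mutate(seg,
    genes = purrr::map(.data$genes,
                       ~ setdiff(stringr::str_split_1(.x, ";"), "")),
    patient_id = patient_id
  )
  arrange(seg, .data$chrom, .data$start)
}

#' Build the binary patients-by-markers matrix
#'
#' For each gene in `gene_panel` and each patient, four binary markers are
#' derived from the call sets:
#' \describe{
#'   \item{`mutation`}{1 if the patient has at least one SNV/indel in the gene
#'     whose effect is in `mutation_effects` (default: anything not annotated
#'     synonymous).}
#'   \item{`cnv_amp`}{1 if any segment listing the gene has
#'     `copy_number >= 2 * ploidy`.}
#'   \item{`cnv_del`}{1 if any segment listing the gene has
#'     `copy_number <= 0.5 * ploidy`.}
#'   \item{`cnv_any`}{elementwise OR of `cnv_amp` and `cnv_del`.}
#' }
#' Ploidy is per patient (the `ploidy` column of the cohort when present,
#' otherwise `default_ploidy`). SNV records with an empty gene symbol are
#' ignored.
#'
#' @param cohort Tibble from [read_sample_sheet()].
#' @param snvs Tibble of SNV records for the whole cohort (rows may be empty
#'   for some patients), as from [read_snv_calls()].
#' @param cnvs Tibble of CNV segments for the whole cohort, as from
#'   [read_cnv_segments()].
#' @param gene_panel Non-empty character vector of gene symbols.
#' @param default_ploidy Average ploidy used for patients without a `ploidy`
#'   column entry. Default 2.
#' @param mutation_effects Effect classes that make a gene "mutated".
#' @return A tibble with a `patient_id` column followed by one 0/1 column per
#'   marker (`"GENE|class"`), patients in cohort order.
#' @export
build_marker_matrix <- function(cohort, snvs, cnvs, gene_panel,
                                default_ploidy = 2,
                                mutation_effects = c("non_synonymous",
                                                     "other")) {
  if (length(gene_panel) == 0) abort("gene_panel must be non-empty")
  ploidy <- if ("ploidy" %in% names(cohort)) cohort$ploidy else
    rep(default_ploidy, nrow(cohort))
  if (any(ploidy <= 0)) abort("ploidy must be positive")
  names(ploidy) <- cohort$patient_id

  empty_snvs <- tibble(gene = character(), effect = character(),
                       patient_id = character())
  snvs <- if (is.null(snvs) || nrow(snvs) == 0) empty_snvs else snvs

  mut_tbl <- snvs |>
    filter(.data$gene %in% gene_panel,
           .data$effect %in% mutation_effects,
           nzchar(.data$gene)) |>
    dplyr::distinct(.data$patient_id, .data$gene)

  cnv_rows <- if (is.null(cnvs) || nrow(cnvs) == 0) {
    tibble(patient_id = character(), gene = character(),
           copy_number = double())
  } else {
    cnvs |>
      select("patient_id", "copy_number", "genes") |>
      tidyr::unnest_longer("genes", values_to = "gene") |>
      filter(.data$gene %in% gene_panel)
  }

  rows <- purrr::map(cohort$patient_id, function(pid) {
    pl <- ploidy[[pid]]
    muts <- mut_tbl$gene[mut_tbl$patient_id == pid]
    pseg <- cnv_rows[cnv_rows$patient_id == pid, ]
    vals <- purrr::map(gene_panel, function(g) {
      cn <- pseg$copy_number[pseg$gene == g]
      amp <- as.integer(any(cn >= 2 * pl))
      del <- as.integer(any(cn <= 0.5 * pl))
      c(as.integer(g %in% muts), amp, del, as.integer(amp | del))
    })
    stats::setNames(unlist(vals),
                    unlist(purrr::map(gene_panel, marker_name,
                                      event_class = MARKER_CLASSES)))
  })
  mat <- dplyr::bind_rows(rows)
  dplyr::bind_cols(tibble(patient_id = cohort$patient_id), mat)
}

#' Write and re-read a marker matrix as TSV
#'
#' The on-disk form is the tibble itself: a `patient_id` column followed by
#' one 0/1 column per `"GENE|class"` marker. Round-trips exactly.
#'
#' @param matrix A marker-matrix tibble.
#' @param path Output path.
#' @return `write_marker_matrix()` returns `path` invisibly;
#'   `read_marker_matrix()` returns the tibble.
#' @export
write_marker_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_marker_matrix
#' @export
read_marker_matrix <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  vals <- as.matrix(m[-1])
  if (length(vals) > 0 && !all(vals %in% c(0L, 1L))) {
    abort("marker matrix entries must be 0 or 1")
  }
  m
}
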