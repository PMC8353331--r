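#' Assemble and validate a pipeline run configuration
#'
#' Central configuration object consumed by the `cmd_*` report functions.
#' Referenced paths must exist at validation time; parameters are checked
#' against their documented ranges. Precedence is caller-supplied values over
#' these defaults.
#'
#' @param sample_sheet Path to the cohort sample-sheet TSV.
#' @param variant_dir Directory holding `<patient_id>.vcf` files.
#' @param cnv_dir Directory holding `<patient_id>.seg.tsv` files.
#' @param out_dir Output directory (created if needed).
#' @param reference_fasta Optional FASTA used for trinucleotide contexts.
#' @param signature_tsv Optional signature reference TSV; when `NULL` the
#'   packaged synthetic reference is used.
#' @param exon_bed Optional BED3 of exon intervals (0-based half-open) for
#'   CNV burden.
#' @param msi_dir Optional directory holding `<patient_id>.sites.tsv`
#'   evidence files.
#' @param alpha Screening significance threshold, in (0, 1].
#' @param max_combo_size Largest marker-panel size searched (>= 1).
#' @param target_size_mb Captured target size for TMB (> 0).
#' @param default_ploidy Average ploidy fallback (> 0).
#' @param msi_min_depth,msi_shift_threshold MSI classifier settings.
#' @param cnv_class_overrides Named character vector mapping gene symbols to
#'   the CNV event class used for that gene's marker (default: `cnv_any` for
#'   every gene except `GAGE2C`, whose reported event is a deletion).
#' @param seed Integer seed recorded in the run manifest and used for any
#'   randomised step.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sample_sheet, variant_dir, cnv_dir, out_dir,
                       reference_fasta = NULL, signature_tsv = NULL,
                       exon_bed = NULL, msi_dir = NULL,
                       alpha = 0.05, max_combo_size = 3,
                       target_size_mb = 50, default_ploidy = 2,
                       msi_min_depth = 20, msi_shift_threshold = 0.3,
                       cnv_class_overrides = c(GAGE2C = "cnv_del"),
                       seed = 1) {
  for (p in c(sample_sheet, variant_dir, cnv_dir, reference_fasta,
              signature_tsv, exon_bed, msi_dir)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("configured path does not exist: ", p))
    }
  }
  stopifnot(alpha > 0, alpha <= 1, max_combo_size >= 1, target_size_mb > 0,
            default_ploidy > 0, msi_min_depth >= 0,
            msi_shift_threshold >= 0, msi_shift_threshold <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(
    sample_sheet = sample_sheet, variant_dir = variant_dir,
    cnv_dir = cnv_dir, out_dir = out_dir,
    reference_fasta = reference_fasta, signature_tsv = signature_tsv,
    exon_bed = exon_bed, msi_dir = msi_dir,
    alpha = alpha, max_combo_size = max_combo_size,
    target_size_mb = target_size_mb, default_ploidy = default_ploidy,
    msi_min_depth = msi_min_depth,
    msi_shift_threshold = msi_shift_threshold,
    cnv_class_overrides = cnv_class_overrides,
    seed = seed
  ), class = "run_config")
}

.load_calls <- function(config) {
  cohort <- read_sample_sheet(config$sample_sheet)
  vcf_paths <- file.path(config$variant_dir,
                         paste0(cohort$patient_id, ".vcf"))
  seg_paths <- file.path(config$cnv_dir,
                         paste0(cohort$patient_id, ".seg.tsv"))
  missing <- cohort$patient_id[!file.exists(vcf_paths) |
                                 !file.exists(seg_paths)]
  if (length(missing) > 0) {
    abort(paste0("missing per-patient call file(s) for: ",
                 paste(missing, collapse = ", ")))
  }
  snvs <- purrr::map2_dfr(vcf_paths, cohort$patient_id, read_snv_calls)
  cnvs <- purrr::map2_dfr(seg_paths, cohort$patient_id, read_cnv_segments)
  list(cohort = cohort, snvs = snvs, cnvs = cnvs)
}

.write_manifest <- function(config, outputs) {
  manifest <- list(
    package = "combimark",
    version = as.character(utils::packageVersion("combimark")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    outputs = outputs
  )
  path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-sample genomic metrics report
#'
#' Computes TMB for every patient, plus MSI score (when `msi_dir` is
#' configured) and exome amplification/deletion fractions (when `exon_bed`
#' is configured), and compares each available metric between the resistant
#' and sensitive groups with the two-sided Mann-Whitney U test. Writes
#' `metrics.tsv`, `metrics_group_tests.tsv` and a run manifest to `out_dir`.
#'
#' @param config A [run_config()].
#' @return A list with tibbles `metrics` (one row per patient) and
#'   `group_tests` (one row per metric).
#' @export
cmd_metrics <- function(config) {
  calls <- .load_calls(config)
  cohort <- calls$cohort
  exons <- if (!is.null(config$exon_bed)) {
    readr::read_tsv(config$exon_bed,
                    col_names = c("chrom", "start", "end"),
                    col_types = "cdd", comment = "#", progress = FALSE)
  }
  ploidy <- if ("ploidy" %in% names(cohort)) cohort$ploidy else
    rep(config$default_ploidy, nrow(cohort))
  metrics <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    psnv <- filter(calls$snvs, .data$patient_id == pid)
    pseg <- filter(calls$cnvs, .data$patient_id == pid)
    burden <- if (!is.null(exons)) cnv_burden(exons, pseg, ploidy[i]) else
      list(amp_fraction = NA_real_, del_fraction = NA_real_)
    msi <- NA_real_
    if (!is.null(config$msi_dir)) {
      ev <- read_msi_evidence(file.path(config$msi_dir,
                                        paste0(pid, ".sites.tsv")))
      msi <- msi_score(classify_site_stability(
        ev, min_depth = config$msi_min_depth,
        shift_threshold = config$msi_shift_threshold
      ))
    }
    tibble(patient_id = pid, group = cohort$group[i],
           tmb = compute_tmb(psnv, config$target_size_mb),
           msi_score = msi,
           amp_fraction = burden$amp_fraction,
           del_fraction = burden$del_fraction)
  })
  group_tests <- purrr::map_dfr(
    c("tmb", "msi_score", "amp_fraction", "del_fraction"),
    function(metric) {
      x <- metrics[[metric]][metrics$group == "resistant"]
      y <- metrics[[metric]][metrics$group == "sensitive"]
      if (anyNA(c(x, y))) {
        return(tibble(metric = metric, median_resistant = NA_real_,
                      median_sensitive = NA_real_, p_value = NA_real_))
      }
      ht <- mann_whitney_u(x, y)
      tibble(metric = metric,
             median_resistant = stats::median(x),
             median_sensitive = stats::median(y),
             p_value = ht$p.value)
    }
  )
  readr::write_tsv(metrics, file.path(config$out_dir, "metrics.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    mutate(group_tests, p_formatted = format_pvalue(.data$p_value)),
    file.path(config$out_dir, "metrics_group_tests.tsv"), progress = FALSE
  )
  .write_manifest(config, c("metrics.tsv", "metrics_group_tests.tsv"))
  list(metrics = metrics, group_tests = group_tests)
}

#' Mutational-signature report
#'
#' Builds the 96-channel spectrum of every patient against the configured
#' reference FASTA, fits signature exposures by NNLS, and compares
#' per-signature exposures between groups. Writes `exposures.tsv` and
#' `signature_group_tests.tsv`.
#'
#' @param config A [run_config()] with `reference_fasta` set.
#' @return A list with `exposures` (patients x signatures tibble),
#'   `fits` (list of `signature_fit`) and `group_tests`.
#' @export
cmd_signatures <- function(config) {
  if (is.null(config$reference_fasta)) {
    abort("cmd_signatures requires reference_fasta in the config")
  }
  calls <- .load_calls(config)
  cohort <- calls$cohort
  dna <- Biostrings::readDNAStringSet(config$reference_fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  reference <- if (is.null(config$signature_tsv)) {
    synthetic_signature_reference()
  } else {
    read_signature_reference(config$signature_tsv)
  }
  fits <- purrr::map(cohort$patient_id, function(pid) {
    psnv <- filter(calls$snvs, .data$patient_id == pid)
    fit_exposures(build_spectrum(psnv, dna), reference, patient_id = pid)
  })
  exposures <- purrr::map_dfr(fits, function(f) {
    wide <- tidyr::pivot_wider(f$exposures, names_from = "signature",
                               values_from = "exposure")
    dplyr::bind_cols(tibble(patient_id = f$patient_id, n_total = f$n_total,
                            residual = f$residual,
                            low_confidence = f$low_confidence), wide)
  })
  grp <- cohort$group
  group_tests <- compare_exposures(fits[grp == "resistant"],
                                   fits[grp == "sensitive"]) |>
    rename(median_resistant = "median_a", median_sensitive = "median_b")
  readr::write_tsv(exposures, file.path(config$out_dir, "exposures.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    mutate(group_tests, p_formatted = format_pvalue(.data$p_value)),
    file.path(config$out_dir, "signature_group_tests.tsv"), progress = FALSE
  )
  .write_manifest(config, c("exposures.tsv", "signature_group_tests.tsv"))
  list(exposures = exposures, fits = fits, group_tests = group_tests)
}

# one marker per gene and event kind: mutation always, plus the gene's CNV
# class (cnv_any unless overridden)
.report_matrix <- function(config, calls) {
  genes <- sort(unique(c(
    calls$snvs$gene[nzchar(calls$snvs$gene)],
    unlist(calls$cnvs$genes)
  )))
  if (length(genes) == 0) abort("no annotated genes found in the call files")
  full <- build_marker_matrix(calls$cohort, calls$snvs, calls$cnvs,
                              gene_panel = genes,
                              default_ploidy = config$default_ploidy)
  cnv_class <- function(g) {
    if (g %in% names(config$cnv_class_overrides)) {
      config$cnv_class_overrides[[g]]
    } else {
      "cnv_any"
    }
  }
  keep <- unlist(purrr::map(genes, function(g) {
    c(marker_name(g, "mutation"), marker_name(g, cnv_class(g)))
  }))
  full[, c("patient_id", keep)]
}

#' Differential-marker screening report
#'
#' Builds the gene-level marker matrix from the configured call files (one
#' mutation marker per gene plus one CNV marker, `cnv_any` unless
#' overridden), screens it with [screen_markers()] at the configured alpha
#' and writes `screen.tsv` with formatted p-values.
#'
#' @param config A [run_config()].
#' @return The screening tibble (see [screen_markers()]).
#' @export
cmd_screen <- function(config) {
  calls <- .load_calls(config)
  matrix <- .report_matrix(config, calls)
  res <- screen_markers(matrix, calls$cohort, alpha = config$alpha)
  out <- mutate(res, p_formatted = format_pvalue(.data$p_value))
  readr::write_tsv(out, file.path(config$out_dir, "screen.tsv"),
                   progress = FALSE)
  .write_manifest(config, "screen.tsv")
  res
}

#' Combination-search report
#'
#' Screens markers, then exhaustively searches OR-rule combinations up to
#' `max_combo_size` separately for resistance (candidates higher in the
#' resistant group, positive class resistant) and susceptibility (the
#' mirror). Writes `combos_resistant.tsv` and `combos_sensitive.tsv` with
#' percentages to one decimal and p-values to three.
#'
#' @param config A [run_config()].
#' @return A list of two `combo_search` tibbles, `resistant` and
#'   `sensitive`.
#' @export
cmd_combos <- function(config) {
  calls <- .load_calls(config)
  matrix <- .report_matrix(config, calls)
  screened <- screen_markers(matrix, calls$cohort, alpha = config$alpha)
  out <- purrr::map(c(resistant = "resistant", sensitive = "sensitive"),
                    function(cls) {
    cand <- screened$marker[screened$direction == paste0("higher_in_", cls)]
    if (length(cand) == 0) return(NULL)
    res <- search_combinations(matrix, cand, calls$cohort,
                               positive_class = cls,
                               max_size = min(config$max_combo_size,
                                              length(cand)))
    formatted <- mutate(res,
      sensitivity_pct = format_percent(.data$sensitivity),
      specificity_pct = format_percent(.data$specificity),
      p_formatted = format_pvalue(.data$p_value)
    )
    readr::write_tsv(formatted,
                     file.path(config$out_dir,
                               paste0("combos_", cls, ".tsv")),
                     progress = FALSE)
    res
  })
  .write_manifest(config, c("combos_resistant.tsv", "combos_sensitive.tsv"))
  out
}
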