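# end-to-end reports over the packaged fixture written to disk
fixture_run <- local({
  fx <- build_fixture_cohort()
  dir <- tempfile("report")
  files <- write_cohort_files(fx$cohort, fx$matrix, dir)
  list(fx = fx, dir = dir, files = files)
})

fixture_config <- function(...) {
  run_config(
    sample_sheet = fixture_run$files$sample_sheet,
    variant_dir = fixture_run$files$variant_dir,
    cnv_dir = fixture_run$files$cnv_dir,
    out_dir = file.path(fixture_run$dir, "out"),
    ...
  )
}

test_that("config validation rejects missing paths and out-of-range parameters", {
  expect_error(
    run_config(tempfile("nope"), fixture_run$files$variant_dir,
               fixture_run$files$cnv_dir, tempfile()),
    "does not exist"
  )
  expect_error(fixture_config(alpha = 0), "alpha")
  expect_error(fixture_config(target_size_mb = -1), "target_size_mb")
})

test_that("screening report recovers the 17 differential markers from files", {
  cfg <- fixture_config()
  res <- cmd_screen(cfg)
  expect_equal(nrow(res), 17)
  want <- fixture_constraints()$single
  expect_setequal(res$marker, want$marker)
  # direction mirrors the positive class of each marker
  got_dir <- res$direction[match(want$marker, res$marker)]
  expect_equal(got_dir,
               paste0("higher_in_", want$positive_class))

  # written TSV re-reads to the in-memory result
  disk <- readr::read_tsv(
    file.path(cfg$out_dir, "screen.tsv"),
    col_types = readr::cols(p_formatted = readr::col_character(),
                            .default = readr::col_guess()),
    progress = FALSE
  )
  expect_equal(disk$marker, res$marker)
  expect_equal(disk$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(disk$p_formatted, format_pvalue(res$p_value))
  expect_true(file.exists(file.path(cfg$out_dir, "run_manifest.json")))

  # a vanishing alpha empties the table
  expect_equal(nrow(cmd_screen(fixture_config(alpha = 1e-6))), 0)
})

test_that("combination report finds the perfect resistance panel and the top pair", {
  cfg <- fixture_config()
  out <- cmd_combos(cfg)
  res <- out$resistant
  expect_equal(res$sensitivity[1], 1)
  expect_equal(res$specificity[1], 1)
  expect_equal(res$size[1], 3)
  perfect <- res$markers[res$sensitivity == 1 & res$specificity == 1]
  expect_true("GAGE2C|cnv_del+HNRNPCL1|mutation+SP8|mutation" %in% perfect)

  sens2 <- cmd_combos(fixture_config(max_combo_size = 2))$sensitive
  expect_equal(sens2$size[1], 2)
  dp <- sens2[sens2$markers == "DPCR1|cnv_any+TMSB4Y|cnv_any", ]
  expect_equal(unlist(dp[, c("tp", "fn", "fp", "tn")]),
               c(tp = 8, fn = 1, fp = 0, tn = 7))
  expect_equal(format_percent(dp$sensitivity), "88.9%")
  expect_equal(format_percent(dp$specificity), "100.0%")

  # size-1 search agrees with the screen-derived single-marker table
  singles <- cmd_combos(fixture_config(max_combo_size = 1))$resistant
  screened <- cmd_screen(cfg)
  for (i in seq_len(nrow(singles))) {
    row <- screened[screened$marker == singles$markers[i], ]
    expect_equal(singles$tp[i], row$count_resistant)
    expect_equal(singles$p_value[i], row$p_value)
  }
})

test_that("metrics report computes per-patient TMB and group comparisons", {
  # exon intervals and per-patient MSI evidence alongside the fixture files
  bed <- file.path(fixture_run$dir, "exons.bed")
  readr::write_tsv(
    tibble::tibble(chrom = "chr1",
                   start = seq(0, 19e6, 1e6) + 10,
                   end = seq(0, 19e6, 1e6) + 110),
    bed, col_names = FALSE, progress = FALSE
  )
  msi_dir <- file.path(fixture_run$dir, "msi")
  dir.create(msi_dir, showWarnings = FALSE)
  cohort <- fixture_run$fx$cohort
  for (i in seq_len(nrow(cohort))) {
    ev <- generate_msi_evidence(40, 0.1, depth = 50, seed = 1000 + i)
    write_msi_evidence(ev, file.path(msi_dir,
                                     paste0(cohort$patient_id[i],
                                            ".sites.tsv")))
  }
  cfg <- fixture_config(exon_bed = bed, msi_dir = msi_dir)
  out <- cmd_metrics(cfg)
  expect_equal(nrow(out$metrics), 16)
  expect_equal(nrow(out$group_tests), 4)
  expect_false(anyNA(out$group_tests$p_value))

  # TMB recount by hand for three patients: mutations / Mb from the VCFs
  for (pid in c("R01", "S01", "S09")) {
    snvs <- read_snv_calls(file.path(fixture_run$files$variant_dir,
                                     paste0(pid, ".vcf")), pid)
    by_hand <- sum(snvs$effect == "non_synonymous") / 50
    expect_equal(out$metrics$tmb[out$metrics$patient_id == pid], by_hand)
  }
})

test_that("identical metric distributions across groups give p = 1", {
  # every patient carries the same single mutation, so all metrics coincide
  specs <- tibble::tibble(gene = "SP8", event_class = "mutation",
                          count_resistant = 3L, count_sensitive = 3L)
  dir <- tempfile("flat")
  out <- generate_cohort(3, 3, specs, seed = 5, dir = dir)
  # make everyone positive so TMB is constant
  m <- out$matrix
  m$`SP8|mutation` <- 1L
  write_cohort_files(out$cohort, m, dir)
  cfg <- run_config(file.path(dir, "sample_sheet.tsv"),
                    file.path(dir, "variants"), file.path(dir, "cnv"),
                    out_dir = file.path(dir, "out"))
  res <- cmd_metrics(cfg)
  expect_equal(res$group_tests$p_value[res$group_tests$metric == "tmb"], 1)
})

test_that("signature report fits every patient and compares groups", {
  set.seed(161)
  fa <- file.path(fixture_run$dir, "chr1.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
                 collapse = "")
  )), fa)
  cfg <- fixture_config(reference_fasta = fa)
  out <- cmd_signatures(cfg)
  expect_equal(nrow(out$exposures), 16)
  expect_equal(nrow(out$group_tests), 30)
  expect_true(all(out$group_tests$p_value >= 0 & out$group_tests$p_value <= 1))
  # the low-confidence flag tracks the per-patient catalog size
  expect_equal(out$exposures$low_confidence, out$exposures$n_total < 20)
  expect_true(file.exists(file.path(cfg$out_dir, "exposures.tsv")))
})

test_that("missing per-patient files are reported by patient id", {
  cfg <- fixture_config()
  broken <- cfg
  broken$variant_dir <- tempfile("empty")
  dir.create(broken$variant_dir)
  expect_error(cmd_screen(broken), "S01")
})
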