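test_that("sample sheet reading derives groups and preserves order", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    patient_id = sprintf("P%02d", 1:16),
    response = c(rep("CR", 3), rep("PR", 6), "SD", rep("PD", 6))
  ), path)
  sheet <- read_sample_sheet(path)
  expect_equal(nrow(sheet), 16)
  expect_equal(sum(sheet$group == "sensitive"), 9)
  expect_equal(sum(sheet$group == "resistant"), 7)
  expect_equal(sheet$patient_id, sprintf("P%02d", 1:16))
})

test_that("sample sheet edge cases: empty body, bad label, duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines("patient_id\tresponse", path)
  expect_equal(nrow(read_sample_sheet(path)), 0)

  writeLines(c("patient_id\tresponse", "P1\tPR", "P2\tXX"), path)
  expect_error(read_sample_sheet(path), "row 2")

  writeLines(c("patient_id\tresponse", "P1\tPR", "P1\tPD"), path)
  expect_error(read_sample_sheet(path), "duplicate")
})

test_that("VCF reading annotates genes, splits multi-allelic sites, handles empties", {
  p <- write_tiny_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tGENE=SP8;EFFECT=non_synonymous",
    "chr1\t200\t.\tC\tT\t.\tPASS\tGENE=SP8;EFFECT=synonymous"
  ))
  recs <- read_snv_calls(p, "P1")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$gene, c("SP8", "SP8"))
  expect_equal(recs$effect, c("non_synonymous", "synonymous"))
  expect_equal(recs$patient_id, rep("P1", 2))

  p2 <- write_tiny_vcf("chr1\t150\t.\tC\tA,T\t.\tPASS\tGENE=FRG1;EFFECT=missense")
  recs2 <- read_snv_calls(p2, "P1")
  expect_equal(nrow(recs2), 2)
  expect_equal(recs2$alt, c("A", "T"))
  expect_equal(recs2$effect, rep("non_synonymous", 2))

  p3 <- write_tiny_vcf(character())
  expect_equal(nrow(read_snv_calls(p3, "P1")), 0)

  # record without the gene key is kept with gene = ""
  p4 <- write_tiny_vcf("chr1\t300\t.\tG\tA\t.\tPASS\tEFFECT=missense")
  expect_equal(read_snv_calls(p4, "P1")$gene, "")
})

test_that("VCF errors: malformed line carries its line number, missing file fails", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA"), p)
  expect_error(read_snv_calls(p, "P1"), "line 3")
  expect_error(read_snv_calls(tempfile(), "P1"), "not found")
})

test_that("CNV segment reading validates, sorts and tolerates empty gene lists", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tstart\tend\tcopy_number\tgenes",
    "chr2\t100\t500\t0.8\tGAGE2C;GAGE2E",
    "chr1\t900\t1200\t5\tCTAGE4",
    "chr1\t100\t300\t2\t"
  ), p)
  seg <- read_cnv_segments(p, "P1")
  expect_equal(seg$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(seg$start, c(100, 900, 100))
  expect_equal(seg$genes[[3]], c("GAGE2C", "GAGE2E"))
  expect_equal(seg$genes[[1]], character())

  writeLines(c("chrom\tstart\tend\tcopy_number\tgenes",
               "chr1\t100\t100\t2\tX"), p)
  expect_error(read_cnv_segments(p, "P1"), "start >= end")

  writeLines(c("chrom\tstart\tend\tcopy_number\tgenes",
               "chr1\t100\t200\t-1\tX"), p)
  expect_error(read_cnv_segments(p, "P1"), "negative copy_number")
})

test_that("marker matrix applies the mutation and CNV positivity rules", {
  cohort <- tiny_cohort()
  snvs <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G",
    gene = c("SP8", "TMBIM4"), effect = c("non_synonymous", "synonymous"),
    patient_id = c("P1", "P2")
  )
  cnvs <- tibble::tibble(
    chrom = "chr1", start = c(0, 0), end = c(100, 100),
    copy_number = c(0.8, 4),
    genes = list("GAGE2C", "CTAGE4"),
    patient_id = c("P2", "P3")
  )
  m <- build_marker_matrix(cohort, snvs, cnvs,
                           gene_panel = c("SP8", "TMBIM4", "GAGE2C", "CTAGE4"))
  expect_equal(m$`SP8|mutation`, c(1L, 0L, 0L))
  # synonymous-only gene stays negative
  expect_equal(m$`TMBIM4|mutation`, c(0L, 0L, 0L))
  # copy number 0.8 <= 0.5 x ploidy 2 -> deletion
  expect_equal(m$`GAGE2C|cnv_del`, c(0L, 1L, 0L))
  expect_equal(m$`GAGE2C|cnv_amp`, c(0L, 0L, 0L))
  # copy number 4 >= 2 x ploidy 2 -> amplification
  expect_equal(m$`CTAGE4|cnv_amp`, c(0L, 0L, 1L))
  expect_error(build_marker_matrix(cohort, snvs, cnvs, gene_panel = character()),
               "non-empty")
})

test_that("cnv_any is the elementwise OR of cnv_amp and cnv_del", {
  set.seed(81)
  cohort <- tiny_cohort()
  cnvs <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, 900, 100), end = seq(100, 1000, 100),
    copy_number = sample(c(0.5, 1, 2, 4, 6), 10, replace = TRUE),
    genes = as.list(sample(c("A1", "B2", "C3"), 10, replace = TRUE)),
    patient_id = sample(cohort$patient_id, 10, replace = TRUE)
  )
  m <- build_marker_matrix(cohort, NULL, cnvs, gene_panel = c("A1", "B2", "C3"))
  for (g in c("A1", "B2", "C3")) {
    expect_equal(
      m[[marker_name(g, "cnv_any")]],
      pmax(m[[marker_name(g, "cnv_amp")]], m[[marker_name(g, "cnv_del")]])
    )
  }
})

test_that("marker matrix building is invariant to patient order up to reordering", {
  fx <- build_fixture_cohort()
  files <- write_cohort_files(fx$cohort, fx$matrix, tempfile("perm"))
  cohort <- read_sample_sheet(files$sample_sheet)
  load_all_calls <- function(cohort) {
    snvs <- purrr::map_dfr(cohort$patient_id, function(pid) {
      read_snv_calls(file.path(files$variant_dir, paste0(pid, ".vcf")), pid)
    })
    cnvs <- purrr::map_dfr(cohort$patient_id, function(pid) {
      read_cnv_segments(file.path(files$cnv_dir, paste0(pid, ".seg.tsv")), pid)
    })
    list(snvs = snvs, cnvs = cnvs)
  }
  genes <- unique(split_marker_name(setdiff(names(fx$matrix), "patient_id"))$gene)
  calls <- load_all_calls(cohort)
  m1 <- build_marker_matrix(cohort, calls$snvs, calls$cnvs, gene_panel = genes)
  set.seed(91)
  shuffled <- cohort[sample(nrow(cohort)), ]
  m2 <- build_marker_matrix(shuffled, calls$snvs, calls$cnvs, gene_panel = genes)
  expect_equal(dplyr::arrange(m1, patient_id), dplyr::arrange(m2, patient_id))
})

test_that("marker matrix TSV round-trips exactly", {
  fx <- build_fixture_cohort()
  path <- tempfile(fileext = ".tsv")
  write_marker_matrix(fx$matrix, path)
  expect_equal(read_marker_matrix(path), fx$matrix)
})
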