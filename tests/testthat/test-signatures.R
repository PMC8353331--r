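test_that("channel set is the canonical 96 in substitution-major order", {
  ch <- spectrum_channels()
  expect_equal(nrow(ch), 96)
  expect_equal(anyDuplicated(ch$channel), 0)
  expect_equal(ch$channel[1:3], c("A[C>A]A", "A[C>A]C", "A[C>A]G"))
  expect_equal(ch$channel[96], "T[T>G]T")
})

test_that("purine-reference substitutions are reverse-complemented into pyrimidine channels", {
  ref <- c(chr1 = "TGC")
  snv <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "G", alt = "A")
  sp <- build_spectrum(snv, ref)
  expect_equal(attr(sp, "n_total"), 1L)
  expect_equal(sp$count[sp$channel == "G[C>T]A"], 1L)
})

test_that("empty input, indels and contig-edge records are handled", {
  ref <- c(chr1 = "ACGTACGT")
  empty <- build_spectrum(tibble::tibble(chrom = character(), pos = integer(),
                                         ref = character(), alt = character()),
                          ref)
  expect_equal(attr(empty, "n_total"), 0L)
  expect_true(all(empty$count == 0))

  mixed <- tibble::tibble(
    chrom = "chr1",
    pos = c(1L, 3L, 4L),
    ref = c("A", "GT", "T"),
    alt = c("C", "G", "A")
  )
  sp <- build_spectrum(mixed, ref)
  expect_equal(attr(sp, "n_skipped"), 1L) # edge position
  expect_equal(attr(sp, "n_indels"), 1L)
  expect_equal(attr(sp, "n_total"), 1L)
})

test_that("spectrum is invariant under reverse-complementing the reference strand", {
  ref <- synthetic_signature_reference()
  expo <- rep(0, 30)
  expo[c(2, 5)] <- c(0.5, 0.5)
  cat1 <- generate_snv_catalog(expo, 400, ref, reference_length = 3e4, seed = 5)
  L <- nchar(cat1$sequence[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(cat1$sequence[[1]], "")[[1]]
  rc_seq <- paste(rev(unname(comp[chars])), collapse = "")
  flipped <- dplyr::mutate(cat1$snvs,
    pos = L + 1L - pos,
    ref = unname(comp[ref]),
    alt = unname(comp[alt])
  )
  sp1 <- build_spectrum(cat1$snvs, cat1$sequence)
  sp2 <- build_spectrum(flipped, c(synth1 = rc_seq))
  expect_equal(sp1$count, sp2$count)
})

test_that("six-class collapse matches a direct per-record tally and sums to 1", {
  ref <- synthetic_signature_reference()
  expo <- rep(1 / 30, 30)
  cat1 <- generate_snv_catalog(expo, 500, ref, reference_length = 3e4, seed = 9)
  sp <- build_spectrum(cat1$snvs, cat1$sequence)
  six <- collapse_to_six(sp)
  expect_equal(sum(six), 1)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  direct <- table(with(cat1$snvs, ifelse(
    ref %in% c("C", "T"), paste0(ref, ">", alt),
    paste0(comp[ref], ">", comp[alt])
  )))
  expect_equal(unname(six[names(direct)] * 500), unname(as.numeric(direct)))

  empty <- build_spectrum(tibble::tibble(chrom = character(), pos = integer(),
                                         ref = character(), alt = character()),
                          c(chr1 = "ACGT"))
  expect_error(collapse_to_six(empty), "empty spectrum")
})

test_that("exposure fitting recovers pure and mixed signatures", {
  ref <- synthetic_signature_reference()
  # pure signature 3, counts proportional to the profile
  sig3_counts <- round(1e4 * unname(ref$matrix[3, ]))
  sp <- dplyr::mutate(spectrum_channels(), count = sig3_counts)
  attr(sp, "n_total") <- sum(sp$count)
  class(sp) <- c("spectrum96", class(sp))
  fit <- fit_exposures(sp, ref)
  expect_gte(fit$exposures$exposure[3], 0.99)
  expect_equal(sum(fit$exposures$exposure), 1, tolerance = 1e-6)
  expect_false(fit$low_confidence)

  # 0.6 / 0.4 mixture sampled at n = 50000
  set.seed(131)
  truth <- rep(0, 30)
  truth[c(1, 3)] <- c(0.6, 0.4)
  spm <- random_spectrum(as.numeric(truth %*% ref$matrix), 50000)
  fit2 <- fit_exposures(spm, ref)
  expect_lt(abs(fit2$exposures$exposure[1] - 0.6), 0.05)
  expect_lt(abs(fit2$exposures$exposure[3] - 0.4), 0.05)

  # tiny catalogs are flagged
  sp_small <- random_spectrum(as.numeric(truth %*% ref$matrix), 10)
  expect_true(fit_exposures(sp_small, ref)$low_confidence)
  sp0 <- random_spectrum(rep(1 / 96, 96), 0)
  expect_error(fit_exposures(sp0, ref), "empty spectrum")
})

test_that("tidy and glance summarise a signature fit", {
  ref <- synthetic_signature_reference()
  sp <- random_spectrum(ref$matrix[2, ], 1000)
  fit <- fit_exposures(sp, ref, patient_id = "P1")
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 30)
  expect_equal(unique(td$patient_id), "P1")
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_total, 1000)
})

test_that("group exposure comparison flags a shifted signature and nothing else", {
  ref <- synthetic_signature_reference()
  mkfit <- function(w, n = 5000, seed = 1) {
    set.seed(seed)
    fit_exposures(random_spectrum(as.numeric(w %*% ref$matrix), n), ref)
  }
  base <- rep(0, 30)
  base[1] <- 1
  shifted <- rep(0, 30)
  shifted[c(1, 12)] <- c(0.3, 0.7)
  ga <- purrr::map(1:9, ~ mkfit(base, seed = .x))
  gb <- purrr::map(1:7, ~ mkfit(shifted, seed = 100 + .x))
  cmp <- compare_exposures(ga, gb)
  expect_lt(cmp$p_value[cmp$signature == "Signature.12"], 0.05)

  # identical groups give p = 1 everywhere
  same <- compare_exposures(ga, ga)
  expect_true(all(same$p_value == 1))

  # singleton groups cannot be significant under the exact test
  one <- compare_exposures(ga[1], gb[1])
  expect_true(all(one$p_value == 1))
  expect_error(compare_exposures(list(), ga), "non-empty")
})

test_that("signature reference TSVs round-trip in both orientations", {
  ref <- synthetic_signature_reference()
  p <- tempfile(fileext = ".tsv")
  write_signature_reference(ref, p)
  back <- read_signature_reference(p)
  expect_equal(back$names, ref$names)
  expect_equal(unname(back$matrix), unname(ref$matrix), tolerance = 1e-12)

  # transposed layout: channels in rows
  tab <- tibble::as_tibble(t(ref$matrix), .name_repair = "minimal")
  names(tab) <- ref$names
  tab <- dplyr::bind_cols(tibble::tibble(channel = colnames(ref$matrix)), tab)
  readr::write_tsv(tab, p)
  back2 <- read_signature_reference(p)
  expect_equal(unname(back2$matrix), unname(ref$matrix), tolerance = 1e-12)
})
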