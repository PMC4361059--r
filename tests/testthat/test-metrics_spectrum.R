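table2_pairs <- list(
  lesion = c(56, 93, 84, 35, 45, 74, 130, 74, 33, 155, 33, 25, 58),
  lesion_idx = c(1.87, 3.10, 2.80, 1.17, 1.50, 2.47, 4.33, 2.47, 1.10,
                 5.17, 1.10, 0.83, 1.93),
  inverse = c(2, 3, 4, 2, 6, 4, 4, 9, 7, 14, 5, 8, 9),
  inverse_idx = c(0.07, 0.10, 0.13, 0.07, 0.20, 0.13, 0.13, 0.30, 0.23,
                  0.47, 0.17, 0.27, 0.30)
)

test_that("mutational index reproduces all published count/index pairs at 30 Mb", {
  expect_equal(mutational_index(table2_pairs$lesion, 30),
               table2_pairs$lesion_idx)
  expect_equal(mutational_index(table2_pairs$inverse, 30),
               table2_pairs$inverse_idx)
  expect_equal(mutational_index(0, 30), 0)
  expect_error(mutational_index(5, 0), "target_mb")
})

test_that("mutational index is linear before rounding and rounds half-up", {
  for (n in c(3, 7, 56, 130)) {
    expect_equal(2 * (n / 30), (2 * n) / 30)
  }
  # 0.125 -> 0.13 under half-up (banker's rounding would give 0.12)
  expect_equal(mutational_index(5, 40), 0.13)
  expect_equal(mutational_index(1, 8), 0.13)
})

test_that("substitution classes collapse purine references onto pyrimidines", {
  expect_equal(substitution_class("G", "A"), "C>T")
  expect_equal(substitution_class("C", "T"), "C>T")
  expect_equal(substitution_class("A", "C"), "T>G")
  expect_equal(substitution_class("A", "G"), "T>C")
  expect_equal(substitution_class("G", "T"), "C>A")
  expect_error(substitution_class("C", "C"), "distinct")
  expect_error(substitution_class("N", "A"), "validation")
})

test_that("CpG dimer detection reads both context orientations", {
  expect_true(is_cpg_dimer("ACG", "C"))
  expect_true(is_cpg_dimer("CGT", "G"))
  expect_false(is_cpg_dimer("ACT", "C"))
  expect_false(is_cpg_dimer("GCA", "C"))
  expect_error(is_cpg_dimer("AAT", "C"), "validation")
})

test_that("spectrum summaries count classes and CpG transitions", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "C", alt = "T",
    tri_context = c("ACG", "TCG", "CCG", "ACT"),
    vaf_tumor = 0.3, vaf_normal = 0, fisher_p = NA_real_, tags = "",
    source = "primary", consequence = "missense", gene = "G1", passed = TRUE)
  s <- spectrum_summary(calls)
  expect_equal(s$cpg_fraction_of_cg_transitions, 0.75)
  expect_equal(s$classes$fraction[s$classes$class == "C>T"], 1.0)
  expect_equal(sum(s$classes$fraction), 1.0)
  # empty input flags itself
  s0 <- spectrum_summary(calls[0, ])
  expect_true(s0$empty)
  expect_true(is.na(s0$cpg_fraction_of_cg_transitions))
})

test_that("spectrum summary is invariant under reverse complement", {
  calls <- random_calls(60, seed = 14)
  calls$passed <- TRUE
  rc <- function(s) vapply(strsplit(chartr("ACGT", "TGCA", s), ""),
                           function(x) paste(rev(x), collapse = ""), "")
  flipped <- calls
  flipped$ref <- chartr("ACGT", "TGCA", calls$ref)
  flipped$alt <- chartr("ACGT", "TGCA", calls$alt)
  flipped$tri_context <- rc(calls$tri_context)
  a <- spectrum_summary(calls)
  b <- spectrum_summary(flipped)
  expect_equal(a$classes, b$classes)
  expect_equal(a$cpg_fraction_of_cg_transitions,
               b$cpg_fraction_of_cg_transitions)
})

test_that("spectra comparison reuses the two-sided Fisher construction", {
  mk <- function(n_cpg, n_non) tibble::tibble(
    chrom = "chr1", pos = seq_len(n_cpg + n_non), ref = "C", alt = "T",
    tri_context = c(rep("ACG", n_cpg), rep("ACT", n_non)),
    vaf_tumor = 0.3, vaf_normal = 0, fisher_p = NA_real_, tags = "",
    source = "primary", consequence = "missense", gene = NA_character_,
    passed = TRUE)
  expect_equal(compare_spectra(mk(5, 5), mk(5, 5)), 1.0)
  expect_equal(compare_spectra(mk(10, 0), mk(0, 10)), 2 / 184756,
               tolerance = 1e-12)
  expect_equal(compare_spectra(mk(1, 1), mk(1, 1)), 1.0)
  # a set without C>T/G>A calls is not comparable
  no_ct <- mk(1, 1)
  no_ct$alt <- "G"
  expect_true(is.na(compare_spectra(mk(5, 5), no_ct)))
})

test_that("inverse analysis is a zero noise floor on error-free data", {
  p <- sim_params(n_sites = 4000, lesions_per_patient = 1, error_rate = 0,
                  strand_bias_artifact_rate = 0, read_end_artifact_rate = 0)
  pt <- simulate_patient(p, 41, "P1")
  inv <- inverse_analysis(pt$pileups[[1]], pt$transcripts)
  expect_equal(inv$n_inverse, 0)
  expect_equal(inv$inverse_index, 0)
})

test_that("swapping tumor and normal twice is the identity", {
  p <- sim_params(n_sites = 1000, lesions_per_patient = 1)
  pt <- simulate_patient(p, 2, "P1")
  pu <- pt$pileups[[1]]
  expect_identical(swap_tumor_normal(swap_tumor_normal(pu)), pu)
  calls1 <- call_primary(pu)
  calls2 <- call_primary(swap_tumor_normal(swap_tumor_normal(pu)))
  expect_equal(calls1, calls2)
})

test_that("lesion metrics count unique passed amino-acid-changing calls", {
  calls <- random_calls(10, seed = 8)
  calls$passed <- TRUE
  calls$consequence <- c(rep("missense", 4), rep("truncating", 2),
                         rep("synonymous", 2), rep("non_coding", 2))
  m <- lesion_metrics(calls, target_mb = 30)
  expect_equal(m$n_aa_changing, 6)
  expect_equal(m$mut_index, mutational_index(6, 30))
  # duplicated keys collapse
  dup <- dplyr::bind_rows(calls, calls[1, ])
  expect_equal(lesion_metrics(dup, 30)$n_aa_changing, 6)
  # failed calls do not count
  calls$passed[1] <- FALSE
  expect_equal(lesion_metrics(calls, 30)$n_aa_changing, 5)
})
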