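# A hand-built plus-strand transcript on chr1: CDS occupies 0-based [10, 22)
# (positions 11..22), sequence ATG CTG CAA TAA.
tx_plus <- tibble::tibble(
  gene = "TP1", chrom = "chr1", strand = "+",
  cds_starts = list(10L), cds_ends = list(22L),
  cds_seq = "ATGCTGCAATAA"
)

test_that("codon changes translate to the documented labels", {
  # CTG -> TTG (L -> L): synonymous; codon 2 starts at position 14
  r <- classify_consequence("chr1", 14, "C", "T", tx_plus)
  expect_equal(r$consequence, "synonymous")
  expect_equal(r$gene, "TP1")
  # CAA -> TAA (Q -> stop): truncating
  expect_equal(classify_consequence("chr1", 17, "C", "T", tx_plus)$consequence,
               "truncating")
  # CTG -> CGG (L -> R): missense
  expect_equal(classify_consequence("chr1", 15, "T", "G", tx_plus)$consequence,
               "missense")
  # start codon loss ATG -> ATA: truncating
  expect_equal(classify_consequence("chr1", 13, "G", "A", tx_plus)$consequence,
               "truncating")
  # stop loss TAA -> CAA: truncating
  expect_equal(classify_consequence("chr1", 20, "T", "C", tx_plus)$consequence,
               "truncating")
  # outside every CDS: non-coding
  r <- classify_consequence("chr1", 5, "C", "T", tx_plus)
  expect_equal(r$consequence, "non_coding")
  expect_true(is.na(r$gene))
})

test_that("amino-acid-changing labels are missense and truncating only", {
  expect_true(is_amino_acid_changing("missense"))
  expect_true(is_amino_acid_changing("truncating"))
  expect_false(is_amino_acid_changing("synonymous"))
  expect_false(is_amino_acid_changing("non_coding"))
  expect_false(is_amino_acid_changing("unassigned"))
})

test_that("minus-strand classification equals the plus-strand equivalent", {
  # Embed the same CDS on the minus strand: genomic interval [10, 22) holds
  # the reverse complement, so transcript coordinate c maps to 22 - c.
  tx_minus <- tibble::tibble(
    gene = "TM1", chrom = "chr1", strand = "-",
    cds_starts = list(10L), cds_ends = list(22L),
    cds_seq = "ATGCTGCAATAA"
  )
  withr::with_seed(19, {
    for (i in 1:25) {
      cpos <- sample(0:11, 1)                       # transcript coordinate
      tx_ref <- substr("ATGCTGCAATAA", cpos + 1, cpos + 1)
      tx_alt <- sample(setdiff(c("A", "C", "G", "T"), tx_ref), 1)
      plus_pos <- 10L + cpos + 1L
      minus_pos <- 22L - cpos
      comp <- function(b) chartr("ACGT", "TGCA", b)
      lab_plus <- classify_consequence("chr1", plus_pos, tx_ref, tx_alt,
                                       tx_plus)$consequence
      lab_minus <- classify_consequence("chr1", minus_pos, comp(tx_ref),
                                        comp(tx_alt), tx_minus)$consequence
      expect_equal(lab_minus, lab_plus)
    }
  })
})

test_that("the most severe consequence wins across overlapping transcripts", {
  # same CDS in two frames: ATG GCT GCA ATA A|TA A -> build a second valid
  # transcript over [13, 25) whose codon boundaries differ from TP1's
  tx_two <- tibble::tibble(
    gene = c("TP1", "TP2"), chrom = "chr1", strand = "+",
    cds_starts = list(10L, 13L), cds_ends = list(22L, 25L),
    cds_seq = c("ATGCTGCAATAA", "ATGCAATAATGA")
  )
  # position 17 (C>T): CAA->TAA truncating in TP1, CAA->TAA codon 2 of TP2
  # is also coding; take a position where severities differ:
  # position 21 (A>T): TP1 codon 4 TAA->TAT (stop loss, truncating);
  # TP2 codon 3 TAA...: check the reported label is the max severity
  r <- classify_consequence("chr1", 21, "A", "T", tx_two)
  lab1 <- classify_consequence("chr1", 21, "A", "T", tx_two[1, ])$consequence
  lab2 <- classify_consequence("chr1", 21, "A", "T", tx_two[2, ])$consequence
  sev <- c(non_coding = 0, synonymous = 1, missense = 2, truncating = 3)
  expect_equal(sev[[r$consequence]], max(sev[lab1], sev[lab2]))
})

test_that("transcript invariants are enforced", {
  bad <- tx_plus
  bad$cds_seq <- "TTGCTGCAATAA"   # does not start with ATG
  expect_error(validate_transcripts(bad), "ATG")
  bad2 <- tx_plus
  bad2$cds_seq <- "ATGCTGCAATAC"  # no stop codon
  expect_error(validate_transcripts(bad2), "stop")
  bad3 <- tx_plus
  bad3$cds_ends <- list(21L)      # length not divisible by 3
  expect_error(validate_transcripts(bad3), "length")
})

test_that("transcripts round-trip through GFF-like TSV plus FASTA", {
  p <- sim_params(n_sites = 5000, lesions_per_patient = 1)
  pt <- simulate_patient(p, 23, "P1")
  gff <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcripts(pt$transcripts, gff, fa)
  back <- read_transcripts(gff, fa)
  orig <- dplyr::arrange(pt$transcripts, gene)
  expect_equal(back$gene, orig$gene)
  expect_equal(back$cds_seq, orig$cds_seq)
  expect_equal(back$cds_starts, orig$cds_starts)
  expect_equal(back$strand, orig$strand)
})

test_that("annotation assigns genes to calls inside CDS regions", {
  p <- sim_params(n_sites = 5000, lesions_per_patient = 1, error_rate = 0,
                  fraction_subclonal = 0,
                  strand_bias_artifact_rate = 0, read_end_artifact_rate = 0)
  pt <- simulate_patient(p, 61, "P1")
  calls <- call_primary(pt$pileups[[1]])
  ann <- annotate_consequence(calls, pt$transcripts)
  expect_true(all(ann$consequence %in%
                    c("synonymous", "missense", "truncating", "non_coding")))
  coding <- ann[ann$consequence != "non_coding", ]
  expect_true(all(!is.na(coding$gene)))
  expect_true(all(is.na(ann$gene[ann$consequence == "non_coding"])))
})
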