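test_that("evidence summary applies quality, confirmation and end-distance gates", {
  # three clean alt reads, clean normal
  site <- make_site(ac_even(C = 97, T = 3), ac_even(C = 100),
                    tumor_reads = rbind(make_reads("T", 3),
                                        make_reads("C", 97)))
  ev <- summarize_evidence(site, "T")
  expect_equal(ev$qualified_mutant_reads, 3)
  expect_equal(ev$normal_mutant_reads, 0)
  expect_false(ev$end_only)
  # unconfirmed reads do not qualify
  reads <- rbind(make_reads("T", 1, confirmed = TRUE),
                 make_reads("T", 1, confirmed = FALSE))
  site <- make_site(ac_even(C = 98, T = 2), ac_even(C = 100),
                    tumor_reads = reads)
  expect_equal(summarize_evidence(site, "T")$qualified_mutant_reads, 1)
  # low base quality does not qualify
  reads <- rbind(make_reads("T", 2, base_quality = 10),
                 make_reads("T", 2, base_quality = 30))
  site <- make_site(ac_even(C = 96, T = 4), ac_even(C = 100),
                    tumor_reads = reads)
  expect_equal(summarize_evidence(site, "T")$qualified_mutant_reads, 2)
  # all mutant evidence inside the end-exclusion zone
  site <- make_site(ac_even(C = 96, T = 4), ac_even(C = 100),
                    tumor_reads = make_reads("T", 4, end_distance = 2))
  ev <- summarize_evidence(site, "T", end_exclusion_bp = 5)
  expect_equal(ev$qualified_mutant_reads, 0)
  expect_true(ev$end_only)
})

test_that("subclonal calls need >= 2 qualified reads and a clean normal", {
  cfg <- test_config()
  # 2 qualified reads, zero normal evidence: called
  site <- make_site(ac_even(C = 98, T = 2), ac_even(C = 100),
                    tumor_reads = make_reads("T", 2))
  calls <- call_subclonal(site, cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$source, "subclonal")
  expect_equal(calls$vaf_tumor, 0.02)
  expect_true(calls$passed)
  # any normal read with the same change vetoes the call
  site <- make_site(ac_even(C = 95, T = 5),
                    allele_counts(C_fwd = 50, C_rev = 49, T_fwd = 1),
                    tumor_reads = make_reads("T", 5))
  expect_equal(nrow(call_subclonal(site, cfg)), 0)
  # a single qualified read is below the minimum
  site <- make_site(ac_even(C = 99, T = 1), ac_even(C = 100),
                    tumor_reads = make_reads("T", 1))
  expect_equal(nrow(call_subclonal(site, cfg)), 0)
})

test_that("subclonal exclusion filters reject repeat, known and end-only calls", {
  cfg <- test_config()
  base_reads <- make_reads("T", 3)
  rep_site <- make_site(ac_even(C = 97, T = 3), ac_even(C = 100),
                        near_repeat = TRUE, tumor_reads = base_reads)
  calls <- call_subclonal(rep_site, cfg)
  expect_match(calls$tags, "NEAR_REPEAT")
  expect_false(calls$passed)
  known_site <- make_site(ac_even(C = 97, T = 3), ac_even(C = 100),
                          known_variant = TRUE, tumor_reads = base_reads)
  calls <- call_subclonal(known_site, cfg)
  expect_match(calls$tags, "KNOWN_VARIANT")
  expect_false(calls$passed)
  clean <- make_site(ac_even(C = 97, T = 3), ac_even(C = 100),
                     tumor_reads = base_reads)
  calls <- call_subclonal(clean, cfg)
  expect_true(calls$passed)
  # READ_END_ONLY is attached when an end-only call is forced through
  forced <- calls
  forced$end_only <- TRUE
  tagged <- apply_subclonal_filters(forced, clean)
  expect_match(tagged$tags, "READ_END_ONLY")
  expect_false(tagged$passed)
})

test_that("count-only input is refused with a pointer to the primary caller", {
  site <- make_site(ac_even(C = 95, T = 5), ac_even(C = 100))
  expect_error(call_subclonal(site), "call_primary")
})

test_that("detection sensitivity has the closed binomial form", {
  expect_equal(subclonal_sensitivity(0.05, 100, 2),
               1 - 0.95^100 - 100 * 0.05 * 0.95^99, tolerance = 1e-12)
  expect_equal(subclonal_sensitivity(0.05, 1, 2), 0)
  expect_equal(subclonal_sensitivity(1.0, 5, 2), 1.0)
})

test_that("empirical recovery at 5% VAF matches the closed form", {
  n_sites <- 2000
  depth <- 100L
  vaf <- 0.05
  pu <- withr::with_seed(17, {
    k <- rbinom(n_sites, depth, vaf)
    rows <- purrr::map(seq_len(n_sites), function(i) {
      make_site(ac_even(C = depth - k[i], T = k[i]), ac_even(C = depth),
                pos = i,
                tumor_reads = if (k[i] > 0) make_reads("T", k[i]) else NULL)
    })
    dplyr::bind_rows(rows)
  })
  calls <- call_subclonal(pu)
  recovered <- sum(calls$passed) / n_sites
  expected <- subclonal_sensitivity(vaf, depth, 2)
  se <- sqrt(expected * (1 - expected) / n_sites)
  expect_lt(abs(recovered - expected), 3 * se)
})

test_that("subclonal passed calls are a superset of primary passed calls", {
  p <- sim_params(n_sites = 4000, lesions_per_patient = 1, error_rate = 0,
                  strand_bias_artifact_rate = 0, read_end_artifact_rate = 0)
  pt <- simulate_patient(p, 12, "P1")
  pu <- pt$pileups[[1]]
  prim <- call_primary(pu)
  sub <- call_subclonal(pu)
  expect_true(all(mutation_key(prim[prim$passed, ]) %in%
                    mutation_key(sub[sub$passed, ])))
})

test_that("a normal alt read always vetoes, regardless of tumor evidence", {
  cfg <- test_config()
  for (kt in c(2, 10, 50)) {
    for (kn in 1:3) {
      site <- make_site(
        ac_even(C = 100 - kt, T = kt),
        ac_even(C = 100 - kn, T = kn),
        tumor_reads = make_reads("T", kt))
      expect_equal(nrow(call_subclonal(site, cfg)), 0)
    }
  }
})
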