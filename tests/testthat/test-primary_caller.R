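test_that("genotype thresholds partition allele fractions", {
  g <- call_genotype(ac_even(C = 95, T = 5), "C")
  expect_equal(g$genotype, "hom_ref")
  expect_equal(g$alt_fraction, 0.05)
  expect_equal(call_genotype(ac_even(C = 50, T = 50), "C")$genotype, "het")
  expect_equal(call_genotype(ac_even(T = 100), "C")$genotype, "hom_alt")
  expect_equal(call_genotype(allele_counts(), "C")$genotype, "no_call")
})

test_that("fisher exact two-sided matches hand-enumerated tables", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  # 2 / choose(20, 10): only the two all-or-nothing tables are as extreme
  expect_equal(fisher_exact_two_sided(0, 10, 10, 0), 2 / 184756,
               tolerance = 1e-12)
  # 2 / choose(6, 3) over the 20 tables with margins (3,3,3)
  expect_equal(fisher_exact_two_sided(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1.0)
})

test_that("fisher exact agrees with enumeration oracle and stats::fisher.test", {
  # every 2x2 table with total <= 12 against the choose()-based oracle
  for (tot in 1:12) {
    for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
      d <- tot - a - b - cc
      expect_equal(fisher_exact_two_sided(a, b, cc, d),
                   fisher_oracle(a, b, cc, d), tolerance = 1e-10)
    }
  }
  # random larger tables against the reference implementation
  withr::with_seed(5, {
    for (i in 1:50) {
      t <- sample(0:80, 4, replace = TRUE)
      if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
          t[1] + t[3] == 0 || t[2] + t[4] == 0) next
      expect_equal(
        fisher_exact_two_sided(t[1], t[2], t[3], t[4]),
        stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
        tolerance = 1e-8)
    }
  })
})

test_that("strand bias probability flags one-strand alt evidence", {
  balanced <- allele_counts(C_fwd = 50, C_rev = 50, T_fwd = 10, T_rev = 10)
  expect_equal(strand_bias_p(balanced, "C", "T"), 1.0)
  skew <- allele_counts(C_fwd = 50, C_rev = 50, T_fwd = 20, T_rev = 0)
  expect_lt(strand_bias_p(skew, "C", "T"), 0.001)
  small <- allele_counts(C_fwd = 5, C_rev = 5, T_fwd = 1, T_rev = 1)
  expect_gt(strand_bias_p(small, "C", "T"), 0.05)
  expect_true(is.na(strand_bias_p(ac_even(C = 100), "C", "T")))
})

test_that("tail-distance bias tag needs alt evidence concentrated at read ends", {
  withr::with_seed(8, {
    # alt reads far from ends: untagged
    far <- rbind(make_reads("T", 10, end_distance = sample(30:37, 10, TRUE)),
                 make_reads("C", 90, end_distance = sample(0:37, 90, TRUE)))
    expect_false(tail_bias_tag(far, "C", "T"))
    # alt reads all within 3 bp of an end vs uniform ref: tagged
    near <- rbind(make_reads("T", 10, end_distance = sample(0:3, 10, TRUE)),
                  make_reads("C", 90, end_distance = sample(0:37, 90, TRUE)))
    expect_true(tail_bias_tag(near, "C", "T"))
    # cross-check with a permutation rank-sum oracle
    stat <- function(d, is_alt) sum(rank(d)[is_alt])
    d <- near$end_distance
    is_alt <- near$base == "T"
    obs <- stat(d, is_alt)
    perm <- replicate(2000, stat(d, sample(is_alt)))
    expect_lt(mean(perm <= obs), 0.005)
    # a single alt read is insufficient evidence
    one <- rbind(make_reads("T", 1, end_distance = 0),
                 make_reads("C", 50, end_distance = sample(0:37, 50, TRUE)))
    expect_false(tail_bias_tag(one, "C", "T"))
  })
})

test_that("somatic candidates require differing genotypes with hom-ref normal", {
  cfg <- test_config()
  site <- make_site(ac_even(C = 50, T = 50), ac_even(C = 100))
  calls <- call_somatic_candidates(site, cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt, "T")
  expect_equal(calls$vaf_tumor, 0.5)
  expect_equal(calls$vaf_normal, 0.0)
  # identical genotypes: no call
  same <- make_site(ac_even(C = 100), ac_even(C = 100))
  expect_equal(nrow(call_somatic_candidates(same, cfg)), 0)
  # tumor alt fraction below the het threshold: genotypes equal, no call
  low <- make_site(ac_even(C = 95, T = 5), ac_even(C = 100))
  expect_equal(nrow(call_somatic_candidates(low, cfg)), 0)
  # het normal (germline) is not a somatic direction
  germ <- make_site(ac_even(C = 50, T = 50), ac_even(C = 50, T = 50))
  expect_equal(nrow(call_somatic_candidates(germ, cfg)), 0)
})

test_that("primary filters tag and disqualify as documented", {
  cfg <- test_config()
  # tumor depth 9: LOW_DEPTH, not passed
  shallow <- make_site(ac_even(C = 4, T = 5), ac_even(C = 100))
  calls <- call_primary(shallow, cfg)
  expect_equal(nrow(calls), 1)
  expect_match(calls$tags, "LOW_DEPTH")
  expect_false(calls$passed)
  # one-strand alt reads on balanced ref: STRAND_BIAS, not passed
  biased <- make_site(
    allele_counts(C_fwd = 40, C_rev = 40, T_fwd = 20, T_rev = 0),
    ac_even(C = 100))
  calls <- call_primary(biased, cfg)
  expect_match(calls$tags, "STRAND_BIAS")
  expect_false(calls$passed)
  # low-mapability site disqualified
  lm <- make_site(ac_even(C = 50, T = 50), ac_even(C = 100),
                  low_mapability = TRUE)
  calls <- call_primary(lm, cfg)
  expect_match(calls$tags, "LOW_MAPABILITY")
  expect_false(calls$passed)
  # TAIL_BIAS annotates but does not disqualify
  tb_reads <- rbind(make_reads("T", 15, end_distance = 0),
                    make_reads("C", 85, end_distance = 25))
  tb <- make_site(ac_even(C = 85, T = 15), ac_even(C = 100),
                  tumor_reads = tb_reads)
  calls <- call_primary(tb, cfg)
  expect_match(calls$tags, "TAIL_BIAS")
  expect_true(calls$passed)
  # clean site passes with no tags
  clean <- make_site(ac_even(C = 50, T = 50), ac_even(C = 100))
  calls <- call_primary(clean, cfg)
  expect_true(calls$passed)
  expect_equal(calls$tags, "")
})

test_that("enabling an additional filter never increases passed calls", {
  p <- sim_params(n_sites = 3000, lesions_per_patient = 1,
                  strand_bias_artifact_rate = 0.002)
  pt <- simulate_patient(p, 21, "P1")
  pu <- pt$pileups[[1]]
  base_passed <- sum(call_primary(pu)$passed)
  # flag an extra mapability stripe: passed count cannot grow
  pu2 <- pu
  pu2$low_mapability[1:500] <- TRUE
  expect_lte(sum(call_primary(pu2)$passed), base_passed)
  # stricter depth floor cannot grow the passed set either
  expect_lte(sum(call_primary(pu, test_config(min_depth = 50))$passed),
             base_passed)
})

test_that("label swap exposes variants private to the normal sample", {
  # a variant carried by the "normal" only surfaces when roles are swapped
  site <- make_site(ac_even(C = 100), ac_even(C = 60, G = 40))
  expect_equal(nrow(call_primary(site)), 0)
  swapped <- call_primary(swap_tumor_normal(site))
  expect_equal(nrow(swapped), 1)
  expect_equal(swapped$alt, "G")
  # double swap restores the original behaviour
  expect_equal(nrow(call_primary(swap_tumor_normal(swap_tumor_normal(site)))),
               0)
})

test_that("error-free clonal simulation is recovered exactly by the primary caller", {
  p <- sim_params(n_sites = 5000, lesions_per_patient = 1, error_rate = 0,
                  strand_bias_artifact_rate = 0, read_end_artifact_rate = 0,
                  fraction_subclonal = 0)
  pt <- simulate_patient(p, 33, "P1")
  pu <- pt$pileups[[1]]
  calls <- call_primary(pu)
  passed <- calls[calls$passed, ]
  truth_keys <- mutation_key(pt$truth)
  call_keys <- mutation_key(passed)
  expect_setequal(call_keys, truth_keys)
})
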