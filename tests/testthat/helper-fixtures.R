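# Shared fixture builders: one-row pileup sites, read-evidence frames,
# random call sets, and a brute-force Fisher oracle.

make_reads <- function(base, n, base_quality = 35, end_distance = 20,
                       strand = "forward", confirmed = TRUE) {
  data.frame(
    base = rep_len(base, n),
    base_quality = as.integer(rep_len(base_quality, n)),
    end_distance = as.integer(rep_len(end_distance, n)),
    strand = rep_len(strand, n),
    confirmed = rep_len(confirmed, n),
    stringsAsFactors = FALSE
  )
}

# Build a one-row pileup tibble from tumor/normal allele_counts vectors.
make_site <- function(tumor, normal, ref = "C", tri = NULL, pos = 100L,
                      chrom = "chr1", low_mapability = FALSE,
                      near_repeat = FALSE, known_variant = FALSE,
                      tumor_reads = NULL, normal_reads = NULL) {
  if (is.null(tri)) tri <- paste0("A", ref, "A")
  x <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                      tri_context = tri)
  for (j in seq_along(tumor)) x[[paste0("tumor_", names(tumor)[j])]] <- tumor[[j]]
  for (j in seq_along(normal)) x[[paste0("normal_", names(normal)[j])]] <- normal[[j]]
  x$low_mapability <- low_mapability
  x$near_repeat <- near_repeat
  x$known_variant <- known_variant
  x$tumor_reads <- list(tumor_reads)
  x$normal_reads <- list(normal_reads)
  x
}

# Even split of per-base totals over strands.
ac_even <- function(...) {
  tot <- c(...)
  args <- stats::setNames(as.list(integer(8)),
                          paste0(rep(c("A", "C", "G", "T"), each = 2),
                                 "_", c("fwd", "rev")))
  for (b in names(tot)) {
    args[[paste0(b, "_fwd")]] <- ceiling(tot[[b]] / 2)
    args[[paste0(b, "_rev")]] <- floor(tot[[b]] / 2)
  }
  do.call(allele_counts, args)
}

random_calls <- function(n, seed = 1) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1), ""))
    source <- sample(c("primary", "subclonal"), n, replace = TRUE)
    tag_pool <- list(
      primary = c("LOW_DEPTH", "STRAND_BIAS", "LOW_MAPABILITY", "TAIL_BIAS"),
      subclonal = c("NEAR_REPEAT", "KNOWN_VARIANT", "READ_END_ONLY"))
    tags <- unname(vapply(source, function(s) {
      k <- sample(0:2, 1)
      paste(sort(sample(tag_pool[[s]], k)), collapse = ";")
    }, ""))
    tibble::tibble(
      chrom = "chr1",
      pos = sort(sample.int(1e6, n)),
      ref = ref, alt = alt,
      tri_context = paste0(sample(bases, n, TRUE), ref, sample(bases, n, TRUE)),
      vaf_tumor = round(runif(n), 6),
      vaf_normal = round(runif(n, 0, 0.05), 6),
      fisher_p = ifelse(runif(n) < 0.2, NA_real_, round(runif(n), 6)),
      tags = tags, source = source,
      consequence = sample(c("missense", "synonymous", "truncating",
                             "non_coding", "unassigned"), n, TRUE),
      gene = ifelse(runif(n) < 0.3, NA_character_,
                    sprintf("GENE%03d", sample.int(50, n, TRUE))),
      passed = mutmosaic:::recompute_passed(tags, source)
    )
  })
}

# Independent two-sided Fisher oracle: explicit enumeration of all tables
# with the observed margins, probabilities from choose() ratios.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp)
  obs <- choose(m, a) * choose(n, c)
  sum(pr[pr <= obs * (1 + 1e-9)]) / sum(pr)
}

test_config <- function(...) pipeline_config(...)
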