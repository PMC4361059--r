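# Primary paired tumor/normal somatic caller.
#
# Per-sample genotypes come from fixed allele-fraction thresholds, somatic
# candidates are sites where the tumor genotype differs from a
# homozygous-reference normal, the tumor-normal allele-count contrast is
# annotated with a two-sided Fisher exact probability, and a filter cascade
# adds LOW_DEPTH / STRAND_BIAS / LOW_MAPABILITY / TAIL_BIAS tags (the first
# three disqualify, TAIL_BIAS annotates only).

#' Two-sided Fisher exact probability for a 2x2 count table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table. All-zero margins return 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows `(a, b)` and
#'   `(c, d)`. Vectorised.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)   # 1
#' fisher_exact_two_sided(0, 10, 10, 0) # 2 / choose(20, 10)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) abort("fisher table cells must be non-negative")
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 total
    nn <- c[i] + d[i]         # row 2 total
    k <- a[i] + c[i]          # column 1 total
    if (m + nn == 0 || k == 0 || k == m + nn) return(1)
    supp <- max(0, k - nn):min(k, m)
    probs <- stats::dhyper(supp, m, nn, k)
    obs <- stats::dhyper(a[i], m, nn, k)
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Call a per-sample genotype from allele counts
#'
#' The alternate base is the non-reference base with the highest total
#' count; the genotype is assigned from its allele fraction using fixed
#' thresholds: `hom_ref` below `het_min`, `hom_alt` above `hom_alt_min`,
#' `het` in between.
#'
#' @param counts An [allele_counts()] vector.
#' @param ref_base Reference base at the site.
#' @param het_min,hom_alt_min Allele-fraction thresholds (defaults 0.10 and
#'   0.85).
#' @return A list with `genotype` (`hom_ref`/`het`/`hom_alt`, or `no_call`
#'   at depth 0), `alt_base` and `alt_fraction`.
#' @export
call_genotype <- function(counts, ref_base, het_min = 0.10,
                          hom_alt_min = 0.85) {
  depth <- sum(counts)
  if (depth == 0) {
    return(list(genotype = "no_call", alt_base = NA_character_,
                alt_fraction = NA_real_))
  }
  totals <- vapply(BASES, function(b) base_total(counts, b), numeric(1))
  alts <- setdiff(BASES, ref_base)
  alt_base <- alts[which.max(totals[alts])]
  af <- unname(totals[alt_base] / depth)
  gt <- if (af < het_min) "hom_ref" else if (af > hom_alt_min) "hom_alt" else "het"
  list(genotype = gt, alt_base = alt_base, alt_fraction = af)
}

#' Strand-bias probability for a candidate variant
#'
#' Two-sided Fisher exact probability on the 2x2 table of forward/reverse
#' counts of reference versus alternate reads.
#'
#' @param counts An [allele_counts()] vector.
#' @param ref_base,alt_base Reference and alternate bases.
#' @return A probability, or `NA` when there are no alternate reads (no
#'   bias assessable).
#' @export
strand_bias_p <- function(counts, ref_base, alt_base) {
  rf <- counts[paste0(ref_base, "_fwd")]
  rr <- counts[paste0(ref_base, "_rev")]
  af <- counts[paste0(alt_base, "_fwd")]
  ar <- counts[paste0(alt_base, "_rev")]
  if (af + ar == 0) return(NA_real_)
  fisher_exact_two_sided(rf, rr, af, ar)
}

#' Tail-distance (read-end) bias tag
#'
#' Rank-sum comparison of distances to the nearer read end between
#' alt-supporting and ref-supporting reads. Tagged when the one-sided
#' Wilcoxon p (alt reads nearer the ends) falls below `alpha`. Fewer than
#' two alt reads, or no ref reads in the evidence, leave the site untagged.
#'
#' @param reads A read-evidence data frame (`base`, `end_distance`, ...).
#' @param ref_base,alt_base Reference and alternate bases.
#' @param alpha One-sided significance threshold (default 0.005).
#' @return `TRUE` when tagged.
#' @export
tail_bias_tag <- function(reads, ref_base, alt_base, alpha = 0.005) {
  if (is.null(reads) || nrow(reads) == 0) return(FALSE)
  alt_d <- reads$end_distance[reads$base == alt_base]
  ref_d <- reads$end_distance[reads$base == ref_base]
  if (length(alt_d) < 2 || length(ref_d) < 1) return(FALSE)
  p <- suppressWarnings(
    stats::wilcox.test(alt_d, ref_d, alternative = "less", exact = FALSE)$p.value
  )
  isTRUE(p < alpha)
}

#' Somatic candidate calls from a paired pileup
#'
#' Emits one candidate per site where the tumor and normal genotypes differ
#' and the normal is homozygous reference (somatic direction only;
#' loss-of-heterozygosity directions are not candidates). Each candidate
#' carries tumor/normal VAFs for the tumor's alternate base and the
#' two-sided Fisher exact probability of the (ref, alt) x (tumor, normal)
#' read-count table.
#'
#' @param pileup A pileup tibble.
#' @param config A [pipeline_config()] list (genotype thresholds).
#' @return An unfiltered call tibble (`tags` empty, `passed = TRUE`,
#'   `source = "primary"`).
#' @seealso [apply_primary_filters()], [call_primary()]
#' @export
call_somatic_candidates <- function(pileup, config = pipeline_config()) {
  mt <- count_matrix(pileup, "tumor")
  mn <- count_matrix(pileup, "normal")
  bt <- base_matrix(mt)
  bn <- base_matrix(mn)
  dt <- rowSums(bt)
  dn <- rowSums(bn)
  ri <- match(pileup$ref, BASES)
  n <- nrow(pileup)
  idx <- seq_len(n)

  # tumor alt base: highest-count non-reference base
  bt_masked <- bt
  bt_masked[cbind(idx, ri)] <- -1L
  ai <- max.col(bt_masked, ties.method = "first")
  t_alt_k <- bt[cbind(idx, ai)]
  t_ref_k <- bt[cbind(idx, ri)]
  t_af <- ifelse(dt > 0, t_alt_k / dt, NA_real_)

  # normal genotype w.r.t. its own best alt
  bn_masked <- bn
  bn_masked[cbind(idx, ri)] <- -1L
  n_ai <- max.col(bn_masked, ties.method = "first")
  n_af_own <- ifelse(dn > 0, bn[cbind(idx, n_ai)] / dn, NA_real_)

  t_gt <- dplyr::case_when(
    dt == 0 ~ "no_call",
    t_af < config$het_min ~ "hom_ref",
    t_af > config$hom_alt_min ~ "hom_alt",
    TRUE ~ "het"
  )
  n_hom_ref <- dn > 0 & n_af_own < config$het_min
  cand <- which(t_gt %in% c("het", "hom_alt") & n_hom_ref)
  if (length(cand) == 0) return(empty_calls())

  alt <- BASES[ai[cand]]
  n_alt_k <- bn[cbind(cand, ai[cand])]
  n_ref_k <- bn[cbind(cand, ri[cand])]
  fp <- fisher_exact_two_sided(t_ref_k[cand], t_alt_k[cand],
                               n_ref_k, n_alt_k)
  tibble(
    chrom = pileup$chrom[cand], pos = pileup$pos[cand],
    ref = pileup$ref[cand], alt = alt,
    tri_context = pileup$tri_context[cand],
    vaf_tumor = t_alt_k[cand] / dt[cand],
    vaf_normal = ifelse(dn[cand] > 0, n_alt_k / dn[cand], NA_real_),
    fisher_p = fp,
    tags = "", source = "primary",
    consequence = "unassigned", gene = NA_character_,
    passed = TRUE
  )
}

#' Apply the primary filter cascade
#'
#' Adds tags to primary candidates: `LOW_DEPTH` (tumor or normal depth below
#' `min_depth`), `STRAND_BIAS` (two-sided strand-bias probability below
#' `strand_bias_alpha`), `LOW_MAPABILITY` (site flagged by the mapability
#' mask) and `TAIL_BIAS` (rank-sum read-end bias, annotate-only). `passed`
#' is `TRUE` iff no tag among `LOW_DEPTH`, `STRAND_BIAS`, `LOW_MAPABILITY`
#' is present.
#'
#' @param calls A call tibble from [call_somatic_candidates()].
#' @param pileup The pileup the calls came from.
#' @param config A [pipeline_config()] list.
#' @return The call tibble with `tags` and `passed` set.
#' @export
apply_primary_filters <- function(calls, pileup, config = pipeline_config()) {
  if (nrow(calls) == 0) return(calls)
  key <- paste(pileup$chrom, pileup$pos)
  row <- match(paste(calls$chrom, calls$pos), key)
  if (anyNA(row)) abort("apply_primary_filters: call site missing from pileup")
  mt <- count_matrix(pileup, "tumor")
  mn <- count_matrix(pileup, "normal")
  dt <- rowSums(mt)[row]
  dn <- rowSums(mn)[row]
  tag_list <- purrr::map(seq_len(nrow(calls)), function(i) {
    tags <- character()
    if (dt[i] < config$min_depth || dn[i] < config$min_depth) {
      tags <- c(tags, "LOW_DEPTH")
    }
    sb <- strand_bias_p(mt[row[i], ], calls$ref[i], calls$alt[i])
    if (!is.na(sb) && sb < config$strand_bias_alpha) {
      tags <- c(tags, "STRAND_BIAS")
    }
    if (isTRUE(pileup$low_mapability[row[i]])) {
      tags <- c(tags, "LOW_MAPABILITY")
    }
    rd <- if ("tumor_reads" %in% names(pileup)) pileup$tumor_reads[[row[i]]] else NULL
    if (tail_bias_tag(rd, calls$ref[i], calls$alt[i],
                      alpha = config$tail_bias_alpha)) {
      tags <- c(tags, "TAIL_BIAS")
    }
    tags
  })
  calls$tags <- join_tags(tag_list)
  calls$passed <- purrr::map_lgl(tag_list,
                                 function(t) !any(t %in% PRIMARY_FAIL_TAGS))
  calls
}

#' Primary somatic calling pipeline for one lesion
#'
#' [call_somatic_candidates()] followed by [apply_primary_filters()].
#'
#' @param pileup A pileup tibble for one tumor/normal pair.
#' @param config A [pipeline_config()] list.
#' @param lesion_id,patient_id Optional identifiers stamped on the output.
#' @return A call tibble (all candidates, with `tags` and `passed`).
#' @export
call_primary <- function(pileup, config = pipeline_config(),
                         lesion_id = NULL, patient_id = NULL) {
  calls <- call_somatic_candidates(pileup, config)
  calls <- apply_primary_filters(calls, pileup, config)
  if (!is.null(lesion_id)) calls$lesion_id <- lesion_id
  if (!is.null(patient_id)) calls$patient_id <- patient_id
  calls
}
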