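# Deep-amplicon validation decision rule and primary/secondary concordance.

#' Apply the amplicon validation decision rule to one variant
#'
#' A variant is `not_evaluable` unless both tumor and normal amplicon depths
#' reach `min_depth` (default 20). It is `validated` iff the tumor carries
#' at least `min_reads` mutant reads (default 5) making up at least
#' `min_fraction` of the tumor reads (default 1%), with zero mutant reads in
#' the matched normal; otherwise `not_validated`.
#'
#' @param tumor,normal [allele_counts()] vectors from the amplicon data.
#' @param alt_base The mutant base.
#' @param min_depth,min_reads,min_fraction Rule thresholds.
#' @return A list: `status`, `tumor_depth`, `tumor_mutant`, `normal_depth`,
#'   `normal_mutant`.
#' @export
validate_call <- function(tumor, normal, alt_base,
                          min_depth = 20, min_reads = 5,
                          min_fraction = 0.01) {
  dt <- sum(tumor)
  dn <- sum(normal)
  kt <- base_total(tumor, alt_base)
  kn <- base_total(normal, alt_base)
  status <- if (dt < min_depth || dn < min_depth) {
    "not_evaluable"
  } else if (kt >= min_reads && kt / dt >= min_fraction && kn == 0) {
    "validated"
  } else {
    "not_validated"
  }
  list(status = status, tumor_depth = dt, tumor_mutant = kt,
       normal_depth = dn, normal_mutant = kn)
}

#' Vectorised validation over an amplicon count table
#'
#' @param amplicons A tibble with one row per assayed variant: `key` (or
#'   `chrom`/`pos`/`ref`/`alt`), `alt`, and the 16 strand-count columns
#'   `tumor_A_fwd` ... `normal_T_rev`.
#' @param config A [pipeline_config()] list (validation thresholds).
#' @return A tibble with the per-variant counts and `status`.
#' @export
validate_calls <- function(amplicons, config = pipeline_config()) {
  mt <- count_matrix(amplicons, "tumor")
  mn <- count_matrix(amplicons, "normal")
  res <- purrr::map(seq_len(nrow(amplicons)), function(i) {
    v <- validate_call(mt[i, ], mn[i, ], amplicons$alt[i],
                       min_depth = config$val_min_depth,
                       min_reads = config$val_min_reads,
                       min_fraction = config$val_min_fraction)
    as_tibble(v)
  })
  bind_cols(
    amplicons[, intersect(c("key", "chrom", "pos", "ref", "alt", "gene"),
                          names(amplicons))],
    bind_rows(res)
  )
}

#' Primary/secondary concordance among high-MP calls
#'
#' Among primary calls whose tumor VAF ("mutational percentage") exceeds
#' `mp_threshold` and that received an evaluable validation result, the
#' fraction validated. Returns `NA` when no call qualifies.
#'
#' @param calls A primary call tibble (keyed by `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param results A validation tibble from [validate_calls()] carrying the
#'   same keys.
#' @param mp_threshold VAF threshold (default 0.15); calls strictly above it
#'   are counted.
#' @return A fraction in `[0, 1]`, or `NA_real_` when the denominator is 0.
#' @export
concordance_rate <- function(calls, results, mp_threshold = 0.15) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  m <- match(key(calls), key(results))
  if (anyNA(m)) abort("concordance_rate: every call needs a validation result")
  status <- results$status[m]
  use <- calls$vaf_tumor > mp_threshold & status != "not_evaluable"
  if (!any(use)) return(NA_real_)
  mean(status[use] == "validated")
}
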