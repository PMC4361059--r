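# Per-patient cross-lesion heterogeneity: shared-mutation overlap,
# clonality classification, gene multi-hit reporting.

#' Canonical mutation identity key
#'
#' Equality of `chrom:pos:ref>alt` defines "the same mutation" across
#' lesions; gene-level recurrence is reported separately by
#' [gene_multihit_report()].
#'
#' @param calls A call tibble (or any tibble with the four key columns).
#' @return A character vector of keys.
#' @export
mutation_key <- function(calls) {
  paste0(calls$chrom, ":", calls$pos, ":", calls$ref, ">", calls$alt)
}

#' Pairwise cross-lesion overlap report
#'
#' For every pair of lesions of one patient: the number of shared passed
#' mutation keys, the union size, and the Jaccard index, plus the list of
#' shared keys.
#'
#' @param calls A call tibble covering >= 2 lesions of one patient
#'   (`lesion_id` column required; only `passed` calls are compared unless
#'   `passed_only = FALSE`).
#' @param passed_only Restrict to passed calls.
#' @return A `mutmosaic_overlap` object: list with `patient_id`, `pairs`
#'   (tibble: `lesion_a`, `lesion_b`, `shared`, `union`, `jaccard`),
#'   `shared_keys`, and per-lesion set sizes `sizes`.
#' @export
overlap_report <- function(calls, passed_only = TRUE) {
  if (!"lesion_id" %in% names(calls)) {
    abort("configuration error: overlap_report needs a lesion_id column")
  }
  x <- if (passed_only) filter(calls, .data$passed) else calls
  lesions <- sort(unique(calls$lesion_id))
  if (length(lesions) < 2) {
    abort("configuration error: overlap_report needs >= 2 lesions")
  }
  sets <- purrr::map(lesions, function(l) {
    unique(mutation_key(filter(x, .data$lesion_id == l)))
  })
  names(sets) <- lesions
  combs <- utils::combn(lesions, 2)
  pairs <- purrr::map(seq_len(ncol(combs)), function(j) {
    a <- sets[[combs[1, j]]]
    b <- sets[[combs[2, j]]]
    sh <- length(intersect(a, b))
    un <- length(union(a, b))
    tibble(lesion_a = combs[1, j], lesion_b = combs[2, j],
           shared = sh, union = un,
           jaccard = if (un == 0) 0 else sh / un)
  })
  shared_keys <- unique(unlist(purrr::map(seq_len(ncol(combs)), function(j) {
    intersect(sets[[combs[1, j]]], sets[[combs[2, j]]])
  })))
  patient_id <- if ("patient_id" %in% names(calls) && nrow(calls) > 0) {
    calls$patient_id[1]
  } else NA_character_
  structure(list(patient_id = patient_id, pairs = bind_rows(pairs),
                 shared_keys = shared_keys, sizes = lengths(sets)),
            class = "mutmosaic_overlap")
}

#' @export
print.mutmosaic_overlap <- function(x, ...) {
  cat("Cross-lesion overlap, patient", x$patient_id, "\n")
  print(x$pairs)
  invisible(x)
}

#' Classify calls as clonal or subclonal by VAF
#'
#' `subclonal` iff `vaf_tumor < threshold`; the boundary itself is clonal.
#' The default threshold 0.25 is half the diploid heterozygous expectation.
#'
#' @param calls A call tibble.
#' @param clonal_vaf_threshold VAF cutoff (default 0.25).
#' @return `calls` with a `clonality` column.
#' @export
classify_clonality <- function(calls, clonal_vaf_threshold = 0.25) {
  calls$clonality <- ifelse(calls$vaf_tumor < clonal_vaf_threshold,
                            "subclonal", "clonal")
  calls
}

#' Per-gene multi-hit report across lesions
#'
#' For each gene hit by at least one passed call: which lesions are hit,
#' how many distinct variants each carries, whether the gene recurs across
#' lesions, and whether the *same* variant key recurs across lesions.
#'
#' @param calls A consequence-annotated call tibble with `lesion_id`.
#' @param aa_changing_only Count only amino-acid-changing calls.
#' @return A tibble: `gene`, `n_lesions_hit`, `n_variants`,
#'   `recurrent_gene`, `recurrent_variant`.
#' @export
gene_multihit_report <- function(calls, aa_changing_only = TRUE) {
  x <- filter(calls, .data$passed, !is.na(.data$gene))
  if (aa_changing_only) {
    x <- filter(x, is_amino_acid_changing(.data$consequence))
  }
  if (nrow(x) == 0) {
    return(tibble(gene = character(), n_lesions_hit = integer(),
                  n_variants = integer(), recurrent_gene = logical(),
                  recurrent_variant = logical()))
  }
  x$key <- mutation_key(x)
  dk <- distinct(x, .data$gene, .data$key, .data$lesion_id)
  key_rec <- dk |>
    dplyr::count(.data$gene, .data$key, name = "n_les") |>
    group_by(.data$gene) |>
    summarise(recurrent_variant = any(.data$n_les > 1), .groups = "drop")
  dk |>
    group_by(.data$gene) |>
    summarise(n_lesions_hit = dplyr::n_distinct(.data$lesion_id),
              n_variants = dplyr::n_distinct(.data$key),
              .groups = "drop") |>
    mutate(recurrent_gene = .data$n_lesions_hit > 1) |>
    left_join(key_rec, by = "gene") |>
    arrange(dplyr::desc(.data$n_variants), .data$gene)
}

#' Estimate the cross-lesion shared-mutation fraction
#'
#' Under the generative model in which each mutation is copied into one
#' sibling lesion with probability `s`, a consistent estimator from a pair
#' of observed sets is `shared / (|A| + |B| - shared)` (shared keys over
#' originating mutations). Aggregated over all lesion pairs and patients by
#' pooling numerators and denominators.
#'
#' @param truth A tibble with `lesion_id` and the mutation key columns; use
#'   one patient's truth (or call) table, or pass `patient_id` to pool.
#' @return A list: `estimate`, `shared`, `origins` (pooled denominator).
#' @export
estimate_shared_fraction <- function(truth) {
  split_by <- if ("patient_id" %in% names(truth)) {
    split(truth, truth$patient_id)
  } else list(truth)
  shared <- 0
  origins <- 0
  for (tp in split_by) {
    lesions <- unique(tp$lesion_id)
    if (length(lesions) < 2) next
    sets <- purrr::map(lesions, function(l) {
      unique(mutation_key(filter(tp, .data$lesion_id == l)))
    })
    combs <- utils::combn(length(lesions), 2)
    for (j in seq_len(ncol(combs))) {
      a <- sets[[combs[1, j]]]
      b <- sets[[combs[2, j]]]
      sh <- length(intersect(a, b))
      shared <- shared + sh
      origins <- origins + length(a) + length(b) - sh
    }
  }
  list(estimate = if (origins > 0) shared / origins else NA_real_,
       shared = shared, origins = origins)
}
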