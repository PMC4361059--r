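# Lesion-level burden metrics (mutational index, inverse analysis) and
# substitution-spectrum / CpG-context summaries.

# Half-up rounding (5 always rounds away from zero at the cut digit),
# matching how per-Mb indices are conventionally printed.
#' @noRd
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Mutational index: mutations per megabase of target
#'
#' `round_half_up(n_mutations / target_mb, 2)`. The default 30 Mb is the
#' effective exome target size consistent with published per-Mb indices for
#' 50 Mb-capture exomes after coverage filtering; it is configurable and
#' echoed in pipeline metadata.
#'
#' @param n_mutations Non-negative mutation count (vectorised).
#' @param target_mb Effective target size in Mb (> 0).
#' @return Mutations per Mb, rounded half-up to 2 decimals.
#' @examples
#' mutational_index(56, 30)  # 1.87
#' mutational_index(155, 30) # 5.17
#' @export
mutational_index <- function(n_mutations, target_mb = 30) {
  if (any(target_mb <= 0)) abort("configuration error: target_mb must be > 0")
  if (any(n_mutations < 0)) abort("n_mutations must be non-negative")
  round_half_up(n_mutations / target_mb, 2)
}

#' Collapse a substitution to one of six pyrimidine-reference classes
#'
#' Purine-reference events are mapped to their pyrimidine complement
#' (`G>A` becomes `C>T`, `A>C` becomes `T>G`, ...).
#'
#' @param ref,alt Single reference and alternate bases (vectorised).
#' @return One of `"C>A" "C>G" "C>T" "T>A" "T>C" "T>G"`.
#' @export
substitution_class <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  if (any(!ref %in% BASES) || any(!alt %in% BASES) || any(ref == alt)) {
    abort("validation error: ref/alt must be distinct bases in {A,C,G,T}")
  }
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  paste0(r, ">", a)
}

#' Is a variant at a CpG dimer?
#'
#' `TRUE` iff the reference base is a C immediately followed by G, or a G
#' immediately preceded by C, in the trinucleotide context. Spectrum
#' summaries weight this only within the collapsed C>T class; for other
#' classes it reports bare context membership.
#'
#' @param tri_context Reference trinucleotide centred on the site.
#' @param ref Reference base (must equal the middle base of the context).
#' @return Logical (vectorised).
#' @export
is_cpg_dimer <- function(tri_context, ref) {
  n <- max(length(tri_context), length(ref))
  tri_context <- rep_len(tri_context, n)
  ref <- rep_len(ref, n)
  if (any(nchar(tri_context) != 3) ||
      any(substr(tri_context, 2, 2) != ref)) {
    abort("validation error: tri_context must be 3 bases centred on ref")
  }
  (ref == "C" & substr(tri_context, 3, 3) == "G") |
    (ref == "G" & substr(tri_context, 1, 1) == "C")
}

#' @noRd
unique_calls <- function(calls) {
  distinct(calls, .data$chrom, .data$pos, .data$ref, .data$alt,
           .keep_all = TRUE)
}

#' Per-lesion burden metrics
#'
#' Counts unique (chrom, pos, ref, alt) passed amino-acid-changing calls
#' and converts to a per-Mb mutational index.
#'
#' @param calls A consequence-annotated call tibble for one lesion.
#' @param target_mb Effective target size in Mb.
#' @return A one-row tibble: `n_aa_changing`, `mut_index`.
#' @export
lesion_metrics <- function(calls, target_mb = 30) {
  aa <- calls |>
    filter(.data$passed, is_amino_acid_changing(.data$consequence)) |>
    unique_calls()
  tibble(n_aa_changing = nrow(aa),
         mut_index = mutational_index(nrow(aa), target_mb))
}

#' Swap tumor and normal roles in a pileup
#'
#' The basis of the inverse (noise-floor) analysis: all `tumor_*` and
#' `normal_*` columns, including read-evidence lists, exchange places.
#' Applying it twice is the identity.
#'
#' @param pileup A pileup tibble.
#' @return The role-swapped pileup.
#' @export
swap_tumor_normal <- function(pileup) {
  out <- pileup
  out[TUMOR_COLS] <- pileup[NORMAL_COLS]
  out[NORMAL_COLS] <- pileup[TUMOR_COLS]
  if (all(c("tumor_reads", "normal_reads") %in% names(pileup))) {
    out$tumor_reads <- pileup$normal_reads
    out$normal_reads <- pileup$tumor_reads
  }
  out
}

#' Inverse analysis: call the normal against the lesion
#'
#' Re-runs the full primary pipeline with sample roles swapped (the lesion
#' acting as "normal") and counts unique passed amino-acid-changing calls.
#' On error-free data this is a noise floor of zero; on real data it
#' estimates the pipeline's artifact background.
#'
#' @param pileup A pileup tibble for one tumor/normal pair.
#' @param transcripts Transcript models for consequence annotation.
#' @param config A [pipeline_config()] list.
#' @return A one-row tibble: `n_inverse`, `inverse_index`.
#' @export
inverse_analysis <- function(pileup, transcripts,
                             config = pipeline_config()) {
  calls <- call_primary(swap_tumor_normal(pileup), config)
  calls <- annotate_consequence(calls, transcripts)
  m <- lesion_metrics(calls, target_mb = config$target_mb)
  tibble(n_inverse = m$n_aa_changing, inverse_index = m$mut_index)
}

#' Substitution spectrum and CpG summary of a call set
#'
#' Fractions of the six collapsed substitution classes over unique passed
#' calls, plus the fraction of C>T/G>A events at CpG dimers.
#'
#' @param calls A call tibble with `tri_context`.
#' @param passed_only Restrict to passed calls (default `TRUE`).
#' @return A `mutmosaic_spectrum` object: list with `classes` (tibble of
#'   class, n, fraction), `cpg_fraction_of_cg_transitions`, `n_total`,
#'   `n_ct`, and `empty` flag.
#' @export
spectrum_summary <- function(calls, passed_only = TRUE) {
  x <- if (passed_only) filter(calls, .data$passed) else calls
  x <- unique_calls(x)
  if (nrow(x) == 0) {
    out <- list(
      classes = tibble(class = SUB_CLASSES, n = 0L, fraction = 0),
      cpg_fraction_of_cg_transitions = NA_real_,
      n_total = 0L, n_ct = 0L, empty = TRUE)
    return(structure(out, class = "mutmosaic_spectrum"))
  }
  cls <- substitution_class(x$ref, x$alt)
  tab <- table(factor(cls, levels = SUB_CLASSES))
  ct <- x[cls == "C>T", ]
  cpg <- if (nrow(ct) > 0) {
    mean(is_cpg_dimer(ct$tri_context, ct$ref))
  } else NA_real_
  out <- list(
    classes = tibble(class = SUB_CLASSES, n = as.integer(tab),
                     fraction = as.numeric(tab) / nrow(x)),
    cpg_fraction_of_cg_transitions = cpg,
    n_total = nrow(x), n_ct = nrow(ct), empty = FALSE)
  structure(out, class = "mutmosaic_spectrum")
}

#' @export
print.mutmosaic_spectrum <- function(x, ...) {
  cat("Substitution spectrum (", x$n_total, " unique calls)\n", sep = "")
  print(x$classes)
  cat("CpG fraction of C>T/G>A transitions:",
      format(x$cpg_fraction_of_cg_transitions, digits = 3), "\n")
  invisible(x)
}

#' Compare the CpG composition of two call sets
#'
#' Two-sided Fisher exact probability on the 2x2 table (CpG vs non-CpG) x
#' (set A vs set B) among C>T/G>A calls.
#'
#' @param calls_a,calls_b Call tibbles with `tri_context`.
#' @param passed_only Restrict to passed calls.
#' @return A probability, or `NA` when either set has no C>T/G>A calls.
#' @export
compare_spectra <- function(calls_a, calls_b, passed_only = TRUE) {
  ct_counts <- function(calls) {
    x <- if (passed_only) filter(calls, .data$passed) else calls
    x <- unique_calls(x)
    if (nrow(x) == 0) return(c(0L, 0L))
    cls <- substitution_class(x$ref, x$alt)
    ct <- x[cls == "C>T", ]
    if (nrow(ct) == 0) return(c(0L, 0L))
    k <- sum(is_cpg_dimer(ct$tri_context, ct$ref))
    c(k, nrow(ct) - k)
  }
  a <- ct_counts(calls_a)
  b <- ct_counts(calls_b)
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  fisher_exact_two_sided(a[1], a[2], b[1], b[2])
}
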