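# Minimum-evidence subclonal caller.
#
# Operates on read-level evidence: a site is called when at least
# `min_evidence` qualified mutant reads support the change in the tumor
# (high base quality, independently confirmed, away from read ends) and the
# matched normal shows absolutely no read carrying the same change.
# Repeat-proximal, known-variant and read-end-only calls are then removed.

#' Summarise read-level mutant evidence at one site
#'
#' A tumor read is *qualified* when it carries the alternate base with base
#' quality at least `min_baseq`, is independently confirmed (re-alignment
#' agreement surrogate), and lies at least `end_exclusion_bp` from the
#' nearer read end. `normal_mutant_reads` counts any normal read carrying
#' the alternate base regardless of quality (taken from the normal count
#' matrix, which by construction equals the read-list tally). `end_only` is
#' `TRUE` when mutant evidence exists, at least one read passes the
#' quality/confirmation gate, and every such read fails the end-distance
#' test.
#'
#' @param site A one-row pileup tibble (must carry `tumor_reads`).
#' @param alt_base Alternate base under consideration.
#' @param min_baseq Minimum base quality (default 20).
#' @param end_exclusion_bp Reads closer than this to a read end do not
#'   qualify (default 5).
#' @return A list: `qualified_mutant_reads`, `total_mutant_reads`,
#'   `normal_mutant_reads`, `end_only`.
#' @export
summarize_evidence <- function(site, alt_base, min_baseq = 20,
                               end_exclusion_bp = 5) {
  rd <- site$tumor_reads[[1]]
  if (is.null(rd)) {
    abort(paste0(
      "read-level evidence missing at ", site$chrom, ":", site$pos,
      "; the subclonal caller requires per-read records -- ",
      "use call_primary() for count-only input"))
  }
  is_alt <- rd$base == alt_base
  qual <- is_alt & rd$base_quality >= min_baseq & rd$confirmed
  qualified <- qual & rd$end_distance >= end_exclusion_bp
  mn <- count_matrix(site, "normal")
  normal_mutant <- unname(base_matrix(mn)[1, alt_base])
  total <- sum(is_alt)
  list(
    qualified_mutant_reads = sum(qualified),
    total_mutant_reads = total,
    normal_mutant_reads = normal_mutant,
    end_only = total > 0 && sum(qual) > 0 && all(rd$end_distance[qual] <
                                                   end_exclusion_bp)
  )
}

#' @noRd
subclonal_candidate_alt <- function(pileup) {
  bt <- base_matrix(count_matrix(pileup, "tumor"))
  ri <- match(pileup$ref, BASES)
  idx <- seq_len(nrow(pileup))
  bt[cbind(idx, ri)] <- -1L
  ai <- max.col(bt, ties.method = "first")
  alt_k <- bt[cbind(idx, ai)]
  list(alt = BASES[ai], alt_k = pmax(alt_k, 0L))
}

#' Minimum-evidence subclonal calling for one lesion
#'
#' For every site with any non-reference tumor reads, summarises the
#' read-level evidence for the best alternate base and emits a call iff the
#' qualified mutant read count reaches `min_evidence` (default 2) and the
#' matched normal carries zero reads with the same change. Emitted calls
#' then pass through [apply_subclonal_filters()].
#'
#' @param pileup A pileup tibble with read-evidence list-columns.
#' @param config A [pipeline_config()] list.
#' @param lesion_id,patient_id Optional identifiers stamped on the output.
#' @return A call tibble with `source = "subclonal"`; `vaf_tumor` is the
#'   total mutant read fraction at the site.
#' @export
call_subclonal <- function(pileup, config = pipeline_config(),
                           lesion_id = NULL, patient_id = NULL) {
  cand <- subclonal_candidate_alt(pileup)
  rows <- which(cand$alt_k > 0)
  dt <- rowSums(count_matrix(pileup, "tumor"))
  dn_alt <- base_matrix(count_matrix(pileup, "normal"))
  out <- purrr::map(rows, function(i) {
    site <- pileup[i, ]
    ev <- summarize_evidence(site, cand$alt[i],
                             min_baseq = config$min_baseq,
                             end_exclusion_bp = config$end_exclusion_bp)
    if (ev$qualified_mutant_reads < config$min_evidence ||
        ev$normal_mutant_reads > 0) {
      return(NULL)
    }
    tibble(
      chrom = site$chrom, pos = site$pos, ref = site$ref,
      alt = cand$alt[i], tri_context = site$tri_context,
      vaf_tumor = ev$total_mutant_reads / dt[i],
      vaf_normal = ev$normal_mutant_reads / max(1, sum(dn_alt[i, ])),
      fisher_p = NA_real_, tags = "", source = "subclonal",
      consequence = "unassigned", gene = NA_character_, passed = TRUE,
      end_only = ev$end_only
    )
  })
  calls <- bind_rows(out)
  if (nrow(calls) == 0) {
    calls <- empty_calls()
    calls$end_only <- logical()
  }
  calls <- apply_subclonal_filters(calls, pileup)
  calls$end_only <- NULL
  if (!is.null(lesion_id)) calls$lesion_id <- lesion_id
  if (!is.null(patient_id)) calls$patient_id <- patient_id
  calls
}

#' Apply the subclonal exclusion filters
#'
#' Rejects (sets `passed = FALSE` with the corresponding tag) calls at
#' sites flagged `near_repeat` (`NEAR_REPEAT`), flagged `known_variant`
#' (`KNOWN_VARIANT`), or whose quality-qualified mutant evidence lies
#' entirely within the read-end exclusion zone (`READ_END_ONLY`).
#'
#' @param calls A call tibble from the subclonal caller; an `end_only`
#'   logical column is honoured when present.
#' @param pileup The pileup the calls came from.
#' @return The call tibble with `tags` and `passed` set.
#' @export
apply_subclonal_filters <- function(calls, pileup) {
  if (nrow(calls) == 0) return(calls)
  key <- paste(pileup$chrom, pileup$pos)
  row <- match(paste(calls$chrom, calls$pos), key)
  if (anyNA(row)) abort("apply_subclonal_filters: call site missing from pileup")
  end_only <- if ("end_only" %in% names(calls)) calls$end_only else
    rep(FALSE, nrow(calls))
  tag_list <- purrr::map(seq_len(nrow(calls)), function(i) {
    tags <- character()
    if (isTRUE(pileup$near_repeat[row[i]])) tags <- c(tags, "NEAR_REPEAT")
    if (isTRUE(pileup$known_variant[row[i]])) tags <- c(tags, "KNOWN_VARIANT")
    if (isTRUE(end_only[i])) tags <- c(tags, "READ_END_ONLY")
    tags
  })
  calls$tags <- join_tags(tag_list)
  calls$passed <- purrr::map_lgl(tag_list,
                                 function(t) !any(t %in% SUBCLONAL_FAIL_TAGS))
  calls
}

#' Detection sensitivity of the minimum-evidence rule
#'
#' Closed-form probability that a variant at allele fraction `vaf` yields at
#' least `min_reads` mutant reads at the given depth:
#' `P(X >= min_reads)` with `X ~ Binomial(depth, vaf)`. Used to verify the
#' caller's detection floor (e.g. ~96% power for a 5% VAF variant at depth
#' 100 with a minimum of 2 reads).
#'
#' @param vaf True variant allele fraction in `(0, 1]`.
#' @param depth Read depth (>= 1).
#' @param min_reads Minimum mutant read count (default 2).
#' @return A probability. Vectorised over all arguments.
#' @export
subclonal_sensitivity <- function(vaf, depth, min_reads = 2) {
  stopifnot(all(vaf > 0), all(vaf <= 1), all(depth >= 1))
  stats::pbinom(min_reads - 1, depth, vaf, lower.tail = FALSE)
}
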