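# Toy-transcript coding-consequence classifier.
#
# Maps SNVs onto strand-aware CDS coordinates of toy transcript models and
# translates the affected codon with the standard genetic code. Used to
# restrict burden metrics to amino-acid-changing mutations.

#' Validate toy transcripts
#'
#' Enforces the transcript invariants: spliced CDS length divisible by 3
#' and equal to the summed interval lengths, sequence starting with ATG and
#' ending with a stop codon.
#'
#' @param transcripts A transcript tibble (see [simulate_transcripts()]).
#' @return `transcripts`, invisibly.
#' @export
validate_transcripts <- function(transcripts) {
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(transcripts))) {
    seq <- transcripts$cds_seq[i]
    len <- sum(transcripts$cds_ends[[i]] - transcripts$cds_starts[[i]])
    if (nchar(seq) != len || len %% 3 != 0) {
      abort(sprintf("configuration error: transcript %s CDS length invalid",
                    transcripts$gene[i]))
    }
    if (substr(seq, 1, 3) != "ATG") {
      abort(sprintf("configuration error: transcript %s does not start ATG",
                    transcripts$gene[i]))
    }
    last <- substr(seq, len - 2, len)
    if (is.na(gc[last]) || gc[last] != "*") {
      abort(sprintf("configuration error: transcript %s does not end in stop",
                    transcripts$gene[i]))
    }
  }
  invisible(transcripts)
}

# 0-based CDS coordinate of a 1-based genomic position within a transcript,
# or NA when outside every interval. Intervals are 0-based half-open,
# ordered 5'->3' in transcript orientation.
#' @noRd
genomic_to_tx <- function(starts, ends, strand, pos) {
  lens <- ends - starts
  offs <- c(0L, cumsum(lens))
  for (ex in seq_along(starts)) {
    if (starts[ex] < pos && pos <= ends[ex]) {
      within <- if (strand == "+") pos - 1L - starts[ex] else ends[ex] - pos
      return(offs[ex] + within)
    }
  }
  NA_integer_
}

SEVERITY <- c(non_coding = 0, synonymous = 1, missense = 2, truncating = 3)

#' Classify the coding consequence of one SNV
#'
#' `non_coding` when the position lies outside every CDS; otherwise the
#' affected codon is located through strand-aware coordinates and translated
#' with the standard genetic code: `synonymous`, `missense`, or
#' `truncating` (gained stop, lost stop, or lost start). When several
#' transcripts are hit the most severe consequence is reported
#' (truncating > missense > synonymous > non_coding).
#'
#' @param chrom,pos,ref,alt The variant (1-based position, single bases).
#' @param transcripts A transcript tibble ([validate_transcripts()] is
#'   applied by [annotate_consequence()], not here).
#' @return A list with `consequence` and `gene` (`NA` when non-coding).
#' @export
classify_consequence <- function(chrom, pos, ref, alt, transcripts) {
  gc <- Biostrings::GENETIC_CODE
  best <- list(consequence = "non_coding", gene = NA_character_)
  for (i in seq_len(nrow(transcripts))) {
    if (transcripts$chrom[i] != chrom) next
    strand <- transcripts$strand[i]
    cpos <- genomic_to_tx(transcripts$cds_starts[[i]],
                          transcripts$cds_ends[[i]], strand, pos)
    if (is.na(cpos)) next
    seq <- transcripts$cds_seq[i]
    tx_ref <- if (strand == "+") ref else comp_base(ref)
    tx_alt <- if (strand == "+") alt else comp_base(alt)
    if (substr(seq, cpos + 1, cpos + 1) != tx_ref) {
      abort(sprintf(
        "configuration error: transcript %s base at CDS pos %d != variant ref",
        transcripts$gene[i], cpos))
    }
    codon_i <- cpos %/% 3L
    codon <- substr(seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    mut <- codon
    substr(mut, cpos %% 3L + 1L, cpos %% 3L + 1L) <- tx_alt
    aa_ref <- gc[codon]
    aa_alt <- gc[mut]
    csq <- if (aa_ref == aa_alt) {
      "synonymous"
    } else if (aa_alt == "*" || aa_ref == "*" ||
               (codon_i == 0L && aa_ref == "M")) {
      "truncating"
    } else {
      "missense"
    }
    if (SEVERITY[csq] > SEVERITY[best$consequence]) {
      best <- list(consequence = csq, gene = transcripts$gene[i])
    }
  }
  best
}

#' Annotate a call set with coding consequences
#'
#' @param calls A call tibble.
#' @param transcripts A transcript tibble; validated before use.
#' @return `calls` with `consequence` and `gene` filled in.
#' @export
annotate_consequence <- function(calls, transcripts) {
  validate_transcripts(transcripts)
  if (nrow(calls) == 0) return(calls)
  res <- purrr::pmap(
    list(calls$chrom, calls$pos, calls$ref, calls$alt),
    classify_consequence, transcripts = transcripts)
  calls$consequence <- purrr::map_chr(res, "consequence")
  calls$gene <- purrr::map_chr(res, "gene")
  calls
}

#' Does a consequence label change the protein?
#'
#' @param label Consequence label(s).
#' @return `TRUE` for `missense` and `truncating`, `FALSE` for `synonymous`
#'   and `non_coding` (and `unassigned`).
#' @export
is_amino_acid_changing <- function(label) {
  label %in% c("missense", "truncating")
}

#' Write toy transcripts as a GFF-like TSV plus a CDS FASTA
#'
#' @param transcripts A transcript tibble.
#' @param gff_path,fasta_path Output paths: interval table (one row per CDS
#'   interval with its 5'->3' rank) and spliced CDS sequences.
#' @return `gff_path`, invisibly.
#' @export
write_transcripts <- function(transcripts, gff_path, fasta_path) {
  rows <- purrr::pmap(
    list(transcripts$gene, transcripts$chrom, transcripts$strand,
         transcripts$cds_starts, transcripts$cds_ends),
    function(g, ch, st, ss, ee) {
      tibble(gene = g, chrom = ch, strand = st, start = ss, end = ee,
             exon_rank = seq_along(ss))
    })
  readr::write_tsv(bind_rows(rows), gff_path, progress = FALSE)
  seqs <- Biostrings::DNAStringSet(transcripts$cds_seq)
  names(seqs) <- transcripts$gene
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(gff_path)
}

#' Read toy transcripts written by [write_transcripts()]
#'
#' @param gff_path,fasta_path Paths to the interval TSV and CDS FASTA.
#' @return A validated transcript tibble.
#' @export
read_transcripts <- function(gff_path, fasta_path) {
  iv <- readr::read_tsv(gff_path, show_col_types = FALSE, progress = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tx <- iv |>
    arrange(.data$gene, .data$exon_rank) |>
    group_by(.data$gene, .data$chrom, .data$strand) |>
    summarise(cds_starts = list(as.integer(.data$start)),
              cds_ends = list(as.integer(.data$end)), .groups = "drop")
  tx$cds_seq <- unname(as.character(seqs[tx$gene]))
  validate_transcripts(tx)
  tx
}
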