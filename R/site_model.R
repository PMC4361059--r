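#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

BASES <- c("A", "C", "G", "T")
COUNT_COLS <- paste0(rep(BASES, each = 2), "_", c("fwd", "rev"))
TUMOR_COLS <- paste0("tumor_", COUNT_COLS)
NORMAL_COLS <- paste0("normal_", COUNT_COLS)
FLAG_COLS <- c("low_mapability", "near_repeat", "known_variant")

# tags the primary caller treats as disqualifying vs the subclonal caller
PRIMARY_FAIL_TAGS <- c("LOW_DEPTH", "STRAND_BIAS", "LOW_MAPABILITY")
SUBCLONAL_FAIL_TAGS <- c("NEAR_REPEAT", "KNOWN_VARIANT", "READ_END_ONLY")
ALL_TAGS <- c(PRIMARY_FAIL_TAGS, "TAIL_BIAS", SUBCLONAL_FAIL_TAGS)

#' Construct a strand-aware allele count vector
#'
#' One site's allele counts for a single sample: forward- and reverse-strand
#' read counts for each of the four bases. This is the per-sample unit both
#' callers consume; its total is the read depth at the site.
#'
#' @param A_fwd,A_rev,C_fwd,C_rev,G_fwd,G_rev,T_fwd,T_rev Non-negative
#'   integer read counts per base and strand.
#' @return A named integer vector of length 8 (names `A_fwd` ... `T_rev`).
#' @examples
#' ac <- allele_counts(C_fwd = 48, C_rev = 42, T_fwd = 5, T_rev = 5)
#' sum(ac) # depth 100
#' @export
allele_counts <- function(A_fwd = 0, A_rev = 0, C_fwd = 0, C_rev = 0,
                          G_fwd = 0, G_rev = 0, T_fwd = 0, T_rev = 0) {
  x <- c(A_fwd = A_fwd, A_rev = A_rev, C_fwd = C_fwd, C_rev = C_rev,
         G_fwd = G_fwd, G_rev = G_rev, T_fwd = T_fwd, T_rev = T_rev)
  if (any(x < 0)) {
    bad <- names(x)[which(x < 0)[1]]
    abort(sprintf("allele counts must be non-negative (field '%s')", bad))
  }
  storage.mode(x) <- "integer"
  x
}

#' @noRd
base_total <- function(counts, base) {
  unname(counts[paste0(base, "_fwd")] + counts[paste0(base, "_rev")])
}

#' @noRd
counts_depth <- function(counts) sum(counts)

# Extract the 8-column strand count matrix for one sample from a pileup tibble.
#' @noRd
count_matrix <- function(pileup, sample = c("tumor", "normal")) {
  sample <- match.arg(sample)
  cols <- if (sample == "tumor") TUMOR_COLS else NORMAL_COLS
  m <- as.matrix(pileup[, cols, drop = FALSE])
  colnames(m) <- COUNT_COLS
  storage.mode(m) <- "integer"
  m
}

# 4-column (A,C,G,T) totals from an 8-column strand matrix.
#' @noRd
base_matrix <- function(m) {
  bt <- m[, paste0(BASES, "_fwd"), drop = FALSE] +
    m[, paste0(BASES, "_rev"), drop = FALSE]
  colnames(bt) <- BASES
  bt
}

#' @noRd
empty_pileup <- function() {
  out <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    tri_context = character()
  )
  for (cc in c(TUMOR_COLS, NORMAL_COLS)) out[[cc]] <- integer()
  out$low_mapability <- logical()
  out$near_repeat <- logical()
  out$known_variant <- logical()
  out$tumor_reads <- list()
  out$normal_reads <- list()
  out
}

#' @noRd
empty_calls <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    tri_context = character(), vaf_tumor = double(), vaf_normal = double(),
    fisher_p = double(), tags = character(), source = character(),
    consequence = character(), gene = character(), passed = logical()
  )
}

# A read-evidence record set: one data frame per site with columns
# base, base_quality, end_distance, strand, confirmed.
#' @noRd
read_evidence <- function(base = character(), base_quality = integer(),
                          end_distance = integer(), strand = character(),
                          confirmed = logical()) {
  data.frame(
    base = as.character(base),
    base_quality = as.integer(base_quality),
    end_distance = as.integer(end_distance),
    strand = as.character(strand),
    confirmed = as.logical(confirmed),
    stringsAsFactors = FALSE
  )
}

#' Validate a site pileup table
#'
#' Checks the structural invariants of a pileup tibble: all strand counts
#' non-negative, the reference base equal to the middle base of its
#' trinucleotide context, and -- where read-evidence lists are present --
#' that per-base counts derived from the reads never exceed the count
#' matrix (with full equality required when the list is complete, i.e. has
#' one row per read).
#'
#' @param pileup A pileup tibble as returned by [read_pileup_table()] or
#'   [simulate_patient()].
#' @return `pileup`, invisibly, if valid; otherwise an error naming the
#'   offending field and row.
#' @export
validate_pileup <- function(pileup) {
  needed <- c("chrom", "pos", "ref", "tri_context", TUMOR_COLS, NORMAL_COLS)
  missing <- setdiff(needed, names(pileup))
  if (length(missing) > 0) {
    abort(sprintf("pileup format error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  for (cc in c(TUMOR_COLS, NORMAL_COLS)) {
    bad <- which(pileup[[cc]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("validation error: negative count in field '%s' at row %d",
                    cc, bad[1]))
    }
  }
  mid <- substr(pileup$tri_context, 2, 2)
  bad <- which(nchar(pileup$tri_context) != 3 | mid != pileup$ref)
  if (length(bad) > 0) {
    abort(sprintf(
      "validation error: tri_context '%s' middle base != ref '%s' at row %d",
      pileup$tri_context[bad[1]], pileup$ref[bad[1]], bad[1]))
  }
  for (side in c("tumor", "normal")) {
    lc <- paste0(side, "_reads")
    if (!lc %in% names(pileup)) next
    m <- base_matrix(count_matrix(pileup, side))
    d <- rowSums(m)
    for (i in seq_len(nrow(pileup))) {
      rd <- pileup[[lc]][[i]]
      if (is.null(rd) || nrow(rd) == 0) next
      tab <- table(factor(rd$base, levels = BASES))
      if (any(tab > m[i, ])) {
        abort(sprintf(
          "validation error: %s read list exceeds counts at row %d", side, i))
      }
      if (nrow(rd) == d[i] && !all(tab == m[i, ])) {
        abort(sprintf(
          "validation error: complete %s read list inconsistent with counts at row %d",
          side, i))
      }
    }
  }
  invisible(pileup)
}

#' Read a pileup table
#'
#' Reads the tab-separated pileup dialect used throughout the package: one
#' row per genomic site with columns `chrom`, `pos` (1-based), `ref`,
#' `tri_context`, eight tumor strand counts (`tumor_A_fwd` ... `tumor_T_rev`),
#' eight normal strand counts, the mask flags `low_mapability`, `near_repeat`
#' and `known_variant` as 0/1, and optional JSON-encoded read-evidence
#' columns `tumor_reads` / `normal_reads`.
#'
#' @param path Path to a pileup TSV.
#' @return A pileup tibble with read-evidence list-columns (`NULL` entries
#'   where no evidence was recorded).
#' @seealso [write_pileup_table()], [validate_pileup()]
#' @export
read_pileup_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("pileup file not found: %s", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), ref = readr::col_character(),
    tri_context = readr::col_character(),
    tumor_reads = readr::col_character(), normal_reads = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  needed <- c("chrom", "pos", "ref", "tri_context", TUMOR_COLS, NORMAL_COLS)
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("pileup format error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  x$pos <- as.integer(x$pos)
  for (cc in c(TUMOR_COLS, NORMAL_COLS)) x[[cc]] <- as.integer(x[[cc]])
  for (fc in FLAG_COLS) {
    x[[fc]] <- if (fc %in% names(x)) as.logical(as.integer(x[[fc]])) else FALSE
  }
  for (side in c("tumor", "normal")) {
    lc <- paste0(side, "_reads")
    json <- if (lc %in% names(x)) x[[lc]] else rep(NA_character_, nrow(x))
    x[[lc]] <- purrr::map(json, function(s) {
      if (is.na(s) || !nzchar(s)) return(NULL)
      df <- jsonlite::fromJSON(s)
      read_evidence(df$base, df$base_quality, df$end_distance, df$strand,
                    df$confirmed)
    })
  }
  x <- x[, names(empty_pileup())]
  validate_pileup(x)
  x
}

#' Write a pileup table
#'
#' Inverse of [read_pileup_table()]; read-evidence list-columns are
#' JSON-encoded, `NULL` entries become empty fields.
#'
#' @param pileup A pileup tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_table <- function(pileup, path) {
  validate_pileup(pileup)
  out <- pileup
  for (fc in FLAG_COLS) out[[fc]] <- as.integer(out[[fc]])
  for (side in c("tumor", "normal")) {
    lc <- paste0(side, "_reads")
    out[[lc]] <- purrr::map_chr(pileup[[lc]], function(rd) {
      if (is.null(rd) || nrow(rd) == 0) return("")
      as.character(jsonlite::toJSON(rd, dataframe = "columns"))
    })
  }
  readr::write_tsv(out, path, progress = FALSE, quote = "none",
                   escape = "none")
  invisible(path)
}

#' Read and merge a BED interval mask
#'
#' Reads a 3+ column BED file (0-based, half-open), optionally pads each
#' interval by `flank` bp, sorts and merges overlapping intervals. A 1-based
#' position `p` is inside a region `[start, end)` iff `start < p <= end`.
#'
#' @param path Path to a BED file. An empty file yields a mask matching
#'   nothing.
#' @param flank Non-negative integer padding added to both sides of every
#'   interval before merging (used e.g. to flank repeat tracks).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   sorted and non-overlapping.
#' @export
read_bed_mask <- function(path, flank = 0) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    abort("BED format error: fewer than 3 columns")
  }
  bed <- tibble(
    chrom = purrr::map_chr(parts, 1),
    start = as.integer(purrr::map_chr(parts, 2)),
    end = as.integer(purrr::map_chr(parts, 3))
  )
  bad <- which(bed$start >= bed$end)
  if (length(bad) > 0) {
    abort(sprintf("validation error: start >= end on BED line %d", bad[1]))
  }
  bed$start <- pmax(0L, bed$start - as.integer(flank))
  bed$end <- bed$end + as.integer(flank)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  ))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  arrange(out, .data$chrom, .data$start)
}

#' Test 1-based positions for membership in a BED mask
#'
#' @param mask A mask tibble from [read_bed_mask()] (or any tibble with
#'   `chrom`, 0-based `start`, `end`).
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions.
#' @return A logical vector: `TRUE` where `start < pos <= end` for some
#'   region on the same chromosome.
#' @export
bed_member <- function(mask, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  if (nrow(mask) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(
    mask$chrom, IRanges::IRanges(mask$start + 1L, mask$end))
  suppressWarnings(IRanges::overlapsAny(q, s))
}

#' Set mask flags on a pileup from BED tracks
#'
#' @param pileup A pileup tibble.
#' @param mapability,repeats,known Optional mask tibbles from
#'   [read_bed_mask()] for low-mapability regions, DNA repeats and known
#'   germline variants (dbSNP/1000 Genomes-style tracks). `NULL` leaves the
#'   corresponding flag untouched.
#' @return The pileup with `low_mapability`, `near_repeat`, `known_variant`
#'   updated.
#' @export
flag_sites <- function(pileup, mapability = NULL, repeats = NULL, known = NULL) {
  if (!is.null(mapability)) {
    pileup$low_mapability <- bed_member(mapability, pileup$chrom, pileup$pos)
  }
  if (!is.null(repeats)) {
    pileup$near_repeat <- bed_member(repeats, pileup$chrom, pileup$pos)
  }
  if (!is.null(known)) {
    pileup$known_variant <- bed_member(known, pileup$chrom, pileup$pos)
  }
  pileup
}

#' @noRd
join_tags <- function(tag_list) {
  purrr::map_chr(tag_list, function(t) paste(sort(unique(t)), collapse = ";"))
}

#' @noRd
split_tags <- function(tags) {
  purrr::map(tags, function(t) {
    if (is.na(t) || !nzchar(t)) character() else strsplit(t, ";", fixed = TRUE)[[1]]
  })
}

#' @noRd
recompute_passed <- function(tags, source) {
  fail <- ifelse(source == "subclonal",
                 list(SUBCLONAL_FAIL_TAGS), list(PRIMARY_FAIL_TAGS))
  purrr::map2_lgl(split_tags(tags), fail, function(t, f) !any(t %in% f))
}

#' Write a lesion call set as VCF 4.2
#'
#' One data line per call; disqualifying and annotate-only tags appear in
#' FILTER (`PASS` when no tag is set), per-call quantities in INFO
#' (`VAFT`, `VAFN`, `FP`, `SRC`, `CSQ`, `GENE`, `TRI`). Lesion and patient
#' identifiers are carried as `##lesion_id=` / `##patient_id=` header lines.
#'
#' @param calls A call tibble (see [call_primary()]).
#' @param path Output path.
#' @param lesion_id,patient_id Identifiers recorded in the header; default to
#'   `calls$lesion_id[1]` / `calls$patient_id[1]` when present.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, lesion_id = NULL, patient_id = NULL) {
  if (is.null(lesion_id)) {
    lesion_id <- if ("lesion_id" %in% names(calls) && nrow(calls) > 0)
      calls$lesion_id[1] else "lesion"
  }
  if (is.null(patient_id)) {
    patient_id <- if ("patient_id" %in% names(calls) && nrow(calls) > 0)
      calls$patient_id[1] else "patient"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutmosaic",
    sprintf("##lesion_id=%s", lesion_id),
    sprintf("##patient_id=%s", patient_id),
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", ALL_TAGS, ALL_TAGS),
    "##INFO=<ID=VAFT,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=VAFN,Number=1,Type=Float,Description=\"Normal variant allele fraction\">",
    "##INFO=<ID=FP,Number=1,Type=Float,Description=\"Tumor-normal Fisher exact p\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Caller: primary or subclonal\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Coding consequence\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=TRI,Number=1,Type=String,Description=\"Reference trinucleotide context\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.8g", x))
  fmt_chr <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)
  rows <- character(0)
  if (nrow(calls) > 0) {
    filt <- ifelse(nzchar(calls$tags), calls$tags, "PASS")
    info <- sprintf(
      "VAFT=%s;VAFN=%s;FP=%s;SRC=%s;CSQ=%s;GENE=%s;TRI=%s",
      fmt_num(calls$vaf_tumor), fmt_num(calls$vaf_normal),
      fmt_num(calls$fisher_p), fmt_chr(calls$source),
      fmt_chr(calls$consequence), fmt_chr(calls$gene),
      fmt_chr(calls$tri_context))
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                    calls$chrom, calls$pos, calls$ref, calls$alt, filt, info)
  }
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("I/O error: cannot write VCF to %s", path))
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into a call tibble
#'
#' @param path Path to a VCF 4.2 file.
#' @return A call tibble; `passed` is recomputed from the FILTER tags using
#'   the caller-specific disqualifying sets.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^##%s=", key), meta, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub(sprintf("^##%s=", key), "", hit[1])
  }
  lesion_id <- get_meta("lesion_id")
  patient_id <- get_meta("patient_id")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    out <- empty_calls()
    out$lesion_id <- character()
    out$patient_id <- character()
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(sprintf("(?<=^|;)%s=[^;]*", key), info,
                                  perl = TRUE))
    v <- sub(sprintf("^%s=", key), "", m)
    if (length(v) == 0 || v == ".") NA_character_ else v
  }
  info <- purrr::map_chr(f, 8)
  filt <- purrr::map_chr(f, 7)
  tags <- ifelse(filt == "PASS" | filt == ".", "", filt)
  src <- purrr::map_chr(info, info_get, key = "SRC")
  out <- tibble(
    chrom = purrr::map_chr(f, 1),
    pos = as.integer(purrr::map_chr(f, 2)),
    ref = purrr::map_chr(f, 4),
    alt = purrr::map_chr(f, 5),
    tri_context = purrr::map_chr(info, info_get, key = "TRI"),
    vaf_tumor = as.numeric(purrr::map_chr(info, info_get, key = "VAFT")),
    vaf_normal = as.numeric(purrr::map_chr(info, info_get, key = "VAFN")),
    fisher_p = as.numeric(purrr::map_chr(info, info_get, key = "FP")),
    tags = tags,
    source = src,
    consequence = purrr::map_chr(info, info_get, key = "CSQ"),
    gene = purrr::map_chr(info, info_get, key = "GENE"),
    passed = recompute_passed(tags, src),
    lesion_id = lesion_id,
    patient_id = patient_id
  )
  out
}
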