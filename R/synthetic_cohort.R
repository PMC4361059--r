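# Synthetic paired tumor/normal exome-like cohort generator.
#
# Emulates the data structure of a multi-lesion study: per patient one
# normal sample plus N lesions, clonal (~50% VAF) and subclonal somatic
# mutations drawn independently per lesion, germline SNPs shared by all
# samples, binomially sampled strand-aware read counts with sequencing
# error, and two injected artifact classes (one-strand alt reads; alt
# reads confined to read ends).

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' @noRd
comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' @noRd
revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulation parameters for a synthetic multi-lesion cohort
#'
#' Defaults emulate the study design the package targets: exome-like mean
#' coverage of 99X with moderate per-site overdispersion, clonal somatic
#' mutations at 50% VAF, a subclonal compartment uniform in 5--25% VAF,
#' somatic mutation sets drawn independently per lesion (no sharing by
#' default), a C>T/G>A-dominated substitution spectrum with 75% of C>T
#' events at CpG dimers, and low-rate sequencing error plus strand-bias and
#' read-end alignment artifacts.
#'
#' @param n_patients Number of patients in the cohort.
#' @param lesions_per_patient Lesions (tumor samples) per patient; each is
#'   paired with the patient's single normal sample.
#' @param n_sites Number of simulated target positions per patient (one
#'   contiguous synthetic chromosome).
#' @param target_mb Effective target size in Mb used as the mutational-index
#'   denominator in downstream metrics.
#' @param depth_mean_tumor,depth_mean_normal Mean per-site read depth.
#' @param depth_overdispersion Negative-binomial overdispersion phi
#'   (variance = mu + phi * mu^2) of per-site depths.
#' @param clonal_vaf True variant allele fraction of clonal somatic
#'   mutations.
#' @param subclonal_vaf_range Length-2 numeric; subclonal true VAFs are
#'   uniform on this interval, which must lie inside (0, clonal_vaf).
#' @param fraction_subclonal Fraction of somatic mutations that are
#'   subclonal.
#' @param somatic_rate Per-site somatic mutation probability per lesion.
#' @param shared_fraction Probability that a somatic mutation is copied into
#'   one other lesion of the same patient (0 = fully independent lesions).
#' @param germline_rate Per-site germline variant probability (VAF 0.5 or
#'   1.0; present in normal and all lesions, flagged as known variants).
#' @param error_rate Per-read sequencing error probability.
#' @param strand_bias_artifact_rate,read_end_artifact_rate Per-site rates of
#'   injected artifact sites in each tumor sample.
#' @param strand_artifact_vaf Alt fraction at strand-bias artifact sites
#'   (all alt reads on one strand); the default 0.5 emulates a mismapped
#'   paralog carrying a heterozygous variant, the classic source of
#'   one-strand artifact calls.
#' @param read_end_artifact_vaf Alt fraction at read-end artifact sites.
#' @param read_end_artifact_max_dist Maximum end distance (bp) of alt reads
#'   at read-end artifact sites; keep below the subclonal caller's
#'   end-exclusion bound.
#' @param amplicon_depth_mean Mean depth of simulated validation amplicons.
#' @param amplicon_overdispersion Negative-binomial phi for amplicon depths.
#' @param spectrum_weights Named numeric over the six collapsed substitution
#'   classes; sampling weights of somatic mutation classes.
#' @param cpg_fraction Fraction of C>T/G>A somatic mutations placed at CpG
#'   dimers.
#' @param n_genes Number of toy transcripts placed on the synthetic
#'   chromosome (default scales with `n_sites`).
#' @param read_len Read length (bp); end distances are uniform on
#'   `0:((read_len - 1) %/% 2)` for genuine reads.
#' @param seed Global seed; per-patient seeds are spawned from it by fixed
#'   arithmetic (see [simulate_cohort()]).
#' @return A validated `mutmosaic_sim_params` list.
#' @export
sim_params <- function(n_patients = 4,
                       lesions_per_patient = 3,
                       n_sites = 20000,
                       target_mb = 30,
                       depth_mean_tumor = 99,
                       depth_mean_normal = 99,
                       depth_overdispersion = 0.04,
                       clonal_vaf = 0.5,
                       subclonal_vaf_range = c(0.05, 0.25),
                       fraction_subclonal = 0.6,
                       somatic_rate = 0.003,
                       shared_fraction = 0,
                       germline_rate = 0.001,
                       error_rate = 0.001,
                       strand_bias_artifact_rate = 5e-4,
                       read_end_artifact_rate = 5e-4,
                       strand_artifact_vaf = 0.5,
                       read_end_artifact_vaf = 0.05,
                       read_end_artifact_max_dist = 3,
                       amplicon_depth_mean = 600,
                       amplicon_overdispersion = 0.05,
                       spectrum_weights = c("C>A" = 0.10, "C>G" = 0.06,
                                            "C>T" = 0.60, "T>A" = 0.06,
                                            "T>C" = 0.12, "T>G" = 0.06),
                       cpg_fraction = 0.75,
                       n_genes = NULL,
                       read_len = 75,
                       seed = 1) {
  p <- list(
    n_patients = n_patients, lesions_per_patient = lesions_per_patient,
    n_sites = n_sites, target_mb = target_mb,
    depth_mean_tumor = depth_mean_tumor,
    depth_mean_normal = depth_mean_normal,
    depth_overdispersion = depth_overdispersion,
    clonal_vaf = clonal_vaf, subclonal_vaf_range = subclonal_vaf_range,
    fraction_subclonal = fraction_subclonal, somatic_rate = somatic_rate,
    shared_fraction = shared_fraction, germline_rate = germline_rate,
    error_rate = error_rate,
    strand_bias_artifact_rate = strand_bias_artifact_rate,
    read_end_artifact_rate = read_end_artifact_rate,
    strand_artifact_vaf = strand_artifact_vaf,
    read_end_artifact_vaf = read_end_artifact_vaf,
    read_end_artifact_max_dist = read_end_artifact_max_dist,
    amplicon_depth_mean = amplicon_depth_mean,
    amplicon_overdispersion = amplicon_overdispersion,
    spectrum_weights = spectrum_weights, cpg_fraction = cpg_fraction,
    n_genes = if (is.null(n_genes)) max(1L, n_sites %/% 600L) else n_genes,
    read_len = read_len, seed = seed
  )
  rates <- c("fraction_subclonal", "somatic_rate", "shared_fraction",
             "germline_rate", "error_rate", "strand_bias_artifact_rate",
             "read_end_artifact_rate", "strand_artifact_vaf",
             "read_end_artifact_vaf", "cpg_fraction", "clonal_vaf")
  for (r in rates) {
    if (p[[r]] < 0 || p[[r]] > 1) {
      abort(sprintf("sim_params: '%s' must be in [0, 1]", r))
    }
  }
  if (p$depth_mean_tumor <= 0 || p$depth_mean_normal <= 0 ||
      p$amplicon_depth_mean <= 0) {
    abort("sim_params: depth means must be > 0")
  }
  if (length(p$subclonal_vaf_range) != 2 ||
      p$subclonal_vaf_range[1] <= 0 ||
      p$subclonal_vaf_range[2] >= p$clonal_vaf ||
      p$subclonal_vaf_range[1] > p$subclonal_vaf_range[2]) {
    abort("sim_params: subclonal_vaf_range must lie within (0, clonal_vaf)")
  }
  if (!setequal(names(p$spectrum_weights), SUB_CLASSES)) {
    abort("sim_params: spectrum_weights must name the six collapsed classes")
  }
  if (p$n_sites < 100) abort("sim_params: n_sites too small (< 100)")
  structure(p, class = "mutmosaic_sim_params")
}

# Fixed arithmetic spawning per-patient seeds from the global seed, kept
# inside 32-bit integer range.
#' @noRd
spawn_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 104729) %% 2147483587)
}

# Run fn with a private, restored-after RNG stream.
#' @noRd
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Simulate toy transcripts on a synthetic chromosome
#'
#' Places non-overlapping toy CDS models (one or two exons, either strand)
#' along a reference base vector, overwriting the start codon to ATG and the
#' final codon to TAA so the transcript invariants hold. Consumes the
#' current RNG stream.
#'
#' @param genome Character vector of reference bases covering positions
#'   0..n_sites+1 (index `p + 1` is position `p`).
#' @param params A [sim_params()] object.
#' @param chrom Chromosome name.
#' @return A list with `transcripts` (tibble: `gene`, `chrom`, `strand`,
#'   list-columns `cds_starts` / `cds_ends` in 0-based half-open
#'   coordinates ordered 5'->3', and `cds_seq`) and the updated `genome`.
#' @export
simulate_transcripts <- function(genome, params, chrom = "chr1") {
  n_sites <- params$n_sites
  cursor <- 1L
  rows <- list()
  for (g in seq_len(params$n_genes)) {
    gap <- sample(50:200, 1)
    cds_len <- 3L * sample(50:120, 1)
    two_exon <- stats::runif(1) < 0.3
    intron <- if (two_exon) sample(20:60, 1) else 0L
    start <- cursor + gap
    if (start + cds_len + intron > n_sites) break
    if (two_exon) {
      split_at <- 3L * sample(10:(cds_len %/% 3L - 10L), 1)
      starts <- c(start, start + split_at + intron)
      ends <- c(start + split_at, start + cds_len + intron)
    } else {
      starts <- start
      ends <- start + cds_len
    }
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") {
      ord <- rev(seq_along(starts))
      starts <- starts[ord]
      ends <- ends[ord]
    }
    # overwrite first codon -> ATG, last codon -> TAA (transcript frame)
    first3 <- vapply(0:2, function(c) tx_to_genomic(starts, ends, strand, c),
                     integer(1))
    last3 <- vapply((cds_len - 3L):(cds_len - 1L),
                    function(c) tx_to_genomic(starts, ends, strand, c),
                    integer(1))
    set_tx_base <- function(gpos, b) {
      genome[gpos + 1L] <<- if (strand == "+") b else comp_base(b)
    }
    purrr::walk2(first3, c("A", "T", "G"), set_tx_base)
    purrr::walk2(last3, c("T", "A", "A"), set_tx_base)
    rows[[length(rows) + 1L]] <- tibble(
      gene = sprintf("GENE%03d", g), chrom = chrom, strand = strand,
      cds_starts = list(as.integer(starts)), cds_ends = list(as.integer(ends))
    )
    cursor <- max(ends) + 1L
  }
  tx <- bind_rows(rows)
  if (nrow(tx) == 0) {
    tx <- tibble(gene = character(), chrom = character(),
                 strand = character(), cds_starts = list(),
                 cds_ends = list(), cds_seq = character())
    return(list(transcripts = tx, genome = genome))
  }
  tx$cds_seq <- purrr::pmap_chr(
    list(tx$cds_starts, tx$cds_ends, tx$strand),
    function(s, e, st) spliced_seq(genome, s, e, st))
  list(transcripts = tx, genome = genome)
}

# Genomic 1-based position of transcript (0-based) CDS coordinate c.
# Exons are stored 5'->3' in transcript order.
#' @noRd
tx_to_genomic <- function(starts, ends, strand, c) {
  lens <- ends - starts
  cum <- cumsum(lens)
  ex <- which(c < cum)[1]
  off <- c - c(0L, cum)[ex]
  if (strand == "+") {
    as.integer(starts[ex] + off + 1L)
  } else {
    as.integer(ends[ex] - off)
  }
}

#' @noRd
spliced_seq <- function(genome, starts, ends, strand) {
  if (strand == "+") {
    paste(unlist(purrr::map2(starts, ends,
                             function(s, e) genome[(s + 1L):e + 1L])),
          collapse = "")
  } else {
    # exons already 5'->3' in transcript order (descending genomic)
    paste(unlist(purrr::map2(starts, ends, function(s, e) {
      rev(comp_base(genome[(s + 1L):e + 1L]))
    })), collapse = "")
  }
}

# Sample strand-aware counts for one sample over all sites.
# variants: tibble(pos, alt, vaf). Returns count matrix plus alt metadata.
#' @noRd
sample_counts <- function(ref, depth, variants, error_rate) {
  n <- length(ref)
  alt_base <- rep(NA_character_, n)
  alt_k <- integer(n)
  if (nrow(variants) > 0) {
    p <- variants$vaf * (1 - error_rate) + (1 - variants$vaf) * error_rate / 3
    alt_k[variants$pos] <- stats::rbinom(nrow(variants), depth[variants$pos], p)
    alt_base[variants$pos] <- variants$alt
  }
  other <- setdiff(seq_len(n), variants$pos)
  if (error_rate > 0 && length(other) > 0) {
    ek <- stats::rbinom(length(other), depth[other], error_rate)
    hit <- other[ek > 0]
    if (length(hit) > 0) {
      alt_k[hit] <- ek[ek > 0]
      # one error base per site, uniform over the three non-reference bases
      shift <- sample(1:3, length(hit), replace = TRUE)
      alt_base[hit] <- BASES[(match(ref[hit], BASES) - 1L + shift) %% 4L + 1L]
    }
  }
  ref_k <- depth - alt_k
  ref_fwd <- stats::rbinom(n, ref_k, 0.5)
  alt_fwd <- stats::rbinom(n, alt_k, 0.5)
  list(alt_base = alt_base, alt_k = alt_k, alt_fwd = alt_fwd,
       ref_fwd = ref_fwd, depth = depth)
}

#' @noRd
counts_to_matrix <- function(ref, cs) {
  n <- length(ref)
  m <- matrix(0L, n, 8, dimnames = list(NULL, COUNT_COLS))
  ri <- match(ref, BASES)
  idx <- seq_len(n)
  m[cbind(idx, 2L * ri - 1L)] <- cs$ref_fwd
  m[cbind(idx, 2L * ri)] <- (cs$depth - cs$alt_k) - cs$ref_fwd
  has <- which(cs$alt_k > 0)
  if (length(has) > 0) {
    ai <- match(cs$alt_base[has], BASES)
    m[cbind(has, 2L * ai - 1L)] <- m[cbind(has, 2L * ai - 1L)] + cs$alt_fwd[has]
    m[cbind(has, 2L * ai)] <- m[cbind(has, 2L * ai)] +
      (cs$alt_k[has] - cs$alt_fwd[has])
  }
  m
}

# Build per-site read-evidence lists for one sample.
# full_idx: sites where ref reads are also materialised (complete lists);
# true_idx: sites whose alt reads are genuine mutations (confirmed=TRUE,
# high quality); end_idx: read-end artifact sites.
#' @noRd
build_evidence <- function(ref, cs, full_idx, true_idx, end_idx, params) {
  n <- length(ref)
  out <- vector("list", n)
  max_d <- (params$read_len - 1L) %/% 2L
  alt_sites <- which(cs$alt_k > 0)
  pieces <- list()
  if (length(alt_sites) > 0) {
    k <- cs$alt_k[alt_sites]
    site <- rep(alt_sites, k)
    is_true <- site %in% true_idx
    is_end <- site %in% end_idx
    strand <- unlist(purrr::map2(cs$alt_fwd[alt_sites], k, function(f, kk) {
      c(rep("forward", f), rep("reverse", kk - f))
    }))
    pieces$alt <- data.frame(
      site = site,
      base = rep(cs$alt_base[alt_sites], k),
      base_quality = ifelse(is_true,
                            sample(30:40, length(site), replace = TRUE),
                            sample(15:35, length(site), replace = TRUE)),
      end_distance = ifelse(is_end,
                            sample(0:params$read_end_artifact_max_dist,
                                   length(site), replace = TRUE),
                            sample(0:max_d, length(site), replace = TRUE)),
      strand = strand,
      confirmed = is_true | stats::runif(length(site)) < 0.5,
      stringsAsFactors = FALSE
    )
  }
  full_idx <- intersect(full_idx, seq_len(n))
  if (length(full_idx) > 0) {
    rk <- cs$depth[full_idx] - cs$alt_k[full_idx]
    keep <- rk > 0
    fi <- full_idx[keep]
    rk <- rk[keep]
    if (length(fi) > 0) {
      site <- rep(fi, rk)
      strand <- unlist(purrr::map2(cs$ref_fwd[fi], rk, function(f, kk) {
        c(rep("forward", f), rep("reverse", kk - f))
      }))
      pieces$ref <- data.frame(
        site = site,
        base = rep(ref[fi], rk),
        base_quality = sample(30:40, length(site), replace = TRUE),
        end_distance = sample(0:max_d, length(site), replace = TRUE),
        strand = strand,
        confirmed = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(pieces) == 0) return(out)
  df <- do.call(rbind, pieces)
  rownames(df) <- NULL
  by_site <- split(df[, -1], df$site)
  idx <- as.integer(names(by_site))
  for (j in seq_along(idx)) {
    rd <- by_site[[j]]
    rownames(rd) <- NULL
    out[[idx[j]]] <- rd
  }
  out
}

#' Simulate one patient: matched normal plus N lesions
#'
#' Generates a synthetic chromosome with toy transcripts, germline variants
#' (shared across all samples, VAF 0.5 or 1.0), independent somatic
#' mutation sets per lesion (positions drawn without replacement across
#' sibling lesions; a `shared_fraction` of mutations is additionally copied
#' into one sibling), negative-binomial per-site depths, binomial
#' strand-split read counts with sequencing error, and injected strand-bias
#' and read-end artifact sites in each tumor sample. Deterministic given
#' `(params, patient_seed)`.
#'
#' @param params A [sim_params()] object.
#' @param patient_seed Integer seed for this patient (see [simulate_cohort()]
#'   for the spawning rule).
#' @param patient_id Identifier stamped on outputs.
#' @param read_evidence Generate per-read evidence lists (required by the
#'   subclonal caller; lists are complete at mutation/artifact sites,
#'   alt-only elsewhere). Set `FALSE` for count-only cohorts.
#' @return A list with `truth` (per-lesion somatic ground truth: `lesion_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `true_vaf`, `clonality`, `shared`,
#'   `tumor_depth`), `germline`, `transcripts`, `pileups` (named list of
#'   pileup tibbles, one per lesion, all sharing the patient's normal
#'   counts), `artifact_sites` (per lesion, with `kind`), and `params`.
#' @export
simulate_patient <- function(params, patient_seed,
                             patient_id = "P1", read_evidence = TRUE) {
  stopifnot(inherits(params, "mutmosaic_sim_params"))
  with_seed(patient_seed, function() {
    n <- params$n_sites
    chrom <- "chr1"
    genome <- sample(BASES, n + 2L, replace = TRUE)
    txres <- simulate_transcripts(genome, params, chrom)
    genome <- txres$genome
    ref <- genome[seq_len(n) + 1L]
    tri <- paste0(genome[seq_len(n)], ref, genome[seq_len(n) + 2L])

    # masks: a handful of random low-mapability and repeat intervals
    mk_mask <- function(frac) {
      covered <- logical(n)
      total <- round(frac * n)
      while (sum(covered) < total) {
        w <- sample(20:80, 1)
        s <- sample(seq_len(n - w), 1)
        covered[s:(s + w - 1L)] <- TRUE
      }
      covered
    }
    low_map <- mk_mask(0.01)
    near_rep <- mk_mask(0.01)

    # germline variants: present in every sample
    n_g <- stats::rbinom(1, n, params$germline_rate)
    g_pos <- sort(sample(which(!low_map & !near_rep), n_g))
    g_ref <- ref[g_pos]
    g_alt <- BASES[(match(g_ref, BASES) - 1L +
                      sample(1:3, n_g, replace = TRUE)) %% 4L + 1L]
    germline <- tibble(
      chrom = chrom, pos = g_pos, ref = g_ref, alt = g_alt,
      true_vaf = ifelse(stats::runif(n_g) < 2 / 3, 0.5, 1.0)
    )
    known_var <- logical(n)
    known_var[g_pos] <- TRUE

    # eligible somatic positions: unmasked, non-germline, sampled without
    # replacement across sibling lesions so truth sets are disjoint by
    # construction when shared_fraction = 0
    pool <- which(!low_map & !near_rep & !known_var)
    is_cpg_site <- (ref == "C" & genome[seq_len(n) + 2L] == "G") |
      (ref == "G" & genome[seq_len(n)] == "C")

    L <- params$lesions_per_patient
    lesion_ids <- sprintf("%s_L%d", patient_id, seq_len(L))
    truth_list <- list()
    for (l in seq_len(L)) {
      n_m <- stats::rpois(1, params$somatic_rate * n)
      n_m <- min(n_m, length(pool))
      if (length(pool) < n_m) {
        abort("configuration error: n_sites too small for requested variants")
      }
      cls <- sample(SUB_CLASSES, n_m, replace = TRUE,
                    prob = params$spectrum_weights)
      at_cpg <- cls == "C>T" & stats::runif(n_m) < params$cpg_fraction
      pos <- integer(n_m)
      alt <- character(n_m)
      for (i in seq_len(n_m)) {
        from <- substr(cls[i], 1, 1)
        to <- substr(cls[i], 3, 3)
        cand <- if (at_cpg[i]) {
          pool[is_cpg_site[pool]]
        } else if (cls[i] == "C>T") {
          pool[ref[pool] %in% c(from, comp_base(from)) & !is_cpg_site[pool]]
        } else {
          pool[ref[pool] %in% c(from, comp_base(from))]
        }
        if (length(cand) == 0) cand <- pool
        pos[i] <- cand[sample.int(length(cand), 1)]
        alt[i] <- if (ref[pos[i]] == from) to else comp_base(to)
        if (ref[pos[i]] != from && ref[pos[i]] != comp_base(from)) {
          # fallback position of another ref base: any non-ref alt
          alt[i] <- BASES[(match(ref[pos[i]], BASES) %% 4L) + 1L]
        }
        pool <- pool[pool != pos[i]]
      }
      subcl <- stats::runif(n_m) < params$fraction_subclonal
      vaf <- ifelse(subcl,
                    stats::runif(n_m, params$subclonal_vaf_range[1],
                                 params$subclonal_vaf_range[2]),
                    params$clonal_vaf)
      truth_list[[l]] <- tibble(
        lesion_id = rep(lesion_ids[l], n_m), chrom = rep(chrom, n_m),
        pos = pos, ref = ref[pos], alt = alt, true_vaf = as.numeric(vaf),
        clonality = as.character(ifelse(subcl, "subclonal", "clonal")),
        shared = rep(FALSE, n_m)
      )
    }
    # sharing: copy a fraction of each lesion's mutations into one sibling
    if (params$shared_fraction > 0 && L >= 2) {
      for (l in seq_len(L)) {
        tl <- truth_list[[l]]
        take <- stats::runif(nrow(tl)) < params$shared_fraction
        for (i in which(take)) {
          others <- setdiff(seq_len(L), l)
          tgt <- others[sample.int(length(others), 1)]
          if (!tl$pos[i] %in% truth_list[[tgt]]$pos) {
            row <- tl[i, ]
            row$lesion_id <- lesion_ids[tgt]
            row$shared <- TRUE
            truth_list[[tgt]] <- bind_rows(truth_list[[tgt]], row)
            truth_list[[l]]$shared[i] <- TRUE
          }
        }
      }
    }

    # normal sample counts, shared by all pairings
    size <- 1 / params$depth_overdispersion
    depth_n <- stats::rnbinom(n, mu = params$depth_mean_normal, size = size)
    gvars <- tibble(pos = germline$pos, alt = germline$alt,
                    vaf = germline$true_vaf)
    cs_n <- sample_counts(ref, depth_n, gvars, params$error_rate)
    mat_n <- counts_to_matrix(ref, cs_n)
    ev_n <- if (read_evidence) {
      build_evidence(ref, cs_n, full_idx = germline$pos,
                     true_idx = germline$pos, end_idx = integer(),
                     params = params)
    } else NULL

    pileups <- list()
    artifact_list <- list()
    for (l in seq_len(L)) {
      tl <- truth_list[[l]]
      depth_t <- stats::rnbinom(n, mu = params$depth_mean_tumor, size = size)
      # guarantee depth at truth sites never collapses to zero
      zero_fix <- c(tl$pos, germline$pos)
      depth_t[zero_fix] <- pmax(depth_t[zero_fix], 1L)
      vars <- bind_rows(
        tibble(pos = tl$pos, alt = tl$alt, vaf = tl$true_vaf),
        gvars
      )
      cs_t <- sample_counts(ref, depth_t, vars, params$error_rate)

      # artifact injection at non-variant, unmasked sites
      free <- setdiff(which(!low_map & !near_rep & !known_var), vars$pos)
      n_sb <- stats::rbinom(1, n, params$strand_bias_artifact_rate)
      n_re <- stats::rbinom(1, n, params$read_end_artifact_rate)
      art <- sample(free, min(n_sb + n_re, length(free)))
      sb_idx <- utils::head(art, n_sb)
      re_idx <- utils::tail(art, length(art) - length(sb_idx))
      inject <- function(idx, vaf, one_strand) {
        for (s in idx) {
          k <- stats::rbinom(1, depth_t[s], vaf)
          if (k == 0) next
          cs_t$alt_k[s] <<- k
          cs_t$alt_base[s] <<- BASES[(match(ref[s], BASES) %% 4L) + 1L]
          cs_t$alt_fwd[s] <<- if (one_strand) {
            if (stats::runif(1) < 0.5) k else 0L
          } else {
            stats::rbinom(1, k, 0.5)
          }
          cs_t$ref_fwd[s] <<- stats::rbinom(1, depth_t[s] - k, 0.5)
        }
      }
      inject(sb_idx, params$strand_artifact_vaf, one_strand = TRUE)
      inject(re_idx, params$read_end_artifact_vaf, one_strand = FALSE)
      mat_t <- counts_to_matrix(ref, cs_t)

      ev_t <- if (read_evidence) {
        build_evidence(ref, cs_t,
                       full_idx = c(tl$pos, germline$pos, sb_idx, re_idx),
                       true_idx = c(tl$pos, germline$pos),
                       end_idx = re_idx, params = params)
      } else NULL

      pu <- tibble(chrom = chrom, pos = seq_len(n), ref = ref,
                   tri_context = tri)
      for (j in seq_along(COUNT_COLS)) pu[[TUMOR_COLS[j]]] <- mat_t[, j]
      for (j in seq_along(COUNT_COLS)) pu[[NORMAL_COLS[j]]] <- mat_n[, j]
      pu$low_mapability <- low_map
      pu$near_repeat <- near_rep
      pu$known_variant <- known_var
      pu$tumor_reads <- if (is.null(ev_t)) vector("list", n) else ev_t
      pu$normal_reads <- if (is.null(ev_n)) vector("list", n) else ev_n
      pileups[[lesion_ids[l]]] <- pu

      truth_list[[l]]$tumor_depth <- depth_t[truth_list[[l]]$pos]
      artifact_list[[l]] <- tibble(
        lesion_id = lesion_ids[l], chrom = chrom,
        pos = c(sb_idx, re_idx),
        kind = rep(c("strand_bias", "read_end"),
                   c(length(sb_idx), length(re_idx))))
    }

    list(
      patient_id = patient_id,
      truth = bind_rows(truth_list),
      germline = germline,
      transcripts = txres$transcripts,
      pileups = pileups,
      artifact_sites = bind_rows(artifact_list),
      params = params
    )
  })
}

#' Simulate a full cohort of patients
#'
#' Per-patient seeds are spawned from `params$seed` by the fixed rule
#' `(seed * 48271 + i * 104729) mod 2147483587`, so any single patient can
#' be regenerated in isolation.
#'
#' @param params A [sim_params()] object.
#' @param read_evidence Passed to [simulate_patient()].
#' @return A list of patient objects (see [simulate_patient()]), named
#'   `P1` ... `Pn`.
#' @export
simulate_cohort <- function(params, read_evidence = TRUE) {
  stopifnot(inherits(params, "mutmosaic_sim_params"))
  out <- purrr::map(seq_len(params$n_patients), function(i) {
    simulate_patient(params, spawn_seed(params$seed, i),
                     patient_id = sprintf("P%d", i),
                     read_evidence = read_evidence)
  })
  names(out) <- sprintf("P%d", seq_len(params$n_patients))
  out
}

#' Simulate paired amplicon counts for one candidate variant
#'
#' Deep targeted resequencing emulation: amplicon depths are drawn around
#' `amplicon_depth_mean`, the tumor mutant count is binomial at the true
#' VAF (plus error), the normal mutant count is binomial at the error rate.
#'
#' @param truth_vaf True variant allele fraction in the tumor (0 for a
#'   false-positive candidate).
#' @param params A [sim_params()] object.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @param ref,alt Reference and alternate bases.
#' @return A list with `tumor` and `normal` [allele_counts()] vectors plus
#'   `ref` and `alt`.
#' @export
simulate_amplicon_counts <- function(truth_vaf, params, seed,
                                     ref = "C", alt = "T") {
  stopifnot(truth_vaf >= 0, truth_vaf <= 1)
  with_seed(seed, function() {
    size <- 1 / params$amplicon_overdispersion
    d_t <- stats::rnbinom(1, mu = params$amplicon_depth_mean, size = size)
    d_n <- stats::rnbinom(1, mu = params$amplicon_depth_mean, size = size)
    p_t <- truth_vaf * (1 - params$error_rate) +
      (1 - truth_vaf) * params$error_rate / 3
    k_t <- stats::rbinom(1, d_t, p_t)
    k_n <- stats::rbinom(1, d_n, params$error_rate / 3)
    mk <- function(d, k) {
      args <- stats::setNames(as.list(integer(8)), COUNT_COLS)
      rf <- stats::rbinom(1, d - k, 0.5)
      af <- stats::rbinom(1, k, 0.5)
      args[[paste0(ref, "_fwd")]] <- rf
      args[[paste0(ref, "_rev")]] <- (d - k) - rf
      args[[paste0(alt, "_fwd")]] <- af
      args[[paste0(alt, "_rev")]] <- k - af
      do.call(allele_counts, args)
    }
    list(tumor = mk(d_t, k_t), normal = mk(d_n, k_n), ref = ref, alt = alt)
  })
}

#' Write ground-truth tables for a simulated patient
#'
#' One TSV per lesion (`truth_<lesion_id>.tsv`) plus `germline.tsv`;
#' round-trips through [read_truth_tables()].
#'
#' @param patient A patient object from [simulate_patient()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_tables <- function(patient, dir) {
  ok <- tryCatch({
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !dir.exists(dir)) {
    abort(sprintf("I/O error: cannot create directory %s", dir))
  }
  for (lid in unique(patient$truth$lesion_id)) {
    readr::write_tsv(filter(patient$truth, .data$lesion_id == lid),
                     file.path(dir, sprintf("truth_%s.tsv", lid)),
                     progress = FALSE)
  }
  readr::write_tsv(patient$germline, file.path(dir, "germline.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read ground-truth tables written by [write_truth_tables()]
#'
#' @param dir Directory containing `truth_*.tsv` and `germline.tsv`.
#' @return A list with `truth` (all lesions bound) and `germline`.
#' @export
read_truth_tables <- function(dir) {
  files <- list.files(dir, pattern = "^truth_.*\\.tsv$", full.names = TRUE)
  ct <- readr::cols(chrom = readr::col_character(),
                    ref = readr::col_character(),
                    alt = readr::col_character(),
                    .default = readr::col_guess())
  truth <- bind_rows(purrr::map(sort(files), function(f) {
    readr::read_tsv(f, col_types = ct, progress = FALSE)
  }))
  germline <- readr::read_tsv(file.path(dir, "germline.tsv"),
                              col_types = ct, progress = FALSE)
  list(truth = truth, germline = germline)
}
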