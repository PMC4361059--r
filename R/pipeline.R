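# Pipeline orchestration: configuration and the end-to-end run.

CONFIG_RANGES <- list(
  min_depth = c(0, Inf),
  strand_bias_alpha = c(0, 1),
  tail_bias_alpha = c(0, 1),
  het_min = c(0, 1),
  hom_alt_min = c(0, 1),
  min_evidence = c(1, Inf),
  min_baseq = c(0, 60),
  end_exclusion_bp = c(0, Inf),
  val_min_depth = c(0, Inf),
  val_min_reads = c(0, Inf),
  val_min_fraction = c(0, 1),
  mp_threshold = c(0, 1),
  clonal_vaf_threshold = c(0, 1),
  target_mb = c(1e-9, Inf),
  repeat_flank = c(0, Inf),
  seed = c(-Inf, Inf)
)

#' Pipeline configuration
#'
#' All thresholds used across the calling, validation, metrics and
#' heterogeneity stages, each at its documented default: minimum depth 10,
#' strand-bias alpha 0.001, tail-bias alpha 0.005, minimum subclonal
#' evidence 2 reads, minimum base quality 20, read-end exclusion 5 bp,
#' validation coverage 20 / mutant reads 5 / mutant fraction 1%, MP
#' threshold 0.15, clonality threshold 0.25, target size 30 Mb, repeat-mask
#' flank 10 bp.
#'
#' @param ... Named overrides of any threshold. Unknown names are rejected;
#'   out-of-range values are rejected naming the key and legal range.
#' @return A `mutmosaic_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_depth = 10,
    strand_bias_alpha = 0.001,
    tail_bias_alpha = 0.005,
    het_min = 0.10,
    hom_alt_min = 0.85,
    min_evidence = 2,
    min_baseq = 20,
    end_exclusion_bp = 5,
    val_min_depth = 20,
    val_min_reads = 5,
    val_min_fraction = 0.01,
    mp_threshold = 0.15,
    clonal_vaf_threshold = 0.25,
    target_mb = 30,
    repeat_flank = 10,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  for (k in names(CONFIG_RANGES)) {
    r <- CONFIG_RANGES[[k]]
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < r[1] || v > r[2]) {
      abort(sprintf(
        "validation error: config key '%s' = %s outside legal range [%s, %s]",
        k, format(v), format(r[1]), format(r[2])))
    }
  }
  structure(cfg, class = c("mutmosaic_config", "list"))
}

#' Load a pipeline configuration from a YAML file
#'
#' Absent keys take their documented defaults; an empty file yields the full
#' default configuration. Unknown keys and out-of-range values are rejected.
#' A `sim:` block, when present, is passed through [sim_params()].
#'
#' @param path Path to a YAML key-value file.
#' @return A list with `config` (a [pipeline_config()]) and `sim` (a
#'   [sim_params()], defaults when no `sim:` block is given).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim_over <- raw$sim
  raw$sim <- NULL
  cfg <- do.call(pipeline_config, raw)
  sim <- if (is.null(sim_over)) {
    sim_params(seed = cfg$seed)
  } else {
    do.call(sim_params, sim_over)
  }
  list(config = cfg, sim = sim)
}

#' @noRd
stage_log <- function(run_log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(run_log, line)
}

#' Run the full analysis on a simulated cohort
#'
#' simulate -> primary calling -> subclonal calling -> consequence
#' annotation -> burden metrics (including the inverse analysis) ->
#' amplicon validation of high-MP primary calls on simulated deep counts ->
#' cross-lesion comparison. All tabular reports are written under
#' `out_dir` along with a machine-readable JSON manifest recording the
#' configuration, seed and package version; re-running with the same
#' configuration and seed reproduces every output byte-identically.
#'
#' @param config A [pipeline_config()] list.
#' @param sim A [sim_params()] object describing the cohort to simulate.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @return A `mutmosaic_run` object: list with `calls` (all lesions,
#'   primary + subclonal), `metrics` (per-lesion burden table),
#'   `spectra`, `validation`, `concordance`, `overlaps`, `gene_report`,
#'   `manifest`, and `log`.
#' @export
run_all <- function(config = pipeline_config(), sim = sim_params(),
                    out_dir = NULL) {
  stopifnot(inherits(config, "mutmosaic_config"),
            inherits(sim, "mutmosaic_sim_params"))
  run_log <- character()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  run_log <- stage_log(run_log, "simulate",
                       sprintf("%d patients x %d lesions, %d sites",
                               sim$n_patients, sim$lesions_per_patient,
                               sim$n_sites))
  cohort <- tryCatch(simulate_cohort(sim),
                     error = function(e) abort(paste0("stage simulate: ",
                                                      conditionMessage(e))))

  all_calls <- list()
  metrics <- list()
  spectra <- list()
  val_rows <- list()
  for (pt in cohort) {
    for (lid in names(pt$pileups)) {
      pu <- pt$pileups[[lid]]
      prim <- tryCatch(
        call_primary(pu, config, lesion_id = lid, patient_id = pt$patient_id),
        error = function(e) abort(paste0("stage call-primary (", lid, "): ",
                                         conditionMessage(e))))
      sub <- tryCatch(
        call_subclonal(pu, config, lesion_id = lid,
                       patient_id = pt$patient_id),
        error = function(e) abort(paste0("stage call-subclonal (", lid, "): ",
                                         conditionMessage(e))))
      run_log <- stage_log(run_log, "call",
                           sprintf("%s: %d primary (%d passed), %d subclonal (%d passed)",
                                   lid, nrow(prim), sum(prim$passed),
                                   nrow(sub), sum(sub$passed)))
      calls <- bind_rows(prim, sub)
      calls <- tryCatch(
        annotate_consequence(calls, pt$transcripts),
        error = function(e) abort(paste0("stage annotate (", lid, "): ",
                                         conditionMessage(e))))
      calls <- classify_clonality(calls, config$clonal_vaf_threshold)
      all_calls[[lid]] <- calls

      prim_a <- filter(calls, .data$source == "primary")
      m <- lesion_metrics(prim_a, target_mb = config$target_mb)
      inv <- tryCatch(
        inverse_analysis(pu, pt$transcripts, config),
        error = function(e) abort(paste0("stage metrics (", lid, "): ",
                                         conditionMessage(e))))
      metrics[[lid]] <- bind_cols(
        tibble(patient_id = pt$patient_id, lesion_id = lid), m, inv)
      spectra[[lid]] <- spectrum_summary(prim_a)

      # amplicon validation of high-MP passed primary calls against truth
      hi <- filter(prim_a, .data$passed,
                   .data$vaf_tumor > config$mp_threshold)
      if (nrow(hi) > 0) {
        tl <- filter(pt$truth, .data$lesion_id == lid)
        tvaf <- tl$true_vaf[match(mutation_key(hi), mutation_key(tl))]
        tvaf[is.na(tvaf)] <- 0
        amp <- purrr::map(seq_len(nrow(hi)), function(i) {
          ac <- simulate_amplicon_counts(
            tvaf[i], sim,
            seed = spawn_seed(sim$seed, hi$pos[i]),
            ref = hi$ref[i], alt = hi$alt[i])
          row <- tibble(chrom = hi$chrom[i], pos = hi$pos[i],
                        ref = hi$ref[i], alt = hi$alt[i],
                        lesion_id = lid)
          for (j in seq_along(COUNT_COLS)) {
            row[[TUMOR_COLS[j]]] <- ac$tumor[[j]]
            row[[NORMAL_COLS[j]]] <- ac$normal[[j]]
          }
          row
        })
        vres <- validate_calls(bind_rows(amp), config)
        vres$lesion_id <- lid
        vres$concordance_mp <- concordance_rate(hi, vres,
                                                config$mp_threshold)
        val_rows[[lid]] <- vres
      }

      if (!is.null(out_dir)) {
        write_vcf(calls, file.path(out_dir, sprintf("calls_%s.vcf", lid)),
                  lesion_id = lid, patient_id = pt$patient_id)
      }
    }
    if (!is.null(out_dir)) write_truth_tables(pt, file.path(out_dir, "truth"))
  }

  calls_all <- bind_rows(all_calls)
  metrics_tbl <- bind_rows(metrics)
  validation_tbl <- bind_rows(val_rows)
  concord <- if (nrow(validation_tbl) > 0) {
    distinct(validation_tbl, .data$lesion_id, .data$concordance_mp)
  } else tibble(lesion_id = character(), concordance_mp = double())

  overlaps <- list()
  gene_reports <- list()
  for (pt in cohort) {
    pcalls <- filter(calls_all, .data$patient_id == pt$patient_id)
    if (length(unique(pcalls$lesion_id)) >= 2) {
      overlaps[[pt$patient_id]] <- overlap_report(pcalls)
      gene_reports[[pt$patient_id]] <-
        mutate(gene_multihit_report(pcalls), patient_id = pt$patient_id)
    } else {
      run_log <- stage_log(run_log, "compare",
                           sprintf("%s: <2 lesions, comparison skipped",
                                   pt$patient_id))
    }
  }
  gene_tbl <- bind_rows(gene_reports)

  manifest <- list(
    package = "mutmosaic",
    version = as.character(utils::packageVersion("mutmosaic")),
    seed = sim$seed,
    config = unclass(config),
    sim = unclass(sim),
    n_calls = nrow(calls_all),
    n_passed = sum(calls_all$passed)
  )

  if (!is.null(out_dir)) {
    readr::write_tsv(metrics_tbl, file.path(out_dir, "lesion_metrics.tsv"),
                     progress = FALSE)
    spec_tbl <- bind_rows(purrr::imap(spectra, function(s, lid) {
      mutate(s$classes, lesion_id = lid,
             cpg_fraction = s$cpg_fraction_of_cg_transitions)
    }))
    readr::write_tsv(spec_tbl, file.path(out_dir, "spectrum.tsv"),
                     progress = FALSE)
    if (nrow(validation_tbl) > 0) {
      readr::write_tsv(validation_tbl, file.path(out_dir, "validation.tsv"),
                       progress = FALSE)
    }
    if (length(overlaps) > 0) {
      ov_tbl <- bind_rows(purrr::imap(overlaps, function(o, pid) {
        mutate(o$pairs, patient_id = pid)
      }))
      readr::write_tsv(ov_tbl, file.path(out_dir, "overlap.tsv"),
                       progress = FALSE)
    }
    if (nrow(gene_tbl) > 0) {
      readr::write_tsv(gene_tbl, file.path(out_dir, "gene_multihit.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(
    calls = calls_all, metrics = metrics_tbl, spectra = spectra,
    validation = validation_tbl, concordance = concord,
    overlaps = overlaps, gene_report = gene_tbl,
    manifest = manifest, log = run_log
  ), class = "mutmosaic_run")
}

#' @export
print.mutmosaic_run <- function(x, ...) {
  cat("mutmosaic run:", x$manifest$n_calls, "calls (",
      x$manifest$n_passed, "passed) across",
      nrow(x$metrics), "lesions\n")
  print(x$metrics)
  invisible(x)
}
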