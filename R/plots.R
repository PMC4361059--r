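# ggplot2 displays and broom-style accessors for result objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile labs
#'   scale_fill_gradient theme_minimal facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a substitution-spectrum summary
#'
#' @param x A `mutmosaic_spectrum` from [spectrum_summary()].
#' @param ... Unused.
#' @return A tibble with one row per collapsed substitution class.
#' @method tidy mutmosaic_spectrum
#' @export
tidy.mutmosaic_spectrum <- function(x, ...) {
  mutate(x$classes,
         cpg_fraction_of_cg_transitions = x$cpg_fraction_of_cg_transitions)
}

#' @rdname tidy.mutmosaic_spectrum
#' @method glance mutmosaic_spectrum
#' @export
glance.mutmosaic_spectrum <- function(x, ...) {
  tibble(n_total = x$n_total, n_ct = x$n_ct,
         cpg_fraction_of_cg_transitions = x$cpg_fraction_of_cg_transitions,
         empty = x$empty)
}

#' Plot a substitution spectrum
#'
#' Bar chart of the six collapsed substitution class fractions.
#'
#' @param object A `mutmosaic_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mutmosaic_spectrum
#' @export
autoplot.mutmosaic_spectrum <- function(object, ...) {
  ggplot(object$classes, aes(x = .data$class, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = "substitution class", y = "fraction of mutations",
         subtitle = sprintf("CpG fraction of C>T/G>A: %s",
                            format(object$cpg_fraction_of_cg_transitions,
                                   digits = 3))) +
    theme_minimal()
}

#' @rdname autoplot.mutmosaic_spectrum
#' @export
plot_spectrum <- function(object, ...) autoplot(object, ...)

#' Tidy a cross-lesion overlap report
#'
#' @param x A `mutmosaic_overlap` from [overlap_report()].
#' @param ... Unused.
#' @return The pairwise tibble with `patient_id` attached.
#' @method tidy mutmosaic_overlap
#' @export
tidy.mutmosaic_overlap <- function(x, ...) {
  mutate(x$pairs, patient_id = x$patient_id)
}

#' @rdname tidy.mutmosaic_overlap
#' @method glance mutmosaic_overlap
#' @export
glance.mutmosaic_overlap <- function(x, ...) {
  tibble(patient_id = x$patient_id,
         n_lesions = length(x$sizes),
         n_shared_keys = length(x$shared_keys),
         max_jaccard = if (nrow(x$pairs) > 0) max(x$pairs$jaccard) else NA_real_)
}

#' Heatmap of pairwise Jaccard overlap between lesions
#'
#' @param object A `mutmosaic_overlap`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mutmosaic_overlap
#' @export
autoplot.mutmosaic_overlap <- function(object, ...) {
  both <- bind_rows(
    object$pairs,
    dplyr::rename(object$pairs, lesion_a = "lesion_b", lesion_b = "lesion_a"))
  ggplot(both, aes(x = .data$lesion_a, y = .data$lesion_b,
                   fill = .data$jaccard)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Jaccard",
         title = sprintf("Shared mutations, patient %s", object$patient_id)) +
    theme_minimal()
}

#' Bar chart of per-lesion mutational indices
#'
#' @param metrics The `metrics` tibble of a [run_all()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_lesion_metrics <- function(metrics, ...) {
  ggplot(metrics, aes(x = .data$lesion_id, y = .data$mut_index)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~patient_id, scales = "free_x") +
    labs(x = NULL, y = "mutations / Mb") +
    theme_minimal()
}

#' Glance at a pipeline run
#'
#' @param x A `mutmosaic_run` from [run_all()].
#' @param ... Unused.
#' @return A one-row tibble of run-level counts.
#' @method glance mutmosaic_run
#' @export
glance.mutmosaic_run <- function(x, ...) {
  tibble(
    n_lesions = nrow(x$metrics),
    n_calls = x$manifest$n_calls,
    n_passed = x$manifest$n_passed,
    mean_mut_index = mean(x$metrics$mut_index),
    mean_inverse_index = mean(x$metrics$inverse_index),
    seed = x$manifest$seed
  )
}

#' @rdname glance.mutmosaic_run
#' @method tidy mutmosaic_run
#' @export
tidy.mutmosaic_run <- function(x, ...) x$metrics
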