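# ggplot2 views of rearrangement tables and concordance summaries.

#' Plot marker counts per junction class (DNAamp vs RNAseq-recovered)
#'
#' Bar chart of DNAamp marker counts and the subset re-identified in the
#' RNAseq data, per junction class.
#'
#' @param summary A `concordance_summary` or its per-class tibble.
#' @return A ggplot object.
#' @export
plot_class_recovery <- function(summary) {
  pc <- if (inherits(summary, "concordance_summary")) summary$per_class
  else tibble::as_tibble(summary)
  df <- pc |>
    dplyr::filter(!is.na(.data$dnaamp_markers)) |>
    dplyr::select("junction_class", "dnaamp_markers", "rnaseq_recovered") |>
    tidyr::pivot_longer(c("dnaamp_markers", "rnaseq_recovered"),
                        names_to = "measure", values_to = "markers") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          dnaamp_markers = "DNAamp markers",
                                          rnaseq_recovered =
                                            "recovered by RNAseq"))
  df$junction_class <- factor(df$junction_class,
                              levels = junction_classes()$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$junction_class,
                                   y = .data$markers,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "MRD markers",
                  fill = NULL,
                  title = "RNAseq re-identification of DNAamp MRD markers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' @rdname plot_class_recovery
#' @param object A `concordance_summary`.
#' @param ... Unused.
#' @method autoplot concordance_summary
#' @export
autoplot.concordance_summary <- function(object, ...) {
  plot_class_recovery(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mean rearrangements per case and locus group
#'
#' @param rearr Combined rearrangement table (both platforms).
#' @return A ggplot object.
#' @export
plot_locus_abundance <- function(rearr) {
  n_cases <- dplyr::n_distinct(rearr$case_id)
  df <- rearr |>
    dplyr::count(.data$platform, .data$locus_group) |>
    dplyr::mutate(per_case = .data$n / n_cases)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus_group,
                                   y = .data$per_case,
                                   fill = .data$platform)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "rearrangements / case", fill = NULL,
                  title = "Detected rearrangements per case by locus") +
    ggplot2::theme_minimal()
}

#' Plot productivity composition per platform
#'
#' Stacked proportion bars of productive, potentially productive,
#' unproductive and unknown rearrangements for each platform.
#'
#' @param rearr Combined rearrangement table (both platforms).
#' @return A ggplot object.
#' @export
plot_productivity <- function(rearr) {
  df <- rearr |>
    dplyr::count(.data$platform, .data$productivity) |>
    dplyr::group_by(.data$platform) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  df$productivity <- factor(df$productivity, levels = PRODUCTIVITY_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$platform, y = .data$fraction,
                                   fill = .data$productivity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of rearrangements", fill = NULL,
                  title = "Productivity of detected rearrangements") +
    ggplot2::theme_minimal()
}
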