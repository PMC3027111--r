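#' Plot a comparative Zipf-like rank profile
#'
#' Reference frequencies as a bold line over rank; comparison organisms as
#' thin lines, colored by host label when a taxonomy is supplied (red =
#' animal-associated, blue = plant-associated, grey = unknown).
#'
#' @param object A `rank_profile`.
#' @param taxonomy Optional taxonomy tibble supplying `host_label`.
#' @param log_y Log-scale the frequency axis (default TRUE, the usual
#'   rank-frequency view).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rank_profile <- function(object, taxonomy = NULL, log_y = TRUE, ...) {
  comp <- object$comparisons
  if (!is.null(taxonomy)) {
    comp <- dplyr::left_join(comp,
                             dplyr::select(taxonomy, "organism_id",
                                           "host_label"),
                             by = "organism_id")
  } else {
    comp$host_label <- "none"
  }
  p <- ggplot2::ggplot(comp, ggplot2::aes(x = .data$rank,
                                          y = .data$frequency)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$organism_id,
                                    color = .data$host_label),
                       linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_line(data = object$ranking,
                       ggplot2::aes(y = .data$reference_freq),
                       color = "magenta4", linewidth = 1.1) +
    ggplot2::scale_color_manual(values = c(animal = "red", plant = "blue",
                                           none = "grey60")) +
    ggplot2::labs(x = sprintf("%d-gram rank in %s", object$n,
                              object$reference_id),
                  y = "frequency (%)", color = "host")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot perplexity against branch distance
#'
#' Scatter of each scanned organism's cross-perplexity versus its branch
#' distance from the reference, colored by taxonomic relation to the
#' reference genus/class when labels are available.
#'
#' @param object A `perplexity_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perplexity_scan <- function(object, ...) {
  self_row <- dplyr::filter(object, .data$is_self)
  ref_genus <- if (nrow(self_row)) self_row$genus[1] else NA_character_
  ref_class <- if (nrow(self_row)) self_row$taxon_class[1] else NA_character_
  dat <- dplyr::mutate(
    object,
    relation = dplyr::case_when(
      .data$is_self ~ "self",
      !is.na(.data$genus) & .data$genus == ref_genus ~ "same genus",
      !is.na(.data$taxon_class) & .data$taxon_class == ref_class ~ "same class",
      TRUE ~ "other"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$branch_distance,
                                    y = .data$perplexity,
                                    color = .data$relation)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(self = "magenta",
                                           `same genus` = "red",
                                           `same class` = "green4",
                                           other = "blue")) +
    ggplot2::labs(x = "branch distance from reference",
                  y = sprintf("%d-gram perplexity", attr(object, "n")),
                  color = NULL)
}

#' Plot a classification report as accuracy bars
#'
#' One bar per predictor (each unigram and PC1), faceted by taxonomy level
#' — the tabular analogue of the classic per-unigram accuracy chart.
#'
#' @param object A `classification_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.classification_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$predictor,
                                       y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_accuracy - .data$sd_accuracy, 0),
      ymax = pmin(.data$mean_accuracy + .data$sd_accuracy, 1)),
      width = 0.3) +
    ggplot2::facet_wrap(~level, ncol = 1) +
    ggplot2::labs(x = NULL, y = "mean CV accuracy")
}
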