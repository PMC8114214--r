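#' Plot a peptide length distribution
#'
#' Bar chart of unique-peptide counts (or percentages) per length and cell
#' line, with SEM error bars when the distribution was computed per
#' replicate.
#'
#' @param ld Output of [length_distribution()].
#' @param percent Plot percentages instead of counts (pooled input only).
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(ld, percent = FALSE) {
  if ("mean_pct" %in% names(ld)) {
    ggplot2::ggplot(ld, ggplot2::aes(x = factor(.data$length), y = .data$mean_pct,
                                     fill = .data$cell_line)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                     ymax = .data$mean_pct + .data$sem_pct),
        position = ggplot2::position_dodge(width = 0.9), width = 0.3
      ) +
      ggplot2::labs(x = "Peptide length", y = "Unique peptides (%, mean ± SEM)",
                    fill = "Cell line") +
      ggplot2::theme_minimal()
  } else {
    y <- if (percent) "pct" else "n_unique"
    ggplot2::ggplot(ld, ggplot2::aes(x = factor(.data$length), y = .data[[y]],
                                     fill = .data$cell_line)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "Peptide length",
                    y = if (percent) "Unique peptides (%)" else "Unique peptides",
                    fill = "Cell line") +
      ggplot2::theme_minimal()
  }
}

#' Plot replicate reproducibility
#'
#' @param rr Output of [replicate_reproducibility()].
#' @return A ggplot object.
#' @export
plot_replicate_reproducibility <- function(rr) {
  ggplot2::ggplot(rr, ggplot2::aes(x = factor(.data$k), y = .data$pct,
                                   fill = .data$cell_line)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Detected in k replicates", y = "Unique 7–15mers (%)",
                  fill = "Cell line") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential source proteins
#'
#' @param diff Output of [differential_source_proteins()].
#' @param p_cutoff,fc_cutoff Significance and fold-change highlight
#'   thresholds (raw p, log2 units).
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, p_cutoff = 0.05, fc_cutoff = 1) {
  diff <- mutate(diff, significant = .data$p_value < p_cutoff &
                   abs(.data$log2_fc) > fc_cutoff)
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$log2_fc,
                                     y = -log10(.data$p_value),
                                     colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "orange")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = paste0("p < ", p_cutoff, ", |FC| > ", fc_cutoff)) +
    ggplot2::theme_minimal()
}

#' Motif plot for a position frequency matrix
#'
#' Tile representation of per-position residue frequencies above the
#' moderate-class floor (10%), coloured by consensus class — a tabular
#' analogue of a sequence logo.
#'
#' @param object A `pfm` from [build_pfm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfm <- function(object, ...) {
  cons <- classify_consensus(object)
  ggplot2::ggplot(cons, ggplot2::aes(x = factor(.data$position),
                                     y = .data$frequency,
                                     fill = .data$class,
                                     label = .data$residue)) +
    ggplot2::geom_col(position = "stack", colour = "white") +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5), size = 3) +
    ggplot2::scale_fill_manual(values = c(dominant = "#d7301f",
                                          strong = "#fc8d59",
                                          moderate = "#fdcc8a")) +
    ggplot2::labs(
      x = "Peptide position", y = "Residue frequency", fill = "Class",
      title = paste0(object$length, "mer consensus motif",
                     if (!is.na(object$cell_line)) paste0(" — ", object$cell_line)),
      subtitle = paste0("n = ", object$n_peptides, " unique peptides")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pocket homology scan
#'
#' Relative scores of every database subject against the query, with the
#' perfect-score line at 1 and the pass cutoff marked.
#'
#' @param object A `pocket_scan` from [scan_database()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pocket_scan <- function(object, ...) {
  ggplot2::ggplot(object$matches,
                  ggplot2::aes(x = .data$rank, y = .data$relative_score,
                               colour = .data$passes)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "solid") +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2b8cbe")) +
    ggplot2::labs(x = "Subject rank", y = "Relative alignment score",
                  colour = paste0("≥ ", object$cutoff, " × max"),
                  title = paste0("Pocket ", object$pocket, " homology: ", object$query)) +
    ggplot2::theme_minimal()
}
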