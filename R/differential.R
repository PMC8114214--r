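#' Differential expression of peptide source proteins
#'
#' Two-sample Student's t-test (equal-variance) on log2 expression values
#' per protein accession, comparing two groups of replicates — the standard
#' whole-cell proteomics comparison behind a volcano plot. Fold change is
#' the difference of group means in log2 space (`group_a` minus `group_b`).
#'
#' @param expr Long tibble with columns `accession`, `group`, `replicate`,
#'   `value`. Values are log2 intensities unless `log2_transform = TRUE`,
#'   in which case raw intensities are log2-transformed first and
#'   non-positive values are dropped with a warning.
#' @param group_a,group_b Labels in `expr$group` to compare; fold change is
#'   `group_a - group_b`.
#' @param log2_transform Transform raw intensities to log2 first.
#' @return A tibble `accession`, `n_a`, `n_b`, `log2_fc`, `statistic`,
#'   `p_value`, `p_adj` (Benjamini-Hochberg), suitable for
#'   [plot_volcano()]. Accessions with fewer than 2 values in either group
#'   are dropped. Degenerate zero-variance cases yield `p_value` 1 when the
#'   means are equal and 0 otherwise.
#' @export
differential_source_proteins <- function(expr, group_a, group_b,
                                         log2_transform = FALSE) {
  need <- c("accession", "group", "replicate", "value")
  missing <- setdiff(need, names(expr))
  if (length(missing)) abort(paste0("expr lacks column(s): ", paste(missing, collapse = ", ")))
  expr <- filter(expr, .data$group %in% c(group_a, group_b))
  if (log2_transform) {
    bad <- expr$value <= 0 | is.na(expr$value)
    if (any(bad)) {
      warn(paste0(sum(bad), " non-positive/missing intensities excluded before log2"))
      expr <- expr[!bad, , drop = FALSE]
    }
    expr$value <- log2(expr$value)
  }
  res <- expr %>%
    group_by(.data$accession) %>%
    summarise(
      n_a = sum(.data$group == group_a),
      n_b = sum(.data$group == group_b),
      log2_fc = mean(.data$value[.data$group == group_a]) -
        mean(.data$value[.data$group == group_b]),
      statistic = unname(student_t(.data$value[.data$group == group_a],
                                   .data$value[.data$group == group_b])["statistic"]),
      p_value = unname(student_t(.data$value[.data$group == group_a],
                                 .data$value[.data$group == group_b])["p"]),
      .groups = "drop"
    ) %>%
    filter(.data$n_a >= 2, .data$n_b >= 2)
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res
}

# Equal-variance two-sample t; degenerate zero-variance case handled
# explicitly because stats::t.test() refuses essentially constant data.
student_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(c(statistic = NA_real_, p = NA_real_))
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0 || !is.finite(sp2)) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(c(statistic = if (equal) 0 else Inf, p = if (equal) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  c(statistic = unname(tt$statistic), p = tt$p.value)
}
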