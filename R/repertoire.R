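#' Summarise a peptide repertoire per cell line
#'
#' Counts, per cell line, total observations (table rows), unique peptide
#' sequences pooled across replicates, and unique sequences in the MHC-I
#' length window (7-15 residues by default). `pct_7_15` is the raw
#' percentage of unique sequences falling in the window;
#' `pct_7_15_display` truncates it to an integer for reporting, matching
#' the convention of published summary tables.
#'
#' @param peptides Peptide tibble (see [read_peptide_table()]).
#' @param min_len,max_len Inclusive length window, default 7-15.
#' @return A tibble with one row per cell line: `cell_line`,
#'   `n_observations`, `n_unique`, `n_unique_7_15`, `pct_7_15`,
#'   `pct_7_15_display`.
#' @export
summarize_repertoire <- function(peptides, min_len = 7, max_len = 15) {
  check_peptides(peptides)
  if (nrow(peptides) == 0L) {
    warn("no peptide observations; returning empty summary")
    return(tibble(cell_line = character(), n_observations = integer(),
                  n_unique = integer(), n_unique_7_15 = integer(),
                  pct_7_15 = double(), pct_7_15_display = integer()))
  }
  peptides %>%
    mutate(.len = nchar(.data$sequence)) %>%
    group_by(.data$cell_line) %>%
    summarise(
      n_observations = dplyr::n(),
      n_unique = n_distinct(.data$sequence),
      n_unique_7_15 = n_distinct(.data$sequence[.data$.len >= min_len & .data$.len <= max_len]),
      .groups = "drop"
    ) %>%
    mutate(
      pct_7_15 = 100 * .data$n_unique_7_15 / .data$n_unique,
      pct_7_15_display = as.integer(floor(.data$pct_7_15))
    )
}

#' Length distribution of unique peptides
#'
#' Counts unique sequences per length within the 7-15 window, per cell
#' line, either pooled across replicates or per replicate with mean and
#' standard error of the mean (SEM = sd / sqrt(n)) across replicates.
#'
#' @inheritParams summarize_repertoire
#' @param per_replicate If `TRUE`, percentages are computed within each
#'   replicate and summarised as mean +/- SEM across replicates.
#' @return Pooled: tibble `cell_line`, `length`, `n_unique`, `pct`
#'   (percent of unique 7-15mers). Per-replicate: tibble `cell_line`,
#'   `length`, `mean_n`, `mean_pct`, `sem_pct` (SEM `NA` with a single
#'   replicate).
#' @export
length_distribution <- function(peptides, min_len = 7, max_len = 15,
                                per_replicate = FALSE) {
  check_peptides(peptides)
  lens <- seq.int(min_len, max_len)
  if (!per_replicate) {
    peptides %>%
      distinct(.data$cell_line, .data$sequence) %>%
      mutate(length = nchar(.data$sequence)) %>%
      filter(.data$length >= min_len, .data$length <= max_len) %>%
      count(.data$cell_line, .data$length, name = "n_unique") %>%
      tidyr::complete(.data$cell_line, length = lens, fill = list(n_unique = 0L)) %>%
      group_by(.data$cell_line) %>%
      mutate(pct = 100 * .data$n_unique / sum(.data$n_unique)) %>%
      ungroup()
  } else {
    per_rep <- peptides %>%
      distinct(.data$cell_line, .data$replicate, .data$sequence) %>%
      mutate(length = nchar(.data$sequence)) %>%
      filter(.data$length >= min_len, .data$length <= max_len) %>%
      count(.data$cell_line, .data$replicate, .data$length, name = "n_unique") %>%
      group_by(.data$cell_line, .data$replicate) %>%
      tidyr::complete(length = lens, fill = list(n_unique = 0L)) %>%
      mutate(pct = 100 * .data$n_unique / sum(.data$n_unique)) %>%
      ungroup()
    per_rep %>%
      group_by(.data$cell_line, .data$length) %>%
      summarise(
        mean_n = mean(.data$n_unique),
        mean_pct = mean(.data$pct),
        sem_pct = if (dplyr::n() > 1) sd(.data$pct) / sqrt(dplyr::n()) else NA_real_,
        .groups = "drop"
      )
  }
}

#' Replicate reproducibility of unique peptides
#'
#' For each cell line, the percentage of unique 7-15mer sequences detected
#' in exactly k of the n replicates. Percentages over k = 1..n sum to 100.
#'
#' @inheritParams summarize_repertoire
#' @param n_replicates Number of replicates per cell line; defaults to the
#'   maximum replicate index observed per cell line.
#' @return A tibble `cell_line`, `k` (replicates detected), `n_sequences`,
#'   `pct`.
#' @export
replicate_reproducibility <- function(peptides, min_len = 7, max_len = 15,
                                      n_replicates = NULL) {
  check_peptides(peptides)
  det <- peptides %>%
    mutate(.len = nchar(.data$sequence)) %>%
    filter(.data$.len >= min_len, .data$.len <= max_len) %>%
    distinct(.data$cell_line, .data$sequence, .data$replicate) %>%
    count(.data$cell_line, .data$sequence, name = "k")
  det %>%
    group_by(.data$cell_line) %>%
    mutate(.n_rep = if (is.null(n_replicates)) max(peptides$replicate[peptides$cell_line == .data$cell_line[1]]) else n_replicates) %>%
    count(.data$cell_line, .data$k, .data$.n_rep, name = "n_sequences") %>%
    group_by(.data$cell_line) %>%
    tidyr::complete(k = seq_len(.data$.n_rep[1]), fill = list(n_sequences = 0L)) %>%
    mutate(pct = 100 * .data$n_sequences / sum(.data$n_sequences)) %>%
    ungroup() %>%
    select("cell_line", "k", "n_sequences", "pct")
}

#' Cross-cell-line overlap of unique peptide sets
#'
#' Partitions the union of unique 7-15mer sequences from the supplied cell
#' lines into the regions of the Venn diagram (7 regions for three lines,
#' 3 for two) and counts sequences in each disjoint region.
#'
#' @inheritParams summarize_repertoire
#' @return A tibble `region` (cell-line names joined by `"&"`), `n_lines`
#'   (how many lines share the region) and `count`. Region counts are
#'   disjoint and sum to the union size.
#' @export
venn_overlap <- function(peptides, min_len = 7, max_len = 15) {
  check_peptides(peptides)
  sets <- peptides %>%
    mutate(.len = nchar(.data$sequence)) %>%
    filter(.data$.len >= min_len, .data$.len <= max_len) %>%
    distinct(.data$cell_line, .data$sequence)
  lines <- sort(unique(sets$cell_line))
  if (length(lines) < 2) abort("venn_overlap needs at least two cell lines")
  membership <- sets %>%
    mutate(present = TRUE) %>%
    tidyr::pivot_wider(names_from = "cell_line", values_from = "present",
                       values_fill = FALSE)
  mem_mat <- as.matrix(membership[lines])
  region <- apply(mem_mat, 1L, function(r) paste(lines[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(lines), function(k) {
    utils::combn(lines, k, paste, collapse = "&")
  }))
  counts <- table(factor(region, levels = combos))
  tibble(region = combos,
         n_lines = stringr::str_count(combos, stringr::fixed("&")) + 1L,
         count = as.integer(counts))
}

check_peptides <- function(peptides) {
  need <- c("sequence", "cell_line", "replicate")
  missing <- setdiff(need, names(peptides))
  if (length(missing)) {
    abort(paste0("peptide table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(peptides)
}
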