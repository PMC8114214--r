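#' Build a position frequency matrix
#'
#' Computes, for unique peptide sequences of exactly `length` residues
#' (pooled across replicates, optionally restricted to one cell line), the
#' frequency of each of the 20 amino acids at each position p1..pL. The
#' C-terminal position pL is the pOmega anchor position whatever the
#' peptide length.
#'
#' @param peptides Peptide tibble (see [read_peptide_table()]).
#' @param length Peptide length L to analyse (e.g. 8 or 9).
#' @param cell_line Optional cell-line label to restrict to.
#' @return An object of class `pfm`: a list with `freqs` (L x 20 matrix,
#'   rows p1..pL, columns the residues; each row sums to 1), `length`,
#'   `n_peptides`, `cell_line`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
#' @examples
#' pep <- tibble::tibble(sequence = c("ALAAAAAL", "AAAAAAAV"),
#'                       cell_line = "x", replicate = 1L)
#' pfm <- build_pfm(pep, length = 8)
#' pfm$freqs["p2", c("A", "L")]  # 0.5 0.5
build_pfm <- function(peptides, length, cell_line = NULL) {
  check_peptides(peptides)
  if (!is.null(cell_line)) {
    peptides <- filter(peptides, .data$cell_line %in% !!cell_line)
  }
  seqs <- unique(peptides$sequence[nchar(peptides$sequence) == length])
  if (base::length(seqs) == 0L) {
    abort(paste0("no unique peptides of length ", length,
                 if (!is.null(cell_line)) paste0(" for cell line ", cell_line)))
  }
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = base::length(seqs), byrow = TRUE)
  freqs <- t(apply(chars, 2L, function(col) {
    tabulate(factor(col, levels = AA_ALPHABET), nbins = 20L) / base::length(col)
  }))
  dimnames(freqs) <- list(paste0("p", seq_len(length)), AA_ALPHABET)
  structure(
    list(freqs = freqs, length = as.integer(length),
         n_peptides = base::length(seqs),
         cell_line = if (is.null(cell_line)) NA_character_ else paste(cell_line, collapse = "+")),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix (", x$length, "mers, n = ", x$n_peptides,
      if (!is.na(x$cell_line)) paste0(", ", x$cell_line), ")\n", sep = "")
  print(round(x$freqs, 3))
  invisible(x)
}

#' Tidy a position frequency matrix
#'
#' @param x A `pfm` object from [build_pfm()].
#' @param ... Unused.
#' @return A long tibble `position` (integer), `residue`, `frequency`.
#' @export
tidy.pfm <- function(x, ...) {
  as_tibble(x$freqs, rownames = "position") %>%
    mutate(position = as.integer(sub("^p", "", .data$position))) %>%
    tidyr::pivot_longer(-"position", names_to = "residue", values_to = "frequency")
}

#' One-line summary of a position frequency matrix
#'
#' @inheritParams tidy.pfm
#' @return A one-row tibble `cell_line`, `length`, `n_peptides`.
#' @export
glance.pfm <- function(x, ...) {
  tibble(cell_line = x$cell_line, length = x$length, n_peptides = x$n_peptides)
}

#' Classify a consensus binding motif from a PFM
#'
#' Applies the frequency-class convention for consensus motifs: a residue
#' is *dominant* at a position when its frequency exceeds 0.30, *strong*
#' in (0.20, 0.30], *moderate* in (0.10, 0.20]; residues at or below 0.10
#' are omitted. Boundaries are half-open with strictness at 0.30 following
#' the ">30%" definition. Within a position, residues are ordered by
#' descending frequency, ties broken alphabetically.
#'
#' @param pfm A `pfm` object from [build_pfm()].
#' @param dominant,strong,moderate Lower class boundaries (defaults 0.30,
#'   0.20, 0.10).
#' @return A tibble `position`, `residue`, `frequency`, `class` (factor
#'   dominant/strong/moderate).
#' @export
classify_consensus <- function(pfm, dominant = 0.30, strong = 0.20, moderate = 0.10) {
  stopifnot(inherits(pfm, "pfm"), moderate < strong, strong < dominant)
  tidy(pfm) %>%
    filter(.data$frequency > moderate) %>%
    mutate(class = factor(
      dplyr::case_when(
        .data$frequency > dominant ~ "dominant",
        .data$frequency > strong ~ "strong",
        TRUE ~ "moderate"
      ),
      levels = c("dominant", "strong", "moderate")
    )) %>%
    arrange(.data$position, desc(.data$frequency), .data$residue)
}

#' Frequency of one residue at one peptide position
#'
#' Fraction of unique length-L sequences carrying `residue` at 1-based
#' `position` — e.g. the leucine-at-p3 frequency that characterises devil
#' MHC-I ligands.
#'
#' @inheritParams build_pfm
#' @param position 1-based position within the peptide (<= `length`).
#' @param residue Single one-letter residue code.
#' @return A single frequency in `[0, 1]`.
#' @export
position_residue_frequency <- function(peptides, length, position, residue,
                                       cell_line = NULL) {
  if (position < 1 || position > length) {
    abort(paste0("position ", position, " out of range for length ", length))
  }
  stopifnot(residue %in% AA_ALPHABET)
  pfm <- build_pfm(peptides, length, cell_line)
  unname(pfm$freqs[position, residue])
}

#' Small versus bulky amino-acid usage by peptide length
#'
#' For each peptide length in `lengths`, the fraction of residue
#' occurrences (pooled over all positions of unique peptides of that
#' length) belonging to the small set {A, D, G, N, P, S} and the bulky set
#' {F, H, K, R, Y}. The other nine residues count toward neither fraction.
#' With `per_replicate = TRUE` the fractions are computed within each
#' replicate and summarised as mean +/- SEM.
#'
#' @inheritParams build_pfm
#' @param lengths Integer vector of peptide lengths, default 7:15.
#' @param per_replicate Summarise across replicates (mean +/- SEM) instead
#'   of pooling.
#' @return Pooled: tibble `cell_line`, `length`, `class` (small/bulky),
#'   `fraction`. Per-replicate: adds `sem` and `fraction` is the mean
#'   across replicates.
#' @export
small_bulky_usage <- function(peptides, lengths = 7:15, per_replicate = FALSE) {
  check_peptides(peptides)
  grouping <- if (per_replicate) c("cell_line", "replicate") else "cell_line"
  base <- peptides %>%
    mutate(length = nchar(.data$sequence)) %>%
    filter(.data$length %in% lengths) %>%
    distinct(across(all_of(c(grouping, "sequence", "length"))))
  usage <- base %>%
    group_by(across(all_of(c(grouping, "length")))) %>%
    summarise(
      small = residue_class_fraction(.data$sequence, AA_SMALL),
      bulky = residue_class_fraction(.data$sequence, AA_BULKY),
      .groups = "drop"
    ) %>%
    tidyr::pivot_longer(c("small", "bulky"), names_to = "class", values_to = "fraction")
  if (!per_replicate) return(usage)
  usage %>%
    group_by(.data$cell_line, .data$length, .data$class) %>%
    summarise(
      sem = if (dplyr::n() > 1) sd(.data$fraction) / sqrt(dplyr::n()) else NA_real_,
      fraction = mean(.data$fraction),
      .groups = "drop"
    ) %>%
    select("cell_line", "length", "class", "fraction", "sem")
}

residue_class_fraction <- function(seqs, class_set) {
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  mean(chars %in% class_set)
}
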