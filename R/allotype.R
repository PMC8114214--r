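#' Assign alpha-chain peptides to MHC-I allotype groups
#'
#' A digested alpha-chain peptide belongs to an allotype group when its
#' sequence is an exact substring of any allele sequence in that group
#' (enzymatic digestion of intact chains yields exact subsequences). A
#' peptide matching alleles from more than one group is *ambiguous* and is
#' excluded from quantification; a peptide matching no allele is
#' *unmatched*. Matching two alleles of the same group (alleles collapsed
#' because the observed peptides cannot distinguish them) is an ordinary
#' assignment.
#'
#' @param peptides Peptide tibble (see [read_peptide_table()]).
#' @param alleles Allele tibble with columns `name`, `group`, `sequence`
#'   (see [read_allele_fasta()]).
#' @return A tibble with one row per distinct peptide sequence: `sequence`,
#'   `group` (`NA` unless uniquely assigned), `n_groups` matched and
#'   `status` in `assigned` / `ambiguous` / `unmatched`.
#' @export
assign_peptides_to_alleles <- function(peptides, alleles) {
  check_peptides(peptides)
  if (nrow(alleles) == 0L) abort("allele set is empty")
  stopifnot(all(c("name", "group", "sequence") %in% names(alleles)))
  seqs <- unique(peptides$sequence)
  hit_groups <- lapply(seq_len(nrow(alleles)), function(i) {
    hit <- stringr::str_detect(alleles$sequence[i], stringr::fixed(seqs))
    ifelse(hit, alleles$group[i], NA_character_)
  })
  hit_mat <- do.call(cbind, hit_groups)
  per_seq <- apply(hit_mat, 1L, function(g) unique(g[!is.na(g)]), simplify = FALSE)
  n_groups <- lengths(per_seq)
  tibble(
    sequence = seqs,
    group = ifelse(n_groups == 1L, vapply(per_seq, function(g) g[1], ""), NA_character_),
    n_groups = as.integer(n_groups),
    status = dplyr::case_when(
      n_groups == 1L ~ "assigned",
      n_groups > 1L ~ "ambiguous",
      TRUE ~ "unmatched"
    )
  )
}

#' Per-replicate normalized allotype intensities
#'
#' Label-free quantification at allotype-group level: within each cell line
#' and replicate, every peptide intensity is divided by that replicate's
#' total peptide intensity (all peptides, before assignment filtering), and
#' the normalized intensities of peptides uniquely assigned to a group are
#' summed. Ambiguous and unmatched peptides therefore account for the
#' shortfall from 1.
#'
#' @inheritParams assign_peptides_to_alleles
#' @param assignments Optional precomputed result of
#'   [assign_peptides_to_alleles()]; computed when `NULL`.
#' @return A tibble `cell_line`, `group`, `replicate`,
#'   `normalized_intensity` with one row per group per replicate in which
#'   the group was detected.
#' @export
allotype_intensity_by_replicate <- function(peptides, alleles, assignments = NULL) {
  check_peptides(peptides)
  if (!"intensity" %in% names(peptides) || anyNA(peptides$intensity)) {
    abort("allotype quantification needs an intensity for every peptide observation")
  }
  if (is.null(assignments)) assignments <- assign_peptides_to_alleles(peptides, alleles)
  totals <- peptides %>%
    group_by(.data$cell_line, .data$replicate) %>%
    summarise(total = sum(.data$intensity), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort("replicate with zero total peptide intensity cannot be normalized")
  }
  peptides %>%
    left_join(assignments, by = "sequence") %>%
    filter(.data$status == "assigned") %>%
    left_join(totals, by = c("cell_line", "replicate")) %>%
    group_by(.data$cell_line, .data$group, .data$replicate) %>%
    summarise(normalized_intensity = sum(.data$intensity / .data$total),
              .groups = "drop")
}

#' Quantify MHC-I allotypes with a replicate-presence rule
#'
#' Summarises per-replicate normalized allotype intensities (see
#' [allotype_intensity_by_replicate()]) and applies the presence rule: a
#' group is retained only when detected (>= 1 assigned peptide) in at
#' least `presence_threshold` of `n_replicates` replicates — by default 3
#' of 4, the convention for calling an allotype surface-expressed.
#'
#' @inheritParams allotype_intensity_by_replicate
#' @param presence_threshold Minimum replicates with detection, default 3.
#' @param n_replicates Declared replicates per cell line; defaults to the
#'   maximum replicate index observed in `peptides` per cell line.
#' @return A tibble `cell_line`, `group`, `n_replicates_detected`,
#'   `mean_intensity`, `sem_intensity` (over detected replicates) and
#'   `retained`.
#' @export
quantify_allotypes <- function(peptides, alleles, presence_threshold = 3,
                               n_replicates = NULL, assignments = NULL) {
  reps <- allotype_intensity_by_replicate(peptides, alleles, assignments)
  declared <- peptides %>%
    group_by(.data$cell_line) %>%
    summarise(n_rep = if (is.null(n_replicates)) max(.data$replicate) else n_replicates,
              .groups = "drop")
  reps %>%
    group_by(.data$cell_line, .data$group) %>%
    summarise(
      n_replicates_detected = dplyr::n(),
      mean_intensity = mean(.data$normalized_intensity),
      sem_intensity = if (dplyr::n() > 1) {
        sd(.data$normalized_intensity) / sqrt(dplyr::n())
      } else NA_real_,
      .groups = "drop"
    ) %>%
    left_join(declared, by = "cell_line") %>%
    mutate(retained = .data$n_replicates_detected >= presence_threshold) %>%
    select(-"n_rep")
}

#' Pairwise comparison of allotype intensities
#'
#' Two-sample Student's t-tests on per-replicate normalized intensities
#' between every pair of allotype groups within a cell line, mirroring the
#' significance annotation of allotype quantification figures.
#'
#' @param replicate_intensities Output of
#'   [allotype_intensity_by_replicate()].
#' @return A tibble `cell_line`, `group_a`, `group_b`, `statistic`,
#'   `p_value`.
#' @export
compare_allotypes <- function(replicate_intensities) {
  replicate_intensities %>%
    group_by(.data$cell_line) %>%
    dplyr::group_modify(function(df, key) {
      groups <- sort(unique(df$group))
      if (length(groups) < 2) {
        return(tibble(group_a = character(), group_b = character(),
                      statistic = double(), p_value = double()))
      }
      pairs <- utils::combn(groups, 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
        a <- df$normalized_intensity[df$group == pairs[1, j]]
        b <- df$normalized_intensity[df$group == pairs[2, j]]
        st <- student_t(a, b)
        tibble(group_a = pairs[1, j], group_b = pairs[2, j],
               statistic = unname(st["statistic"]), p_value = unname(st["p"]))
      })
    }) %>%
    ungroup()
}
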