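#' Specify a synthetic immunopeptidome
#'
#' Builds the full generative specification for a simulated MHC-I
#' immunopeptidome experiment: per cell line, the number of candidate
#' unique peptides, a length distribution over 7-15 residues, a mixture of
#' motif components with planted per-position anchor preferences, a
#' per-replicate Bernoulli detection probability, and a log-normal
#' intensity model. The defaults emulate a three-cell-line design (a host
#' fibroblast line and the two transmissible-tumour lines, four biological
#' replicates each) with 8/9-mer-dominated lengths and a leucine anchor at
#' p3 plus a hydrophobic C-terminal (pOmega) anchor; the p3 anchor is
#' planted at dominant strength in the fibroblast and DFT2 lines and at
#' strong strength in the DFT1 line.
#'
#' @param seed Integer seed; every generator draw derives from it.
#' @param cell_lines Named list of per-line specifications; see
#'   [cell_line_spec()]. Defaults to the three-line design above.
#' @param shared_fraction Fraction of each line's unique peptides drawn
#'   from a common shared pool (controls the centre of the overlap
#'   diagram), default 0.1.
#' @param n_proteins Size of the synthetic source-protein pool,
#'   default 500.
#' @param neural_fraction Fraction of source proteins flagged as
#'   neural-restricted, default 0.1.
#' @return An object of class `synthetic_config` (a named list).
#' @export
synthetic_config <- function(seed = 1, cell_lines = NULL,
                             shared_fraction = 0.1, n_proteins = 500,
                             neural_fraction = 0.1) {
  if (is.null(cell_lines)) {
    cell_lines <- list(
      fibroblast = cell_line_spec(n_unique = 3000, p3_leucine = 0.45),
      DFT1_IFNg = cell_line_spec(n_unique = 2200, p3_leucine = 0.35),
      DFT2 = cell_line_spec(n_unique = 1200, p3_leucine = 0.45)
    )
  }
  stopifnot(shared_fraction >= 0, shared_fraction < 1,
            n_proteins >= 1, neural_fraction >= 0, neural_fraction <= 1)
  for (cl in cell_lines) validate_cell_line_spec(cl)
  structure(
    list(seed = as.integer(seed), cell_lines = cell_lines,
         shared_fraction = shared_fraction, n_proteins = as.integer(n_proteins),
         neural_fraction = neural_fraction),
    class = "synthetic_config"
  )
}

#' Per-cell-line synthetic specification
#'
#' Convenience constructor for one cell line's generative parameters. The
#' default motif mixture has one anchored component (weight
#' `anchor_weight`) carrying a leucine preference at p3 (conditional
#' frequency `p3_leucine`) and a hydrophobic pOmega preference
#' (L/V/F/P at 0.35/0.25/0.20/0.10), plus an unanchored uniform-background
#' component.
#'
#' @param n_replicates Biological replicates, default 4.
#' @param n_unique Candidate unique peptide sequences to draw.
#' @param length_probs Named probabilities over lengths 7-15 (sum 1);
#'   default approximates an 8/9-mer-dominated ligandome.
#' @param motif Optional explicit mixture: list of components, each a list
#'   with `weight`, `anchors` (named list: position number or `"omega"`
#'   -> named residue probabilities, partial allowed) and optional
#'   `background` (20-vector; uniform when `NULL`).
#' @param anchor_weight Weight of the anchored component in the default
#'   mixture, default 0.7.
#' @param p3_leucine Leucine frequency at p3 within the anchored
#'   component, default 0.45.
#' @param detection_prob Per-replicate detection probability in (0, 1],
#'   default 0.5.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity
#'   parameters, defaults `log(1e6)` and 1 (arbitrary LFQ units).
#' @return A named list consumed by [synthetic_config()].
#' @export
cell_line_spec <- function(n_replicates = 4, n_unique = 2000,
                           length_probs = NULL, motif = NULL,
                           anchor_weight = 0.7, p3_leucine = 0.45,
                           detection_prob = 0.5,
                           intensity_meanlog = log(1e6),
                           intensity_sdlog = 1) {
  if (is.null(length_probs)) {
    length_probs <- c(`7` = 0.06, `8` = 0.30, `9` = 0.27, `10` = 0.12,
                      `11` = 0.08, `12` = 0.06, `13` = 0.05, `14` = 0.035,
                      `15` = 0.025)
  }
  if (is.null(motif)) {
    motif <- list(
      list(weight = anchor_weight,
           anchors = list(
             `3` = c(L = p3_leucine),
             omega = c(L = 0.35, V = 0.25, F = 0.20, P = 0.10)
           )),
      list(weight = 1 - anchor_weight, anchors = list())
    )
  }
  list(n_replicates = as.integer(n_replicates), n_unique = as.integer(n_unique),
       length_probs = length_probs, motif = motif,
       detection_prob = detection_prob,
       intensity_meanlog = intensity_meanlog, intensity_sdlog = intensity_sdlog)
}

validate_cell_line_spec <- function(cl) {
  stopifnot(cl$n_replicates >= 1, cl$n_unique >= 1)
  if (abs(sum(cl$length_probs) - 1) > 1e-8) abort("length_probs must sum to 1")
  w <- vapply(cl$motif, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) abort("motif component weights must sum to 1")
  if (cl$detection_prob <= 0 || cl$detection_prob > 1) {
    abort("detection_prob must lie in (0, 1]")
  }
  for (m in cl$motif) {
    for (a in m$anchors) {
      if (any(a < 0) || sum(a) > 1 + 1e-8) abort("anchor probabilities invalid")
      if (!all(names(a) %in% AA_ALPHABET)) abort("anchor residues must be standard amino acids")
    }
  }
  max_len <- max(as.integer(names(cl$length_probs)[cl$length_probs > 0]))
  if (cl$n_unique > 0.5 * 20^max_len) abort("n_unique infeasible for the configured lengths")
  invisible(cl)
}

# Full 20-residue distribution for one position: anchored residues keep
# their stated probability, the remaining mass spreads over the rest in
# proportion to the background.
position_distribution <- function(anchor, background) {
  p <- background
  if (length(anchor)) {
    rest <- setdiff(AA_ALPHABET, names(anchor))
    p[names(anchor)] <- anchor
    rem <- 1 - sum(anchor)
    p[rest] <- rem * background[rest] / sum(background[rest])
  }
  p / sum(p)
}

draw_sequences <- function(n, len, component) {
  background <- component$background %||% setNames(rep(1 / 20, 20), AA_ALPHABET)
  background <- background[AA_ALPHABET] / sum(background)
  anchors <- component$anchors %||% list()
  cols <- lapply(seq_len(len), function(pos) {
    key <- if (pos == len && "omega" %in% names(anchors)) "omega" else as.character(pos)
    a <- if (key %in% names(anchors)) anchors[[key]] else numeric(0)
    sample(AA_ALPHABET, n, replace = TRUE, prob = position_distribution(a, background))
  })
  do.call(paste0, cols)
}

draw_unique_peptides <- function(n, cl) {
  lens <- as.integer(names(cl$length_probs))
  comp_w <- vapply(cl$motif, function(m) m$weight, numeric(1))
  seqs <- character(0)
  # top up until n unique; collisions are rare at these lengths
  while (length(seqs) < n) {
    need <- n - length(seqs)
    len_draw <- lens[sample.int(length(lens), need, replace = TRUE, prob = cl$length_probs)]
    comp_draw <- sample(seq_along(cl$motif), need, replace = TRUE, prob = comp_w)
    batch <- character(need)
    for (ci in unique(comp_draw)) {
      for (l in unique(len_draw[comp_draw == ci])) {
        idx <- which(comp_draw == ci & len_draw == l)
        batch[idx] <- draw_sequences(length(idx), l, cl$motif[[ci]])
      }
    }
    seqs <- unique(c(seqs, batch))
  }
  seqs[seq_len(n)]
}

#' Generate a synthetic immunopeptidome
#'
#' Draws the peptide observation table the analysis stages consume:
#' candidate unique sequences per cell line from the configured motif
#' mixture and length distribution, a shared pool injected across cell
#' lines (controlled overlap), per-replicate Bernoulli detection
#' (sequences detected in no replicate are never observed), log-normal
#' intensities per observation, and a synthetic source-protein accession
#' per sequence. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A peptide tibble in the [read_peptide_table()] schema, with the
#'   source-protein pool (tibble `accession`, `neural`) attached as
#'   attribute `proteins`.
#' @export
generate_peptidome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    proteins <- tibble(
      accession = sprintf("SYNP%04d", seq_len(config$n_proteins)),
      neural = seq_len(config$n_proteins) <= round(config$neural_fraction * config$n_proteins)
    )
    n_shared <- floor(config$shared_fraction *
                        min(vapply(config$cell_lines, `[[`, integer(1), "n_unique")))
    shared_pool <- if (n_shared > 0) {
      draw_unique_peptides(n_shared, config$cell_lines[[1]])
    } else character(0)
    out <- purrr::imap_dfr(config$cell_lines, function(cl, nm) {
      own <- setdiff(draw_unique_peptides(cl$n_unique, cl), shared_pool)
      seqs <- c(shared_pool, own)[seq_len(cl$n_unique)]
      det <- matrix(rbinom(length(seqs) * cl$n_replicates, 1L, cl$detection_prob) == 1L,
                    nrow = length(seqs))
      obs_idx <- which(det, arr.ind = TRUE)
      acc <- sample(proteins$accession, length(seqs), replace = TRUE)
      tibble(
        sequence = seqs[obs_idx[, 1]],
        cell_line = nm,
        replicate = as.integer(obs_idx[, 2]),
        intensity = rlnorm(nrow(obs_idx), cl$intensity_meanlog, cl$intensity_sdlog),
        source_accessions = acc[obs_idx[, 1]]
      ) %>% arrange(.data$replicate, .data$sequence)
    })
    attr(out, "proteins") <- proteins
    out
  })
}

#' Generate a synthetic MHC-I allele set with planted pocket identity
#'
#' Emits a reference allele, a query allele and a database of subject
#' alleles, all the same (ungapped) length, with controlled identity to
#' the query at pocket versus non-pocket positions. One planted subject is
#' identical to the query at every (expanded) pocket position but
#' divergent elsewhere — the ground-truth top hit for [scan_database()];
#' the other subjects match the query at a bounded random fraction
#' (`max_db_pocket_identity`) of pocket positions, so none can tie the
#' planted subject.
#'
#' @param seed Integer seed.
#' @param n_db Number of database subjects (including the planted one),
#'   default 50.
#' @param seq_length Ungapped allele length, default 182 (an
#'   alpha1-alpha2 region).
#' @param model [pocket_model()] defining the pocket positions; default F
#'   pocket with adjacency expansion.
#' @param max_db_pocket_identity Upper bound on non-planted subjects'
#'   pocket identity fraction, default 0.8.
#' @param nonpocket_identity Probability a subject matches the query at a
#'   non-pocket position, default 0.5.
#' @return A list with `alleles` (tibble `name`, `group`, `sequence`,
#'   `role` in reference/query/db) and `ground_truth` (list: `planted`
#'   subject name, `positions` used, per-subject `pocket_identity`
#'   tibble).
#' @export
generate_allele_set <- function(seed = 1, n_db = 50, seq_length = 182,
                                model = pocket_model("F"),
                                max_db_pocket_identity = 0.8,
                                nonpocket_identity = 0.5) {
  positions <- model$positions[model$positions <= seq_length]
  if (length(positions) == 0L) abort("pocket positions inconsistent with seq_length")
  withr::with_seed(seed, {
    reference <- paste(sample(AA_ALPHABET, seq_length, replace = TRUE), collapse = "")
    ref_chars <- strsplit(reference, "")[[1]]
    q_chars <- ref_chars
    flip <- sample(seq_length, round(0.3 * seq_length))
    q_chars[flip] <- vapply(q_chars[flip], function(a) sample(setdiff(AA_ALPHABET, a), 1), "")
    nonpocket <- setdiff(seq_len(seq_length), positions)
    make_subject <- function(pocket_frac) {
      s <- vapply(seq_len(seq_length), function(i) sample(AA_ALPHABET, 1), "")
      keep_np <- nonpocket[stats::runif(length(nonpocket)) < nonpocket_identity]
      s[keep_np] <- q_chars[keep_np]
      keep_p <- sample(positions, round(pocket_frac * length(positions)))
      s[positions] <- vapply(positions, function(i) {
        if (i %in% keep_p) q_chars[i] else sample(setdiff(AA_ALPHABET, q_chars[i]), 1)
      }, "")
      paste(s, collapse = "")
    }
    fracs <- c(1, stats::runif(n_db - 1, 0, max_db_pocket_identity))
    db_seqs <- vapply(fracs, make_subject, "")
    nm <- c("SUBJ_PLANTED", sprintf("SUBJ%03d", seq_len(n_db - 1)))
    alleles <- dplyr::bind_rows(
      tibble(name = "REF", group = "REF", sequence = reference, role = "reference"),
      tibble(name = "QUERY", group = "QUERY",
             sequence = paste(q_chars, collapse = ""), role = "query"),
      tibble(name = nm, group = nm, sequence = db_seqs, role = "db")
    )
    list(alleles = alleles,
         ground_truth = list(
           planted = "SUBJ_PLANTED", positions = positions,
           pocket_identity = tibble(name = nm, identity = fracs)
         ))
  })
}

#' Generate a synthetic alpha-chain digest for allotype quantification
#'
#' Simulates the tryptic/chymotryptic digest of immunoprecipitated MHC-I
#' alpha chains: peptides are substrings (7-25 residues) of allele
#' sequences, each replicate carries a planted per-group intensity share,
#' and group presence per replicate is configurable to exercise the
#' replicate-presence rule. Within each replicate, group intensity sums
#' are scaled to the planted abundance fractions (peptide-level
#' log-normal variation is preserved within groups), so the planted
#' normalized-intensity split is recoverable.
#'
#' @param alleles Allele tibble (`name`, `group`, `sequence`).
#' @param seed Integer seed.
#' @param cell_line Label for the output table, default `"synthetic"`.
#' @param n_replicates Replicates, default 4.
#' @param n_peptides_per_replicate Peptides drawn per replicate,
#'   default 500.
#' @param group_abundance Named planted intensity shares per group
#'   (renormalised over the groups present in each replicate); default
#'   uniform.
#' @param replicate_presence Named list group -> integer replicates in
#'   which the group is present; default all replicates for all groups.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity
#'   parameters.
#' @return A peptide tibble in the [read_peptide_table()] schema (the
#'   group each peptide was drawn from is *not* included — assignment is
#'   the analysis module's job).
#' @export
generate_alpha_chain_digest <- function(alleles, seed = 1,
                                        cell_line = "synthetic",
                                        n_replicates = 4,
                                        n_peptides_per_replicate = 500,
                                        group_abundance = NULL,
                                        replicate_presence = NULL,
                                        intensity_meanlog = log(1e6),
                                        intensity_sdlog = 1) {
  groups <- unique(alleles$group)
  if (is.null(group_abundance)) {
    group_abundance <- setNames(rep(1 / length(groups), length(groups)), groups)
  }
  stopifnot(setequal(names(group_abundance), groups), all(group_abundance > 0))
  if (is.null(replicate_presence)) {
    replicate_presence <- setNames(rep(list(seq_len(n_replicates)), length(groups)), groups)
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      present <- groups[vapply(groups, function(g) r %in% replicate_presence[[g]], TRUE)]
      if (length(present) == 0L) return(empty_peptide_table())
      ab <- group_abundance[present] / sum(group_abundance[present])
      g_draw <- sample(present, n_peptides_per_replicate, replace = TRUE,
                       prob = ab)
      pep <- vapply(g_draw, function(g) {
        allele_seq <- sample(alleles$sequence[alleles$group == g], 1)
        len <- sample(7:min(25, nchar(allele_seq)), 1)
        start <- sample(nchar(allele_seq) - len + 1, 1)
        substr(allele_seq, start, start + len - 1)
      }, "")
      intensity <- rlnorm(n_peptides_per_replicate, intensity_meanlog, intensity_sdlog)
      total <- sum(intensity)
      for (g in present) {
        idx <- g_draw == g
        if (any(idx)) intensity[idx] <- intensity[idx] * ab[[g]] * total / sum(intensity[idx])
      }
      tibble(sequence = pep, cell_line = cell_line, replicate = r,
             intensity = intensity, source_accessions = "")
    })
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
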