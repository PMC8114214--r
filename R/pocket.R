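#' Reference-numbered positions of the MHC-I B and F pockets
#'
#' Residue positions lining the B pocket (accommodating the p2 anchor) and
#' F pocket (accommodating the pOmega anchor) of the MHC-I peptide binding
#' groove, numbered on the mature-chain coordinates of an HLA-A*02:01
#' reference after multiple sequence alignment.
#'
#' @format Integer vectors.
#' @name pocket_positions
NULL

#' @rdname pocket_positions
#' @export
B_POCKET_POSITIONS <- c(7L, 9L, 24L, 34L, 45L, 63L, 66L, 67L, 70L, 99L)

#' @rdname pocket_positions
#' @export
F_POCKET_POSITIONS <- c(77L, 80L, 81L, 84L, 94L, 115L, 122L, 142L, 145L, 146L)

#' Construct a pocket scoring model
#'
#' Bundles everything needed to score pocket-level homology between MHC-I
#' alleles: the pocket's reference-numbered positions (optionally expanded
#' to adjacent residues, which buffers minor register shifts between
#' alleles), per-position contact-probability weights, and a 20x20
#' amino-acid similarity matrix.
#'
#' @param name `"B"` or `"F"` (selects default positions), or any label
#'   when `positions` is supplied.
#' @param positions Integer positions; defaults to
#'   [B_POCKET_POSITIONS]/[F_POCKET_POSITIONS] by `name`.
#' @param include_adjacent Expand the position set by `adjacent_radius` on
#'   each side. Default `TRUE` for the F pocket, `FALSE` for B.
#' @param adjacent_radius Expansion radius in reference numbering,
#'   default 1.
#' @param weights Contact-weight tibble (`position`, `weight` in `[0,1]`)
#'   covering every expanded position; defaults to uniform weight 1.
#' @param matrix 20x20 similarity matrix; defaults to
#'   [synthetic_similarity_matrix()].
#' @return An object of class `pocket_model` with elements `name`,
#'   `positions` (expanded, sorted), `core_positions`, `weights` (named
#'   numeric by position), `matrix`.
#' @export
pocket_model <- function(name = c("B", "F"), positions = NULL,
                         include_adjacent = NULL, adjacent_radius = 1,
                         weights = NULL, matrix = NULL) {
  if (is.null(positions)) {
    name <- match.arg(name)
    positions <- if (name == "B") B_POCKET_POSITIONS else F_POCKET_POSITIONS
  } else {
    name <- name[1]
  }
  positions <- as.integer(positions)
  if (any(positions < 1) || is.unsorted(positions, strictly = TRUE)) {
    abort("pocket positions must be strictly increasing and >= 1")
  }
  if (is.null(include_adjacent)) include_adjacent <- identical(name, "F")
  expanded <- if (include_adjacent) {
    expand_pocket_positions(positions, adjacent_radius)
  } else positions
  if (is.null(matrix)) matrix <- synthetic_similarity_matrix()
  if (!identical(dim(matrix), c(20L, 20L))) abort("similarity matrix must be 20x20")
  if (is.null(weights)) weights <- uniform_contact_weights(expanded)
  w <- setNames(weights$weight, weights$position)
  missing_w <- setdiff(as.character(expanded), names(w))
  if (length(missing_w)) {
    abort(paste0("contact weight missing for position(s): ",
                 paste(missing_w, collapse = ", ")))
  }
  structure(
    list(name = name, positions = expanded, core_positions = positions,
         weights = w[as.character(expanded)], matrix = matrix),
    class = "pocket_model"
  )
}

#' Expand pocket positions to adjacent residues
#'
#' Adds every position within `radius` of a pocket position (in reference
#' numbering), deduplicates, and drops positions below 1. Positions beyond
#' the reference length are clipped later, when mapping onto an actual
#' alignment.
#'
#' @param positions Integer vector of positions.
#' @param radius Non-negative expansion radius, default 1.
#' @return Sorted integer vector.
#' @export
expand_pocket_positions <- function(positions, radius = 1) {
  stopifnot(radius >= 0)
  out <- sort(unique(as.integer(outer(positions, -radius:radius, `+`))))
  out[out >= 1L]
}

#' Map reference-numbered positions through a multiple alignment
#'
#' Locates each 1-based position of the ungapped reference sequence in the
#' alignment (via the reference row's gap structure) and reports every
#' sequence's residue in that alignment column (`"-"` where a sequence is
#' gapped).
#'
#' @param msa Named character vector of aligned (equal-length, gapped)
#'   sequences, including the reference.
#' @param positions Integer positions on the ungapped reference.
#' @param reference Name of the reference row in `msa`.
#' @return A tibble `name`, `position`, `residue`.
#' @export
map_reference_positions <- function(msa, positions, reference) {
  if (!reference %in% names(msa)) abort(paste0("reference '", reference, "' absent from alignment"))
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) abort("aligned sequences must have equal length")
  ref_chars <- strsplit(msa[[reference]], "", fixed = TRUE)[[1]]
  ungapped_idx <- cumsum(ref_chars != "-")
  ref_len <- ungapped_idx[length(ungapped_idx)]
  if (any(positions > ref_len)) {
    abort(paste0("position(s) beyond reference length ", ref_len, ": ",
                 paste(positions[positions > ref_len], collapse = ", ")))
  }
  cols <- vapply(positions, function(p) {
    which(ungapped_idx == p & ref_chars != "-")[1]
  }, integer(1))
  purrr::map_dfr(names(msa), function(nm) {
    chars <- strsplit(msa[[nm]], "", fixed = TRUE)[[1]]
    tibble(name = nm, position = as.integer(positions), residue = chars[cols])
  })
}

#' Align sequences pairwise against a reference
#'
#' Global pairwise alignment (BLOSUM62, affine gap open 10 / extend 1) of
#' each sequence against the reference, used when no precomputed multiple
#' alignment is supplied. Suitable for closely related allele sets and
#' synthetic tests; a real cross-species scan should supply a proper
#' multiple alignment to [scan_database()].
#'
#' @param sequences Named character vector of ungapped protein sequences.
#' @param reference Single ungapped reference sequence.
#' @return A list of two-row aligned pairs: for each input, a named
#'   character vector `c(reference = ..., <name> = ...)` of equal-length
#'   gapped strings.
#' @export
align_to_reference <- function(sequences, reference) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  purrr::imap(sequences, function(sq, nm) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sq), Biostrings::AAString(reference),
      type = "global", substitutionMatrix = B62,
      gapOpening = 10, gapExtension = 1
    )
    out <- c(as.character(Biostrings::alignedSubject(aln)),
             as.character(Biostrings::alignedPattern(aln)))
    names(out) <- c("__reference__", nm)
    out
  })
}

#' Score one query-subject pair at pocket positions
#'
#' The pocket homology score is the contact-weighted similarity sum over
#' the model's (expanded) pocket positions:
#' `score = sum_p w(p) * M[query(p), subject(p)]`. The maximum attainable
#' score is the query's self-score `sum_p w(p) * M[query(p), query(p)]`,
#' and a pair *passes* when `score >= cutoff * max_score` (default cutoff
#' 0.93). A gap at a pocket position contributes the matrix's global
#' minimum (weighted), penalising missing pocket residues.
#'
#' @param query_residues,subject_residues Named character vectors of
#'   residues (names = positions, `"-"` for gaps) covering the model's
#'   positions.
#' @param model A [pocket_model()].
#' @param cutoff Fraction of the maximum score required to pass,
#'   default 0.93.
#' @return A one-row tibble `score`, `max_score`, `relative_score`,
#'   `passes`.
#' @export
pocket_score <- function(query_residues, subject_residues, model, cutoff = 0.93) {
  pos <- as.character(model$positions)
  missing_q <- setdiff(pos, names(query_residues))
  missing_s <- setdiff(pos, names(subject_residues))
  if (length(missing_q) || length(missing_s)) {
    abort("residue vectors must cover every model position")
  }
  w <- model$weights
  q <- query_residues[pos]
  s <- subject_residues[pos]
  score <- sum(w * pair_similarity(q, s, model$matrix))
  max_score <- sum(w * pair_similarity(q, q, model$matrix))
  if (max_score <= 0) abort("degenerate similarity matrix: query self-score <= 0")
  tibble(score = score, max_score = max_score,
         relative_score = score / max_score,
         passes = score >= cutoff * max_score)
}

pair_similarity <- function(a, b, M) {
  mmin <- min(M)
  out <- numeric(length(a))
  gap <- a == "-" | b == "-"
  out[gap] <- mmin
  if (any(!gap)) out[!gap] <- M[cbind(a[!gap], b[!gap])]
  out
}

#' Scan an allele database for pocket homology and transfer motifs
#'
#' Scores one query allele against every database allele at the model's
#' pocket positions, ranks hits by relative score, and, when a
#' subject-allele-to-motif annotation table is supplied, transfers the
#' pocket motifs of the top `k` passing matches to the query. When no
#' subject reaches the cutoff the report states that no pocket prediction
#' is possible.
#'
#' @param query One-row tibble (or list) with `name` and `sequence`.
#' @param db Allele tibble with columns `name`, `sequence`.
#' @param model A [pocket_model()].
#' @param reference One-row tibble (or list) with `name`, `sequence`: the
#'   allele defining the position numbering.
#' @param k Number of top passing matches whose motifs are transferred,
#'   default 3.
#' @param cutoff Pass threshold as a fraction of the query self-score,
#'   default 0.93.
#' @param motifs Optional annotation tibble `allele`, `pocket`, `motif`.
#' @param msa Optional precomputed multiple alignment: named character
#'   vector of gapped sequences containing the reference, query and all
#'   database alleles. When `NULL`, each sequence is aligned pairwise to
#'   the reference with [align_to_reference()].
#' @return An object of class `pocket_scan`: list with `query`, `pocket`,
#'   `cutoff`, `matches` (tibble `subject`, `score`, `max_score`,
#'   `relative_score`, `passes`, ranked), `top_motifs` (tibble `subject`,
#'   `relative_score`, `motif`), `no_prediction` flag. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
scan_database <- function(query, db, model, reference, k = 3, cutoff = 0.93,
                          motifs = NULL, msa = NULL) {
  query <- as.list(query)
  reference <- as.list(reference)
  if (nrow(db) == 0L) abort("allele database is empty")
  if (anyDuplicated(db$name)) abort("duplicate allele names in database")
  ref_len <- nchar(reference$sequence)
  positions <- model$positions[model$positions <= ref_len]
  if (length(positions) == 0L) abort("no pocket positions fall within the reference sequence")
  clipped <- model
  clipped$positions <- positions
  clipped$weights <- model$weights[as.character(positions)]

  residues_of <- function(nm, sq) {
    if (!is.null(msa)) {
      if (!nm %in% names(msa)) abort(paste0("sequence '", nm, "' absent from supplied alignment"))
      mapped <- map_reference_positions(msa[c(reference$name, nm)], positions, reference$name)
    } else {
      pair <- align_to_reference(setNames(sq, nm), reference$sequence)[[1]]
      mapped <- map_reference_positions(pair, positions, "__reference__")
    }
    row <- mapped[mapped$name == nm, ]
    setNames(row$residue, row$position)
  }

  q_res <- residues_of(query$name, query$sequence)
  scores <- purrr::map_dfr(seq_len(nrow(db)), function(i) {
    s_res <- residues_of(db$name[i], db$sequence[i])
    sc <- pocket_score(q_res, s_res, clipped, cutoff)
    mutate(sc, subject = db$name[i], .before = 1)
  })
  matches <- scores %>%
    arrange(desc(.data$relative_score), .data$subject) %>%
    mutate(rank = row_number())
  passing <- filter(matches, .data$passes)
  top <- head(passing, k)
  top_motifs <- if (!is.null(motifs) && nrow(top) > 0) {
    motifs %>%
      filter(.data$pocket == model$name, .data$allele %in% top$subject) %>%
      left_join(select(top, subject = "subject", "relative_score"),
                by = c(allele = "subject")) %>%
      arrange(desc(.data$relative_score)) %>%
      select(subject = "allele", "relative_score", "motif")
  } else {
    tibble(subject = character(), relative_score = double(), motif = character())
  }
  structure(
    list(query = query$name, pocket = model$name, cutoff = cutoff,
         matches = matches, top_motifs = top_motifs,
         no_prediction = nrow(passing) == 0L),
    class = "pocket_scan"
  )
}

#' @export
print.pocket_scan <- function(x, ...) {
  cat("Pocket homology scan: query ", x$query, ", pocket ", x$pocket,
      ", cutoff ", x$cutoff, "\n", sep = "")
  if (x$no_prediction) {
    cat("No subject passed the cutoff: no predicted", x$pocket, "pocket\n")
  } else {
    print(head(x$matches, 5))
    if (nrow(x$top_motifs)) {
      cat("Transferred motifs:\n")
      print(x$top_motifs)
    }
  }
  invisible(x)
}

#' Tidy a pocket scan
#'
#' @param x A `pocket_scan` from [scan_database()].
#' @param ... Unused.
#' @return The ranked match tibble with `query` and `pocket` columns added.
#' @export
tidy.pocket_scan <- function(x, ...) {
  mutate(x$matches, query = x$query, pocket = x$pocket, .before = 1)
}

#' One-line summary of a pocket scan
#'
#' @inheritParams tidy.pocket_scan
#' @return A one-row tibble `query`, `pocket`, `cutoff`, `n_subjects`,
#'   `n_passing`, `no_prediction`.
#' @export
glance.pocket_scan <- function(x, ...) {
  tibble(query = x$query, pocket = x$pocket, cutoff = x$cutoff,
         n_subjects = nrow(x$matches), n_passing = sum(x$matches$passes),
         no_prediction = x$no_prediction)
}
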