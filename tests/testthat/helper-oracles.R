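# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles are deliberately naive (per-element loops) so they
# share no code path with the implementation they check.

pep_tbl <- function(seqs, cell_line = "x", replicate = 1L, intensity = NA_real_) {
  tibble::tibble(sequence = seqs, cell_line = cell_line,
                 replicate = as.integer(replicate), intensity = intensity,
                 source_accessions = "")
}

# deterministic enumeration of distinct sequences of a given length
enum_seqs <- function(n, len) {
  stopifnot(n <= 20^min(len, 12))
  vapply(seq_len(n) - 1, function(i) {
    digits <- integer(len)
    for (p in seq_len(len)) {
      digits[p] <- i %% 20
      i <- i %/% 20
    }
    paste(AA_ALPHABET[digits + 1], collapse = "")
  }, "")
}

random_peps <- function(n, len) {
  unique(vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, ""))
}

# Venn partition by exhaustive per-sequence membership enumeration.
oracle_venn <- function(sets) {
  lines <- sort(names(sets))
  universe <- unique(unlist(sets))
  combos <- unlist(lapply(seq_along(lines), function(k) {
    utils::combn(lines, k, paste, collapse = "&")
  }))
  counts <- setNames(integer(length(combos)), combos)
  for (s in universe) {
    members <- lines[vapply(lines, function(l) s %in% sets[[l]], TRUE)]
    key <- paste(members, collapse = "&")
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Brute-force substring scan of every peptide against every allele.
oracle_assign <- function(seqs, alleles) {
  vapply(seqs, function(p) {
    groups <- character(0)
    for (i in seq_len(nrow(alleles))) {
      if (grepl(p, alleles$sequence[i], fixed = TRUE)) {
        groups <- union(groups, alleles$group[i])
      }
    }
    if (length(groups) == 1) groups else if (length(groups) == 0) "unmatched" else "ambiguous"
  }, "")
}

# Per-position weighted similarity sum, written as an explicit loop.
oracle_pocket_score <- function(q, s, weights, M) {
  total <- 0
  for (p in names(weights)) {
    a <- q[[p]]; b <- s[[p]]
    sim <- if (a == "-" || b == "-") min(M) else M[a, b]
    total <- total + weights[[p]] * sim
  }
  total
}

# Reference-position mapping via a per-column ungapped counter.
oracle_map_positions <- function(aligned_ref, positions) {
  chars <- strsplit(aligned_ref, "")[[1]]
  cols <- integer(length(positions))
  counter <- 0L
  for (col in seq_along(chars)) {
    if (chars[col] != "-") {
      counter <- counter + 1L
      hit <- which(positions == counter)
      if (length(hit)) cols[hit] <- col
    }
  }
  cols
}

# identity-like similarity matrix (diag 1, off-diagonal 0)
identity_matrix20 <- function() {
  M <- diag(20)
  dimnames(M) <- list(AA_ALPHABET, AA_ALPHABET)
  M
}
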