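toy_model <- function(n_pos = 10, matrix = identity_matrix20(), weights = NULL) {
  positions <- seq(2L, by = 3L, length.out = n_pos)
  pocket_model("toy", positions = positions, include_adjacent = FALSE,
               weights = weights, matrix = matrix)
}

residues_at <- function(seq, positions) {
  setNames(strsplit(seq, "")[[1]][positions], positions)
}

test_that("reference-position mapping follows the reference gap structure", {
  msa <- c(ref = "ACDEF", qry = "ACDEF")
  m <- map_reference_positions(msa, c(1, 3, 5), "ref")
  expect_equal(m$residue[m$name == "qry"], c("A", "D", "F"))

  # reference "AC-DE" over ungapped "ACDE": position 3 (D) is column 4
  msa2 <- c(ref = "AC-DE", qry = "ACWDE")
  m2 <- map_reference_positions(msa2, 3, "ref")
  expect_equal(m2$residue[m2$name == "qry"], "D")
  expect_equal(m2$residue[m2$name == "ref"], "D")
  gappy <- c(ref = "AC-DE", qry = "AC-D-")
  expect_equal(map_reference_positions(gappy, 4, "ref")$residue, c("E", "-"))

  expect_error(map_reference_positions(msa2, 5, "ref"), "beyond reference")
  expect_error(map_reference_positions(msa2, 1, "nope"), "absent")
})

test_that("position mapping equals a brute-force ungapped counter on random alignments", {
  withr::with_seed(91, {
    for (i in 1:20) {
      len <- sample(30:60, 1)
      chars <- sample(c(AA_ALPHABET, "-"), len, replace = TRUE, prob = c(rep(0.045, 20), 0.1))
      if (all(chars == "-")) chars[1] <- "A"
      ref <- paste(chars, collapse = "")
      n_ref <- sum(chars != "-")
      positions <- sort(sample(n_ref, min(5, n_ref)))
      m <- map_reference_positions(c(r = ref), positions, "r")
      cols <- oracle_map_positions(ref, positions)
      expect_equal(m$residue, strsplit(ref, "")[[1]][cols])
    }
  })
})

test_that("pocket score is exact on hand-computed examples", {
  model <- toy_model(10)
  q <- setNames(rep("L", 10), model$positions)
  self <- pocket_score(q, q, model)
  expect_equal(self$relative_score, 1)
  expect_true(self$passes)
  expect_equal(self$score, self$max_score)

  s <- q
  s[[4]] <- "V"  # identity matrix, uniform weights: 9 matches / 1 mismatch
  one_off <- pocket_score(q, s, model)
  expect_equal(one_off$relative_score, 0.9)
  expect_false(one_off$passes)

  # a relative score of exactly 0.93 passes (>= rule)
  model100 <- pocket_model("toy100", positions = 1:100, include_adjacent = FALSE,
                           matrix = identity_matrix20())
  q100 <- setNames(rep("L", 100), 1:100)
  s100 <- q100
  s100[1:7] <- "V"
  at_cut <- pocket_score(q100, s100, model100)
  expect_equal(at_cut$relative_score, 0.93)
  expect_true(at_cut$passes)
  expect_false(pocket_score(q100, s100, model100, cutoff = 0.9301)$passes)
})

test_that("pocket score equals the brute-force weighted sum", {
  M <- synthetic_similarity_matrix()
  withr::with_seed(17, {
    for (i in 1:25) {
      n_pos <- sample(5:15, 1)
      positions <- sort(sample(60, n_pos))
      w <- uniform_contact_weights(positions)
      w$weight <- round(runif(n_pos), 3)
      model <- pocket_model("rand", positions = positions,
                            include_adjacent = FALSE, weights = w, matrix = M)
      q <- setNames(sample(AA_ALPHABET, n_pos, replace = TRUE), positions)
      s <- setNames(sample(c(AA_ALPHABET, "-"), n_pos, replace = TRUE), positions)
      got <- pocket_score(q, s, model)
      expected <- oracle_pocket_score(as.list(q), as.list(s),
                                      setNames(w$weight, w$position), M)
      expect_equal(got$score, expected, tolerance = 1e-12)
    }
  })
})

test_that("relative score is invariant to uniform weight rescaling", {
  M <- synthetic_similarity_matrix()
  positions <- B_POCKET_POSITIONS
  q <- setNames(sample(AA_ALPHABET, length(positions), replace = TRUE), positions)
  s <- setNames(sample(AA_ALPHABET, length(positions), replace = TRUE), positions)
  w1 <- uniform_contact_weights(positions, weight = 0.5)
  for (k in c(0.2, 1, 1.9)) {
    wk <- dplyr::mutate(w1, weight = weight * k)
    m1 <- pocket_model("B", positions = positions, include_adjacent = FALSE,
                       weights = w1, matrix = M)
    mk <- pocket_model("B", positions = positions, include_adjacent = FALSE,
                       weights = wk, matrix = M)
    expect_equal(pocket_score(q, s, m1)$relative_score,
                 pocket_score(q, s, mk)$relative_score, tolerance = 1e-9)
  }
})

test_that("restoring the query residue never decreases the score", {
  M <- synthetic_similarity_matrix()  # strictly row-maximal diagonal
  model <- toy_model(10, matrix = M)
  withr::with_seed(23, {
    for (i in 1:10) {
      q <- setNames(sample(AA_ALPHABET, 10, replace = TRUE), model$positions)
      s <- setNames(sample(AA_ALPHABET, 10, replace = TRUE), model$positions)
      base <- pocket_score(q, s, model)$score
      j <- sample(10, 1)
      s2 <- s
      s2[[j]] <- q[[j]]
      expect_gte(pocket_score(q, s2, model)$score, base)
    }
  })
})

test_that("gaps at pocket positions score the matrix minimum", {
  M <- synthetic_similarity_matrix()
  model <- toy_model(4, matrix = M)
  q <- setNames(c("L", "L", "L", "L"), model$positions)
  s <- setNames(c("L", "-", "L", "L"), model$positions)
  expect_equal(pocket_score(q, s, model)$score,
               3 * M["L", "L"] + min(M), tolerance = 1e-12)
})

test_that("adjacency expansion adds flanking reference positions", {
  expect_equal(expand_pocket_positions(c(5L, 6L, 10L), 1), c(4:7, 9:11))
  expect_equal(expand_pocket_positions(1L, 1), c(1L, 2L))
  f <- pocket_model("F")
  expect_true(all(F_POCKET_POSITIONS %in% f$positions))
  expect_true(all(c(76, 78, 147) %in% f$positions))
  b <- pocket_model("B")
  expect_equal(b$positions, B_POCKET_POSITIONS)
  expect_error(pocket_model("B", positions = c(5L, 3L)), "increasing")
})

test_that("a database containing the query ranks it first with relative score 1", {
  aset <- generate_allele_set(seed = 41, n_db = 8)
  ref <- aset$alleles[aset$alleles$role == "reference", ]
  qry <- aset$alleles[aset$alleles$role == "query", ]
  db <- dplyr::bind_rows(
    aset$alleles[aset$alleles$role == "db", ],
    tibble::tibble(name = "SELF", group = "SELF",
                   sequence = qry$sequence, role = "db")
  )
  model <- pocket_model("F")
  msa <- setNames(c(ref$sequence, qry$sequence, db$sequence),
                  c(ref$name, qry$name, db$name))
  scan <- scan_database(qry, db, model, ref, msa = msa)
  expect_equal(scan$matches$relative_score[scan$matches$subject == "SELF"], 1)
  expect_equal(scan$matches$rank[scan$matches$subject == "SELF"], 1L)
  expect_error(scan_database(qry, db[0, ], model, ref), "empty")
})

test_that("scan reports no prediction when nothing passes the cutoff", {
  withr::with_seed(3, {
    ref <- paste(sample(AA_ALPHABET, 150, replace = TRUE), collapse = "")
    qry <- paste(sample(AA_ALPHABET, 150, replace = TRUE), collapse = "")
    db_seqs <- vapply(1:5, function(i) {
      paste(sample(AA_ALPHABET, 150, replace = TRUE), collapse = "")
    }, "")
  })
  ref_t <- tibble::tibble(name = "REF", sequence = ref)
  qry_t <- tibble::tibble(name = "Q", sequence = qry)
  db_t <- tibble::tibble(name = paste0("S", 1:5), sequence = db_seqs)
  model <- pocket_model("B")
  msa <- setNames(c(ref, qry, db_seqs), c("REF", "Q", db_t$name))
  scan <- scan_database(qry_t, db_t, model, ref_t, msa = msa)
  expect_true(scan$no_prediction)
  expect_equal(nrow(scan$top_motifs), 0L)
})

test_that("a pocket-identical planted subject is the top hit and its motif transfers", {
  aset <- generate_allele_set(seed = 13, n_db = 50)
  ref <- aset$alleles[aset$alleles$role == "reference", ]
  qry <- aset$alleles[aset$alleles$role == "query", ]
  db <- aset$alleles[aset$alleles$role == "db", ]
  model <- pocket_model("F")
  msa <- setNames(c(ref$sequence, qry$sequence, db$sequence),
                  c(ref$name, qry$name, db$name))
  motifs <- tibble::tibble(allele = db$name, pocket = "F",
                           motif = paste0("x[LVF]-", db$name))
  scan <- scan_database(qry, db, model, ref, motifs = motifs, msa = msa)
  expect_equal(scan$matches$subject[1], aset$ground_truth$planted)
  expect_equal(scan$matches$relative_score[1], 1)
  expect_false(scan$no_prediction)
  expect_equal(scan$top_motifs$subject[1], "SUBJ_PLANTED")
  expect_s3_class(autoplot(scan), "ggplot")
  expect_equal(glance(scan)$n_subjects, 50L)
})

test_that("scan ranking ignores substitutions outside the expanded pocket", {
  aset <- generate_allele_set(seed = 19, n_db = 10)
  ref <- aset$alleles[aset$alleles$role == "reference", ]
  qry <- aset$alleles[aset$alleles$role == "query", ]
  db <- aset$alleles[aset$alleles$role == "db", ]
  model <- pocket_model("F")
  outside <- setdiff(seq_len(nchar(ref$sequence)), model$positions)
  db2 <- db
  withr::with_seed(7, {
    for (i in seq_len(nrow(db2))) {
      ch <- strsplit(db2$sequence[i], "")[[1]]
      flip <- sample(outside, 20)
      ch[flip] <- sample(AA_ALPHABET, 20, replace = TRUE)
      db2$sequence[i] <- paste(ch, collapse = "")
    }
  })
  msa1 <- setNames(c(ref$sequence, qry$sequence, db$sequence),
                   c(ref$name, qry$name, db$name))
  msa2 <- setNames(c(ref$sequence, qry$sequence, db2$sequence),
                   c(ref$name, qry$name, db2$name))
  s1 <- scan_database(qry, db, model, ref, msa = msa1)
  s2 <- scan_database(qry, db2, model, ref, msa = msa2)
  expect_equal(s1$matches$score, s2$matches$score, tolerance = 1e-12)
})

test_that("the pairwise-alignment fallback maps pocket residues like the trivial alignment", {
  # substitution-only variants of one reference: the gap-free alignment is
  # optimal, so pairwise alignment must reproduce the trivial column mapping
  withr::with_seed(29, {
    ref_seq <- paste(sample(AA_ALPHABET, 182, replace = TRUE), collapse = "")
    mutate_seq <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      at <- sample(length(ch), k)
      ch[at] <- vapply(ch[at], function(a) sample(setdiff(AA_ALPHABET, a), 1), "")
      paste(ch, collapse = "")
    }
    qry_seq <- mutate_seq(ref_seq, 30)
    db_seqs <- vapply(1:4, function(i) mutate_seq(ref_seq, 40), "")
  })
  ref <- tibble::tibble(name = "REF", sequence = ref_seq)
  qry <- tibble::tibble(name = "Q", sequence = qry_seq)
  db <- tibble::tibble(name = paste0("S", 1:4), sequence = db_seqs)
  model <- pocket_model("B")
  msa <- setNames(c(ref_seq, qry_seq, db_seqs), c("REF", "Q", db$name))
  via_msa <- scan_database(qry, db, model, ref, msa = msa)
  via_pairwise <- scan_database(qry, db, model, ref)
  expect_equal(via_pairwise$matches$score, via_msa$matches$score, tolerance = 1e-9)
})
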