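test_that("repertoire summary counts uniques and the 7-15 window", {
  # 100 unique sequences, 40 outside the window -> 60%
  seqs <- c(enum_seqs(60, 9), enum_seqs(25, 6), enum_seqs(15, 16))
  pep <- pep_tbl(c(seqs, seqs[1:10]))  # 10 duplicate observations
  s <- summarize_repertoire(pep)
  expect_equal(s$n_observations, 110L)
  expect_equal(s$n_unique, 100L)
  expect_equal(s$n_unique_7_15, 60L)
  expect_equal(s$pct_7_15, 60)
  expect_equal(s$pct_7_15_display, 60L)
  expect_true(all(s$n_unique_7_15 <= s$n_unique & s$n_unique <= s$n_observations))

  all9 <- summarize_repertoire(pep_tbl(enum_seqs(50, 9)))
  expect_equal(all9$pct_7_15, 100)
})

test_that("display percentage truncates to integer", {
  # 9207 in-window of 13636 unique = 67.52% -> printed as 67
  pep <- pep_tbl(c(enum_seqs(27, 9), enum_seqs(13, 16)))
  s <- summarize_repertoire(pep)
  expect_equal(s$pct_7_15, 100 * 27 / 40)
  expect_equal(s$pct_7_15_display, 67L)
})

test_that("length distribution matches planted length fractions", {
  set.seed(101)
  seqs <- c(random_peps(2000, 8), random_peps(1500, 9), random_peps(1500, 11))
  n <- length(seqs)
  ld <- length_distribution(pep_tbl(seqs))
  expect_equal(sum(ld$pct), 100, tolerance = 1e-9)
  expect_equal(ld$n_unique[ld$length == 8] / n, 0.4, tolerance = 0.002)
  # planted 40%/30% generator draw at n = 5000 recovered within 2 points
  cl <- cell_line_spec(
    n_unique = 5000, detection_prob = 1,
    length_probs = c(`8` = 0.4, `9` = 0.3, `10` = 0.3)
  )
  cfg <- synthetic_config(seed = 9, cell_lines = list(x = cl), shared_fraction = 0)
  pep <- generate_peptidome(cfg)
  ld2 <- length_distribution(pep)
  expect_lt(abs(ld2$pct[ld2$length == 8] - 40), 2)
  expect_lt(abs(ld2$pct[ld2$length == 9] - 30), 2)
})

test_that("length distribution agrees with the repertoire summary", {
  cfg <- synthetic_config(seed = 3, cell_lines = list(
    a = cell_line_spec(n_unique = 800), b = cell_line_spec(n_unique = 500)))
  pep <- generate_peptidome(cfg)
  ld <- length_distribution(pep)
  s <- summarize_repertoire(pep)
  by_line <- tapply(ld$n_unique, ld$cell_line, sum)
  expect_equal(as.integer(by_line[s$cell_line]), s$n_unique_7_15)
})

test_that("per-replicate length distribution reports SEM, or NA for one replicate", {
  pep <- pep_tbl(enum_seqs(40, 9), replicate = rep(1:2, each = 20))
  ld <- length_distribution(pep, per_replicate = TRUE)
  expect_true(all(is.finite(ld$sem_pct[ld$length == 9])))
  ld1 <- length_distribution(pep_tbl(enum_seqs(20, 9)), per_replicate = TRUE)
  expect_true(all(is.na(ld1$sem_pct)))
})

test_that("replicate reproducibility handles degenerate detection patterns", {
  seqs <- enum_seqs(30, 9)
  full <- dplyr::bind_rows(lapply(1:4, function(r) pep_tbl(seqs, replicate = r)))
  rr <- replicate_reproducibility(full)
  expect_equal(rr$pct[rr$k == 4], 100)
  expect_equal(sum(rr$pct), 100, tolerance = 1e-9)

  disjoint <- dplyr::bind_rows(
    pep_tbl(enum_seqs(10, 9), replicate = 1),
    pep_tbl(enum_seqs(20, 9)[11:20], replicate = 2)
  )
  rd <- replicate_reproducibility(disjoint)
  expect_equal(rd$pct[rd$k == 1], 100)
})

test_that("reproducibility percentages always sum to 100", {
  for (seed in 1:5) {
    cfg <- synthetic_config(seed = seed, cell_lines = list(
      a = cell_line_spec(n_unique = 300, detection_prob = 0.3 + 0.1 * seed)))
    pep <- generate_peptidome(cfg)
    rr <- replicate_reproducibility(pep)
    expect_equal(sum(rr$pct), 100, tolerance = 1e-9)
  }
})

test_that("venn partition handles identical and cyclic set families", {
  seqs <- enum_seqs(10, 9)
  pep <- dplyr::bind_rows(pep_tbl(seqs, "a"), pep_tbl(seqs, "b"), pep_tbl(seqs, "c"))
  ov <- venn_overlap(pep)
  expect_equal(ov$count[ov$region == "a&b&c"], 10L)
  expect_equal(sum(ov$count), 10L)

  pep2 <- dplyr::bind_rows(
    pep_tbl(c("AAAAAAAA", "CCCCCCCC"), "a"),
    pep_tbl(c("CCCCCCCC", "DDDDDDDD"), "b"),
    pep_tbl(c("DDDDDDDD", "AAAAAAAA"), "c")
  )
  ov2 <- venn_overlap(pep2)
  expect_equal(ov2$count[ov2$n_lines == 2], rep(1L, 3))
  expect_equal(ov2$count[ov2$region == "a&b&c"], 0L)
  expect_error(venn_overlap(pep_tbl(seqs, "only")), "two cell lines")
})

test_that("venn partition equals brute-force membership enumeration", {
  set.seed(77)
  for (i in 1:20) {
    pool <- enum_seqs(60, 9)
    sets <- list(a = sample(pool, sample(10:50, 1)),
                 b = sample(pool, sample(10:50, 1)),
                 c = sample(pool, sample(10:50, 1)))
    pep <- dplyr::bind_rows(purrr::imap(sets, function(s, nm) pep_tbl(s, nm)))
    ov <- venn_overlap(pep)
    expected <- oracle_venn(sets)
    expect_equal(setNames(ov$count, ov$region), expected[ov$region])
    expect_equal(sum(ov$count), length(unique(unlist(sets))))
  }
})

test_that("differential source-protein test behaves on fixed points", {
  expr <- tibble::tibble(
    accession = rep("P1", 6), group = rep(c("a", "b"), each = 3),
    replicate = rep(1:3, 2), value = rep(5, 6)
  )
  d <- differential_source_proteins(expr, "a", "b")
  expect_equal(d$log2_fc, 0)
  expect_equal(d$p_value, 1)

  set.seed(1)
  expr2 <- tibble::tibble(
    accession = "P2", group = rep(c("a", "b"), each = 3), replicate = rep(1:3, 2),
    value = rep(c(2, 1), each = 3) + rnorm(6, sd = 1e-4)
  )
  d2 <- differential_source_proteins(expr2, "a", "b")
  expect_equal(d2$log2_fc, 1, tolerance = 1e-3)
  expect_lt(d2$p_value, 1e-6)
})

test_that("non-positive raw intensities are excluded before log2", {
  expr <- tibble::tibble(
    accession = rep(c("P1", "P2"), each = 6),
    group = rep(rep(c("a", "b"), each = 3), 2),
    replicate = rep(1:3, 4),
    value = c(2, 4, 8, 2, 4, 8, 0, -1, 8, 2, 4, 8)
  )
  expect_warning(d <- differential_source_proteins(expr, "a", "b",
                                                   log2_transform = TRUE),
                 "non-positive")
  expect_equal(nrow(d), 1L)  # P2 drops below 2 replicates in group a
  expect_equal(d$log2_fc[d$accession == "P1"], 0)
})

test_that("differential test agrees with stats::t.test on random data", {
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4, mean = 0.5)
    expr <- tibble::tibble(accession = "P", group = rep(c("a", "b"), each = 4),
                           replicate = rep(1:4, 2), value = c(a, b))
    d <- differential_source_proteins(expr, "a", "b")
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(d$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(d$log2_fc, mean(a) - mean(b), tolerance = 1e-12)
  }
})
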