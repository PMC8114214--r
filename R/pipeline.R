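#' Default pipeline configuration
#'
#' The configuration skeleton consumed by [run_pipeline()]; user-supplied
#' configs (YAML) override any subset of these entries. Sizes are a
#' scaled-down emulation of a three-cell-line, four-replicate study.
#'
#' @param seed Integer seed.
#' @return A nested named list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    synth = list(
      shared_fraction = 0.1, n_proteins = 300, neural_fraction = 0.1,
      cell_lines = list(
        fibroblast = list(n_unique = 1500, n_replicates = 4,
                          detection_prob = 0.5, p3_leucine = 0.45),
        DFT1_IFNg = list(n_unique = 1100, n_replicates = 4,
                         detection_prob = 0.5, p3_leucine = 0.35),
        DFT2 = list(n_unique = 600, n_replicates = 4,
                    detection_prob = 0.5, p3_leucine = 0.45)
      )
    ),
    repertoire = list(min_len = 7, max_len = 15),
    motif = list(lengths = c(8, 9)),
    allotype = list(n_groups = 3, abundance = c(0.5, 0.3, 0.2),
                    n_peptides_per_replicate = 500, presence_threshold = 3,
                    n_replicates = 4),
    pocket = list(pocket = "F", cutoff = 0.93, top_k = 3,
                  adjacent_radius = 1, n_db = 50, seq_length = 182)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the end-to-end synthetic immunopeptidome analysis
#'
#' Executes the pipeline stages in dependency order — synthetic data
#' generation, repertoire statistics, motif derivation, allotype
#' quantification, pocket-homology scan — writing every stage's outputs
#' as delimited text under `outdir` together with a JSON run manifest.
#' Re-running with an identical config and seed reproduces all outputs.
#'
#' @param config `NULL` (defaults), a YAML file path, or a nested list
#'   overriding [default_run_config()] entries.
#' @param outdir Output directory, created if needed.
#' @param seed Optional seed overriding the config's.
#' @param quiet Suppress stage progress messages.
#' @return The run manifest, invisibly: a list with `config_hash`, `seed`,
#'   `version`, and per-stage output paths and record counts; also written
#'   to `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- default_run_config()
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(paste0("[immunopep] ", ...))
  stages <- list()
  out_path <- function(f) file.path(outdir, f)

  # -- synth ------------------------------------------------------------
  say("stage synth")
  syn_cfg <- synthetic_config(
    seed = cfg$seed,
    cell_lines = purrr::map(cfg$synth$cell_lines, function(cl) {
      do.call(cell_line_spec, cl)
    }),
    shared_fraction = cfg$synth$shared_fraction,
    n_proteins = cfg$synth$n_proteins,
    neural_fraction = cfg$synth$neural_fraction
  )
  peptides <- generate_peptidome(syn_cfg)
  write_peptide_table(peptides, out_path("peptides.csv"))
  aset <- generate_allele_set(seed = cfg$seed + 1000L, n_db = cfg$pocket$n_db,
                              seq_length = cfg$pocket$seq_length,
                              model = pocket_model(cfg$pocket$pocket,
                                                   adjacent_radius = cfg$pocket$adjacent_radius))
  write_allele_fasta(aset$alleles, out_path("alleles.fasta"))
  readr::write_tsv(aset$alleles[c("name", "group")], out_path("allele_groups.tsv"))
  digest_alleles <- random_allele_tibble(cfg$allotype$n_groups,
                                         seed = cfg$seed + 2000L)
  digest <- generate_alpha_chain_digest(
    digest_alleles, seed = cfg$seed + 3000L,
    n_replicates = cfg$allotype$n_replicates,
    n_peptides_per_replicate = cfg$allotype$n_peptides_per_replicate,
    group_abundance = setNames(cfg$allotype$abundance,
                               unique(digest_alleles$group))
  )
  write_peptide_table(digest, out_path("alpha_chain_digest.csv"))
  stages$synth <- list(outputs = c("peptides.csv", "alleles.fasta",
                                   "allele_groups.tsv", "alpha_chain_digest.csv"),
                       n_in = 0L, n_out = nrow(peptides) + nrow(digest))

  # -- repertoire -------------------------------------------------------
  say("stage repertoire")
  rp <- cfg$repertoire
  summ <- summarize_repertoire(peptides, rp$min_len, rp$max_len)
  ld <- length_distribution(peptides, rp$min_len, rp$max_len, per_replicate = TRUE)
  rep_rep <- replicate_reproducibility(peptides, rp$min_len, rp$max_len)
  ov <- venn_overlap(peptides, rp$min_len, rp$max_len)
  readr::write_csv(summ, out_path("repertoire_summary.csv"))
  readr::write_csv(ld, out_path("length_distribution.csv"))
  readr::write_csv(rep_rep, out_path("replicate_reproducibility.csv"))
  readr::write_csv(ov, out_path("overlap_regions.csv"))
  stages$repertoire <- list(
    outputs = c("repertoire_summary.csv", "length_distribution.csv",
                "replicate_reproducibility.csv", "overlap_regions.csv"),
    n_in = nrow(peptides),
    n_out = nrow(summ) + nrow(ld) + nrow(rep_rep) + nrow(ov)
  )

  # -- motif ------------------------------------------------------------
  say("stage motif")
  lines <- unique(peptides$cell_line)
  grid <- tidyr::expand_grid(cell_line = lines, length = cfg$motif$lengths)
  pfms <- purrr::pmap(grid, function(cell_line, length) {
    build_pfm(peptides, length, cell_line)
  })
  pfm_tbl <- purrr::map2_dfr(pfms, seq_len(nrow(grid)), function(p, i) {
    mutate(tidy(p), cell_line = grid$cell_line[i], length = grid$length[i],
           .before = 1)
  })
  consensus_tbl <- purrr::map2_dfr(pfms, seq_len(nrow(grid)), function(p, i) {
    mutate(classify_consensus(p), cell_line = grid$cell_line[i],
           length = grid$length[i], .before = 1)
  })
  usage <- small_bulky_usage(peptides, rp$min_len:rp$max_len, per_replicate = TRUE)
  readr::write_csv(pfm_tbl, out_path("pfm.csv"))
  readr::write_csv(consensus_tbl, out_path("consensus_motifs.csv"))
  readr::write_csv(usage, out_path("small_bulky_usage.csv"))
  stages$motif <- list(outputs = c("pfm.csv", "consensus_motifs.csv",
                                   "small_bulky_usage.csv"),
                       n_in = nrow(peptides),
                       n_out = nrow(pfm_tbl) + nrow(consensus_tbl) + nrow(usage))

  # -- allotype ---------------------------------------------------------
  say("stage allotype")
  quant <- quantify_allotypes(digest, digest_alleles,
                              presence_threshold = cfg$allotype$presence_threshold,
                              n_replicates = cfg$allotype$n_replicates)
  rep_int <- allotype_intensity_by_replicate(digest, digest_alleles)
  readr::write_csv(quant, out_path("allotype_quantification.csv"))
  readr::write_csv(rep_int, out_path("allotype_replicate_intensities.csv"))
  stages$allotype <- list(
    outputs = c("allotype_quantification.csv", "allotype_replicate_intensities.csv"),
    n_in = nrow(digest), n_out = nrow(quant) + nrow(rep_int)
  )

  # -- pocket -----------------------------------------------------------
  say("stage pocket")
  model <- pocket_model(cfg$pocket$pocket, adjacent_radius = cfg$pocket$adjacent_radius)
  ref <- dplyr::filter(aset$alleles, .data$role == "reference")
  qry <- dplyr::filter(aset$alleles, .data$role == "query")
  db <- dplyr::filter(aset$alleles, .data$role == "db")
  scan <- scan_database(qry, db, model, ref, k = cfg$pocket$top_k,
                        cutoff = cfg$pocket$cutoff)
  scan_tbl <- tidy(scan)
  readr::write_csv(scan_tbl, out_path("pocket_scan.csv"))
  stages$pocket <- list(outputs = "pocket_scan.csv",
                        n_in = nrow(db), n_out = nrow(scan_tbl))

  manifest <- list(
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("immunopep")),
    stages = purrr::imap(stages, function(s, nm) {
      s$outputs <- file.path(outdir, s$outputs)
      s
    })
  )
  for (s in manifest$stages) {
    missing <- s$outputs[!file.exists(s$outputs) | file.size(s$outputs) == 0]
    if (length(missing)) abort(paste0("pipeline output missing/empty: ",
                                      paste(missing, collapse = ", ")))
  }
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done; manifest at ", out_path("manifest.json"))
  invisible(manifest)
}

# Random, mutually dissimilar allele groups for digest simulations; the
# first group carries two alleles one substitution apart (a grouped pair
# indistinguishable at the peptide level).
random_allele_tibble <- function(n_groups, seed = 1, seq_length = 182) {
  withr::with_seed(seed, {
    groups <- paste0("SahaS*", seq_len(n_groups))
    seqs <- vapply(seq_len(n_groups), function(i) {
      paste(sample(AA_ALPHABET, seq_length, replace = TRUE), collapse = "")
    }, "")
    paired <- strsplit(seqs[1], "")[[1]]
    pos <- sample(seq_length, 1)
    paired[pos] <- sample(setdiff(AA_ALPHABET, paired[pos]), 1)
    dplyr::bind_rows(
      tibble(name = paste0(groups, "a"), group = groups, sequence = seqs),
      tibble(name = paste0(groups[1], "b"), group = groups[1],
             sequence = paste(paired, collapse = ""))
    )
  })
}
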