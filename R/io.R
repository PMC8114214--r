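#' Read a peptide identification table
#'
#' Ingests a delimited search-engine export of identified MHC-I peptides.
#' One row is one observation (duplicates across replicates and fractions
#' are retained); uniqueness is computed downstream. The delimiter (comma
#' or tab) is auto-detected from the header line. Sequences are uppercased;
#' rows whose sequence contains anything outside the 20 standard one-letter
#' codes are rejected, with the rejection count reported.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named character vector mapping logical fields
#'   (`sequence`, `cell_line`, `replicate`, `intensity`,
#'   `source_accessions`) to the file's column names. Defaults to identity
#'   naming. `intensity` and `source_accessions` are optional columns.
#' @return A tibble with columns `sequence`, `cell_line`, `replicate`
#'   (integer), `intensity` (double, `NA` allowed) and `source_accessions`
#'   (character, `";"`-separated accessions, possibly empty). The number of
#'   rejected rows is attached as attribute `n_rejected`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sequence,cell_line,replicate,intensity,source_accessions",
#'              "aslfelkv,fibroblast,1,1e6,SYNP1",
#'              "ASXLELKV,fibroblast,1,2e6,SYNP2"), tf)
#' pep <- read_peptide_table(tf)
#' attr(pep, "n_rejected")  # 1
read_peptide_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("peptide table not found: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    warn(paste0("empty peptide table: ", path))
    return(empty_peptide_table())
  }
  delim <- detect_delim(header)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    warn(paste0("peptide table has a header but no rows: ", path))
    return(empty_peptide_table())
  }
  schema <- resolve_schema(schema, names(raw))
  tbl <- tibble(
    sequence = toupper(raw[[schema[["sequence"]]]]),
    cell_line = raw[[schema[["cell_line"]]]],
    replicate = as.integer(raw[[schema[["replicate"]]]]),
    intensity = if (!is.na(schema[["intensity"]])) {
      suppressWarnings(as.numeric(raw[[schema[["intensity"]]]]))
    } else NA_real_,
    source_accessions = if (!is.na(schema[["source_accessions"]])) {
      tidyr::replace_na(raw[[schema[["source_accessions"]]]], "")
    } else ""
  )
  valid <- stringr::str_detect(tbl$sequence, "^[ACDEFGHIKLMNPQRSTVWY]+$")
  valid[is.na(valid)] <- FALSE
  n_rejected <- sum(!valid)
  if (n_rejected > 0L) {
    inform(paste0(n_rejected, " row(s) rejected for non-standard residues in ", basename(path)))
  }
  bad_rep <- !is.na(tbl$replicate) & tbl$replicate < 1L
  if (any(bad_rep)) abort("replicate numbers must be >= 1")
  if (anyNA(tbl$replicate)) abort("non-integer replicate values in peptide table")
  if (any(tbl$intensity < 0, na.rm = TRUE)) abort("negative intensities in peptide table")
  out <- tbl[valid, , drop = FALSE]
  attr(out, "n_rejected") <- n_rejected
  out
}

empty_peptide_table <- function() {
  tibble(sequence = character(), cell_line = character(),
         replicate = integer(), intensity = double(),
         source_accessions = character())
}

detect_delim <- function(header) {
  if (stringr::str_detect(header, "\t")) "\t" else ","
}

resolve_schema <- function(schema, cols) {
  fields <- c("sequence", "cell_line", "replicate", "intensity", "source_accessions")
  full <- setNames(fields, fields)
  if (!is.null(schema)) full[names(schema)] <- unname(schema)
  mandatory <- c("sequence", "cell_line", "replicate")
  for (f in mandatory) {
    if (!full[[f]] %in% cols) {
      abort(paste0("mandatory column '", full[[f]], "' (field ", f, ") missing from table"))
    }
  }
  for (f in setdiff(fields, mandatory)) {
    if (!full[[f]] %in% cols) full[[f]] <- NA_character_
  }
  full
}

#' Write a peptide table
#'
#' Inverse of [read_peptide_table()]: writes the observation table as
#' delimited text so that reading it back yields the identical record
#' multiset.
#'
#' @param peptides Peptide tibble (see [read_peptide_table()]).
#' @param path Output path.
#' @param delim `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path, delim = ",") {
  cols <- c("sequence", "cell_line", "replicate", "intensity", "source_accessions")
  missing <- setdiff(cols[1:3], names(peptides))
  if (length(missing)) abort(paste0("peptide table lacks column(s): ", paste(missing, collapse = ", ")))
  out <- peptides
  if (!"intensity" %in% names(out)) out$intensity <- NA_real_
  if (!"source_accessions" %in% names(out)) out$source_accessions <- ""
  readr::write_delim(out[cols], path, delim = delim, na = "")
  invisible(path)
}

#' Read MHC-I allele sequences from FASTA
#'
#' Reads protein FASTA of MHC-I alpha1-alpha2 sequences and attaches an
#' allotype group to each allele. Alleles indistinguishable at the peptide
#' level (for example two alleles differing by a single substitution) can be
#' collapsed into one group via `group_map`; without a map each allele is
#' its own group.
#'
#' @param path FASTA file with unique headers.
#' @param group_map Optional data frame with columns `name`, `group`.
#' @return A tibble with columns `name`, `group`, `sequence`.
#' @export
read_allele_fasta <- function(path, group_map = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  nm <- stringr::str_split_i(names(seqs), "\\s+", 1)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA header(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sq <- toupper(as.character(seqs))
  if (any(stringr::str_detect(sq, "^[ACGTN]+$") & nchar(sq) > 0)) {
    warn("sequence(s) containing only A/C/G/T/N look like nucleotides, not protein")
  }
  bad <- !stringr::str_detect(sq, "^[ACDEFGHIKLMNPQRSTVWYX*-]*$")
  if (any(bad)) abort(paste0("invalid protein sequence for: ", paste(nm[bad], collapse = ", ")))
  out <- tibble(name = nm, group = nm, sequence = unname(sq))
  if (!is.null(group_map)) {
    gm <- as_tibble(group_map)
    if (!all(c("name", "group") %in% names(gm))) abort("group_map needs columns 'name' and 'group'")
    if (anyDuplicated(gm$name)) abort("group_map maps an allele to more than one group")
    idx <- match(out$name, gm$name)
    out$group <- ifelse(is.na(idx), out$name, gm$group[idx])
  }
  out
}

#' Write allele sequences to FASTA
#'
#' @param alleles Tibble with columns `name`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(alleles, path) {
  x <- Biostrings::AAStringSet(setNames(alleles$sequence, alleles$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a 20x20 amino-acid similarity matrix
#'
#' Parses a labelled, whitespace- or comma-delimited 20x20 similarity matrix
#' (PMBEC-style). The matrix must contain each of the 20 standard residues
#' exactly once on both axes and be symmetric to within `tol`.
#'
#' @param path Delimited text file with row and column residue labels.
#' @param tol Symmetry tolerance (default `1e-9`).
#' @return A 20x20 numeric matrix with residue dimnames, rows and columns
#'   ordered alphabetically.
#' @export
read_similarity_matrix <- function(path, tol = 1e-9) {
  header <- readLines(path, n = 1L)
  delim <- if (stringr::str_detect(header, ",")) "," else NULL
  df <- if (is.null(delim)) {
    utils::read.table(path, header = TRUE, row.names = 1, check.names = FALSE)
  } else {
    utils::read.table(path, header = TRUE, row.names = 1, sep = ",", check.names = FALSE)
  }
  M <- as.matrix(df)
  if (!setequal(rownames(M), AA_ALPHABET) || !setequal(colnames(M), AA_ALPHABET)) {
    missing <- setdiff(AA_ALPHABET, union(rownames(M), colnames(M)))
    abort(paste0("similarity matrix must carry all 20 residues exactly once",
                 if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", "))))
  }
  M <- M[AA_ALPHABET, AA_ALPHABET]
  asym <- abs(M - t(M))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    abort(sprintf("similarity matrix asymmetric: M[%s,%s] vs M[%s,%s] differ by %.3g",
                  rownames(M)[ij[1]], colnames(M)[ij[2]],
                  rownames(M)[ij[2]], colnames(M)[ij[1]], max(asym)))
  }
  storage.mode(M) <- "double"
  M
}

#' Read per-residue contact-probability weights
#'
#' Parses a two-column delimited file of reference-numbered residue
#' positions and contact weights in `[0, 1]`.
#'
#' @param path Delimited text with columns `position`, `weight`.
#' @return A tibble with integer `position` and double `weight`.
#' @export
read_contact_weights <- function(path) {
  header <- readLines(path, n = 1L)
  tbl <- readr::read_delim(path, delim = detect_delim(header),
                           col_types = "id", progress = FALSE, show_col_types = FALSE)
  if (!all(c("position", "weight") %in% names(tbl))) {
    abort("contact weights file needs columns 'position' and 'weight'")
  }
  if (any(tbl$weight < 0 | tbl$weight > 1)) abort("contact weights must lie in [0, 1]")
  if (anyDuplicated(tbl$position)) abort("duplicate positions in contact weights")
  as_tibble(tbl[c("position", "weight")])
}

#' Read a pipeline run configuration
#'
#' Loads the YAML configuration driving [run_pipeline()]: synthetic
#' generation parameters, thresholds and the seed.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  yaml::read_yaml(path)
}
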