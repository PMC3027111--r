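#' Read a whole-proteome FASTA file
#'
#' One FASTA file is treated as one organism's proteome (one record per
#' protein). Sequences are uppercased; gap characters (`-`, `.`) and
#' translation stops (`*`, anywhere) are removed. All other symbols —
#' including non-canonical residue codes such as B, J, O, U, X, Z — are kept
#' verbatim; the alphabet policy is applied later, at counting time.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param organism_id Organism identifier; defaults to the file stem.
#'
#' @return A tibble with one row per protein and columns `organism_id`,
#'   `protein_id` (FASTA header up to the first space), `sequence`. Record
#'   order is preserved. Records that are empty after normalization are
#'   dropped with a warning.
#' @export
read_proteome <- function(path, organism_id = NULL) {
  if (!file.exists(path)) {
    plm_abort(paste0("FASTA file not found: ", path), "plm_io_error")
  }
  organism_id <- organism_id %||%
    sub("\\.(fa|fasta|faa|fas)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  if (!nzchar(organism_id)) {
    plm_abort("`organism_id` must be non-empty.", "plm_param_error")
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) plm_abort(
      paste0("Failed to parse FASTA '", path, "': ", conditionMessage(e)),
      "plm_io_error")
  )
  if (length(seqs) == 0L) {
    plm_abort(paste0("FASTA file has no records: ", path), "plm_empty_input")
  }
  raw <- as.character(seqs)
  ids <- stringr::word(names(seqs) %||% as.character(seq_along(seqs)), 1)
  cleaned <- normalize_protein(raw)
  empty <- !nzchar(cleaned)
  if (any(empty)) {
    plm_warn(sprintf("%d empty record(s) skipped in %s: %s",
                     sum(empty), basename(path),
                     paste(head(ids[empty], 5), collapse = ", ")),
             "plm_empty_record")
  }
  tibble(
    organism_id = organism_id,
    protein_id = ids[!empty],
    sequence = unname(cleaned[!empty])
  )
}

# uppercase, strip whitespace/gaps and '*' anywhere
normalize_protein <- function(x) {
  stringi::stri_replace_all_regex(toupper(x), "[\\s.\\-*]+", "")
}

#' Read a directory of proteome FASTA files
#'
#' @param dir Directory containing one FASTA file per organism
#'   (`*.fa|*.faa|*.fasta`).
#' @return A tibble of proteins (rows from [read_proteome()] bound together).
#' @export
read_proteome_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|faa|fasta|fas)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    plm_abort(paste0("No FASTA files found under ", dir), "plm_io_error")
  }
  purrr::map_dfr(files, read_proteome)
}

#' Write proteomes to FASTA
#'
#' One file per organism, named `<organism_id>.fasta`. Round-trips through
#' [read_proteome()] unchanged.
#'
#' @param proteins Protein tibble (`organism_id`, `protein_id`, `sequence`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_proteome_fasta <- function(proteins, dir) {
  check_proteins(proteins)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(split(proteins, proteins$organism_id), function(p) {
    path <- file.path(dir, paste0(p$organism_id[1], ".fasta"))
    set <- Biostrings::BStringSet(setNames(p$sequence, p$protein_id))
    Biostrings::writeXStringSet(set, path, width = 60L)
    path
  })
  invisible(unname(paths))
}

#' Read the taxonomy/metadata table
#'
#' Tab-separated, UTF-8, with a header naming at least `organism_id`,
#' `genus`, `class` (or `taxon_class`), `phylum`. Optional columns:
#' `superkingdom`, `host_label` (values outside animal/plant map to
#' `"none"`), `branch_distance` (non-negative; distance to a designated
#' reference organism in tree units).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `organism_id`, `genus`, `taxon_class`,
#'   `phylum`, `superkingdom`, `host_label`, `branch_distance`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    plm_abort(paste0("Taxonomy file not found: ", path), "plm_io_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  names(tab)[names(tab) == "class"] <- "taxon_class"
  required <- c("organism_id", "genus", "taxon_class", "phylum")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    plm_abort(paste0("Taxonomy table is missing required column(s): ",
                     paste(missing, collapse = ", ")), "plm_schema_error")
  }
  if (anyDuplicated(tab$organism_id)) {
    dup <- unique(tab$organism_id[duplicated(tab$organism_id)])
    plm_abort(paste0("Duplicate organism_id in taxonomy: ",
                     paste(head(dup, 5), collapse = ", ")),
              "plm_validation_error")
  }
  tab <- as_tibble(tab)
  tab$superkingdom <- as.character(tab[["superkingdom"]] %||% NA_character_)
  host <- tolower(as.character(tab[["host_label"]] %||% NA_character_))
  tab$host_label <- ifelse(host %in% c("animal", "plant"), host, "none")
  bd <- suppressWarnings(as.numeric(tab[["branch_distance"]] %||% NA_real_))
  if (any(!is.na(bd) & bd < 0)) {
    plm_abort("branch_distance must be >= 0.", "plm_validation_error")
  }
  tab$branch_distance <- bd
  dplyr::select(tab, "organism_id", "genus", "taxon_class", "phylum",
                "superkingdom", "host_label", "branch_distance",
                dplyr::everything())
}

#' Write the taxonomy table
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path, progress = FALSE)
  invisible(path)
}

check_proteins <- function(proteins, arg = "proteins") {
  if (!is.data.frame(proteins) ||
      !all(c("organism_id", "sequence") %in% names(proteins))) {
    plm_abort(paste0("`", arg,
                     "` must be a data frame with columns organism_id, sequence."),
              "plm_param_error")
  }
  if (nrow(proteins) == 0L) {
    plm_abort(paste0("`", arg, "` has no proteins."), "plm_empty_input")
  }
  invisible(proteins)
}
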