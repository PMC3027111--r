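#' Count amino-acid n-grams per proteome
#'
#' Slides a window of length `n` along every protein independently: windows
#' never span protein boundaries (concatenating proteins would create
#' chimeric n-grams at the junctions), and a protein shorter than `n`
#' contributes nothing. A protein of length `L >= n` contributes `L - n + 1`
#' windows before the alphabet policy is applied. Under the default
#' `drop_ngram` policy any window containing an out-of-alphabet symbol is
#' skipped and counted in the `skipped_windows` attribute.
#'
#' @param proteins Protein tibble (`organism_id`, `sequence`), possibly
#'   covering several organisms.
#' @param n N-gram order (positive integer).
#' @param policy An [alphabet_policy()].
#'
#' @return A tibble of class `ngram_counts` with columns `organism_id`,
#'   `ngram`, `count`, ordered by organism then descending count (ties
#'   broken lexicographically). Attributes: `n`, `policy`, `totals` (named
#'   per-organism token totals), `skipped_windows` (named per-organism).
#' @export
count_ngrams <- function(proteins, n, policy = alphabet_policy()) {
  n <- check_order(n)
  check_proteins(proteins)
  seqs <- apply_noncanonical(proteins$sequence, policy)
  runs_by_org <- split(countable_runs(seqs, policy), proteins$organism_id)
  possible <- vapply(split(pmax(nchar(seqs) - n + 1L, 0L), proteins$organism_id),
                     sum, numeric(1))

  org_ids <- names(runs_by_org)
  pieces <- lapply(org_ids, function(org) {
    runs <- unlist(runs_by_org[[org]], use.names = FALSE)
    runs <- runs[nchar(runs) >= n]
    if (length(runs) == 0L) {
      return(tibble(ngram = character(), count = integer()))
    }
    grams <- unlist(lapply(runs, function(s) {
      stringi::stri_sub(s, from = seq_len(nchar(s) - n + 1L), length = n)
    }), use.names = FALSE)
    tab <- dplyr::count(tibble(ngram = grams), .data$ngram, name = "count")
    dplyr::arrange(tab, dplyr::desc(.data$count), .data$ngram)
  })
  names(pieces) <- org_ids

  totals <- vapply(pieces, function(p) sum(as.numeric(p$count)), numeric(1))
  out <- dplyr::bind_rows(lapply(org_ids, function(org) {
    tibble(organism_id = org,
           ngram = pieces[[org]]$ngram,
           count = as.integer(pieces[[org]]$count))
  }))
  new_ngram_counts(out, n = n, policy = policy, totals = totals,
                   skipped_windows = possible[org_ids] - totals)
}

new_ngram_counts <- function(tbl, n, policy, totals, skipped_windows) {
  structure(as_tibble(tbl),
            n = n, policy = policy, totals = totals,
            skipped_windows = skipped_windows,
            class = c("ngram_counts", class(as_tibble(tbl))))
}

apply_noncanonical <- function(seqs, policy) {
  if (policy$noncanonical == "map_to_nearest") {
    stringi::stri_trans_char(seqs,
                             paste(names(.noncanonical_map), collapse = ""),
                             paste(.noncanonical_map, collapse = ""))
  } else {
    seqs
  }
}

# Maximal runs of in-alphabet symbols. Skipping every window that touches an
# out-of-alphabet symbol is equivalent to counting within these runs.
countable_runs <- function(seqs, policy) {
  if (policy$noncanonical == "keep") return(as.list(seqs))
  cls <- paste0("[^", paste(policy$alphabet, collapse = ""), "]+")
  stringi::stri_split_regex(seqs, cls, omit_empty = TRUE)
}

#' @export
print.ngram_counts <- function(x, ...) {
  cat("<ngram_counts> n =", attr(x, "n"),
      "| organisms:", length(attr(x, "totals")),
      "| tokens:", format(sum(attr(x, "totals")), big.mark = ","), "\n")
  NextMethod()
}

#' Per-organism n-gram token totals
#' @param counts An `ngram_counts` object.
#' @return Named numeric vector of per-organism totals (the `N` of the
#'   entropy normalization).
#' @export
ngram_totals <- function(counts) attr(counts, "totals")

#' Convert n-gram counts to percentage frequencies
#'
#' Frequencies are percentages of each organism's n-gram token total
#' (`count / total * 100`), matching rank-frequency plots; zero-count
#' n-grams are implicitly 0 and not materialized.
#'
#' @param counts An `ngram_counts` tibble from [count_ngrams()].
#' @return A tibble of class `ngram_freqs` with the additional column
#'   `frequency_percent`; attributes carried over.
#' @export
to_frequencies <- function(counts) {
  if (!inherits(counts, "ngram_counts")) {
    plm_abort("`counts` must come from count_ngrams().", "plm_param_error")
  }
  totals <- attr(counts, "totals")
  if (any(totals <= 0)) {
    bad <- names(totals)[totals <= 0]
    plm_abort(paste0("Zero n-gram total for organism(s): ",
                     paste(bad, collapse = ", ")), "plm_degenerate_input")
  }
  out <- dplyr::mutate(counts,
                       frequency_percent = .data$count / unname(totals[.data$organism_id]) * 100)
  structure(out, n = attr(counts, "n"), policy = attr(counts, "policy"),
            totals = totals, skipped_windows = attr(counts, "skipped_windows"),
            class = c("ngram_freqs", "ngram_counts", class(as_tibble(out))))
}

#' Write an n-gram count table to TSV
#'
#' One file per organism per order: columns `ngram`, `count`,
#' `frequency_percent`, ordered by descending count then lexicographically.
#'
#' @param counts An `ngram_counts` or `ngram_freqs` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_ngram_counts <- function(counts, dir) {
  if (!inherits(counts, "ngram_freqs")) counts <- to_frequencies(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- attr(counts, "n")
  paths <- purrr::map_chr(split(counts, counts$organism_id), function(tab) {
    path <- file.path(dir, sprintf("%s_%dgram.tsv", tab$organism_id[1], n))
    readr::write_tsv(dplyr::select(tab, "ngram", "count", "frequency_percent"),
                     path, progress = FALSE)
    path
  })
  invisible(unname(paths))
}
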